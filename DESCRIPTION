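Package: polyphasic
Title: Polyphasic Delineation of Prokaryotic Taxa from Genomic and
    Chemotaxonomic Data
Version: 0.1.0
Authors@R: person("PD Lab", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for genome-based and chemotaxonomic
    delineation of bacterial species and genera. Computes fragment-based
    average nucleotide identity (ANI), reciprocal-best-hit average amino
    acid identity (AAI) and an ANI-derived in silico DNA-DNA hybridization
    (DDH) estimate; selects universal single-copy marker proteins and
    builds concatenated alignments; reconstructs distance trees (UPGMA,
    neighbor joining, minimum evolution with close-neighbor-interchange
    search) with nonparametric bootstrap support; applies standard
    ANI/DDH/AAI thresholds to call novel species and genus candidates; and
    provides chemotaxonomic numerics (respiratory quinone molar-ratio
    profiles and their Pearson correlation, fatty acid methyl ester
    similarity, API phenotype matching, HPLC calibration curves with
    LOD/LOQ). Seeded simulators generate genome pairs, protein families
    and composition profiles with known truth so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
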