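---
title: "Methods: models, thresholds and design choices in polyphasic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in polyphasic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyphasic)
```

`polyphasic` turns the standard polyphasic workflow for delineating
bacterial species and genera — identity statistics, marker
phylogenomics, chemotaxonomic profiles — into one tested pipeline. This
vignette documents the models and their assumptions, the parameters
that matter, what the simulators do and do not emulate, the numerical
choices, and the places where the design was genuinely open.

## Identity statistics

### Fragment ANI

`fragment_ani()` follows the classic fragment-based definition: the
query is cut into consecutive fragments of `fragment_length` (default
1020 bp; a trailing piece is kept when it is at least half a fragment),
each fragment is located in the subject by exact `seed_kmer`-mer
matching on both strands (the most-voted diagonal wins), and extended by
a gapped local alignment inside a band of `band_fraction` × fragment
length (default 0.2) around that diagonal. A fragment is *conserved*
when its identity is at least `min_fragment_identity` (30%) over at
least `min_fragment_coverage` (70%) of its length; ANI is the mean
identity of conserved fragments. When nothing passes, the result is
flagged undefined and reported as 0 rather than silently dropped —
endosymbiont-against-free-living comparisons legitimately produce this.

Assumptions: seeding requires at least one exact shared k-mer per
conserved fragment (virtually certain at ANI ≥ 75% with k = 15 and
1020 bp fragments); the band bounds indel drift within a fragment, so
alignments with very dense indels would need a wider band. Because the
extension is a local alignment, a fragment's low-identity extremities
can be trimmed, which biases ANI upward by a small amount (measured
below +0.2 points at the 80% identity level on 100 kb simulations) —
well inside the ±0.5 acceptance band, and documented rather than
corrected.

Both directions of each pair are computed; `build_matrix()` stores the
mean and records the directional asymmetry, because a published matrix
prints a single number per pair and hiding asymmetry would discard the
only diagnostic of structural difference (large indel load, plasmid
presence) between the two genomes.

### RBH AAI

`rbh_aai()` scores all protein pairs by local alignment (BLOSUM62, gap
open 11, extend 1), takes mutual best hits, filters them at
`min_identity` (30%) and `min_coverage` (70% of the shorter protein),
and averages identity. No pair passing yields a *missing* AAI, never 0.
Reciprocal best hits are one-to-one, so a duplicated in-paralog cannot
create a second ortholog pair — the pair count is invariant to
duplications, which is the property marker selection relies on.

### DDH estimate

The in silico DDH surrogate is the explicit monotone map
`DDH = 100·(ANI/100)^k` with `k = ln 0.7 / ln 0.95 ≈ 6.95`, chosen so
that the two conventional species cutoffs coincide (ANI 95% maps to DDH
70%) and the identity boundary is exact (`DDH(100) = 100`). It is an
estimate for threshold decisions, always flagged as estimated in the
evidence strings; reproducing any particular genome-distance
regression's numeric output is a non-goal.

## Markers and alignments

`cluster_orthologs()` builds families as connected components of the
cross-strain RBH graph, then attaches still-unassigned proteins
(in-paralogs, which RBH's one-to-one matching leaves out) to the family
of their best passing one-directional hit, so a duplicated family is
flagged multi-copy instead of splitting. `select_markers()` keeps
families that are universal (present in all strains), single-copy, and
carry all required tags — the tag route abstracts pathway annotation
(e.g. `"shikimate"` selects the five-enzyme AroBEKAC-style set in the
packaged fixture) without live database calls. The selection implements
the stated criteria only; no ranking score among qualifying families is
attempted, because no defensible ordering is defined by the criteria
themselves.

`progressive_align()` is a self-contained progressive aligner: guide
tree by UPGMA on p-distances of pairwise global alignments
(lexicographic tie-breaks make it deterministic), then profile–profile
merges with sum-of-pairs column scores and affine gaps (open 10, extend
0.5; a gap of length *g* costs `open + g·extend`). One simplification
is standard and documented: gap states chain only from the match state
(no X→Y transitions), which can miss marginal double-gap optima. The
aligner is intended for single-copy marker families at moderate
divergence — reproducing any specific aligner's output
column-for-column is a non-goal.

Distance computation removes every column containing a gap (complete
deletion) before anything else, matching the fixed "final dataset"
position counts that concatenated-marker phylogenies report;
`concatenate_markers()` keeps per-marker partitions and per-strain
ungapped residue counts for exactly that bookkeeping.

## Distances and trees

For aligned residues, `pairwise_distance()` offers p-distance, the
Poisson correction `−ln(1−p)` (error on saturation, p ≥ 1), the Kimura
two-parameter distance for nucleotides, and pairwise maximum likelihood
under the empirical JTT or Dayhoff amino-acid models. The ML distance
maximizes `Σ N_ij log(π_i P_ij(t))` over the observed residue-pair
counts by one-dimensional numerical optimization; `P(t)` comes from the
eigendecomposition of the normalized rate matrix `Q_ij = S_ij π_j`. The
exchangeabilities and frequencies are read at run time from the model
tables shipped with phangorn — the same published tables every ML
program embeds — while the optimizer and matrix algebra are package
code; the test suite cross-checks against `phangorn::dist.ml` as an
independent oracle. "Matrix-based distance" could also mean a
gamma-corrected or ME-specific shortcut; pairwise ML is the defensible
interpretation, and the tests are tolerance-based accordingly.

`upgma()` and `neighbor_joining()` are textbook implementations with
two documented conventions: merge/join ties break by the
lexicographically smallest label pair, and negative NJ terminal lengths
are clamped to zero with the deficit moved to the sister branch so that
reported trees satisfy the non-negative branch-length invariant (the
raw values remain in the objective).

`minimum_evolution()` interprets close-neighbor-interchange at search
level 1 as the nearest-neighbor-interchange neighborhood: starting from
the NJ tree, it evaluates every NNI neighbor's OLS total branch length
(`me_tree_length()`, ordinary least squares on the path-indicator
system; negative fitted lengths stay in the objective and are flagged)
and descends while the objective improves, breaking ties by a canonical
topology key. Whether the original ME implementations used OLS or
balanced minimum evolution for branch lengths is not stated where this
pipeline's conventions come from; OLS was chosen, flagged, and verified
against `exhaustive_minimum_evolution()` — enumeration of all unrooted
topologies — on every 5–6 taxon test instance. Wider neighborhoods are
a `max_iter`/configuration matter, not a different algorithm.

`bootstrap_support()` resamples alignment columns with replacement
(seeded), rebuilds the tree per replicate, and reports for each internal
edge of the point tree the percentage of replicates containing the same
bipartition; support is stored as internal node labels, the common
Newick dialect. Replicates whose distance matrix is undefined (e.g. a
saturated Poisson pair) are dropped and counted in `n_effective`.

## Delineation

`delineation_policy()` carries the conventional cutoffs: species at
ANI ≥ 95 or DDH ≥ 70 (boundary inclusive — a pair exactly at the cutoff
is called same-species), verification at 96/90, genus clustering at AAI
> 80 (strictly above), and a 68% tree-scale parameter.

`threshold_clusters()` has two clearly separated modes: recomputation
(edges where similarity is strictly above the threshold) and an
explicit edge list. The second exists because printed matrices are
integer-rounded: in the packaged fixture the focal strain's 81 against
its nearest neighbor exceeds 80, yet the published box reading keeps it
outside every box — whether by pre-rounding values or by tree evidence
is unknowable from the table. The package does not guess: the box
reading is data (`bold_pairs`), recomputation is a different call.

`genus_call()` requires two independent signals and refuses to merge
them: the strain must be a clustering singleton *and* form its own
branch in the tree. The default tree rule is strain-centric nestedness:
the strain fails the tree test if some bipartition groups it with a
nonempty proper subset of one multi-member cluster (i.e. the tree pulls
it inside a genus), while sitting sister to a complete cluster clade
still counts as an own branch. This was a genuinely open design point —
requiring every cluster to be monophyletic is too strict, since
published clusters are routinely non-monophyletic in a recomputed NJ
tree without that bearing on the focal strain at all. The 68% value
cannot act as a pairwise AAI threshold on the packaged matrix (all
printed values exceed it), so it is kept as a configurable path-distance
cutoff used only in the optional `tree_rule = "distance"` mode. When
cluster and tree evidence disagree the verdict is `"ambiguous"` with
both facts reported — never silently resolved.

## Chemotaxonomy

Molar ratios normalize over *detected* components only; not-determined
(ND) cells stay ND, never zero — a strain with one detected quinone is
100% that quinone, and any ND inside a correlation pairing makes the
correlation ND. Profile correlations use the six printed
condition × quinone *means* in fixed order (aerobic Q8, DMK8, MK8, then
anaerobic), not replicate-level values; the suite's flagship regression
test verifies that this choice reproduces all six packaged reference
coefficients to three decimal places, and the standard deviations are
carried for display only. FAME similarity treats a component missing
from one profile as 0% (absent, not undetermined) — the alternative ND
reading would discard most comparisons between strains profiled with
different panels. The API similarity index is not defined by the
published sources that report one; the simple matching coefficient over
comparable positions (excluding V and ND) is the documented default,
with Jaccard as an option. Calibration is OLS with
`LOD = 3σ_noise/slope` and `LOQ = 10σ_noise/slope`; inversion divides
by one explicit dimensionless `concentration_factor` instead of
hard-coding extraction volumes, flags extrapolation outside the linear
range, and reports sub-LOD values as `"<LOD"` rather than a number.

## Simulators: what a green test establishes

`evolve_genome()` plants substitutions (always to a different base, so
true identity equals one minus the realized substitution fraction),
geometric-length indels, and 1 kb-block gene loss, and returns the true
gapped alignment — identity oracles are exact, not estimated.
`simulate_families()` evolves single-copy families along a known tree
under the empirical models with optional planted absences and
duplications; `simulate_profiles()` draws gamma-noise compositions
around archetype means with optional ND masking. One global seed fans
out to per-generator child seeds via a fixed string hash
(`child_seed()`), so adding a generator never shifts existing fixtures.

These simulators deliberately do *not* emulate genome architecture
(operons, codon bias, GC skew structure, repeats), rate heterogeneity
across sites, horizontal transfer, or correlated replicate noise. A
green parameter-recovery test therefore establishes that the estimators
are unbiased under the stated generative model at the stated sizes — it
does not certify accuracy on real genomes with repeat-induced ambiguous
fragment placement, nor tree correctness under among-site rate
variation.

## Numerical choices

* Percent values keep full precision internally; integer rounding
  (half-up, `floor(x + 0.5)`) happens only in `report_table1()`.
* Additive-matrix recovery by NJ is tested at 1e-9; OLS systems are
  solved by QR with an explicit singularity error.
* ML distance optimization runs on `[1e-8, 15]` substitutions per site;
  hitting the upper end is reported as non-convergence (saturation).
* All stochastic operations take explicit integer seeds; derived seeds
  stay below 2^31.
* Config hashing uses a self-contained 32-bit FNV-1a implemented with
  split 16-bit arithmetic (R doubles cannot hold the 56-bit
  intermediate product).

## Known limitations

Fragment placement uses a single best diagonal per fragment, so a
fragment spanning a large rearrangement breakpoint aligns on one side
only. The progressive aligner has no iterative refinement. Bootstrap on
`builder = "me"` is quadratic-times-NNI per replicate and slow beyond
small marker sets. The DDH map is a calibrated approximation, suitable
for threshold calls, not for reporting as a measured DDH. YAML configs
require the suggested yaml package; JSON is the guaranteed path.
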