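# Accessors for the packaged plain-text fixtures: the published
# ANI/AAI matrix with its bold-box cluster reading, the quinone
# molar-ratio table with its printed correlation column, the API
# phenotype table, and a synthetic five-marker alignment set.

pkg_extdata <- function(...) {
  p <- system.file("extdata", ..., package = "polyphasic")
  if (!nzchar(p)) stop("fixture not found: ", file.path(...))
  p
}

#' Packaged ANI/AAI matrix fixture
#'
#' The published 15-strain combined matrix (ANI below the diagonal, AAI
#' above) together with the bold-box pair list encoding the printed
#' cluster reading. Values are integer-rounded as printed.
#'
#' @return list with `ani` and `aai` ([similarity_matrix()] objects,
#'   symmetric), `combined` (the printed lower/upper matrix), and
#'   `bold_pairs` (data frame `a`, `b`).
#' @export
erwiniaceae_matrices <- function() {
  df <- utils::read.delim(pkg_extdata("erwiniaceae_ani_aai.tsv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  lab <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(lab, lab)
  ani <- aai <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  low <- row(m) > col(m)
  up <- row(m) < col(m)
  ani[low] <- m[low]; ani[up] <- t(m)[up]; diag(ani) <- 100
  aai[up] <- m[up];   aai[low] <- t(m)[low]; diag(aai) <- 100
  bold <- utils::read.delim(pkg_extdata("erwiniaceae_bold_pairs.tsv"),
                            stringsAsFactors = FALSE)
  list(ani = similarity_matrix(ani, lab, "ANI"),
       aai = similarity_matrix(aai, lab, "AAI"),
       combined = m, bold_pairs = bold)
}

#' Packaged respiratory-quinone molar-ratio fixture
#'
#' Per-strain Q8/DMK8/MK8 molar ratios (mean and sd) under aerobic and
#' anaerobic growth, plus the printed Pearson correlation of every
#' reference strain against the focal strain PD-1.
#'
#' @return list with `profiles` (named list of [chem_profile()]),
#'   `pairing` (the six condition x quinone cells in printed order) and
#'   `reference_r` (data frame `strain`, `r`; `NA` where printed ND).
#' @export
quinone_fixture <- function() {
  profiles <- read_profile_tsv(pkg_extdata("quinone_profiles.tsv"))
  ref <- utils::read.delim(pkg_extdata("quinone_reference_r.tsv"),
                           stringsAsFactors = FALSE)
  ref$r <- suppressWarnings(as.numeric(ref$r))
  pairing <- c("aerobic.Q8", "aerobic.DMK8", "aerobic.MK8",
               "anaerobic.Q8", "anaerobic.DMK8", "anaerobic.MK8")
  list(profiles = profiles, pairing = pairing, reference_r = ref)
}

#' Packaged API phenotype fixture
#'
#' Binary biochemical test results (`+`, `-`, `V`, `ND`) of the focal
#' strain (24 h and 48 h readings) and four reference strains.
#'
#' @return data frame, tests in rows, strains in columns.
#' @export
api_fixture <- function() {
  utils::read.delim(pkg_extdata("api_phenotypes.tsv"), check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Packaged synthetic five-marker alignment fixture
#'
#' Five aligned marker FASTA files (shikimate-pathway enzyme analogs,
#' simulated sequences labelled synthetic) over eight strains whose
#' concatenation spans 1587 columns.
#'
#' @return named list of alignment matrices.
#' @export
marker_alignment_fixture <- function() {
  markers <- c("aroB", "aroE", "aroK", "aroA", "aroC")
  out <- lapply(markers, function(m)
    read_alignment(pkg_extdata("markers", paste0(m, "_synthetic.fasta"))))
  names(out) <- markers
  out
}

#' Packaged synthetic ortholog-table fixture
#'
#' Eight strains with five shikimate-tagged universal single-copy
#' families plus three decoy families (one missing in a strain, one
#' duplicated in a strain, one universal but untagged).
#'
#' @return an `ortholog_table`.
#' @export
ortholog_fixture <- function() {
  read_ortholog_tsv(pkg_extdata("ortholog_fixture.tsv"))
}
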