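#' Pairwise evolutionary distances from an alignment
#'
#' Distances in substitutions per site under one of:
#' * `p` — raw proportion of mismatching sites;
#' * `poisson` — Poisson correction `-ln(1 - p)`;
#' * `jtt`, `dayhoff` — pairwise maximum likelihood under the empirical
#'   amino-acid model (numerical 1-D optimization, see [aa_ml_distance()]);
#' * `kimura-nt` — Kimura two-parameter distance for nucleotides.
#'
#' Columns containing a gap in any row are removed first (complete
#' deletion); ambiguous residues (`X`, `N`) are excluded pair by pair.
#'
#' @param aln character matrix (rows = strains) or named character vector
#'   of equal-length gapped strings.
#' @param model model name.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance <- function(aln,
                              model = c("p", "poisson", "jtt", "dayhoff",
                                        "kimura-nt")) {
  model <- match.arg(model)
  if (!is.matrix(aln)) aln <- aln_matrix(unlist(aln))
  if (nrow(aln) < 2L) stop("need at least 2 sequences")
  if (is.null(rownames(aln))) rownames(aln) <- paste0("s", seq_len(nrow(aln)))
  keep <- colSums(aln == "-" | aln == ".") == 0L
  aln <- aln[, keep, drop = FALSE]
  if (ncol(aln) == 0L) stop("no gap-free columns left after complete deletion")
  n <- nrow(aln)
  labs <- rownames(aln)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  mod <- if (model %in% c("jtt", "dayhoff")) aa_model(model) else NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    x <- aln[i, ]; y <- aln[j, ]
    d[i, j] <- d[j, i] <- switch(
      model,
      "p" = p_distance(x, y),
      "poisson" = {
        p <- p_distance(x, y)
        if (p >= 1) stop("saturated distance (p >= 1) for pair (",
                         labs[i], ", ", labs[j], ")")
        -log(1 - p)
      },
      "jtt" = ,
      "dayhoff" = tryCatch(aa_ml_distance(x, y, mod),
                           error = function(e) stop(
                             "pair (", labs[i], ", ", labs[j], "): ",
                             conditionMessage(e))),
      "kimura-nt" = k2p_distance(x, y, labs[i], labs[j]))
  }
  d
}

p_distance <- function(x, y) {
  keep <- !(x %in% c("X", "N", "?")) & !(y %in% c("X", "N", "?"))
  if (!any(keep)) stop("no comparable sites")
  mean(x[keep] != y[keep])
}

k2p_distance <- function(x, y, li, lj) {
  keep <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("no comparable sites")
  x <- x[keep]; y <- y[keep]
  pur <- c("A", "G")
  ts <- mean(x != y & (x %in% pur) == (y %in% pur))   # transitions
  tv <- mean((x %in% pur) != (y %in% pur))            # transversions
  w1 <- 1 - 2 * ts - tv
  w2 <- 1 - 2 * tv
  if (w1 <= 0 || w2 <= 0)
    stop("saturated K2P distance for pair (", li, ", ", lj, ")")
  -0.5 * log(w1) - 0.25 * log(w2)
}
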