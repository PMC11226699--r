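#' Parameters for fragment-based ANI
#'
#' Defaults follow the classic fragment-ANI definition: the query genome is
#' cut into consecutive 1020 bp fragments and a fragment counts as
#' conserved when its best local match in the subject reaches at least 30%
#' identity over at least 70% of the fragment.
#'
#' @param fragment_length fragment size in bp.
#' @param min_fragment_identity percent identity a fragment must reach.
#' @param min_fragment_coverage percent of the fragment that must align.
#' @param seed_kmer exact k-mer length used for seeding.
#' @param band_fraction half-width of the banded extension window as a
#'   fraction of `fragment_length`.
#' @return an `ani_params` list.
#' @export
ani_params <- function(fragment_length = 1020L, min_fragment_identity = 30,
                       min_fragment_coverage = 70, seed_kmer = 15L,
                       band_fraction = 0.2) {
  stopifnot(fragment_length >= seed_kmer,
            min_fragment_identity > 0, min_fragment_identity <= 100,
            min_fragment_coverage > 0, min_fragment_coverage <= 100)
  structure(list(fragment_length = as.integer(fragment_length),
                 min_fragment_identity = min_fragment_identity,
                 min_fragment_coverage = min_fragment_coverage,
                 seed_kmer = as.integer(seed_kmer),
                 band_fraction = band_fraction),
            class = "ani_params")
}

#' Parameters for reciprocal-best-hit AAI
#'
#' @param min_identity minimum percent identity of an ortholog pair.
#' @param min_coverage minimum percent of the shorter protein aligned.
#' @param substitution_matrix amino-acid scoring matrix name.
#' @param gap_open,gap_extend affine gap penalties (positive numbers).
#' @return an `aai_params` list.
#' @export
aai_params <- function(min_identity = 30, min_coverage = 70,
                       substitution_matrix = "BLOSUM62",
                       gap_open = 11, gap_extend = 1) {
  stopifnot(min_identity > 0, min_identity <= 100,
            min_coverage > 0, min_coverage <= 100)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "aai_params")
}

# all k-mers of a string (may be large; vectorized substring)
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

# cut replicons into consecutive fragments; trailing piece kept when it is
# at least half a fragment long (documented choice)
cut_fragments <- function(genome, L) {
  out <- character(0)
  for (s in genome$replicons) {
    n <- nchar(s)
    starts <- seq(1L, max(n - L + 1L, 1L), by = L)
    ends <- pmin(starts + L - 1L, n)
    keep <- (ends - starts + 1L) >= max(L %/% 2L, 1L)
    if (n < L) keep <- TRUE   # single-fragment fallback handled by caller
    out <- c(out, substring(s, starts[keep], ends[keep]))
  }
  out
}

#' Fragment-based average nucleotide identity
#'
#' Cuts the query genome into consecutive fragments, finds each fragment's
#' best match in the subject by exact k-mer seeding on both strands,
#' extends with a banded gapped local alignment, and averages percent
#' identity over the fragments passing the identity and coverage filters.
#'
#' @param query,subject [genome_record()] objects.
#' @param params an [ani_params()] object.
#' @return list with `ani` (percent; 0 with `defined = FALSE` when no
#'   fragment is conserved), `n_conserved_fragments`, `n_fragments`,
#'   `defined`, and the per-fragment `identity`/`coverage` vectors.
#' @export
fragment_ani <- function(query, subject, params = ani_params()) {
  stopifnot(inherits(query, "genome_record"), inherits(subject, "genome_record"))
  L <- params$fragment_length
  k <- params$seed_kmer
  band <- ceiling(params$band_fraction * L)
  if (genome_length(query) < L)
    warning("query genome shorter than one fragment; using single-fragment fallback")
  frags <- cut_fragments(query, L)

  # subject index: forward and reverse-complement concatenations
  subj_fwd <- paste(subject$replicons, collapse = strrep("N", 50L))
  subj_rc <- revcomp(subj_fwd)
  kmers_fwd <- seq_kmers(subj_fwd, k)
  kmers_rc <- seq_kmers(subj_rc, k)

  stride <- 4L
  qk <- lapply(frags, function(f) {
    pos <- seq(1L, max(nchar(f) - k + 1L, 1L), by = stride)
    pos <- pos[pos + k - 1L <= nchar(f)]
    list(pos = pos, kmer = substring(f, pos, pos + k - 1L))
  })
  allk <- unlist(lapply(qk, `[[`, "kmer"))
  grp <- rep(seq_along(qk), vapply(qk, function(x) length(x$pos), integer(1)))
  hit_f <- match(allk, kmers_fwd)
  hit_r <- match(allk, kmers_rc)

  identity <- numeric(length(frags))
  coverage <- numeric(length(frags))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = FALSE)
  for (i in seq_along(frags)) {
    sel <- grp == i
    qpos <- qk[[i]]$pos
    best <- best_diagonal(qpos, hit_f[sel], hit_r[sel])
    if (is.null(best)) next
    subj_seq <- if (best$strand == "+") subj_fwd else subj_rc
    lo <- max(1L, best$diag + 1L - band)
    hi <- min(nchar(subj_seq), best$diag + nchar(frags[i]) + band)
    win <- substr(subj_seq, lo, hi)
    aln <- Biostrings::pairwiseAlignment(
      pattern = frags[i], subject = win, type = "local",
      substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    identity[i] <- Biostrings::pid(aln, type = "PID1")
    pr <- aln@pattern@range
    coverage[i] <- 100 * BiocGenerics::width(pr) / nchar(frags[i])
  }
  conserved <- identity >= params$min_fragment_identity &
               coverage >= params$min_fragment_coverage
  defined <- any(conserved)
  list(ani = if (defined) mean(identity[conserved]) else 0,
       n_conserved_fragments = sum(conserved),
       n_fragments = length(frags),
       defined = defined, identity = identity, coverage = coverage)
}

# most-voted diagonal among forward/reverse seed hits; NULL when no seed
best_diagonal <- function(qpos, hit_f, hit_r) {
  vote <- function(hits) {
    ok <- !is.na(hits)
    if (!any(ok)) return(NULL)
    d <- hits[ok] - qpos[ok]
    tb <- table(d)
    list(diag = as.integer(names(tb)[which.max(tb)]), n = max(tb),
         total = sum(ok))
  }
  vf <- vote(hit_f); vr <- vote(hit_r)
  if (is.null(vf) && is.null(vr)) return(NULL)
  if (is.null(vr) || (!is.null(vf) && vf$total >= vr$total))
    c(vf, strand = "+") else c(vr, strand = "-")
}

#' Reciprocal-best-hit average amino acid identity
#'
#' All-vs-all local protein alignment; mutual best-scoring pairs passing
#' the identity and coverage filters define orthologs; AAI is the mean
#' percent identity over those pairs. When no pair passes, the AAI is
#' reported as missing (`NA`), never as 0.
#'
#' @param a,b [protein_set()] objects.
#' @param params an [aai_params()] object.
#' @return list with `aai`, `n_orthologs` and a data frame `pairs`
#'   (`id_a`, `id_b`, `identity`, `coverage`).
#' @export
rbh_aai <- function(a, b, params = aai_params()) {
  stopifnot(inherits(a, "protein_set"), inherits(b, "protein_set"))
  pa <- Biostrings::AAStringSet(a$proteins)
  pb <- Biostrings::AAStringSet(b$proteins)
  na_ <- length(pa); nb <- length(pb)
  sc <- id <- cov <- matrix(0, na_, nb)
  for (j in seq_len(nb)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = pa, subject = pb[[j]], type = "local",
      substitutionMatrix = params$substitution_matrix,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    sc[, j] <- BiocGenerics::score(aln)
    id[, j] <- Biostrings::pid(aln, type = "PID1")
    wp <- BiocGenerics::width(aln@pattern@range)
    shorter <- pmin(nchar(a$proteins), nchar(b$proteins[j]))
    cov[, j] <- 100 * wp / shorter
  }
  best_ab <- apply(sc, 1L, which.max)       # ties -> first index
  best_ba <- apply(sc, 2L, which.max)
  i <- seq_len(na_)
  mutual <- best_ba[best_ab] == i
  pass <- mutual & id[cbind(i, best_ab)] >= params$min_identity &
          cov[cbind(i, best_ab)] >= params$min_coverage
  pairs <- data.frame(id_a = names(a$proteins)[i][pass],
                      id_b = names(b$proteins)[best_ab][pass],
                      identity = id[cbind(i, best_ab)][pass],
                      coverage = cov[cbind(i, best_ab)][pass],
                      stringsAsFactors = FALSE)
  j <- seq_len(nb)
  best_tab <- function(from, to, idx, idm, covm) {
    data.frame(id_from = from, id_to = to[idx],
               identity = idm, coverage = covm,
               pass = idm >= params$min_identity &
                 covm >= params$min_coverage,
               stringsAsFactors = FALSE)
  }
  list(aai = if (nrow(pairs)) mean(pairs$identity) else NA_real_,
       n_orthologs = nrow(pairs), pairs = pairs,
       best_ab = best_tab(names(a$proteins), names(b$proteins), best_ab,
                          id[cbind(i, best_ab)], cov[cbind(i, best_ab)]),
       best_ba = best_tab(names(b$proteins), names(a$proteins), best_ba,
                          id[cbind(best_ba, j)], cov[cbind(best_ba, j)]))
}

#' Pairwise 16S rRNA gene identity
#'
#' Global alignment identity computed as matches over alignment columns,
#' excluding terminal gap columns (so a shorter partial sequence is not
#' penalized for missing ends).
#'
#' @param a,b nucleotide strings, each at least 500 bp.
#' @return percent identity.
#' @export
pairwise_16s_identity <- function(a, b) {
  stopifnot(nchar(a) >= 500, nchar(b) >= 500)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(toupper(a), toupper(b),
                                       type = "global",
                                       substitutionMatrix = submat,
                                       gapOpening = 4, gapExtension = 1)
  x <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  y <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gapx <- x == "-"; gapy <- y == "-"
  term <- function(g) {
    lead <- cumsum(!g) == 0
    trail <- rev(cumsum(rev(!g)) == 0)
    lead | trail
  }
  keep <- !(term(gapx) | term(gapy))
  100 * sum(x[keep] == y[keep]) / sum(keep)
}

#' In silico DDH estimate from ANI
#'
#' Explicit monotone approximation `DDH = 100 * (ANI/100)^k` with
#' `k = log(0.7)/log(0.95)`, calibrated so the conventional paired species
#' cutoffs coincide (95% ANI maps to 70% DDH) and `DDH(100) = 100`
#' exactly. This is an estimate, not a reproduction of any specific
#' genome-to-genome distance regression.
#'
#' @param ani percent ANI in `[0, 100]` (vectorized).
#' @return estimated percent DDH.
#' @export
ddh_estimate <- function(ani) {
  stopifnot(all(ani >= 0 & ani <= 100))
  k <- log(0.7) / log(0.95)
  100 * (ani / 100)^k
}

#' Build a similarity matrix from pairwise comparisons
#'
#' Computes each unordered pair once in each direction, stores the mean of
#' the two directional values and records the maximum directional
#' asymmetry. The diagonal is set to 100 without computation.
#'
#' @param items list of [genome_record()] or [protein_set()] objects.
#' @param fn pairwise function `fn(a, b, ...)` returning a percent value
#'   (or a list whose `ani`/`aai` element is the percent value).
#' @param kind matrix kind label.
#' @param symmetric if `TRUE`, `fn` is assumed symmetric and evaluated
#'   once per pair.
#' @param ... passed on to `fn`.
#' @return a [similarity_matrix()] with an `asymmetry` attribute.
#' @export
build_matrix <- function(items, fn, kind = "custom", symmetric = FALSE, ...) {
  stopifnot(length(items) >= 2L)
  labels <- vapply(items, function(x) x$id, character(1))
  if (anyDuplicated(labels)) stop("duplicate strain ids")
  n <- length(items)
  v <- matrix(100, n, n, dimnames = list(labels, labels))
  asym <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ij <- tryCatch(extract_percent(fn(items[[i]], items[[j]], ...)),
                   error = function(e) stop("pair (", labels[i], ", ",
                                            labels[j], "): ",
                                            conditionMessage(e)))
    ji <- if (symmetric) ij else
      extract_percent(fn(items[[j]], items[[i]], ...))
    v[i, j] <- v[j, i] <- (ij + ji) / 2
    asym[i, j] <- asym[j, i] <- abs(ij - ji)
  }
  similarity_matrix(v, labels, kind = kind, asymmetry = asym)
}

extract_percent <- function(res) {
  if (is.numeric(res)) return(res[[1]])
  for (nm in c("ani", "aai", "percent", "identity"))
    if (!is.null(res[[nm]])) return(res[[nm]])
  as.numeric(res[[1]])
}
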