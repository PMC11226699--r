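# Universal single-copy marker selection and concatenated alignments.

#' Cluster proteins into ortholog families across strains
#'
#' Families are the connected components of the cross-strain
#' reciprocal-best-hit graph built from [rbh_aai()] pairs over every
#' strain pair. Per-strain copy numbers and per-family annotation tags
#' (the union of member protein tags) are recorded.
#'
#' @param proteomes list of at least three [protein_set()] objects.
#' @param params an [aai_params()] object.
#' @return an `ortholog_table`: list with `families` (family id ->
#'   data frame of `strain`, `protein`), `tags`, `copy_number` (family x
#'   strain matrix), `strains`.
#' @export
cluster_orthologs <- function(proteomes, params = aai_params()) {
  stopifnot(length(proteomes) >= 3L)
  strains <- vapply(proteomes, `[[`, character(1), "id")
  if (anyDuplicated(strains)) stop("duplicate strain ids")
  node <- function(s, p) paste0(s, "::", p)
  nodes <- unlist(lapply(proteomes, function(ps)
    node(ps$id, names(ps$proteins))))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  best <- list()
  for (i in seq_len(length(proteomes) - 1L))
    for (j in (i + 1L):length(proteomes)) {
      res <- rbh_aai(proteomes[[i]], proteomes[[j]], params)
      prs <- res$pairs
      ab <- res$best_ab; ab$s_from <- strains[i]; ab$s_to <- strains[j]
      ba <- res$best_ba; ba$s_from <- strains[j]; ba$s_to <- strains[i]
      rownames(ab) <- rownames(ba) <- NULL
      best[[length(best) + 1L]] <- ab
      best[[length(best) + 1L]] <- ba
      if (!nrow(prs)) next
      a <- match(node(strains[i], prs$id_a), nodes)
      b <- match(node(strains[j], prs$id_b), nodes)
      for (k in seq_along(a)) {
        ra <- find(a[k]); rb <- find(b[k])
        if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
      }
    }
  # reciprocal best hits are one-to-one, so in-paralogs (extra copies)
  # end up unassigned: attach each singleton to its best passing hit's
  # family so duplicated families are flagged multi-copy, not split
  comp <- vapply(seq_along(nodes), find, integer(1))
  size <- table(comp)
  for (tb in best) for (k in seq_len(nrow(tb))) {
    if (!tb$pass[k]) next
    u <- match(node(tb$s_from[k], tb$id_from[k]), nodes)
    if (size[[as.character(comp[u])]] > 1L) next
    v <- match(node(tb$s_to[k], tb$id_to[k]), nodes)
    ru <- find(u); rv <- find(v)
    if (ru != rv) parent[[max(ru, rv)]] <- min(ru, rv)
  }
  comp <- vapply(seq_along(nodes), find, integer(1))
  groups <- split(nodes, comp)
  groups <- groups[order(vapply(groups, min, character(1)))]
  fid <- sprintf("F%04d", seq_along(groups))
  tag_of <- function(s, p) {
    ps <- proteomes[[match(s, strains)]]
    ps$tags[[p]]
  }
  families <- tags <- vector("list", length(groups))
  names(families) <- names(tags) <- fid
  cn <- matrix(0L, length(groups), length(strains),
               dimnames = list(fid, strains))
  for (g in seq_along(groups)) {
    parts <- strsplit(groups[[g]], "::", fixed = TRUE)
    df <- data.frame(strain = vapply(parts, `[`, character(1), 1L),
                     protein = vapply(parts, `[`, character(1), 2L),
                     stringsAsFactors = FALSE)
    families[[g]] <- df[order(df$strain, df$protein), ]
    tb <- table(factor(df$strain, strains))
    cn[g, ] <- as.integer(tb)
    tags[[g]] <- sort(unique(unlist(Map(tag_of, df$strain, df$protein))))
  }
  structure(list(families = families, tags = tags, copy_number = cn,
                 strains = strains),
            class = "ortholog_table")
}

#' @export
print.ortholog_table <- function(x, ...) {
  cat("<ortholog_table> ", length(x$families), " families across ",
      length(x$strains), " strains\n", sep = "")
  invisible(x)
}

#' Select marker families
#'
#' Returns the families present in every strain (`universal`), in exactly
#' one copy per strain (`single_copy`), and carrying all `required_tags`
#' (a pathway tag such as `"shikimate"` selects the five-enzyme
#' AroB/AroE/AroK/AroA/AroC set in the packaged fixture).
#'
#' @param table an `ortholog_table` from [cluster_orthologs()] or
#'   [read_ortholog_tsv()].
#' @param required_tags character vector of tags a family must carry.
#' @param universal require presence in all strains.
#' @param single_copy require exactly one copy per strain.
#' @return character vector of family ids (possibly empty, with a
#'   warning stating that no markers satisfy the criteria).
#' @export
select_markers <- function(table, required_tags = character(),
                           universal = TRUE, single_copy = TRUE) {
  stopifnot(inherits(table, "ortholog_table"), length(table$families) > 0L)
  cn <- table$copy_number
  ok <- rep(TRUE, nrow(cn))
  if (universal) ok <- ok & apply(cn >= 1L, 1L, all)
  if (single_copy) ok <- ok & apply(cn <= 1L, 1L, all)
  for (tg in required_tags)
    ok <- ok & vapply(table$tags, function(t) tg %in% t, logical(1))
  res <- rownames(cn)[ok]
  if (!length(res)) warning("no markers satisfy criteria")
  res
}

#' Flag families as universal / single-copy
#' @param table an `ortholog_table`.
#' @return data frame with `family`, `universal`, `single_copy`,
#'   `max_copies`.
#' @export
family_status <- function(table) {
  cn <- table$copy_number
  data.frame(family = rownames(cn),
             universal = apply(cn >= 1L, 1L, all),
             single_copy = apply(cn <= 1L, 1L, all),
             max_copies = apply(cn, 1L, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Progressive multiple sequence alignment
#'
#' Builds a UPGMA guide tree from p-distances of pairwise global
#' alignments, then merges profiles along the guide tree with an affine
#' gap profile-profile aligner (sum-of-pairs column scores). Guide-tree
#' ties are broken by lexicographic label order, so the result is
#' deterministic for a fixed input.
#'
#' @param seqs named character vector of ungapped sequences (>= 2).
#' @param matrix substitution matrix name (amino acids) or `"dna"`.
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @return character matrix (rows = input sequences, in input order).
#' @export
progressive_align <- function(seqs, matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 0.5) {
  seqs <- unlist(seqs)
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  if (any(grepl("-", seqs, fixed = TRUE)))
    stop("input sequences must not contain gaps")
  seqs <- toupper(seqs)
  submat <- score_matrix(matrix)
  if (length(seqs) == 2L) {
    prof <- profile_pair_align(aln_matrix(seqs[1]), aln_matrix(seqs[2]),
                               submat, gap_open, gap_extend)
    return(prof[names(seqs), , drop = FALSE])
  }
  d <- guide_distances(seqs, submat, gap_open, gap_extend)
  merges <- upgma_merge_order(d)
  profiles <- lapply(names(seqs), function(nm) aln_matrix(seqs[nm]))
  for (m in merges) {
    merged <- profile_pair_align(profiles[[m[1L]]], profiles[[m[2L]]],
                                 submat, gap_open, gap_extend)
    profiles[[m[1L]]] <- merged
    profiles[m[2L]] <- list(NULL)
  }
  out <- profiles[[merges[[length(merges)]][1L]]]
  out[names(seqs), , drop = FALSE]
}

score_matrix <- function(matrix) {
  if (identical(matrix, "dna"))
    return(Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                                    baseOnly = FALSE))
  utils::data(list = matrix, package = "Biostrings", envir = environment())
  get(matrix, envir = environment())
}

guide_distances <- function(seqs, submat, gap_open, gap_extend) {
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  for (i in seq_len(n - 1L)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = set[(i + 1L):n], subject = set[[i]], type = "global",
      substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend)
    pid <- Biostrings::pid(aln, type = "PID1")
    d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- 1 - pid / 100
  }
  d
}

# UPGMA agglomeration order as pairs of profile slots (1..n then merged
# into the lower slot); lexicographic tie-break on smallest member label
upgma_merge_order <- function(d) {
  n <- nrow(d)
  first <- rownames(d)
  size <- rep(1L, n)
  active <- seq_len(n)
  merges <- list()
  while (length(active) > 1L) {
    da <- d[active, active, drop = FALSE]
    diag(da) <- Inf
    m <- min(da)
    cand <- which(da - m <= 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(first[active][cand[, 1]], first[active][cand[, 2]]),
                 pmax(first[active][cand[, 1]], first[active][cand[, 2]]))
    pick <- cand[order(key)[1L], ]
    i <- active[pick[1L]]; j <- active[pick[2L]]
    if (first[j] < first[i]) { tmp <- i; i <- j; j <- tmp }
    merges[[length(merges) + 1L]] <- c(i, j)
    drow <- (size[i] * d[i, ] + size[j] * d[j, ]) / (size[i] + size[j])
    d[i, ] <- d[, i] <- drow
    d[i, i] <- 0
    size[i] <- size[i] + size[j]
    first[i] <- min(first[i], first[j])
    active <- setdiff(active, j)
  }
  merges
}

ALN_LETTERS <- c(LETTERS, "*")

# column letter-count representation of a profile
profile_counts <- function(prof, letters) {
  cnt <- matrix(0, length(letters), ncol(prof),
                dimnames = list(letters, NULL))
  for (l in letters) cnt[l, ] <- colSums(prof == l)
  cnt
}

# affine-gap global profile-profile alignment (gaps open from match state
# only; terminal gaps penalized). Returns the merged character matrix.
profile_pair_align <- function(p1, p2, submat, go, ge) {
  letters <- intersect(ALN_LETTERS, rownames(submat))
  c1 <- profile_counts(p1, letters)
  c2 <- profile_counts(p2, letters)
  nz1 <- pmax(colSums(c1), 1); nz2 <- pmax(colSums(c2), 1)
  S <- t(c1) %*% submat[letters, letters] %*% c2 / outer(nz1, nz2)
  n1 <- ncol(p1); n2 <- ncol(p2)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n1 + 1L, n2 + 1L)
  M[1L, 1L] <- 0
  X[, 1L] <- -go - ge * (0:n1)       # gap in profile 2 (consume p1)
  Y[1L, ] <- -go - ge * (0:n2)       # gap in profile 1 (consume p2)
  X[1L, 1L] <- Y[1L, 1L] <- NEG
  for (i in 2L:(n1 + 1L)) {
    prevM <- M[i - 1L, ]; prevX <- X[i - 1L, ]; prevY <- Y[i - 1L, ]
    M[i, 2L:(n2 + 1L)] <- S[i - 1L, ] +
      pmax(prevM[1L:n2], prevX[1L:n2], prevY[1L:n2])
    X[i, ] <- pmax(prevM - go - ge, prevX - ge)   # gap of length g costs go + ge*g
    # cummax scan for Y along j using this row's M
    A <- M[i, ] + ge * (0:n2)
    cm <- cummax(c(NEG, A[1L:n2]))
    Y[i, ] <- pmax(cm[1L:(n2 + 1L)] - go - ge * (0:n2),
                   NEG)
    Y[i, 1L] <- NEG
  }
  # traceback
  i <- n1 + 1L; j <- n2 + 1L
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  cols1 <- integer(0); cols2 <- integer(0)   # 0 = gap column
  while (i > 1L || j > 1L) {
    if (i == 1L) state <- 3L
    if (j == 1L) state <- 2L
    if (state == 1L) {
      cols1 <- c(i - 1L, cols1); cols2 <- c(j - 1L, cols2)
      i <- i - 1L; j <- j - 1L
      if (i >= 1L && j >= 1L) {
        opts <- c(M[i, j], X[i, j], Y[i, j])
        state <- which.max(opts)
      }
    } else if (state == 2L) {                 # gap in p2
      cols1 <- c(i - 1L, cols1); cols2 <- c(0L, cols2)
      i <- i - 1L
      if (abs(X[i + 1L, j] - (M[i, j] - go - ge)) < 1e-9) state <- 1L
    } else {                                  # gap in p1
      cols1 <- c(0L, cols1); cols2 <- c(j - 1L, cols2)
      j <- j - 1L
      if (abs(Y[i, j + 1L] - (M[i, j] - go - ge)) < 1e-9) state <- 1L
    }
  }
  merge_profiles(p1, p2, cols1, cols2)
}

merge_profiles <- function(p1, p2, cols1, cols2) {
  L <- length(cols1)
  out <- matrix("-", nrow(p1) + nrow(p2), L)
  rownames(out) <- c(rownames(p1), rownames(p2))
  out[seq_len(nrow(p1)), cols1 > 0L] <- p1[, cols1[cols1 > 0L], drop = FALSE]
  out[nrow(p1) + seq_len(nrow(p2)), cols2 > 0L] <-
    p2[, cols2[cols2 > 0L], drop = FALSE]
  out
}

#' Concatenate marker alignments
#'
#' Column-wise concatenation of per-marker alignments covering the same
#' strain set, with partition bookkeeping and per-strain ungapped residue
#' counts.
#'
#' @param alignments named list of alignment matrices (or named gapped
#'   string vectors), one per marker.
#' @return list of class `concatenated_alignment` with `alignment`
#'   (matrix), `partitions` (data frame `marker`, `start`, `end`) and
#'   `residue_counts` (per-strain ungapped residues).
#' @export
concatenate_markers <- function(alignments) {
  stopifnot(length(alignments) >= 1L, !is.null(names(alignments)))
  alns <- lapply(alignments, function(a)
    if (is.matrix(a)) a else aln_matrix(unlist(a)))
  labs <- sort(rownames(alns[[1L]]))
  for (nm in names(alns)) {
    got <- sort(rownames(alns[[nm]]))
    if (!identical(got, labs))
      stop("marker '", nm, "': strain labels differ; missing: ",
           paste(setdiff(labs, got), collapse = ", "),
           if (length(setdiff(got, labs)))
             paste0("; extra: ", paste(setdiff(got, labs), collapse = ", ")))
  }
  alns <- lapply(alns, function(a) a[labs, , drop = FALSE])
  widths <- vapply(alns, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  big <- do.call(cbind, alns)
  structure(list(alignment = big,
                 partitions = data.frame(marker = names(alns),
                                         start = starts, end = ends,
                                         row.names = NULL),
                 residue_counts = rowSums(big != "-")),
            class = "concatenated_alignment")
}

#' @export
print.concatenated_alignment <- function(x, ...) {
  cat("<concatenated_alignment> ", nrow(x$alignment), " strains, ",
      ncol(x$alignment), " columns, ", nrow(x$partitions),
      " partition(s)\n", sep = "")
  invisible(x)
}

#' Read / write ortholog annotation tables
#'
#' TSV with columns `strain`, `protein_id`, `family_id` (optional) and
#' `tags` (semicolon-separated). When `family_id` is present the table is
#' taken as given; otherwise use [cluster_orthologs()].
#'
#' @param path TSV file.
#' @return an `ortholog_table`.
#' @export
read_ortholog_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain", "protein_id", "family_id")
  if (!all(need %in% names(df)))
    stop("ortholog TSV needs columns: ", paste(need, collapse = ", "))
  strains <- sort(unique(df$strain))
  fids <- sort(unique(df$family_id))
  families <- tags <- stats::setNames(vector("list", length(fids)), fids)
  cn <- matrix(0L, length(fids), length(strains),
               dimnames = list(fids, strains))
  for (f in fids) {
    sub <- df[df$family_id == f, ]
    families[[f]] <- data.frame(strain = sub$strain, protein = sub$protein_id,
                                stringsAsFactors = FALSE)
    tb <- table(factor(sub$strain, strains))
    cn[f, ] <- as.integer(tb)
    tg <- if ("tags" %in% names(df))
      unlist(strsplit(sub$tags[!is.na(sub$tags)], ";", fixed = TRUE))
    else character(0)
    tags[[f]] <- sort(unique(trimws(tg[nzchar(tg)])))
  }
  structure(list(families = families, tags = tags, copy_number = cn,
                 strains = strains),
            class = "ortholog_table")
}
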