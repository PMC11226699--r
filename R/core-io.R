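#' Read a FASTA file into a genome record or protein set
#'
#' The header token before the first whitespace becomes the record id;
#' sequence case is normalized to upper case. With `as = "genome"` every
#' FASTA entry becomes one replicon of a single strain; with
#' `as = "proteins"` every entry becomes one protein.
#'
#' @param path FASTA file.
#' @param as `"genome"` or `"proteins"`.
#' @param id strain identifier; defaults to the file name without extension.
#' @return a [genome_record()] or [protein_set()].
#' @export
read_fasta <- function(path, as = c("genome", "proteins"), id = NULL) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  set <- if (as == "genome") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readBStringSet(path)
  }
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- nms
  if (as == "genome") genome_record(id, seqs) else protein_set(id, seqs)
}

#' Write sequences as FASTA
#'
#' Accepts a `genome_record`, `protein_set`, or named character vector.
#' Emits UTF-8 with LF line endings, 70 columns per line.
#'
#' @param x sequences.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- if (inherits(x, "genome_record")) x$replicons
          else if (inherits(x, "protein_set")) x$proteins
          else unlist(x)
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "wb")   # binary: guaranteed LF endings
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con, sep = "\n")
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read an aligned FASTA file as an alignment matrix
#'
#' @param path aligned FASTA (all sequences equal length, `-` for gaps).
#' @return character matrix, rows = sequences, columns = alignment columns.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (length(unique(nchar(seqs))) != 1L)
    stop("not an alignment: unequal sequence lengths in ", path)
  aln_matrix(seqs)
}

#' @rdname read_alignment
#' @param aln alignment matrix.
#' @export
write_alignment <- function(aln, path) {
  write_fasta(apply(aln, 1L, paste, collapse = ""), path)
}

# named gapped strings -> character matrix
aln_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' GC content of a nucleotide sequence
#'
#' Fraction (G + C) / (A + C + G + T); `N` is excluded from the
#' denominator. Errors if no unambiguous base is present.
#'
#' @param seq a nucleotide string or a [genome_record()] (all replicons
#'   pooled).
#' @return fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  if (inherits(seq, "genome_record")) seq <- paste(seq$replicons, collapse = "")
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  cnt <- base_counts(seq)
  denom <- sum(cnt[c("A", "C", "G", "T")])
  if (denom == 0L) stop("gc_content undefined: no unambiguous bases")
  unname((cnt[["G"]] + cnt[["C"]]) / denom)
}

#' GC skew along a sequence
#'
#' Sliding-window (G - C) / (G + C). Windows containing no G or C are
#' reported as `NA`.
#'
#' @param seq nucleotide string.
#' @param window window length in bp.
#' @param step step between window starts in bp.
#' @return data frame with columns `start`, `end` (1-based inclusive, as in
#'   user-facing reports) and `skew`.
#' @export
gc_skew <- function(seq, window = 10000L, step = window) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  if (window > n) stop("window (", window, ") longer than sequence (", n, ")")
  v <- strsplit(toupper(seq), "")[[1]]
  gcum <- cumsum(v == "G")
  ccum <- cumsum(v == "C")
  starts <- seq(1L, n - window + 1L, by = step)
  g <- gcum[starts + window - 1L] - c(0L, gcum)[starts]
  cc <- ccum[starts + window - 1L] - c(0L, ccum)[starts]
  skew <- ifelse(g + cc == 0L, NA_real_, (g - cc) / (g + cc))
  data.frame(start = starts, end = starts + window - 1L, skew = skew)
}

#' Read / write phylogenetic trees in Newick format
#'
#' Thin wrappers around 'ape' that preserve bootstrap support values
#' stored as internal node labels (the common dialect). Branch lengths and
#' topology round-trip losslessly.
#'
#' @param path Newick file.
#' @return `read_newick` returns an `ape` `phylo` object (with numeric
#'   node labels interpreted as percent support in `$node.label`).
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path,
                                          ": ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in ", path)
  tr
}

#' @rdname read_newick
#' @param tree `phylo` object.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(tree, path, digits = 10) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

base_counts <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  c(A = sum(v == "A"), C = sum(v == "C"), G = sum(v == "G"),
    T = sum(v == "T"), N = sum(v == "N"))
}

#' Reverse complement of a nucleotide string
#' @param seq nucleotide string over A,C,G,T,N.
#' @return reverse-complemented string.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(seq), "")[[1]]),
                                 collapse = ""))
}
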