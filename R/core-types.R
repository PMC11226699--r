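#' Construct a genome record
#'
#' A `genome_record` holds the nucleotide replicons (chromosome, plasmids)
#' of one strain. Sequences are upper-cased and restricted to the alphabet
#' `A, C, G, T, N`; other IUPAC ambiguity codes are rejected so that
#' unexpected input fails loudly rather than being silently remapped.
#'
#' @param id strain identifier (single string).
#' @param replicons named character vector or named list of sequences.
#' @param topology character vector, `"circular"` or `"linear"`, recycled
#'   across replicons.
#' @return an object of class `genome_record` with elements `id`,
#'   `replicons` (named character vector) and `topology`.
#' @export
genome_record <- function(id, replicons, topology = "circular") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  replicons <- unlist(replicons)
  if (length(replicons) == 0L) stop("genome '", id, "': no replicons")
  if (is.null(names(replicons)) || anyNA(names(replicons)) ||
      any(!nzchar(names(replicons)))) {
    names(replicons) <- paste0("replicon", seq_along(replicons))
  }
  if (anyDuplicated(names(replicons)))
    stop("genome '", id, "': duplicate replicon names")
  replicons <- toupper(replicons)
  if (any(!nzchar(replicons)))
    stop("genome '", id, "': empty replicon sequence")
  bad <- vapply(replicons, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad))
    stop("genome '", id, "': illegal characters in replicon(s) ",
         paste(names(replicons)[bad], collapse = ", "),
         " (only A, C, G, T, N are accepted)")
  topology <- rep_len(match.arg(topology, c("circular", "linear"),
                                several.ok = TRUE), length(replicons))
  structure(list(id = id, replicons = replicons, topology = topology),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$id, ": ", length(x$replicons), " replicon(s), ",
      format(sum(nchar(x$replicons)), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Total length of a genome in base pairs
#' @param x a `genome_record`.
#' @return integer total length.
#' @export
genome_length <- function(x) sum(nchar(x$replicons))

#' Construct a protein set
#'
#' Named amino-acid sequences of one strain, each optionally carrying
#' annotation tags (gene names, pathway labels) used by marker selection.
#'
#' @param id strain identifier.
#' @param proteins named character vector of amino-acid sequences
#'   (20-letter alphabet plus `X`).
#' @param tags optional named list mapping protein id to a character
#'   vector of annotation strings.
#' @return an object of class `protein_set`.
#' @export
protein_set <- function(id, proteins, tags = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  proteins <- unlist(proteins)
  if (length(proteins) == 0L) stop("protein set '", id, "': empty")
  if (is.null(names(proteins)) || any(!nzchar(names(proteins))))
    stop("protein set '", id, "': proteins must be named")
  if (anyDuplicated(names(proteins)))
    stop("protein set '", id, "': duplicate protein ids: ",
         paste(unique(names(proteins)[duplicated(names(proteins))]),
               collapse = ", "))
  proteins <- toupper(proteins)
  bad <- vapply(proteins, function(s)
    grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", s), logical(1))
  if (any(bad))
    stop("protein set '", id, "': illegal residue in ",
         paste(names(proteins)[bad], collapse = ", "))
  proteins <- gsub("\\*$", "", proteins)   # trailing stop codons tolerated
  tg <- vector("list", length(proteins))
  names(tg) <- names(proteins)
  for (nm in intersect(names(tags), names(proteins)))
    tg[[nm]] <- as.character(tags[[nm]])
  structure(list(id = id, proteins = proteins, tags = tg),
            class = "protein_set")
}

#' @export
print.protein_set <- function(x, ...) {
  cat("<protein_set> ", x$id, ": ", length(x$proteins), " protein(s)\n",
      sep = "")
  invisible(x)
}

#' Construct a similarity matrix
#'
#' Symmetric labelled matrix of percent identities (ANI, AAI, DDH, 16S) or
#' a custom percent-scale statistic. The diagonal is forced to exactly 100.
#'
#' @param values square numeric matrix (percent scale).
#' @param labels strain identifiers; defaults to the matrix dimnames.
#' @param kind one of `"ANI"`, `"AAI"`, `"DDH"`, `"16S"`, `"custom"`.
#' @param asymmetry optional matrix of directional asymmetries recorded by
#'   [build_matrix()].
#' @return an object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, labels = rownames(values),
                              kind = c("ANI", "AAI", "DDH", "16S", "custom"),
                              asymmetry = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  if (is.null(labels)) labels <- paste0("s", seq_len(nrow(values)))
  if (anyDuplicated(labels)) stop("duplicate strain labels")
  dimnames(values) <- list(labels, labels)
  diag(values) <- 100
  off <- values[row(values) != col(values)]
  if (any(!is.na(off) & (off < 0 | off > 100)))
    stop("off-diagonal values must lie in [0, 100]")
  structure(list(values = values, labels = labels, kind = kind,
                 asymmetry = asymmetry),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, digits = 1, ...) {
  cat("<similarity_matrix> kind=", x$kind, ", ", length(x$labels),
      " strains\n", sep = "")
  print(round(x$values, digits))
  invisible(x)
}

#' @export
dim.similarity_matrix <- function(x) dim(x$values)

#' @export
as.matrix.similarity_matrix <- function(x, ...) x$values

#' Write / read a similarity matrix as TSV
#'
#' Plain TSV with the label row and column; values full precision.
#' @param m a `similarity_matrix`.
#' @param path output file.
#' @param kind matrix kind for [read_matrix_tsv()].
#' @return `read_matrix_tsv` returns a `similarity_matrix`;
#'   `write_matrix_tsv` returns `path` invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(strain = m$labels, m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, kind = "custom") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lab <- as.character(df[[1]])
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- lab
  similarity_matrix(v, lab, kind = kind)
}
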