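# NCBI-format substitution-matrix reader and ungapped column-sum similarity.

#' Read a substitution matrix in NCBI text format
#'
#' Parses the plain-text layout used by NCBI BLAST matrices: `#` comment
#' lines, a header row of single letters, then one row per letter. The
#' matrix must be square and symmetric.
#'
#' @param path path to the matrix file.
#' @return an integer matrix with letter dimnames, class `substitution_matrix`.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix: ", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  n <- length(header)
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1]])
  if (length(rows) != n) {
    stop("substitution matrix has ", length(rows), " rows for ", n, " columns")
  }
  m <- matrix(NA_integer_, n, n, dimnames = list(header, header))
  for (r in rows) {
    if (length(r) != n + 1L) stop("malformed matrix row: ", paste(r, collapse = " "))
    m[r[1L], ] <- as.integer(r[-1L])
  }
  if (any(is.na(m))) stop("substitution matrix has missing entries")
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    stop("substitution matrix is not symmetric")
  }
  structure(m, class = c("substitution_matrix", class(m)))
}

#' The BLOSUM62 matrix shipped with the package
#'
#' Loads the NCBI-format BLOSUM62 file from the package's `extdata`. Any
#' other matrix in the same format is a drop-in replacement via
#' [read_substitution_matrix()].
#'
#' @return a `substitution_matrix`.
#' @export
blosum62 <- function() {
  read_substitution_matrix(
    system.file("extdata", "BLOSUM62.txt", package = "phosforest",
                mustWork = TRUE))
}

#' Ungapped similarity between two equal-length peptides
#'
#' The sum over aligned columns of the substitution score
#' `matrix[a_i, b_i]`. This is the similarity used to rank nearest
#' neighbors in the KNNS feature view.
#'
#' @param a,b equal-length peptide strings.
#' @param matrix a `substitution_matrix` (default BLOSUM62).
#' @return integer similarity score.
#' @export
blosum_similarity <- function(a, b, matrix = blosum62()) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) {
    stop("peptides differ in length (", length(ca), " vs ", length(cb), ")")
  }
  sum(matrix[cbind(ca, cb)])
}

# All-pairs similarity between two sets of windows, as an nq x nr matrix.
# Q, R are character matrices from window_char_matrix(); loops over the 13
# columns rather than the (much larger) pair set.
similarity_matrix <- function(Q, R, matrix) {
  stopifnot(ncol(Q) == ncol(R))
  S <- matrix(0, nrow(Q), nrow(R))
  for (p in seq_len(ncol(Q))) {
    S <- S + matrix[Q[, p], R[, p], drop = FALSE]
  }
  S
}
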