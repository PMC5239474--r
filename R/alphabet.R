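# Amino-acid alphabet handling shared by all modules.

#' The 20 standard amino acids in single-letter alphabetical order
#'
#' Order used by the occurrence-frequency encoder: A, C, D, E, F, G, H, I, K,
#' L, M, N, P, Q, R, S, T, V, W, Y.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Letters a window may legally contain after normalization.
AA_WINDOW <- c(AA_STANDARD, "X")

#' Normalize a protein sequence for window extraction
#'
#' Upper-cases the sequence and maps every non-standard letter (U, B, Z, J,
#' O, `*`, gaps, ...) to `X`. `X` matches no attribute group and contributes
#' its own BLOSUM62 column in similarity sums.
#'
#' @param sequence character scalar, a protein sequence.
#' @return normalized character scalar over the 20 standard letters plus X.
#' @export
normalize_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  chars[!(chars %in% AA_STANDARD)] <- "X"
  paste(chars, collapse = "")
}

# Split a vector of equal-length window strings into an n x width character
# matrix. Workhorse for the vectorized encoders.
window_char_matrix <- function(seqs, width) {
  if (length(seqs) == 0L) {
    return(matrix(character(0), nrow = 0L, ncol = width))
  }
  chars <- strsplit(seqs, "", fixed = TRUE)
  bad <- lengths(chars) != width
  if (any(bad)) {
    stop("window string of wrong length at index ", which(bad)[1L],
         " (expected ", width, ")")
  }
  matrix(unlist(chars), nrow = length(seqs), ncol = width, byrow = TRUE)
}
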