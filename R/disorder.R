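# Per-residue intrinsic-disorder scores. Scores may come from files written
# by an external disorder predictor (read_disorder_scores) or from the
# built-in deterministic propensity provider below.

# TOP-IDP amino-acid disorder propensities (Campen et al. 2008). Higher
# means more disorder-prone. X is assigned the scale midpoint after scaling.
TOP_IDP <- c(A = 0.060, R = 0.180, N = 0.007, D = 0.192, C = 0.020,
             Q = 0.318, E = 0.736, G = 0.166, H = 0.303, I = -0.486,
             L = -0.326, K = 0.586, M = -0.397, F = -0.697, P = 0.987,
             S = 0.341, T = 0.059, W = -0.884, Y = -0.510, V = -0.121)

#' Built-in per-residue disorder-score provider
#'
#' A deterministic stand-in for an external disorder predictor: each residue
#' gets the TOP-IDP disorder propensity of its amino-acid type, min-max
#' scaled to \[0, 1\] over the 20-letter scale, then mean-smoothed over a
#' sliding window of `2*smoothing_halfwidth + 1` residues (truncated at the
#' termini). `X` residues take the scale midpoint 0.5.
#'
#' @param protein_sequence normalized sequence.
#' @param smoothing_halfwidth half-width of the smoothing window (default 10).
#' @return numeric vector of per-residue scores in \[0, 1\].
#' @export
default_disorder_provider <- function(protein_sequence, smoothing_halfwidth = 10L) {
  chars <- strsplit(protein_sequence, "", fixed = TRUE)[[1]]
  scaled <- (TOP_IDP - min(TOP_IDP)) / (max(TOP_IDP) - min(TOP_IDP))
  raw <- ifelse(chars %in% names(scaled), scaled[chars], 0.5)
  h <- as.integer(smoothing_halfwidth)
  if (h == 0L || length(raw) == 1L) return(pmin(pmax(unname(raw), 0), 1))
  L <- length(raw)
  cs <- cumsum(c(0, raw))
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  pmin(pmax(unname(sm), 0), 1)
}

# Compute disorder profiles for a set of proteins with a provider function.
compute_profiles <- function(proteins, provider = default_disorder_provider) {
  lapply(proteins, provider)
}
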