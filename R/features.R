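# The four pseudo-component feature views. Each encoder maps a set of
# peptide windows to a fixed-width numeric matrix (one row per window):
#   DS    - per-slot intrinsic-disorder scores            (2*xi+1 columns)
#   KNNS  - positive-label fractions among the k nearest
#           reference windows under BLOSUM62 similarity   (5 columns)
#   AAOF  - amino-acid occurrence frequencies             (20 columns)
#   PWAAC - position-weighted attribute-group composition (5 columns)

#' Default five-group residue attribute partition
#'
#' Disjoint groups covering the 20 standard letters: aliphatic
#' \{G,A,V,L,I,P\}, aromatic \{F,Y,W\}, polar-neutral \{S,T,C,M,N,Q\},
#' positively charged \{K,R,H\}, negatively charged \{D,E\}. `X` belongs to
#' no group.
#'
#' @return named list of character vectors, class `attribute_grouping`.
#' @export
default_attribute_grouping <- function() {
  g <- list(aliphatic = c("G", "A", "V", "L", "I", "P"),
            aromatic = c("F", "Y", "W"),
            polar_neutral = c("S", "T", "C", "M", "N", "Q"),
            positive = c("K", "R", "H"),
            negative = c("D", "E"))
  validate_grouping(g)
  structure(g, class = "attribute_grouping")
}

validate_grouping <- function(g) {
  all_letters <- unlist(g, use.names = FALSE)
  if (anyDuplicated(all_letters)) stop("attribute groups must be disjoint")
  if (!setequal(all_letters, AA_STANDARD)) {
    stop("attribute groups must cover exactly the 20 standard amino acids")
  }
  invisible(g)
}

#' Nearest-neighbor configuration for the KNNS view
#'
#' @param k_values strictly increasing positive integers; one feature
#'   component per k. Default `c(2, 4, 8, 16, 32)`.
#' @param exclude_self omit a query window from its own neighbor list when
#'   it is itself a reference member (default TRUE; prevents label leakage
#'   when encoding the training set).
#' @return a `knn_config` list.
#' @export
knn_config <- function(k_values = c(2L, 4L, 8L, 16L, 32L), exclude_self = TRUE) {
  k_values <- as.integer(k_values)
  stopifnot(all(k_values >= 1L), !is.unsorted(k_values, strictly = TRUE))
  structure(list(k_values = k_values, exclude_self = isTRUE(exclude_self)),
            class = "knn_config")
}

#' Bundle of everything the encoders need
#'
#' @param matrix substitution matrix for KNNS (default BLOSUM62).
#' @param grouping attribute partition for PWAAC.
#' @param knn a [knn_config()].
#' @param profiles named list of per-protein disorder-score vectors; windows
#'   from proteins absent here fall back to `provider`.
#' @param provider function(sequence) -> scores, used to fill in missing
#'   profiles when sequences are available (default the built-in provider);
#'   NULL disables the fallback.
#' @param xi window half-width (must match the windows being encoded).
#' @return an `encoder_context` list.
#' @export
encoder_context <- function(matrix = blosum62(),
                            grouping = default_attribute_grouping(),
                            knn = knn_config(), profiles = list(),
                            provider = default_disorder_provider, xi = 6L) {
  structure(list(matrix = matrix, grouping = grouping, knn = knn,
                 profiles = profiles, provider = provider,
                 xi = as.integer(xi)),
            class = "encoder_context")
}

#' Disorder-score (DS) encoding
#'
#' Component i is the disorder score of the residue occupying window slot i.
#' Padded slots inherit the score of the replicated terminal residue.
#'
#' @param windows peptide-window data.frame (see [extract_windows()]).
#' @param context an [encoder_context()]; its `profiles` must cover the
#'   windows' source proteins (or `sequences` must allow the provider to).
#' @param sequences optional named sequences used to compute missing
#'   profiles via `context$provider`.
#' @return numeric matrix, one row per window, `2*xi + 1` columns.
#' @export
encode_ds <- function(windows, context, sequences = NULL) {
  xi <- context$xi
  width <- 2L * xi + 1L
  profiles <- context$profiles
  need <- setdiff(unique(windows$protein_id), names(profiles))
  if (length(need)) {
    if (is.null(context$provider) || is.null(sequences) ||
        !all(need %in% names(sequences))) {
      stop("no disorder profile for protein(s) ",
           paste(utils::head(need, 3L), collapse = ", "),
           "; supply scores via read_disorder_scores() or sequences for the ",
           "built-in provider")
    }
    profiles <- c(profiles, lapply(sequences[need], context$provider))
  }
  out <- matrix(NA_real_, nrow(windows), width)
  for (i in seq_len(nrow(windows))) {
    s <- profiles[[windows$protein_id[i]]]
    idx <- pmin(pmax(windows$center_position[i] + seq(-xi, xi), 1L), length(s))
    out[i, ] <- s[idx]
  }
  out
}

#' Amino-acid occurrence-frequency (AAOF) encoding
#'
#' Component j is the count of amino acid j in the window divided by the
#' window length, amino acids in single-letter alphabetical order
#' (A, C, D, ..., Y). `X` counts toward no component, so rows containing X
#' sum to less than one by exactly `#X / (2*xi + 1)`.
#'
#' @param windows peptide-window data.frame.
#' @param xi window half-width.
#' @return numeric matrix with 20 columns named by residue.
#' @export
encode_aaof <- function(windows, xi = 6L) {
  width <- 2L * xi + 1L
  M <- window_char_matrix(windows$sequence, width)
  out <- vapply(AA_STANDARD, function(a) rowSums(M == a) / width,
                numeric(nrow(M)))
  out <- matrix(out, nrow = nrow(M), ncol = 20L,
                dimnames = list(NULL, AA_STANDARD))
  out
}

#' Position-weighted amino-acid composition (PWAAC) encoding
#'
#' Window slots are indexed j = -xi..+xi with 0 at the center. Component i
#' is `sum_j [residue at j in group i] * w(j) / (xi*(xi+1))` with the
#' default weight `w(j) = j + |j|`: 2j for downstream slots, zero for the
#' center and upstream slots. Since `sum_{j=1..xi} 2j = xi*(xi+1)`, each
#' component lies in \[0, 1\] and the components sum to 1 when every
#' downstream residue belongs to some group.
#'
#' @param windows peptide-window data.frame.
#' @param grouping an attribute partition (default
#'   [default_attribute_grouping()]).
#' @param xi window half-width.
#' @param weights optional replacement weight vector of length `2*xi + 1`
#'   (slots in j = -xi..+xi order) for alternative position weightings; it
#'   is used with the same `xi*(xi+1)` normalizer.
#' @return numeric matrix with one column per group.
#' @export
encode_pwaac <- function(windows, grouping = default_attribute_grouping(),
                         xi = 6L, weights = NULL) {
  width <- 2L * xi + 1L
  j <- seq(-xi, xi)
  if (is.null(weights)) weights <- j + abs(j)
  stopifnot(length(weights) == width)
  M <- window_char_matrix(windows$sequence, width)
  known <- unique(c(unlist(grouping, use.names = FALSE), "X"))
  if (nrow(M) && !all(M %in% known)) {
    stop("residue '", setdiff(unique(as.vector(M)), known)[1L],
         "' belongs to no attribute group; fix the grouping or normalize ",
         "the sequence")
  }
  norm <- xi * (xi + 1L)
  out <- vapply(grouping, function(g) {
    member <- matrix(M %in% g, nrow(M), width)
    as.numeric(member %*% weights) / norm
  }, numeric(nrow(M)))
  matrix(out, nrow = nrow(M), ncol = length(grouping),
         dimnames = list(NULL, names(grouping)))
}

#' BLOSUM62 k-nearest-neighbor score (KNNS) encoding
#'
#' For each k in `config$k_values`, the component is the fraction of
#' positive-labeled windows among the k reference windows most similar to
#' the query under the ungapped column-sum BLOSUM62 similarity. Similarity
#' ties are broken by stable reference order. With `exclude_self`, a query
#' that is itself a reference member (same protein, position and sequence)
#' is dropped from its own neighbor list.
#'
#' @param windows query peptide-window data.frame.
#' @param reference a `labeled_dataset` providing the neighbor pool.
#' @param context an [encoder_context()] (substitution matrix + knn config).
#' @param self_index optional integer vector, one entry per query row: the
#'   row of the reference pool that IS this query (NA if none). Overrides
#'   the key-based self detection; used by the cross-validation driver.
#' @return numeric matrix with `length(k_values)` columns.
#' @export
encode_knns <- function(windows, reference, context, self_index = NULL) {
  cfg <- context$knn
  ref <- dataset_frame(reference)
  if (nrow(ref) == 0L) stop("KNNS reference set is empty")
  width <- 2L * context$xi + 1L
  Q <- window_char_matrix(windows$sequence, width)
  R <- window_char_matrix(ref$sequence, width)
  S <- similarity_matrix(Q, R, context$matrix)
  if (is.null(self_index) && cfg$exclude_self) {
    qkey <- paste(windows$protein_id, windows$center_position, windows$sequence)
    rkey <- paste(ref$protein_id, ref$center_position, ref$sequence)
    self_index <- match(qkey, rkey)
  }
  if (!is.null(self_index) && cfg$exclude_self) {
    has <- which(!is.na(self_index))
    if (length(has)) S[cbind(has, self_index[has])] <- -Inf
  }
  avail <- nrow(ref) - if (!is.null(self_index) && cfg$exclude_self &&
                           any(!is.na(self_index))) 1L else 0L
  if (max(cfg$k_values) > avail) {
    stop("k = ", max(cfg$k_values), " exceeds the ", avail,
         " available reference windows")
  }
  labels <- ref$label
  kmax <- max(cfg$k_values)
  out <- matrix(NA_real_, nrow(Q), length(cfg$k_values))
  colnames(out) <- paste0("k", cfg$k_values)
  for (i in seq_len(nrow(Q))) {
    # stable: ties in similarity resolve by reference order
    ord <- order(-S[i, ], seq_len(ncol(S)))[seq_len(kmax)]
    top <- labels[ord]
    out[i, ] <- vapply(cfg$k_values, function(k) sum(top[seq_len(k)]) / k,
                       numeric(1))
  }
  out
}

#' Encode windows under all four feature views
#'
#' @param windows peptide-window data.frame.
#' @param context an [encoder_context()].
#' @param reference `labeled_dataset` neighbor pool for KNNS.
#' @param sequences optional named sequences for on-the-fly disorder
#'   profiles.
#' @param self_index passed through to [encode_knns()].
#' @return named list of matrices `DS`, `KNNS`, `AAOF`, `PWAAC` with
#'   13 / 5 / 20 / 5 columns at the default `xi = 6`.
#' @export
encode_all <- function(windows, context, reference, sequences = NULL,
                       self_index = NULL) {
  list(DS = encode_ds(windows, context, sequences),
       KNNS = encode_knns(windows, reference, context, self_index),
       AAOF = encode_aaof(windows, context$xi),
       PWAAC = encode_pwaac(windows, context$grouping, context$xi))
}
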