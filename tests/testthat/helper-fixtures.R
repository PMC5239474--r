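# Shared fixtures: the BLOSUM62 matrix is loaded once, and small synthetic
# studies are built in code at fixed seeds.

B62 <- blosum62()

# Wrap raw 13-mer strings into a peptide-window frame (interior, unpadded).
as_windows <- function(seqs, center_type = "S", protein_id = NULL,
                       center_position = NULL, xi = 6L) {
  n <- length(seqs)
  data.frame(sequence = seqs,
             protein_id = if (is.null(protein_id)) sprintf("w%03d", seq_len(n))
                          else protein_id,
             center_position = if (is.null(center_position)) rep(xi + 1L, n)
                               else center_position,
             center_type = center_type,
             padded_left = 0L, padded_right = 0L)
}

# Random X-free 13-mer windows with the given center letter.
random_windows <- function(n, center_type = "S", seed = 1L, xi = 6L) {
  with_seed <- phosforest:::with_seed
  seqs <- with_seed(seed, vapply(seq_len(n), function(i) {
    chars <- sample(AA_STANDARD, 2L * xi + 1L, replace = TRUE)
    chars[xi + 1L] <- center_type
    paste(chars, collapse = "")
  }, character(1)))
  as_windows(seqs, center_type, xi = xi)
}

# A small labeled dataset + context with planted signal, for ensemble and
# evaluation tests. ~6:1 imbalance before balancing.
small_study <- function(effect = 1, seed = 101L, n_proteins = 8L,
                        rate = 0.25, ratio = 6) {
  generate_synthetic_study(n_proteins = n_proteins,
                           length_range = c(200L, 300L),
                           sites_per_protein_rate = rate,
                           model = signal_model(effect_strength = effect),
                           center_type = "S", neg_pos_ratio_target = ratio,
                           seed = seed)
}

# Benchmark-shaped study: ~600 positives, ~6,000 negatives at a ~10:1
# class ratio, mirroring the scale of a per-type phosphoproteome benchmark.
benchmark_study <- function(effect, seed = 601L) {
  generate_synthetic_study(n_proteins = 60L, length_range = c(1250L, 1350L),
                           sites_per_protein_rate = 0.105,
                           model = signal_model(effect_strength = effect),
                           center_type = "S", neg_pos_ratio_target = 10,
                           seed = seed)
}

study_dataset <- function(study) {
  build_dataset(study$proteins, study$annotations,
                window_config(study$xi, study$center_type))
}

study_context <- function(study) {
  encoder_context(matrix = B62, profiles = study$profiles, xi = study$xi)
}
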