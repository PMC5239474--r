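# The four encoders, checked against brute-force oracles and their
# invariants.

test_that("substitution-matrix reader matches the reference BLOSUM62", {
  letters24 <- rownames(B62)
  expect_true(isSymmetric(unclass(B62)))
  # independent reference: the Biostrings copy of the same public matrix
  data(BLOSUM62, package = "Biostrings", envir = environment())
  ref <- BLOSUM62[letters24, letters24]
  expect_equal(unclass(B62), ref, ignore_attr = TRUE)
  expect_true(all(diag(unclass(B62))[AA_STANDARD] >= 0))
})

test_that("ungapped similarity is the column sum of substitution scores", {
  expect_equal(blosum_similarity("SSS", "SSS", B62), 3L * B62["S", "S"])
  expect_equal(blosum_similarity("SSS", "SSS", B62), 12L)
  expect_equal(blosum_similarity("A", "X", B62), B62["A", "X"])
  expect_error(blosum_similarity("AA", "A", B62), "length")
  # symmetry on random pairs
  a <- random_windows(10L, seed = 2L)$sequence
  b <- random_windows(10L, seed = 3L)$sequence
  for (i in seq_along(a)) {
    expect_equal(blosum_similarity(a[i], b[i], B62),
                 blosum_similarity(b[i], a[i], B62))
  }
  # the vectorized all-pairs matrix agrees with the scalar definition
  Q <- phosforest:::window_char_matrix(a, 13L)
  R <- phosforest:::window_char_matrix(b, 13L)
  S <- phosforest:::similarity_matrix(Q, R, B62)
  expect_equal(S[3, 7], blosum_similarity(a[3], b[7], B62))
  expect_equal(S[10, 1], blosum_similarity(a[10], b[1], B62))
})

test_that("occurrence frequencies count letters over the window length", {
  w <- as_windows(c("AAAAAAAAAAAAA", "SPKSPARTSYQGS"))
  X <- encode_aaof(w)
  expect_equal(dim(X), c(2L, 20L))
  expect_equal(unname(X[1, "A"]), 1)
  expect_equal(sum(X[1, ]), 1)
  # oracle: direct letter counting
  counts <- table(strsplit("SPKSPARTSYQGS", "")[[1]])
  for (a in names(counts)) expect_equal(unname(X[2, a]), counts[[a]] / 13)
  expect_equal(unname(X[2, "S"]), 4 / 13)
  expect_equal(unname(X[2, "P"]), 2 / 13)
  expect_equal(sum(X[2, ]), 1)

  # X counts toward no component: the row sum drops by #X / 13
  wx <- as_windows("AXXSAAAAAAAAA")
  expect_equal(sum(encode_aaof(wx)), 1 - 2 / 13)

  # property: X-free windows always sum to exactly 1
  R <- encode_aaof(random_windows(50L, seed = 9L))
  expect_equal(unname(rowSums(R)), rep(1, 50L))
})

test_that("position-weighted composition weights downstream slots by 2j", {
  g <- default_attribute_grouping()
  # all residues in one group: that component is exactly 1
  X <- encode_pwaac(as_windows("GGGGGGGGGGGGG"), g)
  expect_equal(unname(X[1, "aliphatic"]), 1)
  expect_equal(sum(X[1, ]), 1)
  # a group occupying only upstream slots scores 0
  X2 <- encode_pwaac(as_windows("FYWFYWSGGGGGG"), g)
  expect_equal(unname(X2[1, "aromatic"]), 0)
  # brute-force double loop over positions and groups
  w <- random_windows(25L, seed = 11L)
  X3 <- encode_pwaac(w, g)
  xi <- 6L
  for (i in seq_len(nrow(w))) {
    chars <- strsplit(w$sequence[i], "")[[1]]
    for (gi in seq_along(g)) {
      acc <- 0
      for (j in seq(-xi, xi)) {
        if (chars[j + xi + 1L] %in% g[[gi]]) acc <- acc + (j + abs(j))
      }
      expect_equal(unname(X3[i, gi]), acc / (xi * (xi + 1L)))
    }
  }
  expect_true(all(X3 >= 0 & X3 <= 1))
  # full grouping covers every downstream residue, so components sum to 1
  expect_equal(unname(rowSums(X3)), rep(1, nrow(w)))
  # an ungrouped non-X residue is a configuration error
  bad <- list(a = setdiff(AA_STANDARD, "W"))
  expect_error(encode_pwaac(w, bad), "group")
})

test_that("nearest-neighbor scores agree with an exhaustive-sort oracle", {
  ctx <- encoder_context(matrix = B62, knn = knn_config(c(1L, 2L, 3L, 4L),
                                                        exclude_self = FALSE))
  mk_ref <- function(wpos, wneg) {
    structure(list(positives = wpos, negatives = wneg, center_type = "S",
                   xi = 6L, report = list()), class = "labeled_dataset")
  }
  # all-positive / all-negative reference pools pin the fractions
  pool <- random_windows(6L, seed = 21L)
  q <- random_windows(3L, seed = 22L)
  expect_equal(unname(encode_knns(q, mk_ref(pool, pool[0, ]), ctx)),
               matrix(1, 3L, 4L))
  expect_equal(unname(encode_knns(q, mk_ref(pool[0, ], pool), ctx)),
               matrix(0, 3L, 4L))

  # exhaustive oracle on every reference size up to 8
  for (nref in 4:8) {
    ref_w <- random_windows(nref, seed = 30L + nref)
    lab <- rep_len(c(1L, 0L), nref)
    ref <- mk_ref(ref_w[lab == 1L, ], ref_w[lab == 0L, ])
    # dataset_frame stacks positives first; mirror that order in the oracle
    ord_ref <- rbind(ref_w[lab == 1L, ], ref_w[lab == 0L, ])
    ord_lab <- c(lab[lab == 1L], lab[lab == 0L])
    qs <- random_windows(5L, seed = 50L + nref)
    K <- encode_knns(qs, ref, ctx)
    for (i in 1:5) {
      sims <- vapply(ord_ref$sequence, function(r) {
        blosum_similarity(qs$sequence[i], r, B62)
      }, numeric(1))
      ranked <- ord_lab[order(-sims, seq_along(sims))]
      for (kk in 1:4) {
        expect_equal(unname(K[i, kk]), sum(ranked[seq_len(kk)]) / kk)
      }
    }
  }

  # k larger than the pool is an error
  ctx_big <- encoder_context(matrix = B62, knn = knn_config(c(2L, 64L)))
  expect_error(encode_knns(q, mk_ref(pool, pool[0, ]), ctx_big), "exceeds")
})

test_that("self-exclusion and positive-monotonicity hold for KNNS", {
  base <- random_windows(6L, seed = 61L)
  mk_ref <- function(wpos, wneg) {
    structure(list(positives = wpos, negatives = wneg, center_type = "S",
                   xi = 6L, report = list()), class = "labeled_dataset")
  }
  # a positive reference window queried against its own pool must not see
  # itself: with itself the k=1 fraction would always be 1
  ref <- mk_ref(base[1:2, ], base[3:6, ])
  ctx_ex <- encoder_context(matrix = B62,
                            knn = knn_config(c(1L, 2L), exclude_self = TRUE))
  K <- encode_knns(base[1:2, ], ref, ctx_ex, self_index = 1:2)
  sims <- phosforest:::similarity_matrix(
    phosforest:::window_char_matrix(base$sequence[1], 13L),
    phosforest:::window_char_matrix(rbind(base[1:2, ], base[3:6, ])$sequence, 13L),
    B62)
  nn <- order(-replace(sims[1, ], 1L, -Inf), 1:6)[1L]
  expect_equal(unname(K[1, 1]), as.numeric(nn <= 2L))

  # adding positive-only references never decreases any component
  q <- random_windows(4L, seed = 62L)
  ctx <- encoder_context(matrix = B62,
                         knn = knn_config(c(1L, 2L, 4L), exclude_self = FALSE))
  K1 <- encode_knns(q, ref, ctx)
  grown <- mk_ref(rbind(base[1:2, ], random_windows(4L, seed = 63L)),
                  base[3:6, ])
  K2 <- encode_knns(q, grown, ctx)
  expect_true(all(K2 - K1 >= -1e-12))
})

test_that("disorder encoding slices profiles and inherits pad scores", {
  prot <- paste(rep("ASDFG", 8L), collapse = "")  # length 40
  wins <- extract_windows(prot, window_config(6L, "S"))
  # uniform profile: every component 0.5
  ctx_u <- encoder_context(profiles = list(protein = rep(0.5, 40L)))
  expect_equal(unname(encode_ds(wins, ctx_u)),
               matrix(0.5, nrow(wins), 13L))
  # ramp profile: an interior window picks 13 consecutive entries
  ramp <- seq(0, 1, length.out = 40L)
  ctx_r <- encoder_context(profiles = list(protein = ramp))
  D <- encode_ds(wins, ctx_r)
  interior <- which(wins$padded_left == 0L & wins$padded_right == 0L)[1L]
  p <- wins$center_position[interior]
  expect_equal(D[interior, ], ramp[(p - 6L):(p + 6L)])
  # padded slots inherit the replicated terminal residue's score
  first <- which(wins$padded_left > 0L)[1L]
  pl <- wins$padded_left[first]
  expect_equal(D[first, seq_len(pl)], rep(ramp[1L], pl))
  # missing profile without provider fallback is an error
  ctx_none <- encoder_context(profiles = list(), provider = NULL)
  expect_error(encode_ds(wins, ctx_none), "disorder")
})

test_that("builtin disorder provider is a scaled, smoothed propensity", {
  # homopolymer smooths to a constant
  expect_equal(default_disorder_provider(strrep("A", 30L)),
               rep(default_disorder_provider("A", 0L), 30L))
  # direct table-lookup oracle at halfwidth 0
  scale <- phosforest:::TOP_IDP
  expect_equal(default_disorder_provider("S", 0L),
               unname((scale["S"] - min(scale)) / (max(scale) - min(scale))))
  # clipping contract on arbitrary sequences
  s <- random_windows(1L, seed = 71L)$sequence
  p <- default_disorder_provider(strrep(s, 5L))
  expect_true(all(p >= 0 & p <= 1))
  expect_length(p, 65L)
})

test_that("encode_all yields the four views deterministically", {
  study <- small_study(effect = 1, seed = 81L, n_proteins = 3L)
  ds <- study_dataset(study)
  ctx <- study_context(study)
  w <- ds$positives[1:4, ]
  e1 <- encode_all(w, ctx, reference = ds)
  e2 <- encode_all(w, ctx, reference = ds)
  expect_identical(e1, e2)
  expect_equal(vapply(e1, ncol, integer(1)),
               c(DS = 13L, KNNS = 5L, AAOF = 20L, PWAAC = 5L))
  expect_equal(sum(vapply(e1, ncol, integer(1))), 43L)

  # changing residues only upstream of the center leaves PWAAC unchanged
  # but moves AAOF
  w1 <- as_windows("AAAAAASGGGGGG")
  w2 <- as_windows("CCCCCCSGGGGGG")
  g <- default_attribute_grouping()
  expect_equal(encode_pwaac(w1, g), encode_pwaac(w2, g))
  expect_false(isTRUE(all.equal(encode_aaof(w1), encode_aaof(w2))))
})
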