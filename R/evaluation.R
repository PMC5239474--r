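# Intuitive-form performance metrics, stratified five-fold cross-validation,
# the balanced ten-group protocol for the ~10:1 negative majority, and
# ROC/AUC reporting.

#' Confusion counts in the intuitive notation
#'
#' `n_pos` / `n_neg` are the total true- and false-phosphorylation samples;
#' `fn` is the number of positives predicted negative, `fp` the number of
#' negatives predicted positive.
#'
#' @param n_pos,n_neg,fn,fp non-negative integers with `fn <= n_pos`,
#'   `fp <= n_neg`.
#' @return a `confusion_counts` list.
#' @export
confusion_counts <- function(n_pos, n_neg, fn, fp) {
  stopifnot(n_pos >= 0, n_neg >= 0, fn >= 0, fp >= 0, fn <= n_pos, fp <= n_neg)
  structure(list(n_pos = as.numeric(n_pos), n_neg = as.numeric(n_neg),
                 fn = as.numeric(fn), fp = as.numeric(fp)),
            class = "confusion_counts")
}

# Counts from parallel 0/1 label and call vectors.
counts_from_calls <- function(labels, calls) {
  confusion_counts(n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
                   fn = sum(labels == 1L & calls == 0L),
                   fp = sum(labels == 0L & calls == 1L))
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' Uses the intuitive formulation: `Sn = 1 - fn/n_pos`, `Sp = 1 - fp/n_neg`,
#' `Acc = 1 - (fn + fp)/(n_pos + n_neg)`, and
#' `MCC = (1 - (fn/n_pos + fp/n_neg)) /
#'   sqrt((1 + (fp - fn)/n_pos) * (1 + (fn - fp)/n_neg))`,
#' algebraically equal to the standard Matthews correlation coefficient.
#' When a factor under the radical is zero (one class predicted uniformly),
#' the MCC is reported as undefined (`NA` with `mcc_defined = FALSE`),
#' never silently as 0.
#'
#' @param counts a [confusion_counts()].
#' @return a `metrics_report` list with `sn`, `sp`, `acc`, `mcc`,
#'   `mcc_defined`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  np <- counts$n_pos; nn <- counts$n_neg
  fn <- counts$fn; fp <- counts$fp
  if (np <= 0 || nn <= 0) stop("both classes must be non-empty")
  sn <- 1 - fn / np
  sp <- 1 - fp / nn
  acc <- 1 - (fn + fp) / (np + nn)
  rad <- (1 + (fp - fn) / np) * (1 + (fn - fp) / nn)
  if (rad <= 0) {
    mcc <- NA_real_; defined <- FALSE
  } else {
    mcc <- (1 - (fn / np + fp / nn)) / sqrt(rad)
    defined <- TRUE
  }
  structure(list(sn = sn, sp = sp, acc = acc, mcc = mcc,
                 mcc_defined = defined, counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Sn = %.2f%%, Sp = %.2f%%, Acc = %.2f%%, MCC = %s\n",
              100 * x$sn, 100 * x$sp, 100 * x$acc,
              if (x$mcc_defined) sprintf("%.4f", x$mcc) else "undefined"))
  invisible(x)
}

#' Stratified k-fold partition of a labeled dataset
#'
#' Rows of `dataset_frame(dataset)` (positives first, then negatives) are
#' split into `k` disjoint folds; within each class the fold sizes differ by
#' at most one. Deterministic under a fixed seed.
#'
#' @param dataset a `labeled_dataset`.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return a `fold_partition`: list of `k` integer index vectors plus the
#'   seed.
#' @export
make_folds <- function(dataset, k = 5L, seed = 1L) {
  np <- nrow(dataset$positives); nn <- nrow(dataset$negatives)
  if (np < k || nn < k) {
    stop("each class needs at least k = ", k, " members (have ", np, "+, ",
         nn, "-)")
  }
  assign_class <- function(n, offset, seed_off) {
    perm <- with_seed(seed + seed_off, sample.int(n))
    split(perm + offset, rep(seq_len(k), length.out = n))
  }
  pos_folds <- assign_class(np, 0L, 101L)
  neg_folds <- assign_class(nn, np, 211L)
  folds <- lapply(seq_len(k), function(i) {
    sort(c(pos_folds[[i]], neg_folds[[i]]))
  })
  structure(list(folds = folds, k = k, seed = seed), class = "fold_partition")
}

# Labeled dataset from a subset of dataset_frame rows.
subset_dataset <- function(dataset, rows) {
  df <- dataset_frame(dataset)
  sub <- df[rows, , drop = FALSE]
  pos <- sub[sub$label == 1L, setdiff(names(sub), "label"), drop = FALSE]
  neg <- sub[sub$label == 0L, setdiff(names(sub), "label"), drop = FALSE]
  rownames(pos) <- rownames(neg) <- NULL
  structure(list(positives = pos, negatives = neg,
                 center_type = dataset$center_type, xi = dataset$xi,
                 report = list(n_positive = nrow(pos), n_negative = nrow(neg),
                               duplicates_removed = 0L,
                               conflicts_resolved = 0L)),
            class = "labeled_dataset")
}

#' Stratified five-fold cross-validation of the ensemble
#'
#' Each fold is held out in turn; the model (including the KNNS neighbor
#' pool, which is restricted to the training folds so no test label can
#' leak into the encoding) is trained on the remaining folds and applied to
#' the held-out windows. Both the mean over fold metrics (the convention
#' used for headline figures) and the metrics pooled over all held-out
#' predictions are returned.
#'
#' @param dataset a (typically balanced) `labeled_dataset`.
#' @param context an [encoder_context()] covering the dataset's proteins.
#' @param specs per-view [forest_spec()]s.
#' @param seed integer seed driving the fold partition.
#' @param k number of folds (default 5).
#' @param ties tie mode for [predict_ensemble()] (default deterministic, so
#'   reports are reproducible byte-for-byte).
#' @return a `cv_report`: `fold_metrics` (one row per fold), `mean` and
#'   `pooled` `metrics_report`s, `mean_auc`, `pooled_auc`, and the pooled
#'   per-window `predictions`.
#' @export
cross_validate <- function(dataset, context, specs = default_forest_specs(),
                           seed = 1L, k = 5L,
                           ties = c("deterministic", "random")) {
  ties <- match.arg(ties)
  part <- make_folds(dataset, k = k, seed = seed)
  df <- dataset_frame(dataset)
  fold_rows <- list()
  preds <- list()
  for (i in seq_len(k)) {
    test_idx <- part$folds[[i]]
    train_set <- subset_dataset(dataset, setdiff(seq_len(nrow(df)), test_idx))
    model <- train_ensemble(train_set, context, specs)
    test <- df[test_idx, , drop = FALSE]
    votes <- predict_ensemble(model, test, ties = ties, tie_seed = seed + i)
    m <- compute_metrics(counts_from_calls(test$label, votes$call))
    auc <- roc_curve(test$label, votes$fused_score)$auc
    fold_rows[[i]] <- data.frame(fold = i, n_test = nrow(test),
                                 sn = m$sn, sp = m$sp, acc = m$acc,
                                 mcc = m$mcc, auc = auc)
    preds[[i]] <- data.frame(fold = i, label = test$label,
                             call = votes$call,
                             fused_score = votes$fused_score)
  }
  fold_metrics <- do.call(rbind, fold_rows)
  pred <- do.call(rbind, preds)
  mean_metrics <- list(sn = mean(fold_metrics$sn), sp = mean(fold_metrics$sp),
                       acc = mean(fold_metrics$acc),
                       mcc = mean(fold_metrics$mcc),
                       mcc_defined = !anyNA(fold_metrics$mcc))
  pooled <- compute_metrics(counts_from_calls(pred$label, pred$call))
  structure(list(fold_metrics = fold_metrics, mean = mean_metrics,
                 pooled = pooled,
                 mean_auc = mean(fold_metrics$auc),
                 pooled_auc = roc_curve(pred$label, pred$fused_score)$auc,
                 predictions = pred, seed = seed, k = k),
            class = "cv_report")
}

#' Split negatives into about-equal groups
#'
#' @param dataset a `labeled_dataset`.
#' @param n_groups number of groups (default 10).
#' @param seed integer seed.
#' @return list of `n_groups` integer vectors indexing
#'   `dataset$negatives`; sizes differ by at most one.
#' @export
split_negative_groups <- function(dataset, n_groups = 10L, seed = 1L) {
  nn <- nrow(dataset$negatives)
  if (nn < n_groups) stop("need at least ", n_groups, " negatives, have ", nn)
  perm <- with_seed(seed + 307L, sample.int(nn))
  unname(split(perm, rep(seq_len(n_groups), length.out = nn)))
}

#' Balanced evaluation of an imbalanced dataset
#'
#' The negative subset (about ten times the positive subset in typical
#' phosphoproteome data) is split into `n_groups` seeded groups of
#' near-equal size. Each group is paired with the full positive subset to
#' form an approximately balanced dataset, which is evaluated by
#' [cross_validate()]; the final score is the mean over the `n_groups`
#' per-run means.
#'
#' @param dataset the full imbalanced `labeled_dataset`.
#' @param context an [encoder_context()].
#' @param specs per-view [forest_spec()]s.
#' @param n_groups number of negative groups (default 10).
#' @param seed integer master seed.
#' @param k folds per run (default 5).
#' @return a `balanced_report`: `aggregate` (means over runs), `run_metrics`
#'   (one row per run), `fold_table` (one row per run x fold), `runs` (the
#'   per-run `cv_report`s), `seed`.
#' @export
balanced_evaluation <- function(dataset, context,
                                specs = default_forest_specs(),
                                n_groups = 10L, seed = 1L, k = 5L) {
  groups <- split_negative_groups(dataset, n_groups, seed)
  runs <- vector("list", n_groups)
  run_rows <- fold_rows <- list()
  for (g in seq_len(n_groups)) {
    neg <- dataset$negatives[sort(groups[[g]]), , drop = FALSE]
    rownames(neg) <- NULL
    bal <- structure(list(positives = dataset$positives, negatives = neg,
                          center_type = dataset$center_type, xi = dataset$xi,
                          report = dataset$report),
                     class = "labeled_dataset")
    cv <- cross_validate(bal, context, specs, seed = seed + 1000L * g, k = k)
    runs[[g]] <- cv
    run_rows[[g]] <- data.frame(run = g, n_pos = nrow(bal$positives),
                                n_neg = nrow(neg), sn = cv$mean$sn,
                                sp = cv$mean$sp, acc = cv$mean$acc,
                                mcc = cv$mean$mcc, auc = cv$mean_auc)
    fr <- cv$fold_metrics; fr$run <- g
    fold_rows[[g]] <- fr[c("run", setdiff(names(fr), "run"))]
  }
  run_metrics <- do.call(rbind, run_rows)
  aggregate <- list(sn = mean(run_metrics$sn), sp = mean(run_metrics$sp),
                    acc = mean(run_metrics$acc), mcc = mean(run_metrics$mcc),
                    auc = mean(run_metrics$auc))
  structure(list(aggregate = aggregate, run_metrics = run_metrics,
                 fold_table = do.call(rbind, fold_rows), runs = runs,
                 n_groups = n_groups, seed = seed, k = k),
            class = "balanced_report")
}

#' @export
print.balanced_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf(paste0("balanced_report: %d runs x %d folds; mean Acc = ",
                     "%.2f%%, MCC = %.4f, Sn = %.2f%%, Sp = %.2f%%, ",
                     "AUC = %.4f\n"),
              x$n_groups, x$k, 100 * a$acc, a$mcc, 100 * a$sn, 100 * a$sp,
              a$auc))
  invisible(x)
}

#' ROC curve and area under it
#'
#' Threshold sweep over the unique scores (a site is called positive when
#' its score is at least the threshold); points are (false-positive rate,
#' true-positive rate) and the AUC is computed by the trapezoidal rule.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, higher meaning more positive.
#' @return list with `points` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_curve <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) {
    stop("ROC requires both classes to be present")
  }
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1L) / np,
                numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0L) / nn,
                numeric(1))
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                    threshold = c(Inf, th, -Inf))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Write a layered evaluation report as TSV
#'
#' One row per (run, fold), then one aggregate row per run, then the final
#' aggregate row; fixed numeric formatting so identical evaluations produce
#' byte-identical files.
#'
#' @param report a `balanced_report`.
#' @param path output path.
#' @export
write_evaluation_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("level\trun\tfold\tn_pos\tn_neg\tsn\tsp\tacc\tmcc\tauc", con)
  fmt <- function(x) sprintf("%.6f", x)
  ft <- report$fold_table
  rm_ <- report$run_metrics
  for (i in seq_len(nrow(ft))) {
    r <- rm_[rm_$run == ft$run[i], ]
    writeLines(paste("fold", ft$run[i], ft$fold[i], r$n_pos, r$n_neg,
                     fmt(ft$sn[i]), fmt(ft$sp[i]), fmt(ft$acc[i]),
                     fmt(ft$mcc[i]), fmt(ft$auc[i]), sep = "\t"), con)
  }
  for (i in seq_len(nrow(rm_))) {
    writeLines(paste("run", rm_$run[i], "", rm_$n_pos[i], rm_$n_neg[i],
                     fmt(rm_$sn[i]), fmt(rm_$sp[i]), fmt(rm_$acc[i]),
                     fmt(rm_$mcc[i]), fmt(rm_$auc[i]), sep = "\t"), con)
  }
  a <- report$aggregate
  writeLines(paste("aggregate", "", "", "", "", fmt(a$sn), fmt(a$sp),
                   fmt(a$acc), fmt(a$mcc), fmt(a$auc), sep = "\t"), con)
  invisible(path)
}

#' Write ROC points as a two-column TSV
#'
#' @param roc list from [roc_curve()].
#' @param path output path.
#' @export
write_roc_points <- function(roc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("fpr\ttpr", con)
  writeLines(sprintf("%.6f\t%.6f", roc$points$fpr, roc$points$tpr), con)
  invisible(path)
}
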