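# Four view-specific random forests fused by majority vote. Each forest is
# trained on its own view's encodings of the same windows; a query is
# predicted by all four and called a phosphosite when more than two views
# vote positive. A 2-2 tie is resolved by a seeded random pick (the default)
# or, in deterministic mode, by thresholding the fused score at 0.5.

VIEWS <- c("DS", "KNNS", "AAOF", "PWAAC")
MODEL_FORMAT_VERSION <- 1L

#' Specification of one view's random forest
#'
#' @param view one of "DS", "KNNS", "AAOF", "PWAAC".
#' @param tree_count number of trees (default 100).
#' @param max_depth optional depth cap (default unlimited).
#' @param seed integer seed for this forest.
#' @return a `forest_spec` list.
#' @export
forest_spec <- function(view, tree_count = 100L, max_depth = NULL, seed = 1L) {
  view <- match.arg(view, VIEWS)
  stopifnot(tree_count >= 1L)
  structure(list(view = view, tree_count = as.integer(tree_count),
                 max_depth = if (is.null(max_depth)) 0L else as.integer(max_depth),
                 seed = as.integer(seed)),
            class = "forest_spec")
}

#' Default per-view forest specifications
#'
#' One spec per view; each view's seed is derived from the master seed by a
#' fixed offset so the whole ensemble is reproducible from one integer.
#'
#' @param master_seed integer master seed.
#' @param tree_count trees per forest.
#' @param max_depth optional shared depth cap.
#' @return named list of four [forest_spec()]s.
#' @export
default_forest_specs <- function(master_seed = 1L, tree_count = 100L,
                                 max_depth = NULL) {
  offs <- c(DS = 11L, KNNS = 13L, AAOF = 17L, PWAAC = 19L)
  stats::setNames(lapply(VIEWS, function(v) {
    forest_spec(v, tree_count, max_depth, seed = master_seed + offs[[v]])
  }), VIEWS)
}

train_one_forest <- function(X, labels, spec) {
  d <- as.data.frame(X)
  colnames(d) <- paste0("f", seq_len(ncol(d)))
  d$.label <- factor(labels, levels = c(0L, 1L))
  ranger::ranger(dependent.variable.name = ".label", data = d,
                 num.trees = spec$tree_count, max.depth = spec$max_depth,
                 probability = TRUE, seed = spec$seed, num.threads = 1L,
                 respect.unordered.factors = "order")
}

forest_prob <- function(forest, X) {
  d <- as.data.frame(X)
  colnames(d) <- paste0("f", seq_len(ncol(d)))
  p <- stats::predict(forest, data = d, num.threads = 1L)$predictions
  as.numeric(p[, "1"])
}

#' Train the four-view ensemble
#'
#' Encodes the dataset's windows under the four views (the KNNS view uses
#' the training windows themselves as the neighbor pool, with each window
#' excluded from its own neighbor list) and fits one probability random
#' forest per view.
#'
#' @param dataset a balanced `labeled_dataset` with at least one window in
#'   each class (balancing is the caller's job; see
#'   [balanced_evaluation()]).
#' @param context an [encoder_context()] whose profiles cover the dataset's
#'   proteins.
#' @param specs named list of four [forest_spec()]s (default
#'   [default_forest_specs()]).
#' @param sequences optional named sequences for on-the-fly disorder
#'   profiles.
#' @return an `ensemble_model`.
#' @export
train_ensemble <- function(dataset, context, specs = default_forest_specs(),
                           sequences = NULL) {
  df <- dataset_frame(dataset)
  if (sum(df$label == 1L) == 0L || sum(df$label == 0L) == 0L) {
    stop("training dataset must contain both classes")
  }
  stopifnot(setequal(names(specs), VIEWS))
  enc <- encode_all(df, context, reference = dataset, sequences = sequences,
                    self_index = seq_len(nrow(df)))
  forests <- stats::setNames(lapply(VIEWS, function(v) {
    train_one_forest(enc[[v]], df$label, specs[[v]])
  }), VIEWS)
  structure(list(
    forests = forests, context = context, reference = dataset,
    specs = specs, center_type = dataset$center_type, xi = dataset$xi,
    meta = list(n_positive = nrow(dataset$positives),
                n_negative = nrow(dataset$negatives),
                trained = TRUE)),
    class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf(paste0("ensemble_model (%s, xi = %d): 4 forests (%s), trained ",
                     "on %d+/%d- windows\n"),
              x$center_type, x$xi, paste(VIEWS, collapse = "/"),
              x$meta$n_positive, x$meta$n_negative))
  invisible(x)
}

#' Fuse four per-view positive-class probabilities into an ensemble call
#'
#' A view votes positive when its probability is at least 0.5. The fused
#' call is positive when more than two of the four views vote positive; the
#' fused score is the arithmetic mean of the four probabilities. A 2-2 tie
#' is resolved by a seeded uniform pick between the two labels
#' (`ties = "random"`) or by thresholding the fused score at 0.5
#' (`ties = "deterministic"`).
#'
#' @param probs numeric matrix with one row per sample and four columns of
#'   per-view positive-class probabilities.
#' @param ties tie-resolution mode.
#' @param tie_seed integer seed for the random mode.
#' @return list with `call` (0/1), `fused_score`, `n_pos_votes`,
#'   `tie_broken`.
#' @export
fuse_votes <- function(probs, ties = c("random", "deterministic"),
                       tie_seed = 1L) {
  ties <- match.arg(ties)
  probs <- matrix(probs, ncol = 4L)
  stopifnot(all(probs >= 0 & probs <= 1))
  n_pos_votes <- rowSums(probs >= 0.5)
  fused <- rowMeans(probs)
  call <- as.integer(n_pos_votes > 2L)
  tie <- n_pos_votes == 2L
  if (any(tie)) {
    if (ties == "random") {
      call[tie] <- with_seed(tie_seed, stats::rbinom(sum(tie), 1L, 0.5))
    } else {
      call[tie] <- as.integer(fused[tie] >= 0.5)
    }
  }
  list(call = call, fused_score = fused, n_pos_votes = n_pos_votes,
       tie_broken = tie)
}

#' Predict a set of windows with the ensemble
#'
#' Each window is encoded under the four views and scored by the four
#' forests. A view votes positive when its positive-class probability is at
#' least 0.5. The fused call is positive when more than two views vote
#' positive; a 2-2 tie is resolved randomly between the two labels
#' (`ties = "random"`, seeded by `tie_seed`) or by thresholding the fused
#' score — the mean of the four probabilities — at 0.5
#' (`ties = "deterministic"`).
#'
#' @param model an `ensemble_model`.
#' @param windows peptide-window data.frame with the model's center type.
#' @param sequences optional named sequences for on-the-fly disorder
#'   profiles.
#' @param ties tie-resolution mode.
#' @param tie_seed integer seed for random tie resolution.
#' @param self_index passed to [encode_knns()] when scoring windows that are
#'   themselves reference members.
#' @return data.frame with per-view probabilities (`prob_DS`, ...), per-view
#'   votes, `fused_score`, `call` (0/1), and `tie_broken`.
#' @export
predict_ensemble <- function(model, windows, sequences = NULL,
                             ties = c("random", "deterministic"),
                             tie_seed = 1L, self_index = NULL) {
  ties <- match.arg(ties)
  if (nrow(windows) && !all(windows$center_type == model$center_type)) {
    stop("window center type does not match the model's type '",
         model$center_type, "'")
  }
  enc <- encode_all(windows, model$context, reference = model$reference,
                    sequences = sequences, self_index = self_index)
  probs <- vapply(VIEWS, function(v) forest_prob(model$forests[[v]], enc[[v]]),
                  numeric(nrow(windows)))
  probs <- matrix(probs, nrow = nrow(windows), ncol = 4L,
                  dimnames = list(NULL, VIEWS))
  f <- fuse_votes(probs, ties = ties, tie_seed = tie_seed)
  votes <- probs >= 0.5
  out <- data.frame(protein_id = windows$protein_id,
                    center_position = windows$center_position,
                    fused_score = f$fused_score, call = f$call,
                    tie_broken = f$tie_broken)
  for (v in VIEWS) {
    out[[paste0("prob_", v)]] <- probs[, v]
    out[[paste0("vote_", v)]] <- as.integer(votes[, v])
  }
  out
}

#' Scan one protein and report predicted phosphosites
#'
#' Extracts every window centered on the model's residue type, predicts each
#' and returns the candidate count plus the 1-based positions called
#' positive, ascending.
#'
#' @param model an `ensemble_model`.
#' @param protein_sequence protein sequence (normalized internally).
#' @param protein_id identifier for the report.
#' @param profile optional per-residue disorder scores; computed by the
#'   context's provider when absent.
#' @param ties,tie_seed see [predict_ensemble()].
#' @return list with `protein_id`, `center_type`, `n_candidates`,
#'   `positions` (predicted positive), and the per-site `table`.
#' @export
predict_protein <- function(model, protein_sequence, protein_id = "query",
                            profile = NULL,
                            ties = c("random", "deterministic"),
                            tie_seed = 1L) {
  ties <- match.arg(ties)
  seq <- normalize_sequence(protein_sequence)
  cfg <- window_config(model$xi, model$center_type)
  wins <- extract_windows(seq, cfg, protein_id = protein_id)
  if (nrow(wins) == 0L) {
    return(list(protein_id = protein_id, center_type = model$center_type,
                n_candidates = 0L, positions = integer(0),
                table = data.frame()))
  }
  ctx <- model$context
  if (!is.null(profile)) ctx$profiles[[protein_id]] <- pmin(pmax(profile, 0), 1)
  model$context <- ctx
  seqs <- stats::setNames(list(seq), protein_id)
  votes <- predict_ensemble(model, wins, sequences = seqs, ties = ties,
                            tie_seed = tie_seed)
  list(protein_id = protein_id, center_type = model$center_type,
       n_candidates = nrow(wins),
       positions = sort(wins$center_position[votes$call == 1L]),
       table = cbind(wins[c("protein_id", "center_position", "center_type")],
                     votes[c("fused_score", "call")]))
}

#' Save an ensemble model archive
#'
#' Single-file bundle (RDS) holding the four forests, the encoder context,
#' the KNNS reference windows, the specs and a format version.
#' [load_model()] refuses archives with a different format version.
#'
#' @param model an `ensemble_model`.
#' @param path archive path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format_version = MODEL_FORMAT_VERSION, model = model), path)
  invisible(path)
}

#' Load an ensemble model archive
#'
#' @param path archive written by [save_model()].
#' @return the `ensemble_model`.
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format_version, MODEL_FORMAT_VERSION)) {
    stop("model archive format version ", x$format_version,
         " does not match supported version ", MODEL_FORMAT_VERSION)
  }
  x$model
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
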