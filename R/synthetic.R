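# Synthetic annotated proteomes with a controllable, plantable
# phospho-signal. The generator exists to validate the machinery (encoders,
# ensemble, evaluation protocol) end-to-end without any download; it makes
# no attempt to mimic real phosphosite motif statistics.

#' Signal model for the synthetic generator
#'
#' Signal is injected into both channels the feature views can see: residue
#' composition around planted sites (motif bias, drawn per position with
#' probability `effect_strength`) and intrinsic disorder (an additive
#' elevation near planted sites, emulating the known enrichment of
#' phosphosites in disordered regions). At `effect_strength = 0` the
#' neighborhoods are exactly the background process.
#'
#' @param effect_strength scalar in \[0, 1\]: 0 is pure background (null),
#'   1 is full motif bias.
#' @param upstream_motif,downstream_motif named probability vectors over
#'   residues used (after scaling by `effect_strength`) for upstream /
#'   downstream window slots around planted sites. The defaults use
#'   disjoint, center-type-free alphabets (upstream R/K, downstream P/E/D)
#'   so that composition, position-weighted and neighbor-score views all
#'   receive recoverable signal; downstream bias matters because the
#'   position-weighted view only weights downstream slots.
#' @param disorder_shift additive disorder elevation (scaled by
#'   `effect_strength`) applied within +/-10 residues of a planted site.
#' @param background named probability vector over the 20 standard letters
#'   (default uniform 1/20).
#' @return a `signal_model` list.
#' @export
signal_model <- function(effect_strength = 1,
                         upstream_motif = c(R = 0.5, K = 0.5),
                         downstream_motif = c(P = 0.4, E = 0.3, D = 0.3),
                         disorder_shift = 0.3,
                         background = stats::setNames(rep(1 / 20, 20),
                                                      AA_STANDARD)) {
  stopifnot(effect_strength >= 0, effect_strength <= 1,
            abs(sum(background) - 1) < 1e-9,
            abs(sum(upstream_motif) - 1) < 1e-9,
            abs(sum(downstream_motif) - 1) < 1e-9)
  structure(list(effect_strength = effect_strength,
                 upstream_motif = upstream_motif,
                 downstream_motif = downstream_motif,
                 disorder_shift = disorder_shift,
                 background = background),
            class = "signal_model")
}

#' Generate a synthetic annotated proteome
#'
#' Proteins are drawn residue-by-residue from the background distribution.
#' Candidate anchors are laid out every `2*xi + 1` residues away from the
#' termini; each anchor is planted as a positive site with probability
#' `sites_per_protein_rate`. The center-type letter's background frequency
#' at non-anchor positions is tuned so the realized negative:positive ratio
#' lands near `neg_pos_ratio_target` (an error is raised if it misses by
#' more than 20%). Around each planted site, each of the `2*xi` flanking
#' residues is replaced by a motif draw with probability `effect_strength`,
#' and the disorder profile (built by [default_disorder_provider()]) is
#' raised by `disorder_shift * effect_strength` within +/-10 residues.
#' Regeneration with the same seed is byte-identical.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer c(min, max); minimum length 50.
#' @param sites_per_protein_rate per-anchor planting probability in (0, 1).
#' @param model a [signal_model()].
#' @param center_type "S", "T" or "Y".
#' @param neg_pos_ratio_target desired negatives per positive (default 10).
#' @param seed integer seed.
#' @param xi window half-width used to space anchors (default 6).
#' @return a `synthetic_study`: `proteins` (named sequences), `annotations`
#'   (data.frame), `profiles` (disorder), `truth` (planted-site table),
#'   `realized_ratio`, `seed`, `model`.
#' @export
generate_synthetic_study <- function(n_proteins, length_range = c(200L, 400L),
                                     sites_per_protein_rate = 0.2,
                                     model = signal_model(),
                                     center_type = c("S", "T", "Y"),
                                     neg_pos_ratio_target = 10,
                                     seed = 1L, xi = 6L) {
  center_type <- match.arg(center_type)
  stopifnot(n_proteins >= 1L, length_range[1] >= 50L,
            length_range[1] <= length_range[2],
            sites_per_protein_rate > 0, sites_per_protein_rate < 1,
            neg_pos_ratio_target > 0)
  width <- 2L * xi + 1L
  bg_other <- model$background[setdiff(names(model$background), center_type)]
  bg_other <- bg_other / sum(bg_other)
  with_seed(seed, {
    lengths <- sample(seq(length_range[1], length_range[2]), n_proteins,
                      replace = TRUE)
    anchors <- lapply(lengths, function(L) seq(xi + 1L, L - xi, by = width))
    planted <- lapply(anchors, function(a) {
      a[stats::runif(length(a)) < sites_per_protein_rate]
    })
    n_planted <- sum(lengths(planted))
    if (n_planted == 0L) {
      stop("no sites planted; increase n_proteins, lengths or the site rate")
    }
    n_other <- sum(lengths) - n_planted
    p_center <- n_planted * neg_pos_ratio_target / n_other
    if (p_center > 0.5) {
      stop("infeasible combination: would need center-residue frequency ",
           round(p_center, 2), " to reach the requested ratio")
    }
    ids <- sprintf("SYN%04d", seq_len(n_proteins))
    proteins <- character(n_proteins)
    profiles <- vector("list", n_proteins)
    truth <- list()
    e <- model$effect_strength
    for (i in seq_len(n_proteins)) {
      L <- lengths[i]
      chars <- sample(names(bg_other), L, replace = TRUE, prob = bg_other)
      is_center <- stats::runif(L) < p_center
      is_center[planted[[i]]] <- TRUE
      chars[is_center] <- center_type
      # motif bias never overwrites a center-type letter: candidate residues
      # keep their background rate inside positive neighborhoods, so the
      # realized class ratio stays on target and the null case (e = 0) is
      # exactly the background process
      for (p in planted[[i]]) {
        for (j in c(seq(-xi, -1L), seq(1L, xi))) {
          if (e > 0 && chars[p + j] != center_type && stats::runif(1) < e) {
            motif <- if (j < 0) model$upstream_motif else model$downstream_motif
            chars[p + j] <- sample(names(motif), 1L, prob = motif)
          }
        }
      }
      seqv <- paste(chars, collapse = "")
      prof <- default_disorder_provider(seqv)
      for (p in planted[[i]]) {
        lo <- max(1L, p - 10L); hi <- min(L, p + 10L)
        prof[lo:hi] <- prof[lo:hi] + model$disorder_shift * e
      }
      proteins[i] <- seqv
      profiles[[i]] <- pmin(pmax(prof, 0), 1)
      if (length(planted[[i]])) {
        truth[[length(truth) + 1L]] <-
          data.frame(protein_id = ids[i], position = planted[[i]],
                     residue = center_type)
      }
    }
  })
  names(proteins) <- names(profiles) <- ids
  truth <- do.call(rbind, truth)
  ann <- do.call(rbind, lapply(seq_len(n_proteins), function(i) {
    pos <- which(strsplit(proteins[i], "", fixed = TRUE)[[1]] == center_type)
    data.frame(protein_id = ids[i], position = pos, residue = center_type,
               label = as.integer(pos %in%
                                    truth$position[truth$protein_id == ids[i]]))
  }))
  rownames(ann) <- NULL
  n_pos <- sum(ann$label == 1L); n_neg <- sum(ann$label == 0L)
  ratio <- n_neg / n_pos
  if (abs(ratio - neg_pos_ratio_target) > 0.2 * neg_pos_ratio_target) {
    stop("realized negative:positive ratio ", round(ratio, 2),
         " misses the target ", neg_pos_ratio_target, " by more than 20%; ",
         "adjust the generator settings")
  }
  structure(list(proteins = proteins, annotations = ann, profiles = profiles,
                 truth = truth, realized_ratio = ratio, seed = seed,
                 center_type = center_type, xi = xi, model = model),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("synthetic_study (%s): %d proteins, %d planted sites, ",
                     "neg:pos ratio %.2f, effect strength %.2f\n"),
              x$center_type, length(x$proteins), nrow(x$truth),
              x$realized_ratio, x$model$effect_strength))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits the exact dialects the builders consume: `proteins.fasta`,
#' `annotations.tsv`, `disorder.tsv`, plus `truth.tsv`.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_proteins(study$proteins, file.path(dir, "proteins.fasta"))
  write_annotations(study$annotations, file.path(dir, "annotations.tsv"))
  write_disorder_scores(study$profiles, file.path(dir, "disorder.tsv"))
  con <- file(file.path(dir, "truth.tsv"), "w")
  writeLines("protein_id\tposition\tresidue", con)
  writeLines(sprintf("%s\t%d\t%s", study$truth$protein_id,
                     study$truth$position, study$truth$residue), con)
  close(con)
  invisible(dir)
}

#' The web-report worked example as a fixture
#'
#' A three-protein scan (one protein per phosphorylation type, with 11, 11
#' and 12 candidate residues) yields 7 true sites of which 1 is missed and
#' 27 non-sites of which 4 are falsely called. Returns those confusion
#' counts together with the metric values they imply, as printed:
#' Sn = 85.71%, Sp = 85.19%, Acc = 85.29%, MCC = 0.6292.
#'
#' @return list with `counts` (a [confusion_counts()]), `expected` (printed
#'   metric values; sn/sp/acc in percent), and `per_type` (the per-protein
#'   breakdown).
#' @export
worked_example_fixture <- function() {
  list(
    counts = confusion_counts(n_pos = 7, n_neg = 27, fn = 1, fp = 4),
    expected = list(sn = 85.71, sp = 85.19, acc = 85.29, mcc = 0.6292),
    per_type = data.frame(
      type = c("S", "T", "Y"),
      n_candidates = c(11L, 11L, 12L),
      n_true_sites = c(3L, 2L, 2L),
      predicted_positive = c(2L, 5L, 3L)))
}
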