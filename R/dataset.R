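# Benchmark-dataset construction: slide a (2*xi+1)-residue window along each
# protein, keep windows centered on the candidate residue type, pad windows
# that overrun a terminus by replicating the terminal residue, split into
# positive (annotated) and negative subsets, and deduplicate.

#' Window configuration
#'
#' @param xi non-negative integer half-width; the window spans `2*xi + 1`
#'   residues. Default 6 (13-residue windows).
#' @param center_type candidate residue type, one of "S", "T", "Y".
#' @return a `window_config` list.
#' @export
window_config <- function(xi = 6L, center_type = c("S", "T", "Y")) {
  center_type <- match.arg(center_type)
  xi <- as.integer(xi)
  stopifnot(length(xi) == 1L, xi >= 0L)
  structure(list(xi = xi, center_type = center_type), class = "window_config")
}

#' @export
print.window_config <- function(x, ...) {
  cat(sprintf("window_config: center %s, xi = %d (length %d)\n",
              x$center_type, x$xi, 2L * x$xi + 1L))
  invisible(x)
}

#' Extract the padded window around one residue
#'
#' Slots that fall before the first or after the last residue are filled by
#' replicating the nearest existing residue toward that terminus, i.e. the
#' terminal residue is repeated, independently per side.
#'
#' @param protein_sequence normalized protein sequence.
#' @param center_index 1-based position of the center residue.
#' @param xi window half-width.
#' @return character scalar of length `2*xi + 1`.
#' @export
pad_window <- function(protein_sequence, center_index, xi) {
  L <- nchar(protein_sequence)
  stopifnot(center_index >= 1L, center_index <= L)
  idx <- pmin(pmax(seq(center_index - xi, center_index + xi), 1L), L)
  paste(strsplit(protein_sequence, "", fixed = TRUE)[[1]][idx], collapse = "")
}

# Zero-row peptide-window frame with the canonical columns.
empty_windows <- function() {
  data.frame(sequence = character(0), protein_id = character(0),
             center_position = integer(0), center_type = character(0),
             padded_left = integer(0), padded_right = integer(0))
}

#' Extract all candidate windows from one protein
#'
#' One window per occurrence of the configured center residue, in increasing
#' position order; windows overrunning a terminus are padded per
#' [pad_window()].
#'
#' @param protein_sequence normalized amino-acid string.
#' @param config a [window_config()].
#' @param protein_id identifier recorded in the output.
#' @return data.frame with columns `sequence`, `protein_id`,
#'   `center_position`, `center_type`, `padded_left`, `padded_right`.
#' @export
extract_windows <- function(protein_sequence, config = window_config(),
                            protein_id = "protein") {
  if (!is.character(protein_sequence) || length(protein_sequence) != 1L ||
      nchar(protein_sequence) == 0L) {
    stop("protein_sequence must be a non-empty string")
  }
  xi <- config$xi
  L <- nchar(protein_sequence)
  chars <- strsplit(protein_sequence, "", fixed = TRUE)[[1]]
  centers <- which(chars == config$center_type)
  if (length(centers) == 0L) return(empty_windows())
  seqs <- vapply(centers, function(p) {
    idx <- pmin(pmax(seq(p - xi, p + xi), 1L), L)
    paste(chars[idx], collapse = "")
  }, character(1))
  data.frame(sequence = seqs, protein_id = protein_id,
             center_position = centers, center_type = config$center_type,
             padded_left = pmax(xi - (centers - 1L), 0L),
             padded_right = pmax(centers + xi - L, 0L))
}

#' Build a labeled window dataset from proteins and site annotations
#'
#' Every occurrence of the center residue yields a window; windows whose
#' center is annotated positive go to the positive subset, all other
#' occurrences to the negative subset. Within each class, duplicate window
#' sequences are collapsed to one representative; a sequence appearing in
#' both classes is kept as positive only (experimentally asserted labels
#' win).
#'
#' @param proteins named character vector of normalized sequences.
#' @param annotations data.frame as from [read_annotations()]; only rows
#'   with `label == 1` and `residue == config$center_type` mark positives.
#' @param config a [window_config()].
#' @return a `labeled_dataset`: list with `positives`, `negatives` (window
#'   data.frames), `center_type`, `xi`, and a `report` of construction
#'   counts.
#' @export
build_dataset <- function(proteins, annotations, config = window_config()) {
  stopifnot(!is.null(names(proteins)))
  type <- config$center_type
  ann <- annotations[annotations$residue == type & annotations$label == 1L, ,
                     drop = FALSE]
  # every positive annotation must resolve to a matching residue
  for (i in seq_len(nrow(ann))) {
    id <- ann$protein_id[i]; p <- ann$position[i]
    if (!id %in% names(proteins)) {
      stop("annotation names unknown protein '", id, "'")
    }
    res <- substr(proteins[[id]], p, p)
    if (res != ann$residue[i]) {
      stop("annotation mismatch in protein '", id, "' at position ", p,
           ": sequence has '", res, "', annotation says '", ann$residue[i], "'")
    }
  }
  wins <- do.call(rbind, lapply(names(proteins), function(id) {
    extract_windows(proteins[[id]], config, protein_id = id)
  }))
  if (is.null(wins)) wins <- empty_windows()
  key <- paste(wins$protein_id, wins$center_position)
  pos_key <- paste(ann$protein_id, ann$position)
  is_pos <- key %in% pos_key
  pos_raw <- wins[is_pos, , drop = FALSE]
  neg_raw <- wins[!is_pos, , drop = FALSE]
  pos <- pos_raw[!duplicated(pos_raw$sequence), , drop = FALSE]
  neg <- neg_raw[!duplicated(neg_raw$sequence), , drop = FALSE]
  conflict <- neg$sequence %in% pos$sequence
  neg <- neg[!conflict, , drop = FALSE]
  rownames(pos) <- rownames(neg) <- NULL
  structure(list(
    positives = pos, negatives = neg, center_type = type, xi = config$xi,
    report = list(
      n_positive = nrow(pos), n_negative = nrow(neg),
      duplicates_removed = (nrow(pos_raw) - nrow(pos)) +
        (nrow(neg_raw) - (nrow(neg) + sum(conflict))),
      conflicts_resolved = sum(conflict))),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset (%s, xi = %d): %d positives, %d negatives\n",
              x$center_type, x$xi, nrow(x$positives), nrow(x$negatives)))
  invisible(x)
}

# Stack the two classes into one frame with a 0/1 label column.
dataset_frame <- function(dataset) {
  pos <- dataset$positives; neg <- dataset$negatives
  pos$label <- if (nrow(pos)) 1L else integer(0)
  neg$label <- if (nrow(neg)) 0L else integer(0)
  rbind(pos, neg)
}

#' Write a labeled dataset dump
#'
#' TSV of `window_sequence`, `protein_id`, `center_position`, `label`,
#' prefixed by `#` header lines carrying center type and xi. Round-trips
#' bit-exactly through [read_dataset()].
#'
#' @param dataset a `labeled_dataset`.
#' @param path output path.
#' @export
write_dataset <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# center_type=%s", dataset$center_type),
               sprintf("# xi=%d", dataset$xi),
               "window_sequence\tprotein_id\tcenter_position\tlabel"), con)
  df <- dataset_frame(dataset)
  writeLines(sprintf("%s\t%s\t%d\t%d", df$sequence, df$protein_id,
                     df$center_position, df$label), con)
  invisible(path)
}

#' Read a labeled dataset dump written by [write_dataset()]
#'
#' @param path dump path.
#' @return a `labeled_dataset` (padding counts are reconstructed as 0; they
#'   are not needed once the window strings are fixed).
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  meta <- lines[grepl("^#", lines)]
  type <- sub("^# center_type=", "", meta[grepl("center_type=", meta)])
  xi <- as.integer(sub("^# xi=", "", meta[grepl("xi=", meta)]))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  body <- body[-1L]  # column header
  make <- function(rows) {
    if (length(rows) == 0L) return(empty_windows())
    m <- matrix(unlist(strsplit(rows, "\t", fixed = TRUE)), ncol = 4L,
                byrow = TRUE)
    data.frame(sequence = m[, 1L], protein_id = m[, 2L],
               center_position = as.integer(m[, 3L]), center_type = type,
               padded_left = 0L, padded_right = 0L)
  }
  lab <- as.integer(sub(".*\t", "", body))
  pos <- make(body[lab == 1L]); neg <- make(body[lab == 0L])
  structure(list(positives = pos, negatives = neg, center_type = type,
                 xi = xi,
                 report = list(n_positive = nrow(pos), n_negative = nrow(neg),
                               duplicates_removed = NA_integer_,
                               conflicts_resolved = NA_integer_)),
            class = "labeled_dataset")
}
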