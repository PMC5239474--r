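# Readers and writers for the plain-text formats the package consumes:
# multi-record FASTA, site-annotation TSV, disorder-score TSV, dataset dumps.

#' Read a protein FASTA file
#'
#' Multi-record, wrapped lines allowed. The record id is the description up
#' to the first whitespace. Sequences are normalized with
#' [normalize_sequence()] unless `normalize = FALSE`.
#'
#' @param path FASTA file path.
#' @param normalize map non-standard letters to X (default TRUE).
#' @return named character vector of sequences.
#' @export
read_proteins <- function(path, normalize = TRUE) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate protein ids in ", path)
  }
  if (normalize) seqs <- vapply(seqs, normalize_sequence, character(1))
  seqs
}

#' Write proteins to FASTA
#'
#' @param proteins named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_proteins <- function(proteins, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(proteins)) {
    writeLines(paste0(">", id), con)
    s <- proteins[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a site-annotation table
#'
#' Tab-separated columns: `protein_id`, `position` (1-based), `residue`
#' (S/T/Y), `label` (1 positive, 0 negative). Lines starting with `#` are
#' ignored. A header row naming the four columns is optional.
#'
#' @param path TSV path.
#' @return data.frame with columns protein_id, position, residue, label.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) {
    return(data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0), label = integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(fields[[1]][1]), "protein_id")) {
    fields <- fields[-1L]
    line_no <- line_no[-1L]
  }
  if (length(fields) == 0L) {
    return(data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0), label = integer(0)))
  }
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) {
    stop("malformed annotation line ", line_no[bad[1L]], " in ", path,
         ": expected 4 tab-separated fields")
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  lab <- suppressWarnings(as.integer(m[, 3L + 1L]))
  bad <- which(is.na(pos) | is.na(lab) | !(lab %in% c(0L, 1L)))
  if (length(bad)) {
    stop("malformed annotation line ", line_no[bad[1L]], " in ", path,
         ": position must be an integer and label 0 or 1")
  }
  data.frame(protein_id = m[, 1L], position = pos,
             residue = toupper(m[, 3L]), label = lab)
}

#' Write a site-annotation table
#'
#' @param annotations data.frame as returned by [read_annotations()].
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("protein_id\tposition\tresidue\tlabel", con)
  writeLines(sprintf("%s\t%d\t%s\t%d", annotations$protein_id,
                     annotations$position, annotations$residue,
                     annotations$label), con)
  invisible(path)
}

#' Read per-residue disorder scores
#'
#' Two dialects are accepted:
#' * long TSV with columns `protein_id`, `position`, `score` (header
#'   optional, `#` comments ignored);
#' * one-score-per-line files, one file per protein, read with
#'   `protein_id` taken from the file name (pass `per_protein_id`).
#'
#' Scores are clipped to \[0, 1\].
#'
#' @param path file path.
#' @param per_protein_id if non-NULL, read the one-score-per-line dialect
#'   and attach this protein id.
#' @return named list of numeric score vectors, one per protein.
#' @export
read_disorder_scores <- function(path, per_protein_id = NULL) {
  if (!is.null(per_protein_id)) {
    scores <- as.numeric(readLines(path))
    return(stats::setNames(list(pmin(pmax(scores, 0), 1)), per_protein_id))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(fields[[1]][1]), "protein_id")) fields <- fields[-1L]
  m <- matrix(unlist(fields), ncol = 3L, byrow = TRUE)
  df <- data.frame(protein_id = m[, 1L], position = as.integer(m[, 2L]),
                   score = as.numeric(m[, 3L]))
  out <- lapply(split(df, df$protein_id), function(d) {
    s <- numeric(max(d$position))
    s[d$position] <- d$score
    pmin(pmax(s, 0), 1)
  })
  out[order(names(out))]
}

#' Write disorder profiles as a long TSV
#'
#' @param profiles named list of numeric vectors.
#' @param path output path.
#' @export
write_disorder_scores <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("protein_id\tposition\tscore", con)
  for (id in names(profiles)) {
    s <- profiles[[id]]
    writeLines(sprintf("%s\t%d\t%.6f", id, seq_along(s), s), con)
  }
  invisible(path)
}
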