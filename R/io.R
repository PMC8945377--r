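# Delimited-text readers/writers for modalities, labels and survival tables.
# TSV by default; a ".csv" extension switches to comma separation.

sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Load one modality from a delimited text file
#'
#' The file must have a header row of feature identifiers and a first column
#' of sample identifiers (or the transpose, with
#' `orientation = "samples_in_cols"`). Cells must all be numeric: missing or
#' non-numeric entries are a parse error naming the offending row and column —
#' the loader never imputes.
#'
#' @param path File path (`.tsv`/`.txt` tab-separated, `.csv` comma-separated).
#' @param name Modality label; defaults to the file name without extension.
#' @param orientation `"samples_in_rows"` (default) or `"samples_in_cols"`.
#' @return A [modality_matrix()] with samples in rows.
#' @export
load_modality <- function(path, name = NULL,
                          orientation = c("samples_in_rows", "samples_in_cols")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.table(path, sep = sep_for(path), header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2L) stopf("'%s': need an identifier column plus data", path)
  row_ids <- raw[[1L]]
  if (anyDuplicated(row_ids)) {
    stopf("'%s': duplicate identifiers: %s", path,
          paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) | !is.finite(vals))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(vals))
    stopf("'%s': non-numeric value '%s' at row '%s', column '%s' (missing values must be resolved upstream, not imputed here)",
          path, cells[i[1L], i[2L]], row_ids[i[1L]], colnames(cells)[i[2L]])
  }
  dimnames(vals) <- list(row_ids, colnames(cells))
  if (orientation == "samples_in_cols") vals <- t(vals)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  modality_matrix(name, vals)
}

#' Write one modality to a delimited text file
#'
#' Inverse of [load_modality()]: full double precision is kept so that a
#' write/load round trip reproduces the values.
#'
#' @param mod A [modality_matrix()].
#' @param path Output path (`.csv` for comma-separated, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_modality <- function(mod, path) {
  df <- data.frame(sample_id = rownames(mod),
                   format(unclass(mod), digits = 17, trim = TRUE,
                          scientific = NA),
                  check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(mod))
  utils::write.table(df, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a two-column label table
#'
#' @param path TSV/CSV with columns `sample_id` and `class` (0/1).
#' @return Named integer vector of labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = sep_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("'%s': expected columns sample_id, class", path)
  assert_binary(df[[2L]], "class")
  stats::setNames(as.integer(df[[2L]]), as.character(df[[1L]]))
}

#' Write a label table
#' @param labels Named 0/1 vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), class = as.integer(labels)),
    path, sep = sep_for(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table
#'
#' @param path TSV/CSV with columns `sample_id`, `days`, `event` (0/1).
#' @return Data frame with those three columns.
#' @export
read_survival <- function(path) {
  df <- utils::read.table(path, sep = sep_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("sample_id", "days", "event")
  if (!all(req %in% names(df))) {
    stopf("'%s': expected columns %s", path, paste(req, collapse = ", "))
  }
  if (any(df$days < 0)) stopf("'%s': negative survival days", path)
  assert_binary(df$event, "event")
  df[, req]
}
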