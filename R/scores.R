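#' Read an external per-cell doublet-score table
#'
#' Chord's expandable interface accepts score tables produced by external
#' doublet detectors (e.g. Scrublet, DoubletDetection run outside R). The CSV
#' must have a cell-id column first and one or more numeric score columns;
#' higher scores mean more doublet-like.
#'
#' @param path CSV path.
#' @return A tibble with a `cell_id` column and one numeric column per method.
#' @export
read_external_scores <- function(path) {
  if (!file.exists(path)) abort(paste0("score file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) abort("score table needs a cell-id column and >= 1 score column")
  names(df)[1] <- "cell_id"
  df$cell_id <- as.character(df$cell_id)
  for (col in names(df)[-1]) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      abort(sprintf("score column '%s' is not numeric", col))
    }
    if (anyNA(v)) abort(sprintf("score column '%s' contains NA", col))
  }
  if (anyDuplicated(df$cell_id)) abort("duplicate cell ids in score table")
  tibble::as_tibble(df)
}

#' Align a score table to a set of cell ids
#'
#' Reorders the rows of a score table to match `cell_ids` exactly; any
#' mismatch in membership is an error.
#'
#' @param table Score tibble (`cell_id` + numeric columns).
#' @param cell_ids Character vector of cell ids (e.g. `colnames(counts)`).
#' @return The table reordered to `cell_ids`.
#' @export
align_scores <- function(table, cell_ids) {
  missing <- setdiff(cell_ids, table$cell_id)
  extra <- setdiff(table$cell_id, cell_ids)
  if (length(missing) || length(extra)) {
    abort(sprintf(
      "score table does not match cells: %d cell%s absent, %d extra",
      length(missing), if (length(missing) == 1) "" else "s", length(extra)))
  }
  table[match(cell_ids, table$cell_id), , drop = FALSE]
}

#' Write a score table (and optional doublet calls) to CSV
#'
#' @param table Score tibble (`cell_id` + numeric columns).
#' @param path Output CSV path.
#' @param calls Optional logical vector of doublet calls, written as a 0/1
#'   `is_doublet` column.
#' @return `path`, invisibly.
#' @export
write_scores <- function(table, path, calls = NULL) {
  stopifnot(is.data.frame(table), names(table)[1] == "cell_id")
  out <- table
  # 6 significant digits: enough to preserve rank order for calling
  for (col in names(out)[-1]) out[[col]] <- signif(out[[col]], 6)
  if (!is.null(calls)) {
    stopifnot(length(calls) == nrow(out))
    out$is_doublet <- as.integer(calls)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
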