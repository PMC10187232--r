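#' Per-cell results table
#'
#' The common long-format container for every assay's per-cell measurements:
#' one row per (condition, replicate, cell, metric), with a numeric value.
#' This is the unit consumed by [compare_groups()] and written by each
#' assay's batch driver.
#'
#' @param condition_label Character vector of condition labels.
#' @param replicate_id Replicate identifiers (biological replicate).
#' @param cell_id Cell identifiers, unique within a replicate.
#' @param metric_name Name of the measured quantity (e.g. `"fwhm_um"`).
#' @param value Numeric measurement values.
#' @return A `data.frame` of class `"GroupTable"` with those five columns.
#' @export
group_table <- function(condition_label, replicate_id, cell_id, metric_name,
                        value) {
  df <- data.frame(
    condition_label = as.character(condition_label),
    replicate_id = as.character(replicate_id),
    cell_id = as.character(cell_id),
    metric_name = as.character(metric_name),
    value = as.numeric(value),
    stringsAsFactors = FALSE
  )
  validate_group_table(df)
  class(df) <- c("GroupTable", "data.frame")
  df
}

validate_group_table <- function(df) {
  need <- c("condition_label", "replicate_id", "cell_id", "metric_name",
            "value")
  if (!all(need %in% names(df)))
    stop("GroupTable must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  key <- do.call(paste, c(df[c("condition_label", "replicate_id", "cell_id",
                               "metric_name")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (condition, replicate, cell, metric) rows in GroupTable",
         call. = FALSE)
  invisible(df)
}

#' Write a GroupTable to CSV
#'
#' Columns are written in the fixed order condition_label, replicate_id,
#' cell_id, metric_name, value; [read_results_table()] restores the table
#' losslessly.
#'
#' @param table A [group_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(table, path) {
  validate_group_table(table)
  cols <- c("condition_label", "replicate_id", "cell_id", "metric_name",
            "value")
  utils::write.csv(as.data.frame(table)[, cols, drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a GroupTable CSV written by [write_results_table()]
#'
#' @param path CSV path.
#' @return A `"GroupTable"` data frame.
#' @export
read_results_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(condition_label = "character",
                                       replicate_id = "character",
                                       cell_id = "character",
                                       metric_name = "character",
                                       value = "numeric"))
  validate_group_table(df)
  class(df) <- c("GroupTable", "data.frame")
  df
}

#' Per-cell mitotic event table
#'
#' Records the frames of nuclear envelope breakdown (NEB) and anaphase onset
#' (AO) for each cell in a timing movie. Missing events are `NA`: a cell with
#' NEB but no AO either arrested or was censored by the movie end (see
#' [mitotic_timing()]).
#'
#' @param cell_id Cell identifiers.
#' @param neb_frame Integer NEB frame, or `NA` if the cell never entered
#'   mitosis on camera.
#' @param anaphase_frame Integer AO frame, or `NA`.
#' @param movie_end_frame Integer last frame of each cell's movie.
#' @return A `data.frame` of class `"EventTable"`.
#' @export
event_table <- function(cell_id, neb_frame, anaphase_frame, movie_end_frame) {
  df <- data.frame(
    cell_id = as.character(cell_id),
    neb_frame = as.integer(neb_frame),
    anaphase_frame = as.integer(anaphase_frame),
    movie_end_frame = as.integer(movie_end_frame),
    stringsAsFactors = FALSE
  )
  bad <- !is.na(df$anaphase_frame) & is.na(df$neb_frame)
  if (any(bad))
    stop("anaphase recorded without nuclear envelope breakdown for cell(s): ",
         paste(df$cell_id[bad], collapse = ", "), call. = FALSE)
  bad <- !is.na(df$anaphase_frame) & df$anaphase_frame <= df$neb_frame
  if (any(bad))
    stop("anaphase_frame must be greater than neb_frame (cells: ",
         paste(df$cell_id[bad], collapse = ", "), ")", call. = FALSE)
  over <- function(f) !is.na(f) & f > df$movie_end_frame
  if (any(over(df$neb_frame)) || any(over(df$anaphase_frame)))
    stop("event frames must not exceed movie_end_frame", call. = FALSE)
  class(df) <- c("EventTable", "data.frame")
  df
}

#' Read an event CSV (columns cell_id, neb_frame, anaphase_frame,
#' movie_end_frame) as an EventTable
#' @param path CSV path.
#' @return An [event_table()].
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  event_table(df$cell_id, df$neb_frame, df$anaphase_frame,
              df$movie_end_frame)
}
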