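#' Scenario table input/output (CSV)
#'
#' The scenario series CSV has columns `country_id, year,
#' total_population, urban_share`; the scenario probability matrix CSV
#' has a leading `ssp` column (SSP1..SSP5 or 1..5) and columns
#' `RCP2.6, RCP4.5, RCP6.0, RCP8.5`.  Invariants (shares in `[0, 1]`,
#' totals >= 0) are enforced at load, with the offending row named.
#'
#' @param path CSV file path.
#' @return `read_scenario_csv` a [scenario_series()];
#'   `read_matrix_csv` a [scenario_matrix()].
#' @name csv_io
NULL

#' @rdname csv_io
#' @export
read_scenario_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  scenario_series(df)
}

#' @rdname csv_io
#' @param series a [scenario_series()].
#' @export
write_scenario_csv <- function(series, path) {
  stopifnot(inherits(series, "scenario_series"))
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) != 5L || ncol(df) < 5L)
    stop("scenario matrix CSV must have 5 SSP rows and 4 RCP columns")
  m <- as.matrix(df[, -1L, drop = FALSE][, 1:4])
  scenario_matrix(m)
}

#' @rdname csv_io
#' @param matrix a [scenario_matrix()].
#' @export
write_matrix_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "scenario_matrix"))
  df <- data.frame(ssp = rownames(matrix), unclass(matrix),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
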