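#' Country-level scenario series
#'
#' A `scenario_series` holds, per country and year, the total population
#' and the urban share (fraction of the total living in urban pixels).
#' SSP database releases publish these at multi-year steps; [annualize()]
#' interpolates them to the annual steps the projection loop needs.
#'
#' @param df data frame with columns `country_id` (positive integer),
#'   `year` (integer), `total_population` (>= 0) and `urban_share`
#'   (in `[0, 1]`).
#' @return A `scenario_series` (validated, sorted data frame).
#' @export
scenario_series <- function(df) {
  need <- c("country_id", "year", "total_population", "urban_share")
  if (!all(need %in% names(df)))
    stop("scenario series needs columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$country_id <- as.integer(df$country_id)
  df$year <- as.integer(df$year)
  bad <- which(!is.finite(df$total_population) | df$total_population < 0)
  if (length(bad))
    stop("total_population must be finite and >= 0 (row ", bad[1L], ")")
  bad <- which(!is.finite(df$urban_share) | df$urban_share < 0 | df$urban_share > 1)
  if (length(bad))
    stop("urban_share must lie in [0, 1] (row ", bad[1L], ")")
  if (anyDuplicated(df[c("country_id", "year")]))
    stop("duplicate (country_id, year) entries")
  df <- df[order(df$country_id, df$year), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("scenario_series", "data.frame")
  df
}

#' Interpolate a scenario series to annual steps
#'
#' Linear interpolation per country of both `total_population` and
#' `urban_share` between the provided time steps; years that coincide
#' with an input step reproduce the input exactly.  No extrapolation: a
#' requested year outside a country's span is an error.
#'
#' @param series a [scenario_series()].
#' @param years integer vector of years to produce (default: every year
#'   spanned by the input).
#' @return A `scenario_series` with one row per (country, year).
#' @export
annualize <- function(series, years = NULL) {
  stopifnot(inherits(series, "scenario_series"))
  out <- lapply(split(series, series$country_id), function(d) {
    if (nrow(d) < 2L)
      stop("country ", d$country_id[1L], ": need >= 2 time points to annualize")
    yrs <- if (is.null(years)) seq(min(d$year), max(d$year)) else as.integer(years)
    if (any(yrs < min(d$year) | yrs > max(d$year)))
      stop("country ", d$country_id[1L], ": requested years outside the ",
           "provided span [", min(d$year), ", ", max(d$year), "]; ",
           "no extrapolation")
    data.frame(
      country_id = d$country_id[1L],
      year = yrs,
      total_population = stats::approx(d$year, d$total_population, xout = yrs)$y,
      urban_share = stats::approx(d$year, d$urban_share, xout = yrs)$y
    )
  })
  scenario_series(do.call(rbind, out))
}

#' SSP-RCP scenario probability matrix
#'
#' The 5 x 4 matrix of plausibility weights for combining each SSP
#' (rows 1..5) with each RCP (columns 2.6, 4.5, 6.0, 8.5).  The package
#' ships the published matrix as `inst/extdata/ssp_rcp_probabilities.csv`;
#' see [default_scenario_matrix()].  The probabilities are used only for
#' inclusion/exclusion of combinations, never as weights.
#'
#' @param m numeric 5 x 4 matrix with values in `[0, 1]`; dimnames are
#'   set to SSP1..SSP5 and RCP2.6/4.5/6.0/8.5.
#' @return A `scenario_matrix`.
#' @export
scenario_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(5L, 4L)))
    stop("scenario matrix must be 5 SSPs x 4 RCPs")
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0 | m > 1))
    stop("scenario probabilities must lie in [0, 1]")
  dimnames(m) <- list(paste0("SSP", 1:5), c("RCP2.6", "RCP4.5", "RCP6.0", "RCP8.5"))
  class(m) <- c("scenario_matrix", class(m))
  m
}

#' Select the plausible SSP-RCP combinations
#'
#' Returns every combination with probability strictly greater than zero,
#' in stable SSP-major order (SSP1 first; within an SSP, RCPs in
#' increasing forcing order).  With the published matrix this yields the
#' 15 plausible combinations; implausible pairs such as SSP1-RCP8.5
#' (probability 0.00) are excluded.
#'
#' @param matrix a [scenario_matrix()].
#' @return Data frame with columns `ssp` (integer 1..5), `rcp` (numeric
#'   2.6/4.5/6.0/8.5) and `probability`.
#' @export
select_scenarios <- function(matrix) {
  stopifnot(inherits(matrix, "scenario_matrix"))
  rcps <- c(2.6, 4.5, 6.0, 8.5)
  rows <- list()
  for (s in 1:5) for (r in 1:4) {
    if (matrix[s, r] > 0)
      rows[[length(rows) + 1L]] <- data.frame(ssp = s, rcp = rcps[r],
                                              probability = matrix[s, r])
  }
  if (length(rows) == 0L)
    return(data.frame(ssp = integer(), rcp = numeric(), probability = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The published SSP-RCP probability matrix
#'
#' Reads the plausibility matrix shipped with the package (rows SSP1..5,
#' columns RCP2.6/4.5/6.0/8.5).
#'
#' @return A [scenario_matrix()].
#' @export
default_scenario_matrix <- function() {
  read_matrix_csv(system.file("extdata", "ssp_rcp_probabilities.csv",
                              package = "dasypop", mustWork = TRUE))
}
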