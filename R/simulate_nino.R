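#' Simulate a monthly NINO3.4-style SST index
#'
#' Monthly series = deterministic seasonal cycle + AR(1) anomaly whose
#' innovation SD is scaled by a seasonal multiplier
#' `1 + phase_amp * cos(2*pi*(month - 12)/12)`, so anomaly variance is
#' phase-locked with a November-January peak, mimicking the observed ENSO
#' life cycle. A 240-month burn-in removes initialization transients; with
#' `innov_sd = 0` the series equals the seasonal cycle exactly.
#'
#' @param config a [world_config()]; uses `n_years`, `start_year`, `seed`
#'   and `nino_params`.
#' @return `data.table` with columns `year`, `month`, `value` (degC), one
#'   row per month of the simulation window, ordered chronologically.
#' @export
simulate_nino <- function(config) {
  stopifnot(inherits(config, "world_config"))
  p <- config$nino_params
  if (p$ar >= 1) stop("AR coefficient must be < 1 (stationary index)")
  if (config$n_years < 10L) stop("n_years must be at least 10")
  set.seed(config$seed + 303L)

  n <- config$n_years * 12L
  burn <- 240L
  month_seq <- rep(1:12, length.out = burn + n)  # burn-in aligned so month 1 starts after burn
  mult <- 1 + p$phase_amp * cos(2 * pi * (month_seq - 12) / 12)
  eps <- stats::rnorm(burn + n, 0, p$innov_sd) * mult
  a <- numeric(burn + n)
  for (t in 2:(burn + n)) a[t] <- p$ar * a[t - 1] + eps[t]
  a <- a[(burn + 1):(burn + n)]

  out <- data.table::data.table(
    year = rep(seq(config$start_year, length.out = config$n_years), each = 12L),
    month = rep(1:12, config$n_years))
  cycle <- p$seasonal_mean +
    p$seasonal_amp * cos(2 * pi * (out$month - 1) / 12)
  out[, value := cycle + a]
  out[]
}

#' Monthly anomalies of an index series
#'
#' Subtracts a per-calendar-month reference climatology from the raw values.
#' By default the climatology is the empirical per-month mean over the whole
#' series (the static mode of [enso_climatology()]).
#'
#' @param series index `data.table` (`year`, `month`, `value`).
#' @param climatology optional length-12 numeric vector of per-month
#'   reference means (index = calendar month), or a `data.table`
#'   (`year`, `month`, `ref`) as returned by [enso_climatology()].
#' @return copy of `series` with an `anom` column.
#' @export
nino_anomaly <- function(series, climatology = NULL) {
  s <- check_nino_series(series)
  if (is.null(climatology)) {
    s[, anom := value - mean(value), by = month]
  } else if (is.numeric(climatology)) {
    if (length(climatology) != 12L)
      stop("numeric climatology must have 12 per-month reference means")
    s[, anom := value - climatology[month]]
  } else {
    cl <- data.table::as.data.table(climatology)
    if (!all(c("year", "month", "ref") %in% names(cl)))
      stop("climatology table needs columns year, month, ref")
    s <- cl[s, on = c("year", "month")]
    if (anyNA(s$ref)) stop("climatology missing for some series months")
    s[, anom := value - ref]
    s[, ref := NULL]
  }
  s[]
}

# shared validation for index series tables
check_nino_series <- function(series) {
  s <- data.table::as.data.table(series)
  if (!all(c("year", "month", "value") %in% names(s)))
    stop("index series needs columns year, month, value")
  if (anyNA(s$value) || !all(is.finite(s$value)))
    stop("index series values must be finite")
  if (any(s$month < 1L | s$month > 12L)) stop("months must be in 1..12")
  data.table::setorder(s, year, month)
  idx <- s$year * 12L + s$month
  if (anyDuplicated(idx)) stop("duplicate (year, month) entries in index series")
  if (nrow(s) > 1L && any(diff(idx) != 1L))
    stop("index series months must be contiguous")
  s
}
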