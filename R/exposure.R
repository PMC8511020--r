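#' May-December mean of an index series for one tropical year
#'
#' The exposure assigned to a tropical year `t` is the arithmetic mean of
#' the eight monthly index values May through December of calendar year `t`.
#' All eight months must be present; a partial mean is never returned.
#'
#' @param series index `data.table` (`year`, `month`, `value`).
#' @param t calendar-year label of the tropical year.
#' @return mean index value (degC), a length-1 numeric.
#' @export
tropical_year_mean <- function(series, t) {
  s <- check_nino_series(series)
  v <- s[year == t & month >= 5L & month <= 12L, value]
  if (length(v) != 8L)
    stop(sprintf("tropical year %d: need all 8 months May-December, found %d",
                 t, length(v)))
  mean(v)
}

#' Assign an interview date to its tropical year
#'
#' ENSO events develop from late boreal spring, peak near the year's end and
#' decay by the following spring ("spring barrier"), so exposure windows run
#' May of year t through April of year t+1. Interviews in May-December of
#' year y belong to tropical year y; interviews in January-April belong to
#' tropical year y-1.
#'
#' @param year interview calendar year (vectorized).
#' @param month interview month 1-12 (vectorized).
#' @return integer vector of tropical-year labels.
#' @export
assign_tropical_year <- function(year, month) {
  month <- as.integer(month)
  if (anyNA(month) || any(month < 1L | month > 12L))
    stop("interview month must be in 1..12")
  as.integer(year) - (month < 5L)
}

#' Per-month reference climatology for ENSO state classification
#'
#' `mode = "static"` uses the per-calendar-month mean over the whole series.
#' `mode = "moving"` approximates the NOAA CPC practice of re-basing the
#' Oceanic Nino Index climatology: years are grouped into 5-year blocks and
#' each block's reference is the per-month mean over the 30-year window
#' centered on that block (clipped to the available record).
#'
#' @param series index `data.table` (`year`, `month`, `value`).
#' @param mode `"static"` or `"moving"`.
#' @param window base-period length in years for `"moving"` (default 30).
#' @param step years between climatology updates for `"moving"` (default 5).
#' @return `data.table` (`year`, `month`, `ref`) covering every series year.
#' @export
enso_climatology <- function(series, mode = c("static", "moving"),
                             window = 30L, step = 5L) {
  mode <- match.arg(mode)
  s <- check_nino_series(series)
  years <- sort(unique(s$year))
  if (mode == "static") {
    ref <- s[, .(ref = mean(value)), by = month]
    out <- data.table::CJ(year = years, month = 1:12)
    out <- ref[out, on = "month"]
    data.table::setcolorder(out, c("year", "month", "ref"))
    data.table::setorder(out, year, month)
    return(out[])
  }
  y0 <- min(years)
  blk <- (years - y0) %/% step
  out_list <- lapply(unique(blk), function(b) {
    byrs <- years[blk == b]
    center <- min(byrs) + (step - 1) / 2
    lo <- ceiling(center - window / 2)
    hi <- lo + window - 1
    base <- s[year >= lo & year <= hi]
    if (nrow(base) == 0L) base <- s
    ref <- base[, .(ref = mean(value)), by = month]
    grid <- data.table::CJ(year = byrs, month = 1:12)
    ref[grid, on = "month"]
  })
  out <- data.table::rbindlist(out_list)
  data.table::setcolorder(out, c("year", "month", "ref"))
  data.table::setorder(out, year, month)
  out[]
}

#' Classify the ENSO state of one tropical year
#'
#' Follows the Oceanic-Nino-Index convention: monthly anomalies relative to
#' a per-month reference climatology are averaged in 3-month centered
#' rolling windows across the tropical year (May of `t` through April of
#' `t+1`); the year is `el_nino` if the maximum rolling mean exceeds
#' +0.5 degC, `la_nina` if the minimum is below -0.5 degC, else `neutral`.
#' If both thresholds are crossed the larger absolute excursion wins. Edge
#' windows borrow the adjacent month outside the tropical year when the
#' series provides it (April of `t`, May of `t+1`); otherwise that edge
#' window is dropped.
#'
#' @param series index `data.table` (`year`, `month`, `value`).
#' @param climatology length-12 numeric vector of per-month reference means,
#'   or a (`year`, `month`, `ref`) table from [enso_climatology()].
#' @param t tropical-year label.
#' @param threshold excursion threshold in degC (default 0.5).
#' @return one of `"el_nino"`, `"la_nina"`, `"neutral"`.
#' @export
classify_enso_state <- function(series, climatology, t, threshold = 0.5) {
  s <- nino_anomaly(series, climatology)
  # core window plus one borrowed month each side for centered edge windows
  months <- data.table::data.table(
    year = c(t, rep(t, 8L), rep(t + 1L, 5L)),
    month = c(4L, 5:12, 1:5))
  w <- s[months, on = c("year", "month")]
  core <- which(!(w$year == t & w$month == 4L) & !(w$year == t + 1L & w$month == 5L))
  if (anyNA(w$anom[core]))
    stop(sprintf("tropical year %d: incomplete May-April anomaly window", t))
  roll <- vapply(core, function(i) {
    tri <- c(i - 1L, i, i + 1L)
    tri <- tri[tri >= 1L & tri <= nrow(w)]
    a <- w$anom[tri]
    if (length(tri) < 3L || anyNA(a)) NA_real_ else mean(a)
  }, numeric(1))
  roll <- roll[!is.na(roll)]
  if (length(roll) == 0L)
    stop(sprintf("tropical year %d: no computable 3-month window", t))
  hi <- max(roll); lo <- min(roll)
  if (hi > threshold && lo < -threshold)
    return(if (abs(hi) >= abs(lo)) "el_nino" else "la_nina")
  if (hi > threshold) return("el_nino")
  if (lo < -threshold) return("la_nina")
  "neutral"
}

#' Detrended tropical-year exposure anomalies
#'
#' Residuals of the May-December mean index on an ordinary-least-squares
#' linear trend in tropical year, over a configurable window (default: all
#' supplied years). This is the sense in which an event year's exposure can
#' be quoted as a detrended anomaly (e.g. +1.92 degC for a strong El Nino).
#'
#' @param exposures `data.table` with `tropical_year` and `mean_may_dec`.
#' @param window optional length-2 year range to fit the trend on.
#' @return copy of `exposures` with a `detrended_anomaly` column.
#' @export
detrended_anomaly <- function(exposures, window = NULL) {
  e <- data.table::as.data.table(exposures)
  if (!all(c("tropical_year", "mean_may_dec") %in% names(e)))
    stop("exposures needs columns tropical_year, mean_may_dec")
  fit_rows <- if (is.null(window)) rep(TRUE, nrow(e)) else
    e$tropical_year >= window[1] & e$tropical_year <= window[2]
  if (sum(fit_rows) < 3L)
    stop("fewer than 3 tropical years: linear trend undefined")
  fit <- stats::lm(mean_may_dec ~ tropical_year, data = e[fit_rows])
  e[, detrended_anomaly := mean_may_dec -
      stats::predict(fit, newdata = e[, .(tropical_year)])]
  e[]
}

#' Tropical-year exposure table for an index series
#'
#' One row per tropical year that has a complete May-December window:
#' the May-December mean exposure, its detrended anomaly, and the ENSO state
#' label from the rolling-mean rule (years whose May-April classification
#' window is incomplete at the series edge get `NA`).
#'
#' @param series index `data.table` (`year`, `month`, `value`).
#' @param climatology_mode `"static"` or `"moving"` (see [enso_climatology()]).
#' @param detrend_window optional length-2 year range for the trend fit.
#' @param threshold state-classification threshold (degC).
#' @return `data.table` (`tropical_year`, `mean_may_dec`,
#'   `detrended_anomaly`, `state`).
#' @export
build_exposure_table <- function(series, climatology_mode = "static",
                                 detrend_window = NULL, threshold = 0.5) {
  s <- check_nino_series(series)
  cnt <- s[month >= 5L, .N, by = year]
  years <- sort(cnt[N == 8L, year])
  if (length(years) < 3L) stop("need at least 3 complete tropical years")
  clim <- enso_climatology(s, mode = climatology_mode)
  out <- data.table::data.table(tropical_year = years)
  out[, mean_may_dec := vapply(tropical_year, function(t)
    tropical_year_mean(s, t), numeric(1))]
  out <- detrended_anomaly(out, window = detrend_window)
  out[, state := vapply(tropical_year, function(t) {
    tryCatch(classify_enso_state(s, clim, t, threshold = threshold),
             error = function(e) NA_character_)
  }, character(1))]
  out[]
}
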