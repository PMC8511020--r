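#' Attach tropical-year exposure and teleconnection flags to child records
#'
#' Adds the tropical-year label (May boundary rule), the May-December mean
#' index exposure of that tropical year, and the admin1 positive-precip
#' indicator. Errors if any required month of the index or any admin1 unit
#' is missing, rather than silently dropping children.
#'
#' @param children child-level `data.table` with `int_year`, `int_month`,
#'   `admin1`.
#' @param series index `data.table` (`year`, `month`, `value`).
#' @param tele a `teleconnection_map` or admin1 table with `admin1`,
#'   `pos_precip`.
#' @param lags integer vector of tropical-year lags; each adds a
#'   `nino_lag<k>` column with the exposure of tropical year `t - k`
#'   (`NA` where the lagged year precedes the index record).
#' @return copy of `children` with `tropical_year`, `nino`, `pos_precip`
#'   and any requested lag columns.
#' @export
attach_exposure <- function(children, series, tele, lags = integer(0)) {
  ch <- data.table::as.data.table(children)
  s <- check_nino_series(series)
  admin_tab <- if (inherits(tele, "teleconnection_map")) tele$admin1 else
    data.table::as.data.table(tele)
  ch <- data.table::copy(ch)
  ch[, tropical_year := assign_tropical_year(int_year, int_month)]
  expo <- exposure_lookup(s, sort(unique(ch$tropical_year)))
  ch[, nino := expo[match(ch$tropical_year, tropical_year), exposure]]
  ch[, pos_precip := admin_tab[match(ch$admin1, admin1),
                               as.integer(pos_precip)]]
  if (anyNA(ch$pos_precip))
    stop("some admin1 units are missing from the teleconnection table")
  for (k in as.integer(lags)) {
    lag_years <- sort(unique(ch$tropical_year)) - k
    lag_expo <- vapply(lag_years, function(t)
      tryCatch(tropical_year_mean(s, t), error = function(e) NA_real_),
      numeric(1))
    data.table::set(ch, j = sprintf("nino_lag%d", k),
                    value = lag_expo[match(ch$tropical_year - k, lag_years)])
  }
  ch[]
}

#' Drop flagged and missing anthropometric records
#'
#' Removes records flagged as biologically improbable and records missing
#' the requested outcome, logging how many were removed for each reason
#' (attribute `"removal_log"`). Refuses to return an empty table.
#'
#' @param raw child-level `data.table` with a logical `flagged` column and
#'   the outcome column.
#' @param outcome outcome column name (`"waz"`, `"whz"` or `"bmiz"`).
#' @return filtered copy, with attribute `removal_log`: a `data.table`
#'   (`reason`, `n`, `frac`) where `frac` is relative to the input rows.
#' @export
filter_anthropometrics <- function(raw, outcome = "waz") {
  ch <- data.table::as.data.table(raw)
  if (!outcome %in% names(ch)) stop("unknown outcome column: ", outcome)
  if (!"flagged" %in% names(ch)) stop("quality flag column 'flagged' missing")
  n0 <- nrow(ch)
  is_flagged <- ch$flagged %in% TRUE
  is_missing <- is.na(ch[[outcome]]) & !is_flagged
  keep <- !is_flagged & !is_missing
  if (!any(keep)) stop("all records removed by filtering")
  log <- data.table::data.table(
    reason = c("flagged_improbable", paste0("missing_", outcome)),
    n = c(sum(is_flagged), sum(is_missing)))
  log[, frac := n / n0]
  out <- ch[keep]
  data.table::setattr(out, "removal_log", log)
  out
}

#' Add WHO threshold indicator outcomes
#'
#' `underweight` is weight-for-age strictly below -2 sigma, `wasted` is
#' weight-for-height strictly below -2 sigma (a z-score of exactly -2 is
#' not below the threshold). Missing z-scores give missing indicators.
#'
#' @param table child-level `data.table` with `waz` and/or `whz`.
#' @return copy with integer columns `underweight` and/or `wasted`.
#' @export
threshold_indicators <- function(table) {
  ch <- data.table::copy(data.table::as.data.table(table))
  if ("waz" %in% names(ch)) ch[, underweight := as.integer(waz < -2)]
  if ("whz" %in% names(ch)) ch[, wasted := as.integer(whz < -2)]
  ch[]
}

#' Build observation weights for the two estimands
#'
#' `average_country`: DHS-style sampling weights normalized so that all
#' observations across all surveys sum to one within each country, making
#' the estimate representative of the average sample country.
#' `average_child`: those normalized weights multiplied by the country's
#' under-5 population, making the estimate representative of the average
#' child in the sample countries. With `per_survey = TRUE` normalization is
#' first within country-by-survey-year, then across a country's surveys, so
#' each survey contributes equally within its country (country totals are
#' still one).
#'
#' @param table child-level `data.table` with `country`, `dhs_weight` and
#'   (if `per_survey`) `int_year`.
#' @param mode `"average_country"` or `"average_child"`.
#' @param populations named numeric vector (or `data.table` with `country`,
#'   `pop_u5`) of country under-5 populations; required for
#'   `"average_child"`.
#' @param per_survey normalize per survey before pooling (default FALSE).
#' @return copy with a `weight` column.
#' @export
build_weights <- function(table, mode = c("average_country", "average_child"),
                          populations = NULL, per_survey = FALSE) {
  mode <- match.arg(mode)
  ch <- data.table::copy(data.table::as.data.table(table))
  if (any(ch$dhs_weight <= 0)) stop("dhs_weight must be strictly positive")
  if (per_survey) {
    ch[, weight := dhs_weight / sum(dhs_weight), by = .(country, int_year)]
    ch[, weight := weight / data.table::uniqueN(int_year), by = country]
  } else {
    ch[, weight := dhs_weight / sum(dhs_weight), by = country]
  }
  if (mode == "average_child") {
    if (is.null(populations)) stop("average_child mode needs country populations")
    if (is.data.frame(populations)) {
      pt <- data.table::as.data.table(populations)
      populations <- stats::setNames(pt$pop_u5, pt$country)
    }
    pop <- populations[ch$country]
    if (anyNA(pop)) stop("missing under-5 population for some countries")
    ch[, weight := weight * pop]
  }
  ch[]
}

#' Prepare an estimation sample in one call
#'
#' Convenience wrapper: attach exposure and flags, filter the requested
#' outcome, add threshold indicators, and build weights.
#'
#' @inheritParams attach_exposure
#' @inheritParams filter_anthropometrics
#' @inheritParams build_weights
#' @return prepared `data.table` (removal log attached as attribute).
#' @export
prepare_sample <- function(children, series, tele, outcome = "waz",
                           mode = "average_country", populations = NULL,
                           per_survey = FALSE, lags = integer(0)) {
  ch <- attach_exposure(children, series, tele, lags = lags)
  ch <- filter_anthropometrics(ch, outcome = outcome)
  log <- attr(ch, "removal_log")
  ch <- threshold_indicators(ch)
  ch <- build_weights(ch, mode = mode, populations = populations,
                      per_survey = per_survey)
  data.table::setattr(ch, "removal_log", log)
  ch
}
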