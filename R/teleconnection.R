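#' Per-pixel, per-calendar-month lagged correlations with an index
#'
#' For each pixel and calendar month m, the Pearson correlation across years
#' between the pixel's month-m value and the index value at month m - lag
#' (crossing the calendar-year boundary when m - lag < 1). Correlating within
#' a calendar month across years removes mean seasonality by construction;
#' with `detrend = TRUE` (default) a linear trend in year is additionally
#' removed from both series before correlating, so shared secular warming
#' cannot masquerade as a teleconnection. Two-sided p-values come from the t
#' distribution with n - 2 df (n - 3 when detrending, since one more
#' parameter is removed from each series). Zero-variance pixel-months are
#' degenerate: r and p are `NA` and they never count as significant.
#'
#' @param grid a `climate_grid` (or a list with `monthly` in its format).
#' @param series index `data.table` (`year`, `month`, `value`).
#' @param variable `"temperature"` or `"precipitation"`.
#' @param lag lag in months (>= 0, default 2).
#' @param detrend remove a per-month linear year trend first (default TRUE).
#' @return `data.table` (`pixel_id`, `month`, `n`, `r`, `p`).
#' @export
monthly_lag_correlation <- function(grid, series,
                                    variable = c("temperature", "precipitation"),
                                    lag = 2L, detrend = TRUE) {
  variable <- match.arg(variable)
  if (lag < 0L) stop("lag must be >= 0")
  s <- check_nino_series(series)
  m <- data.table::as.data.table(grid$monthly)
  years <- sort(unique(m$year))
  if (length(years) < 10L) stop("overlapping window shorter than 10 years")

  out <- vector("list", 12L)
  for (mo in 1:12) {
    lag_year_off <- as.integer(mo - lag < 1L)
    lag_month <- ((mo - lag - 1L) %% 12L) + 1L
    x_tab <- s[month == lag_month & (year + lag_year_off) %in% years]
    x_tab[, grid_year := year + lag_year_off]
    wide <- data.table::dcast(m[month == mo], pixel_id ~ year,
                              value.var = variable)
    yrs <- intersect(as.integer(names(wide)[-1]), x_tab$grid_year)
    V <- as.matrix(wide[, as.character(yrs), with = FALSE])
    x <- x_tab[match(yrs, grid_year), value]
    n <- length(yrs)
    if (detrend) {
      tt <- yrs - mean(yrs)
      proj <- tt / sum(tt^2)
      x <- x - mean(x) - sum(x * proj) * tt
      Vc <- V - rowMeans(V)
      V <- Vc - tcrossprod(Vc %*% proj, tt)
    } else {
      x <- x - mean(x)
      V <- V - rowMeans(V)
    }
    sx <- sqrt(sum(x^2))
    sv <- sqrt(rowSums(V^2))
    r <- as.vector(V %*% x) / (sv * sx)
    r[sv == 0 | sx == 0] <- NA_real_
    df <- n - 2L - as.integer(detrend)
    tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = df)
    out[[mo]] <- data.table::data.table(pixel_id = wide$pixel_id, month = mo,
                                        n = n, r = r, p = p)
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, pixel_id, month)
  res[]
}

#' Flag pixels with enough significant months of correlation
#'
#' A pixel is teleconnected when at least `min_months` of its 12 calendar
#' months show a correlation significant at `alpha`, optionally restricted
#' to one sign. Degenerate months (`NA`) never count.
#'
#' @param r_p per-month correlation table from [monthly_lag_correlation()].
#' @param min_months minimum significant months (default 3).
#' @param alpha significance level (default 0.05).
#' @param sign `"any"`, `"positive"` or `"negative"` restriction on r.
#' @return `data.table` (`pixel_id`, `n_sig`, `flag`).
#' @export
pixel_teleconnected <- function(r_p, min_months = 3L, alpha = 0.05,
                                sign = c("any", "positive", "negative")) {
  sign <- match.arg(sign)
  rp <- data.table::as.data.table(r_p)
  sig <- !is.na(rp$p) & rp$p < alpha
  sig <- sig & switch(sign,
                      any = TRUE,
                      positive = !is.na(rp$r) & rp$r > 0,
                      negative = !is.na(rp$r) & rp$r < 0)
  tmp <- data.table::data.table(pixel_id = rp$pixel_id, sig = sig)
  out <- tmp[, .(n_sig = sum(sig)), by = pixel_id]
  out[, flag := n_sig >= min_months]
  out[]
}

#' Country-level temperature teleconnection flag
#'
#' A country is teleconnected when at least 50% of its population lives in
#' flagged pixels (weak inequality, per the population rule).
#'
#' @param flags pixel flag table from [pixel_teleconnected()].
#' @param meta pixel metadata with `pixel_id`, `country`, `population`.
#' @return `data.table` (`country`, `pop_share`, `teleconnected`).
#' @export
country_teleconnected <- function(flags, meta) {
  g <- data.table::as.data.table(meta)[
    data.table::as.data.table(flags), on = "pixel_id"]
  out <- g[, .(pop_total = sum(population),
               pop_flagged = sum(population * flag)), by = country]
  if (any(out$pop_total <= 0))
    stop("country with zero total population: share undefined")
  out[, pop_share := pop_flagged / pop_total]
  out[, teleconnected := pop_share >= 0.5]
  data.table::setorder(out, country)
  out[, .(country, pop_share, teleconnected)]
}

#' Admin1-level positive-precipitation flag
#'
#' An admin1 unit is flagged when strictly more than 50% of its land area
#' lies in pixels with >= `min_months` significant positive precipitation
#' correlations (strict inequality, unlike the country population rule).
#'
#' @param flags pixel positive-precip flag table from [pixel_teleconnected()].
#' @param meta pixel metadata with `pixel_id`, `admin1`, `country`, `land_area`.
#' @return `data.table` (`admin1`, `country`, `area_share`, `pos_precip`).
#' @export
admin_positive_precip <- function(flags, meta) {
  g <- data.table::as.data.table(meta)[
    data.table::as.data.table(flags), on = "pixel_id"]
  out <- g[, .(country = country[1L],
               area_total = sum(land_area),
               area_flagged = sum(land_area * flag)), by = admin1]
  if (any(out$area_total <= 0))
    stop("admin1 unit with zero land area: share undefined")
  out[, area_share := area_flagged / area_total]
  out[, pos_precip := area_share > 0.5]
  data.table::setorder(out, admin1)
  out[, .(admin1, country, area_share, pos_precip)]
}

#' Full teleconnection map for a climate grid
#'
#' Runs the lagged-correlation analysis for temperature and precipitation,
#' applies the >= 3-significant-months pixel rule (any sign for temperature,
#' positive sign for the precipitation flag), and aggregates to the
#' country-level teleconnected flag (population rule) and the admin1-level
#' positive-precipitation flag (land-area rule).
#'
#' @param grid a `climate_grid`.
#' @param series index `data.table`.
#' @param lag lag in months (default 2).
#' @param alpha per-month significance level (default 0.05).
#' @param min_months minimum significant months (default 3).
#' @param detrend remove per-month year trends first (default TRUE).
#' @return object of class `teleconnection_map`: list with `pixel_temp`,
#'   `pixel_precip` (correlation + flag tables), `country`, `admin1`, and
#'   the parameters used.
#' @export
teleconnection_map <- function(grid, series, lag = 2L, alpha = 0.05,
                               min_months = 3L, detrend = TRUE) {
  rt <- monthly_lag_correlation(grid, series, "temperature", lag = lag,
                                detrend = detrend)
  rp <- monthly_lag_correlation(grid, series, "precipitation", lag = lag,
                                detrend = detrend)
  ft <- pixel_teleconnected(rt, min_months = min_months, alpha = alpha,
                            sign = "any")
  fp <- pixel_teleconnected(rp, min_months = min_months, alpha = alpha,
                            sign = "positive")
  structure(list(
    pixel_temp = ft, pixel_precip = fp,
    corr_temp = rt, corr_precip = rp,
    country = country_teleconnected(ft, grid$meta),
    admin1 = admin_positive_precip(fp, grid$meta),
    params = list(lag = lag, alpha = alpha, min_months = min_months,
                  detrend = detrend)),
    class = "teleconnection_map")
}

#' Ground-truth teleconnection map from planted loadings
#'
#' Builds the map a perfect detector would produce: countries are
#' teleconnected iff their planted temperature loading is nonzero, admin1
#' units are positive-precip iff their planted precipitation loading is
#' positive. Used to drive the outcome generator and as the reference in
#' recovery tests.
#'
#' @param geography a [world_geography()] table.
#' @return object of class `teleconnection_map` (pixel tables omitted).
#' @export
truth_teleconnection_map <- function(geography) {
  g <- data.table::as.data.table(geography)
  country <- g[, .(pop_share = as.numeric(temp_loading[1L] != 0)),
               by = country]
  country[, teleconnected := pop_share >= 0.5]
  admin1 <- g[, .(country = country[1L],
                  area_share = as.numeric(precip_loading[1L] > 0)),
              by = admin1]
  admin1[, pos_precip := area_share > 0.5]
  structure(list(pixel_temp = NULL, pixel_precip = NULL,
                 country = country[order(country)],
                 admin1 = admin1[order(admin1)],
                 params = list(truth = TRUE)),
            class = "teleconnection_map")
}

#' @export
print.teleconnection_map <- function(x, ...) {
  cat(sprintf("<teleconnection_map> %d/%d countries teleconnected; %d/%d admin1 positive-precip\n",
              sum(x$country$teleconnected), nrow(x$country),
              sum(x$admin1$pos_precip), nrow(x$admin1)))
  invisible(x)
}
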