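#' Simulate a gridded monthly climate with planted ENSO teleconnections
#'
#' Pixel temperature in month t is a per-month climatology plus the pixel's
#' planted loading times the index anomaly two months earlier, plus Gaussian
#' noise; precipitation is analogous with a signed loading and is floored at
#' zero. The grid window starts one year after the index so the lag-2 index
#' is always available. Pixel membership (country, admin1, region),
#' population and land area come from [world_geography()].
#'
#' @param nino index `data.table` (`year`, `month`, `value`) covering at
#'   least the simulation window plus the lag months.
#' @param config a [world_config()].
#' @param geography optional precomputed [world_geography()].
#' @param lag teleconnection lag in months (default 2).
#' @return object of class `climate_grid`: a list with `meta` (the geography
#'   table) and `monthly` (`pixel_id`, `year`, `month`, `temperature`,
#'   `precipitation`).
#' @export
simulate_climate_grid <- function(nino, config,
                                  geography = world_geography(config),
                                  lag = 2L) {
  stopifnot(inherits(config, "world_config"))
  s <- nino_anomaly(nino)
  set.seed(config$seed + 404L)
  years <- seq(config$start_year + 1L, config$start_year + config$n_years - 1L)
  if (!all(years %in% s$year) || !((min(years) - 1L) %in% s$year))
    stop("index series does not cover the grid window (plus lag months)")

  grid <- data.table::CJ(pixel_id = geography$pixel_id, year = years,
                         month = 1:12, sorted = FALSE)
  data.table::setorder(grid, pixel_id, year, month)
  # lag-2 index anomaly, crossing the calendar-year boundary when needed
  lag_key <- data.table::data.table(
    year = grid$year - (grid$month - lag < 1L),
    month = ((grid$month - lag - 1L) %% 12L) + 1L)
  grid[, lag_anom := s[lag_key, on = c("year", "month"), anom]]
  if (anyNA(grid$lag_anom)) stop("lagged index anomaly missing inside window")

  grid <- geography[, .(pixel_id, lat, temp_loading, precip_loading)][
    grid, on = "pixel_id"]
  tp <- config$tele_params
  grid[, temperature := 24 + 0.1 * lat + 4 * cos(2 * pi * (month - 1) / 12) +
         temp_loading * lag_anom +
         stats::rnorm(.N, 0, tp$temp_noise_sd)]
  grid[, precipitation := pmax(0, 80 + 60 * sin(2 * pi * (month - 6) / 12) +
         precip_loading * lag_anom +
         stats::rnorm(.N, 0, tp$precip_noise_sd))]
  monthly <- grid[, .(pixel_id, year, month, temperature, precipitation)]
  structure(list(meta = geography, monthly = monthly),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %d pixels x %d months (%d-%d)\n",
              nrow(x$meta), length(unique(x$monthly$year)) * 12L,
              min(x$monthly$year), max(x$monthly$year)))
  invisible(x)
}
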