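#' Configuration for the synthetic world generator
#'
#' Bundles every knob of the synthetic data-generating process: the AR(1)
#' index model, the planted pixel-level teleconnection loadings, the planted
#' child-outcome model (main ENSO slope, positive-precipitation slope,
#' country-specific controls, region trends, month effects, fixed effects and
#' noise components), and the survey design (waves, clusters, sampling
#' weights, data-quality flags). The seed fully determines every artifact the
#' generators emit.
#'
#' Partial lists are merged into the defaults, so
#' `world_config(effect_params = list(beta = list(waz = c(beta_n = 0, beta_p = 0))))`
#' overrides only what it names.
#'
#' @param n_years number of simulated calendar years of the index (>= 10).
#' @param start_year first calendar year of the index.
#' @param n_countries number of countries.
#' @param admin1_per_country first-level administrative units per country.
#' @param pixels_per_admin1 0.5-degree pixels per admin1 unit.
#' @param n_regions number of world regions countries are grouped into.
#' @param n_children total number of child records across all survey waves.
#' @param survey_gap a country is surveyed every `survey_gap` years.
#' @param clusters_per_wave DHS-style sampling clusters per survey wave.
#' @param seed integer seed; bit-reproducibility is guaranteed given the seed.
#' @param nino_params list: `ar` (AR(1) coefficient, must be < 1), `innov_sd`
#'   (innovation SD, degC), `seasonal_mean` and `seasonal_amp` (degC residual
#'   seasonal cycle; the index is an SST *anomaly* index as used for ONI-style
#'   state classification, so both default near zero), `phase_amp`
#'   (multiplicative seasonal scaling of the innovation SD; variance peaks
#'   Nov-Jan).
#' @param tele_params list: `temp_loading` (degC per degC of lag-2 index
#'   anomaly in teleconnected countries), `frac_nontele` (fraction of
#'   countries with zero loading), `precip_loading` (mm per degC, magnitude),
#'   `frac_pos_precip` (fraction of admin1 units in teleconnected countries
#'   with a positive precipitation loading; the rest are negative),
#'   `temp_noise_sd` (degC), `precip_noise_sd` (mm).
#' @param effect_params list of planted outcome-model parameters; see Details.
#' @param survey_params list: `flagged_frac` (share of records flagged as
#'   improbable), `missing_frac` (share with a missing outcome, per outcome),
#'   `weight_meanlog`/`weight_sdlog` (log-normal cluster sampling weights),
#'   `timing_depends_on_enso` (if `TRUE`, interview months shift with ENSO
#'   state, for timing-robustness experiments), `urban_frac`.
#'
#' @details `effect_params` plants the outcome model
#' \deqn{Y = FE_{cr} + \beta NINO_t + \gamma_{educ,c} educ + \gamma_{mage,c} mage
#'   + trend_r (t - t_0) + month_{r,m} + u_{year} + u_{admin1} + u_{admin1,year} + e}
#' with `beta` equal to `beta_n` in admin1 units with non-positive planted
#' precipitation loading and `beta_p` (the total slope, not the interaction
#' contrast) where the loading is positive. Fields: `alpha` (grand mean of
#' the country-by-urban intercepts), `beta` (per outcome, named vector
#' `c(beta_n=, beta_p=)` for `waz`, `whz`, `bmiz`), `gamma_educ_mean/sd` and
#' `gamma_mage_mean/sd` (country-specific control slopes), `fe_cr_sd`,
#' `urban_shift`, `trend_sd` (region trend slopes, sigma/year), `month_amp`
#' (region-specific seasonal amplitude, sigma), `year_shock_sd`,
#' `admin_shock_sd` (time-constant), `admin_year_shock_sd`, `child_noise_sd`.
#'
#' @return a list of class `world_config`.
#' @export
world_config <- function(n_years = 33L,
                         start_year = 1986L,
                         n_countries = 10L,
                         admin1_per_country = 10L,
                         pixels_per_admin1 = 2L,
                         n_regions = 5L,
                         n_children = 200000L,
                         survey_gap = 3L,
                         clusters_per_wave = 25L,
                         seed = 1L,
                         nino_params = list(),
                         tele_params = list(),
                         effect_params = list(),
                         survey_params = list()) {
  nino_default <- list(ar = 0.85, innov_sd = 0.35, seasonal_mean = 0,
                       seasonal_amp = 0.15, phase_amp = 0.5)
  tele_default <- list(temp_loading = 1.0, frac_nontele = 0.2,
                       precip_loading = 20, frac_pos_precip = 0.25,
                       temp_noise_sd = 0.9, precip_noise_sd = 20)
  effect_default <- list(
    alpha = -0.9,
    beta = list(waz  = c(beta_n = -0.0251, beta_p = 0.0482),
                whz  = c(beta_n = -0.0377, beta_p = 0.0112),
                bmiz = c(beta_n = -0.0381, beta_p = -0.0011)),
    gamma_educ_mean = 0.02, gamma_educ_sd = 0.01,
    gamma_mage_mean = 0.005, gamma_mage_sd = 0.003,
    fe_cr_sd = 0.4, urban_shift = 0.2,
    trend_sd = 0.008, month_amp = 0.05,
    year_shock_sd = 0.001, admin_shock_sd = 0.002,
    admin_year_shock_sd = 0.005, child_noise_sd = 0.1)
  survey_default <- list(flagged_frac = 0.0056, missing_frac = 0.0057,
                         weight_meanlog = 0, weight_sdlog = 0.5,
                         timing_depends_on_enso = FALSE, urban_frac = 0.35)

  cfg <- list(
    n_years = as.integer(n_years), start_year = as.integer(start_year),
    n_countries = as.integer(n_countries),
    admin1_per_country = as.integer(admin1_per_country),
    pixels_per_admin1 = as.integer(pixels_per_admin1),
    n_regions = as.integer(n_regions),
    n_children = as.integer(n_children),
    survey_gap = as.integer(survey_gap),
    clusters_per_wave = as.integer(clusters_per_wave),
    seed = as.integer(seed),
    nino_params = utils::modifyList(nino_default, nino_params),
    tele_params = utils::modifyList(tele_default, tele_params),
    effect_params = utils::modifyList(effect_default, effect_params),
    survey_params = utils::modifyList(survey_default, survey_params))

  if (cfg$n_years < 10L)
    stop("n_years must be at least 10 (one AR decade of index history)")
  if (cfg$nino_params$ar >= 1)
    stop("AR coefficient must be < 1 (stationary index)")
  if (cfg$nino_params$ar <= 0)
    stop("AR coefficient must be in (0, 1)")
  if (cfg$n_countries < 2L || cfg$admin1_per_country < 1L)
    stop("need at least 2 countries and 1 admin1 unit per country")
  tp <- cfg$tele_params
  if (tp$frac_nontele <= 0 || tp$frac_nontele >= 1)
    stop("frac_nontele must be in (0,1): the world needs a non-teleconnected block")
  if (tp$frac_pos_precip <= 0 || tp$frac_pos_precip >= 1)
    stop("frac_pos_precip must be in (0,1): need both precip-loading signs")
  class(cfg) <- "world_config"
  cfg
}

#' Deterministic geography and planted loadings for a synthetic world
#'
#' Lays pixels out one latitude band per country, one contiguous longitude
#' run per admin1 unit, and attaches the planted teleconnection loadings:
#' the last `ceiling(frac_nontele * n_countries)` countries get zero loadings
#' (the non-teleconnected negative-control block); within each teleconnected
#' country the first `ceiling(frac_pos_precip * admin1_per_country)` admin1
#' units get a positive precipitation loading and the rest a negative one.
#' Pixel population is log-normal and land area roughly that of a 0.5-degree
#' cell. Country under-5 population is proportional to summed pixel
#' population.
#'
#' @param config a [world_config()].
#' @return `data.table` with one row per pixel: `pixel_id`, `lat`, `lon`,
#'   `country`, `admin1`, `region`, `population`, `land_area`,
#'   `temp_loading`, `precip_loading`, `country_pop_u5`.
#' @export
world_geography <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed + 101L)
  C <- config$n_countries; A <- config$admin1_per_country
  P <- config$pixels_per_admin1
  n_nontele <- max(1L, ceiling(config$tele_params$frac_nontele * C))
  n_pos <- max(1L, ceiling(config$tele_params$frac_pos_precip * A))

  g <- data.table::CJ(ci = seq_len(C), ai = seq_len(A), pi = seq_len(P),
                      sorted = FALSE)
  data.table::setorder(g, ci, ai, pi)
  g[, pixel_id := sprintf("px%04d", .I)]
  g[, lat := -9.75 + (ci - 1) * 0.5]
  g[, lon := 10.25 + ((ai - 1) * P + (pi - 1)) * 0.5]
  g[, country := sprintf("C%02d", ci)]
  g[, admin1 := sprintf("C%02dA%d", ci, ai)]
  g[, region := sprintf("R%d", ((ci - 1L) %% config$n_regions) + 1L)]
  tele_country <- g$ci <= (C - n_nontele)
  g[, temp_loading := ifelse(tele_country, config$tele_params$temp_loading, 0)]
  g[, precip_loading := data.table::fifelse(
        !tele_country, 0,
        ifelse(ai <= n_pos, config$tele_params$precip_loading,
               -config$tele_params$precip_loading))]
  g[, population := stats::rlnorm(.N, meanlog = 10, sdlog = 0.8)]
  g[, land_area := stats::runif(.N, 2300, 3100)]
  g[, country_pop_u5 := {
      tot <- sum(population)
      rep(round(tot * 40), .N)  # ~under-5 headcount scaled from pixel pop
    }, by = country]
  g[, c("ci", "ai", "pi") := NULL]
  g[]
}

#' Planted outcome-model coefficient draws for a synthetic world
#'
#' Draws, deterministically given the config seed, every country-, region-,
#' admin1- and year-level coefficient of the planted outcome model: country
#' by urban intercepts, country-specific control slopes, region trend slopes,
#' region-by-month seasonal effects, and the year / admin1 / admin1-by-year
#' shock components shared by all outcomes.
#'
#' @param config a [world_config()].
#' @param geography optional precomputed [world_geography()].
#' @return a list of named numeric vectors / tables (class `world_effects`).
#' @export
world_effects <- function(config, geography = world_geography(config)) {
  stopifnot(inherits(config, "world_config"))
  ep <- config$effect_params
  set.seed(config$seed + 202L)
  countries <- sort(unique(geography$country))
  admins <- sort(unique(geography$admin1))
  regions <- sort(unique(geography$region))
  years <- seq(config$start_year, length.out = config$n_years)

  fe_cr <- data.table::CJ(country = countries, urban = c(0L, 1L))
  fe_cr[, fe := ep$alpha + stats::rnorm(.N, 0, ep$fe_cr_sd) +
          ep$urban_shift * urban]

  month_eff <- data.table::CJ(region = regions, month = 1:12)
  month_eff[, phase := stats::runif(1), by = region]
  month_eff[, eff := ep$month_amp * cos(2 * pi * (month / 12 + phase))]
  month_eff[, phase := NULL]

  list(
    fe_cr = fe_cr,
    gamma_educ = stats::setNames(
      stats::rnorm(length(countries), ep$gamma_educ_mean, ep$gamma_educ_sd),
      countries),
    gamma_mage = stats::setNames(
      stats::rnorm(length(countries), ep$gamma_mage_mean, ep$gamma_mage_sd),
      countries),
    trend = stats::setNames(
      stats::rnorm(length(regions), 0, ep$trend_sd), regions),
    month_eff = month_eff,
    year_shock = stats::setNames(
      stats::rnorm(length(years), 0, ep$year_shock_sd), as.character(years)),
    admin_shock = stats::setNames(
      stats::rnorm(length(admins), 0, ep$admin_shock_sd), admins),
    admin_year_shock = {
      ay <- data.table::CJ(admin1 = admins, tropical_year = years)
      ay[, shock := stats::rnorm(.N, 0, ep$admin_year_shock_sd)]
      ay
    })
}
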