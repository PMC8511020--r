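# Small synthetic worlds shared across test files. Sizes are chosen so a
# full test run stays fast while every structural feature (teleconnected
# and non-teleconnected countries, both precipitation-loading signs,
# rotating survey waves) is present.

small_config <- function(seed = 42L, ...) {
  world_config(n_countries = 6L, n_years = 20L, admin1_per_country = 10L,
               pixels_per_admin1 = 2L, n_regions = 2L, n_children = 6000L,
               seed = seed, ...)
}

# config whose planted outcome model is fully deterministic apart from the
# exposure term: all noise components, controls and structural effects zero
deterministic_config <- function(seed = 7L, beta_n = -0.03, beta_p = 0,
                                 alpha = -0.5) {
  world_config(
    n_countries = 4L, n_years = 15L, admin1_per_country = 2L,
    pixels_per_admin1 = 2L, n_children = 800L, seed = seed,
    effect_params = list(
      alpha = alpha,
      beta = list(waz = c(beta_n = beta_n, beta_p = beta_p),
                  whz = c(beta_n = beta_n, beta_p = beta_p),
                  bmiz = c(beta_n = beta_n, beta_p = beta_p)),
      gamma_educ_mean = 0, gamma_educ_sd = 0,
      gamma_mage_mean = 0, gamma_mage_sd = 0,
      fe_cr_sd = 0, urban_shift = 0, trend_sd = 0, month_amp = 0,
      year_shock_sd = 0, admin_shock_sd = 0, admin_year_shock_sd = 0,
      child_noise_sd = 0),
    survey_params = list(flagged_frac = 0, missing_frac = 0))
}

# a tiny hand-made index series: `years` full calendar years of given values
constant_series <- function(value, years = 2000:2005) {
  data.table::CJ(year = years, month = 1:12)[, .(year, month, value = value)]
}

# prepared estimation sample for a seeded small world (memoised per session)
.sample_cache <- new.env(parent = emptyenv())
cached_sample <- function(seed = 42L) {
  key <- as.character(seed)
  if (is.null(.sample_cache[[key]])) {
    w <- simulate_world(small_config(seed = seed), tele = "truth")
    .sample_cache[[key]] <- list(
      world = w,
      tab = prepare_sample(w$children, w$nino, w$tele, outcome = "waz"))
  }
  .sample_cache[[key]]
}
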