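#' Simulate child-level survey microdata with planted ENSO effects
#'
#' Emulates a rotating household-survey program over the teleconnected
#' countries of a synthetic world. Each teleconnected country is surveyed
#' every `survey_gap` years (offset by country so waves rotate); each wave
#' draws children into sampling clusters with log-normal cluster weights,
#' uniform interview months, and mother covariates. Outcomes follow the
#' planted linear model (see [world_config()] details): the ENSO slope is
#' `beta_p` in admin1 units the supplied teleconnection table flags as
#' positive-precip and `beta_n` elsewhere, the exposure being the
#' May-December mean index of the child's tropical year. A configurable
#' fraction of records is flagged as improbable and a fraction of each
#' outcome is set missing, to exercise downstream filtering.
#'
#' @param nino index `data.table` (`year`, `month`, `value`) covering every
#'   tropical year any interview maps to.
#' @param tele a `teleconnection_map` (its `country` and `admin1` tables are
#'   used), or an admin1 table with columns `admin1`, `pos_precip`.
#' @param config a [world_config()].
#' @param geography optional precomputed [world_geography()].
#' @param effects optional precomputed [world_effects()].
#' @return `data.table`, one row per child: `child_id`, `country`, `admin1`,
#'   `region`, `urban`, `cluster_id`, `int_year`, `int_month`, `age_months`,
#'   `sex`, `mother_educ`, `mother_age_birth`, `dhs_weight`, `waz`, `whz`,
#'   `bmiz`, `flagged`. The planted truth (config, effects, per-admin slope
#'   flags) is attached as attribute `"truth"`.
#' @export
simulate_surveys <- function(nino, tele, config,
                             geography = world_geography(config),
                             effects = world_effects(config, geography)) {
  stopifnot(inherits(config, "world_config"))
  s <- check_nino_series(nino)
  sp <- config$survey_params; ep <- config$effect_params

  admin_tab <- if (inherits(tele, "teleconnection_map")) tele$admin1 else
    data.table::as.data.table(tele)
  if (!all(c("admin1", "pos_precip") %in% names(admin_tab)))
    stop("teleconnection table needs columns admin1, pos_precip")
  ctry_tab <- if (inherits(tele, "teleconnection_map")) tele$country else NULL

  geo_admin <- unique(geography[, .(country, admin1, region)])
  sample_countries <- sort(unique(geo_admin$country))
  if (!is.null(ctry_tab))
    sample_countries <- intersect(sample_countries,
                                  ctry_tab[teleconnected == TRUE, country])
  if (length(sample_countries) == 0L)
    stop("no teleconnected countries to survey")

  # wave calendar: years with a complete own (May-Dec) and prior tropical year
  wave_years <- seq(config$start_year + 1L,
                    config$start_year + config$n_years - 1L)
  have_full <- s[month >= 5L, .N, by = year][N == 8L, year]
  if (!all(c(wave_years, wave_years - 1L) %in% have_full))
    stop("requested survey years fall outside the index window")

  waves <- data.table::CJ(country = sample_countries, int_year = wave_years)
  waves[, ci := match(country, sample_countries)]
  waves <- waves[(int_year - config$start_year) %% config$survey_gap ==
                   ci %% config$survey_gap]
  if (nrow(waves) == 0L) stop("survey calendar is empty; check survey_gap")
  n_per_wave <- max(1L, round(config$n_children / nrow(waves)))

  set.seed(config$seed + 505L)
  # cluster frame: clusters_per_wave clusters per wave, each in a random admin1
  cl <- waves[rep(seq_len(.N), each = config$clusters_per_wave)]
  cl[, cluster_id := sprintf("%s_%d_c%02d", country, int_year,
                             data.table::rowid(country, int_year))]
  cl[, admin1 := {
      adm <- geo_admin[country == .BY$country, admin1]
      adm[sample.int(length(adm), .N, replace = TRUE)]
    }, by = country]
  cl[, urban := as.integer(stats::runif(.N) < sp$urban_frac)]
  cl[, dhs_weight := stats::rlnorm(.N, sp$weight_meanlog, sp$weight_sdlog)]

  # children distributed over a wave's clusters by a uniform multinomial
  counts <- as.vector(vapply(seq_len(nrow(waves)), function(i)
    as.vector(stats::rmultinom(1, n_per_wave,
                               rep(1, config$clusters_per_wave))),
    integer(config$clusters_per_wave)))
  kids <- cl[rep(seq_len(.N), times = counts)]
  kids[, child_id := sprintf("k%07d", .I)]
  kids[, int_month := sample.int(12L, .N, replace = TRUE)]
  kids[, age_months := sample.int(60L, .N, replace = TRUE) - 1L]
  kids[, sex := sample(c("f", "m"), .N, replace = TRUE)]
  kids[, mother_educ := pmin(stats::rpois(.N, 6), 18L)]
  kids[, mother_age_birth := pmin(pmax(round(stats::rnorm(.N, 26, 6)), 15L), 45L)]
  kids <- geo_admin[, .(admin1, region)][kids, on = "admin1"]

  # optional ENSO-dependent interview timing (robustness-check machinery):
  # warm tropical years pull interviews toward later calendar months
  if (isTRUE(sp$timing_depends_on_enso)) {
    ty0 <- assign_tropical_year(kids$int_year, kids$int_month)
    ex0 <- exposure_lookup(s, sort(unique(ty0)))
    shift <- ex0[match(ty0, tropical_year), exposure]
    shift <- shift - mean(shift)
    kids[, int_month := pmin(12L, pmax(1L, int_month + as.integer(round(shift))))]
  }

  kids[, tropical_year := assign_tropical_year(int_year, int_month)]
  expo <- exposure_lookup(s, sort(unique(kids$tropical_year)))
  kids[, nino := expo[match(kids$tropical_year, tropical_year), exposure]]
  kids[, pos_precip := admin_tab[match(kids$admin1, admin1),
                                 as.integer(pos_precip)]]
  if (anyNA(kids$pos_precip))
    stop("admin1 units missing from the teleconnection table")

  # planted linear predictor shared across outcomes
  fe <- effects$fe_cr[kids, on = c("country", "urban"), fe]
  me <- effects$month_eff[kids[, .(region, month = int_month)],
                          on = c("region", "month"), eff]
  trend <- effects$trend[kids$region] * (kids$int_year - config$start_year)
  ys <- effects$year_shock[as.character(kids$tropical_year)]
  as_ <- effects$admin_shock[kids$admin1]
  ays <- effects$admin_year_shock[kids[, .(admin1, tropical_year)],
                                  on = c("admin1", "tropical_year"), shock]
  base <- fe + effects$gamma_educ[kids$country] * kids$mother_educ +
    effects$gamma_mage[kids$country] * kids$mother_age_birth +
    trend + me + ys + as_ + ays

  for (oc in c("waz", "whz", "bmiz")) {
    b <- ep$beta[[oc]]
    slope <- ifelse(kids$pos_precip == 1L, b[["beta_p"]], b[["beta_n"]])
    y <- base + slope * kids$nino + stats::rnorm(nrow(kids), 0, ep$child_noise_sd)
    y[stats::runif(nrow(kids)) < sp$missing_frac] <- NA_real_
    data.table::set(kids, j = oc, value = y)
  }
  kids[, flagged := stats::runif(.N) < sp$flagged_frac]
  kids[, c("ci", "tropical_year", "nino", "pos_precip") := NULL]

  out <- kids[, .(child_id, country, admin1, region, urban, cluster_id,
                  int_year, int_month, age_months, sex, mother_educ,
                  mother_age_birth, dhs_weight, waz, whz, bmiz, flagged)]
  data.table::setattr(out, "truth",
                      list(config = config, effects = effects,
                           admin_flags = admin_tab))
  out
}

# May-December mean exposure for a set of tropical years (internal)
exposure_lookup <- function(series, years) {
  data.table::data.table(
    tropical_year = years,
    exposure = vapply(years, function(t) tropical_year_mean(series, t),
                      numeric(1)))
}
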