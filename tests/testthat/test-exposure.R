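test_that("tropical-year mean is the exact May-December average", {
  s <- constant_series(1.5, 2000:2002)
  expect_equal(tropical_year_mean(s, 2001), 1.5)

  s2 <- constant_series(0, 2000:2002)
  s2[year == 2001 & month >= 5, value := as.numeric(1:8)]
  expect_equal(tropical_year_mean(s2, 2001), 4.5)

  cfg <- small_config(seed = 3L)
  s3 <- simulate_nino(cfg)
  t0 <- cfg$start_year + 4L
  oracle <- mean(s3[year == t0 & month %in% 5:12, value])  # brute-force slice
  expect_equal(tropical_year_mean(s3, t0), oracle, tolerance = 1e-14)

  # record truncated mid-year: no silent partial mean
  s_trunc <- s3[year < t0 | (year == t0 & month <= 6L)]
  expect_error(tropical_year_mean(s_trunc, t0), "all 8 months")
})

test_that("tropical-year assignment has a sharp May boundary and partitions months", {
  expect_identical(assign_tropical_year(2016L, 2L), 2015L)
  expect_identical(assign_tropical_year(2015L, 5L), 2015L)
  expect_identical(assign_tropical_year(2015L, 4L), 2014L)
  expect_error(assign_tropical_year(2015L, 13L), "1..12")

  # every month of calendar years 2000-2002 lands in exactly one tropical year
  grid <- data.table::CJ(year = 2000:2002, month = 1:12)
  ty <- assign_tropical_year(grid$year, grid$month)
  expect_true(all(ty %in% 1999:2002))
  # a tropical year owns exactly 12 consecutive months (May..April)
  counts <- table(ty[grid$year %in% 2001])
  expect_equal(unname(counts[["2000"]]), 4L)  # Jan-Apr
  expect_equal(unname(counts[["2001"]]), 8L)  # May-Dec
})

test_that("state classification follows the rolling-mean threshold rule", {
  clim <- rep(0, 12)
  warm <- constant_series(0.6, 2000:2002)
  expect_equal(classify_enso_state(warm, clim, 2001), "el_nino")
  flat <- constant_series(0, 2000:2002)
  expect_equal(classify_enso_state(flat, clim, 2001), "neutral")
  cold <- constant_series(-0.6, 2000:2002)
  expect_equal(classify_enso_state(cold, clim, 2001), "la_nina")

  # both thresholds crossed: larger absolute excursion wins
  s <- constant_series(0, 2000:2002)
  s[year == 2001 & month %in% 6:8, value := 0.7]
  s[year == 2001 & month %in% 10:12, value := -1.5]
  expect_equal(classify_enso_state(s, clim, 2001), "la_nina")

  # invariance to adding a constant to both series and climatology
  s_shift <- data.table::copy(s)[, value := value + 26.5]
  expect_equal(classify_enso_state(s_shift, clim + 26.5, 2001), "la_nina")
})

test_that("state label matches an exhaustive scan of all 3-month windows", {
  cfg <- small_config(seed = 17L)
  s <- simulate_nino(cfg)
  clim <- s[, .(ref = mean(value)), by = month][order(month), ref]
  anom <- s$value - clim[s$month]
  idx <- function(y, m) which(s$year == y & s$month == m)
  for (t0 in (cfg$start_year + 1L):(cfg$start_year + cfg$n_years - 2L)) {
    # brute force: centered windows for May t0 .. Apr t0+1, using neighbors
    centers <- c(idx(t0, 5L):idx(t0, 12L), idx(t0 + 1L, 1L):idx(t0 + 1L, 4L))
    means <- vapply(centers, function(i) {
      tri <- (i - 1L):(i + 1L)
      if (min(tri) < 1L || max(tri) > nrow(s)) NA_real_ else mean(anom[tri])
    }, numeric(1))
    means <- means[!is.na(means)]
    expected <- if (max(means) > 0.5 && min(means) < -0.5) {
      if (abs(max(means)) >= abs(min(means))) "el_nino" else "la_nina"
    } else if (max(means) > 0.5) "el_nino"
    else if (min(means) < -0.5) "la_nina" else "neutral"
    expect_equal(classify_enso_state(s, clim, t0), expected,
                 label = sprintf("tropical year %d", t0))
  }
})

test_that("moving climatology re-bases by 5-year block and static matches global means", {
  cfg <- world_config(n_countries = 4, n_years = 40L, seed = 23L)
  s <- simulate_nino(cfg)
  st <- enso_climatology(s, "static")
  expect_equal(unique(st[month == 1, ref]), mean(s[month == 1, value]))
  mv <- enso_climatology(s, "moving", window = 10L, step = 5L)
  y0 <- min(s$year)
  # first block: window centered on (y0 .. y0+4), clipped at the record start
  b1 <- mv[year == y0 & month == 6, ref]
  lo <- ceiling(y0 + 2 - 5); hi <- lo + 9
  expect_equal(b1, mean(s[year >= lo & year <= hi & month == 6, value]))
  # references change across blocks for a trending record
  s_trend <- data.table::copy(s)[, value := value + 0.02 * (year - y0)]
  mv2 <- enso_climatology(s_trend, "moving", window = 10L, step = 5L)
  expect_gt(mv2[year == y0 + 35 & month == 1, ref],
            mv2[year == y0 & month == 1, ref])
})

test_that("detrended anomalies are OLS residuals about the year trend", {
  set.seed(99)
  e0 <- data.table::data.table(tropical_year = 2000:2014,
                               mean_may_dec = rnorm(15))
  e0[, mean_may_dec := mean_may_dec - mean(mean_may_dec)]
  e0_flat <- data.table::copy(e0)
  # remove any incidental trend so raw means are already trendless
  fit <- lm(mean_may_dec ~ tropical_year, e0_flat)
  e0_flat[, mean_may_dec := mean_may_dec - fitted(fit) + mean(fitted(fit))]
  r <- detrended_anomaly(e0_flat)
  expect_equal(r$detrended_anomaly, r$mean_may_dec - mean(r$mean_may_dec),
               tolerance = 1e-10)

  lin <- data.table::data.table(tropical_year = 2000:2012,
                                mean_may_dec = 0.1 * (2000:2012) - 3)
  expect_equal(detrended_anomaly(lin)$detrended_anomaly, rep(0, 13),
               tolerance = 1e-10)

  set.seed(1)
  e <- data.table::data.table(tropical_year = 1986:2015,
                              mean_may_dec = rnorm(30))
  r <- detrended_anomaly(e)
  # closed-form two-parameter least squares oracle
  x <- e$tropical_year; y <- e$mean_may_dec
  bhat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ahat <- mean(y) - bhat * mean(x)
  expect_equal(r$detrended_anomaly, y - (ahat + bhat * x), tolerance = 1e-12)
  expect_lt(abs(sum(r$detrended_anomaly)), 1e-10)

  expect_error(detrended_anomaly(e[1:2]), "fewer than 3")
})

test_that("exposure table combines means, anomalies and states consistently", {
  cfg <- small_config(seed = 29L)
  s <- simulate_nino(cfg)
  et <- build_exposure_table(s)
  expect_equal(nrow(et), cfg$n_years)
  t0 <- cfg$start_year + 3L
  expect_equal(et[tropical_year == t0, mean_may_dec],
               tropical_year_mean(s, t0))
  expect_lt(abs(sum(et$detrended_anomaly)), 1e-8)
  expect_true(all(stats::na.omit(et$state) %in%
                    c("el_nino", "la_nina", "neutral")))
})
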