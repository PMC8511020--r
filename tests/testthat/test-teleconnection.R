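# builds a minimal climate_grid-shaped object from a pixel-by-month matrix
toy_grid <- function(monthly, meta) {
  structure(list(meta = data.table::as.data.table(meta),
                 monthly = data.table::as.data.table(monthly)),
            class = "climate_grid")
}

test_that("a pixel equal to the lag-2 index correlates perfectly in all months", {
  cfg <- small_config(seed = 51L)
  s <- nino_anomaly(simulate_nino(cfg))
  years <- (cfg$start_year + 1L):(cfg$start_year + cfg$n_years - 1L)
  grid_rows <- data.table::CJ(year = years, month = 1:12)
  lag_key <- data.table::data.table(
    year = grid_rows$year - (grid_rows$month - 2 < 1),
    month = ((grid_rows$month - 2 - 1) %% 12) + 1)
  grid_rows[, temperature := s[lag_key, on = c("year", "month"), anom]]
  grid_rows[, `:=`(pixel_id = "px1", precipitation = 0)]
  g <- toy_grid(grid_rows,
                data.table::data.table(pixel_id = "px1", country = "C01",
                                       admin1 = "C01A1", population = 1,
                                       land_area = 1))
  rp <- monthly_lag_correlation(g, simulate_nino(cfg), "temperature",
                                lag = 2, detrend = FALSE)
  expect_equal(rp$r, rep(1, 12), tolerance = 1e-10)
  expect_true(all(rp$p < 1e-12))
})

test_that("correlations match a brute-force year-paired oracle on a noisy pixel", {
  cfg <- small_config(seed = 52L)
  nino <- simulate_nino(cfg)
  grid <- simulate_climate_grid(nino, cfg)
  rp <- monthly_lag_correlation(grid, nino, "temperature", lag = 2,
                                detrend = FALSE)
  s <- nino_anomaly(nino)
  px <- grid$meta[temp_loading != 0, pixel_id][1]
  for (mo in c(1L, 2L, 7L)) {
    mm <- grid$monthly[pixel_id == px & month == mo][order(year)]
    lag_m <- ((mo - 2 - 1) %% 12) + 1
    off <- as.integer(mo - 2 < 1)
    x <- s[data.table::data.table(year = mm$year - off, month = lag_m),
           on = c("year", "month"), value]
    oracle <- stats::cor.test(mm$temperature, x)
    got <- rp[pixel_id == px & month == mo]
    expect_equal(got$r, unname(oracle$estimate), tolerance = 1e-10)
    expect_equal(got$p, oracle$p.value, tolerance = 1e-8)
  }
})

test_that("correlations are invariant to affine rescaling of either series", {
  cfg <- small_config(seed = 53L)
  nino <- simulate_nino(cfg)
  grid <- simulate_climate_grid(nino, cfg)
  r1 <- monthly_lag_correlation(grid, nino, "temperature")
  nino2 <- data.table::copy(nino)[, value := 3.5 * value - 10]
  grid2 <- toy_grid(data.table::copy(grid$monthly)[
    , temperature := -2 * temperature + 7], grid$meta)
  r2 <- monthly_lag_correlation(grid2, nino2, "temperature")
  expect_equal(abs(r1$r), abs(r2$r), tolerance = 1e-10)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
})

test_that("pixel flag applies the >=3-significant-months rule with sign restriction", {
  rp <- data.table::data.table(
    pixel_id = rep(c("a", "b", "c"), each = 12), month = rep(1:12, 3),
    n = 30, r = c(rep(0.9, 3), rep(0.01, 9),    # a: 3 significant months
                  rep(0.9, 2), rep(0.01, 10),   # b: 2 significant months
                  rep(-0.9, 12)),               # c: 12 significant, negative
    p = c(rep(0.001, 3), rep(0.9, 9),
          rep(0.001, 2), rep(0.9, 10),
          rep(0.001, 12)))
  any_sign <- pixel_teleconnected(rp, sign = "any")
  expect_true(any_sign[pixel_id == "a", flag])
  expect_false(any_sign[pixel_id == "b", flag])
  pos_only <- pixel_teleconnected(rp, sign = "positive")
  expect_false(pos_only[pixel_id == "c", flag])
  expect_true(pixel_teleconnected(rp, sign = "negative")[pixel_id == "c", flag])
  # degenerate months never count as significant
  rp_na <- data.table::copy(rp)[pixel_id == "a", p := NA_real_]
  expect_false(pixel_teleconnected(rp_na, sign = "any")[pixel_id == "a", flag])
})

test_that("country rule is weak (>=50% population) and admin rule strict (>50% area)", {
  meta <- data.table::data.table(
    pixel_id = c("p1", "p2", "p3", "p4"),
    country = "C01", admin1 = c("A1", "A1", "A2", "A2"),
    population = c(499, 501, 500, 500), land_area = c(499, 501, 500, 500))
  flags <- data.table::data.table(pixel_id = c("p1", "p2", "p3", "p4"),
                                  n_sig = c(12L, 0L, 12L, 0L),
                                  flag = c(TRUE, FALSE, TRUE, FALSE))
  ct <- country_teleconnected(flags, meta)
  expect_false(ct$teleconnected)            # 49.9% of population
  expect_equal(ct$pop_share, 999 / 2000)
  flags2 <- data.table::copy(flags)[pixel_id == "p2", flag := TRUE]
  expect_true(country_teleconnected(flags2, meta)$teleconnected)  # >= 50%
  # exactly 50.0% of land area: strict rule says not flagged
  ad <- admin_positive_precip(flags, meta)
  expect_false(ad[admin1 == "A2", pos_precip])
  expect_equal(ad[admin1 == "A2", area_share], 0.5)
  # 50.1% of area: flagged
  expect_false(ad[admin1 == "A1", pos_precip])  # flagged pixel has 499/1000
  meta51 <- data.table::copy(meta)[pixel_id == "p1", land_area := 501][
    pixel_id == "p2", land_area := 499]
  expect_true(admin_positive_precip(flags, meta51)[admin1 == "A1", pos_precip])
  # all pixels flagged is always true
  flags_all <- data.table::copy(flags)[, flag := TRUE]
  expect_true(country_teleconnected(flags_all, meta)$teleconnected)
})

test_that("weighted shares match hand-summed oracles on a mixed toy country", {
  set.seed(77)
  meta <- data.table::data.table(
    pixel_id = sprintf("p%02d", 1:10), country = "C01",
    admin1 = rep(c("A1", "A2"), 5),
    population = runif(10, 10, 1000), land_area = runif(10, 10, 1000))
  flags <- data.table::data.table(pixel_id = meta$pixel_id, n_sig = 0L,
                                  flag = runif(10) > 0.5)
  ct <- country_teleconnected(flags, meta)
  hand <- sum(meta$population * flags$flag) / sum(meta$population)
  expect_equal(ct$pop_share, hand, tolerance = 1e-12)
  ad <- admin_positive_precip(flags, meta)
  for (a in c("A1", "A2")) {
    i <- meta$admin1 == a
    expect_equal(ad[admin1 == a, area_share],
                 sum(meta$land_area[i] * flags$flag[i]) / sum(meta$land_area[i]),
                 tolerance = 1e-12)
  }
})

test_that("aggregate flags are monotone in adding a flagged pixel's weight", {
  set.seed(78)
  meta <- data.table::data.table(
    pixel_id = sprintf("p%02d", 1:8), country = "C01", admin1 = "A1",
    population = runif(8, 1, 100), land_area = runif(8, 1, 100))
  flags <- data.table::data.table(pixel_id = meta$pixel_id, n_sig = 0L,
                                  flag = c(rep(TRUE, 5), rep(FALSE, 3)))
  before <- country_teleconnected(flags, meta)$teleconnected
  meta2 <- data.table::copy(meta)[flags$flag == TRUE, population := population * 10]
  after <- country_teleconnected(flags, meta2)$teleconnected
  expect_true(!before || after)
  expect_true(after >= before)
})

test_that("zero-population countries and zero-area admin units are errors", {
  meta <- data.table::data.table(pixel_id = "p1", country = "C01",
                                 admin1 = "A1", population = 0, land_area = 0)
  flags <- data.table::data.table(pixel_id = "p1", n_sig = 0L, flag = FALSE)
  expect_error(country_teleconnected(flags, meta), "zero total population")
  expect_error(admin_positive_precip(flags, meta), "zero land area")
})
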