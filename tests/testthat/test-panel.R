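# small prepared sample reused across blocks
panel_fixture <- function(seed = 42L, n = NULL) {
  sc <- cached_sample(seed = seed)
  tab <- sc$tab
  if (!is.null(n) && n < nrow(tab)) tab <- tab[seq_len(n)]
  tab
}

test_that("design expands controls by country and counts columns as expected", {
  tab <- panel_fixture()
  d <- build_design(tab, model_spec())
  cn <- colnames(d$X)
  n_country <- data.table::uniqueN(tab$country)
  n_region <- data.table::uniqueN(tab$region)
  n_fe <- data.table::uniqueN(paste(tab$country, tab$urban))
  n_mr <- data.table::uniqueN(paste(tab$region, tab$int_month))
  expect_equal(sum(grepl("^mother_educ:country", cn)), n_country)
  expect_equal(sum(grepl("mother_age_birth$", cn)), n_country)
  expect_equal(sum(grepl("^tnorm:region", cn)), n_region)
  # combinatorial count: intercept + 2 exposure + (FE cells - 1) +
  # (month-region cells - 1) + 2 controls x countries + region trends,
  # minus the region identities implied by a full month-region set
  full <- 1 + 2 + (n_fe - 1) + (n_mr - 1) + 2 * n_country + n_region
  expect_equal(ncol(d$X) + length(d$dropped), full)
  expect_true(length(d$dropped) >= n_region - 1)
  expect_false(any(c("nino", "nino_pos") %in% d$dropped))
})

test_that("noise-free planted effects are identified to machine precision", {
  cfg <- deterministic_config(beta_n = -0.03, beta_p = 0.02, alpha = -0.5)
  w <- simulate_world(cfg, tele = "truth")
  tab <- prepare_sample(w$children, w$nino, w$tele, outcome = "waz")
  fit <- fit_fe_wls(build_design(tab, model_spec()))
  expect_equal(unname(fit$coef["nino"]), -0.03, tolerance = 1e-10)
  expect_equal(unname(fit$coef["nino"] + fit$coef["nino_pos"]), 0.02,
               tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("sparse FE solver matches a dense normal-equations oracle", {
  tab <- panel_fixture(n = 900L)
  d <- build_design(tab, model_spec())
  fit <- fit_fe_wls(d)
  # dense brute force: explicit dummies, weighted normal equations
  Xd <- as.matrix(d$X)
  b_dense <- solve(crossprod(Xd, Xd * d$w), crossprod(Xd, d$y * d$w))
  expect_equal(unname(fit$coef), as.numeric(b_dense), tolerance = 1e-8)
  # and an lm.wfit cross-check on the same basis
  b_lm <- stats::lm.wfit(Xd, d$y, d$w)$coefficients
  expect_equal(unname(fit$coef), unname(b_lm), tolerance = 1e-8)
})

test_that("cluster sandwich terms match an explicit score-outer-product construction", {
  tab <- panel_fixture(n = 900L)
  d <- build_design(tab, model_spec())
  fit <- twoway_cluster_se(fit_fe_wls(d))
  meats <- attr(fit, "meats")
  Xd <- as.matrix(d$X)
  score <- Xd * (d$w * fit$resid)
  brute <- function(cl) {
    M <- matrix(0, ncol(Xd), ncol(Xd))
    for (g in unique(cl)) {
      s_g <- colSums(score[cl == g, , drop = FALSE])
      M <- M + tcrossprod(s_g)
    }
    M
  }
  expect_equal(meats$dim1, brute(d$cl1), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(meats$dim2, brute(d$cl2), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(meats$intersection, brute(paste(d$cl1, d$cl2, sep = "\r")),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("singleton clusters in both dimensions reduce to HC1 robust SEs", {
  tab <- panel_fixture(n = 400L)
  d <- build_design(tab, model_spec())
  d$cl1 <- sprintf("a%06d", seq_len(d$n))
  d$cl2 <- sprintf("b%06d", seq_len(d$n))
  fit <- twoway_cluster_se(fit_fe_wls(d))
  Xd <- as.matrix(d$X)
  bread <- solve(crossprod(Xd, Xd * d$w))
  meat_hc <- crossprod(Xd * (d$w * fit$resid))
  v_hc1 <- (d$n / (d$n - ncol(Xd))) * bread %*% meat_hc %*% bread
  expect_equal(unname(fit$se["nino"]), sqrt(v_hc1[2, 2]), tolerance = 1e-6)
})

test_that("estimates and SEs are invariant to rescaling all weights", {
  tab <- panel_fixture(n = 2000L)
  r1 <- estimate_enso_effect(tab, model_spec())
  tab2 <- data.table::copy(tab)[, weight := weight * 1234.5]
  r2 <- estimate_enso_effect(tab2, model_spec())
  expect_equal(r1$terms$estimate, r2$terms$estimate, tolerance = 1e-10)
  expect_equal(r1$terms$se, r2$terms$se, tolerance = 1e-10)
  expect_equal(r1$r2, r2$r2, tolerance = 1e-10)
})

test_that("FWL residual-on-residual slope equals the joint-fit coefficient", {
  tab <- panel_fixture()
  d <- build_design(tab, model_spec())
  fit <- fit_fe_wls(d)
  slopes <- fwl_slope(d)
  expect_equal(slopes["nino"], fit$coef["nino"], tolerance = 1e-8)
  expect_equal(slopes["nino_pos"], fit$coef["nino_pos"], tolerance = 1e-8)
})

test_that("t-critical intervals are wider than normal ones and CIs follow est +/- crit*SE", {
  tab <- panel_fixture(n = 3000L)
  rn <- estimate_enso_effect(tab, model_spec(critical = "normal"))
  expect_equal(rn$terms$ci_upper - rn$terms$estimate,
               stats::qnorm(0.975) * rn$terms$se, tolerance = 1e-10)
  rt <- estimate_enso_effect(tab, model_spec(critical = "t"))
  expect_true(all(rt$terms$ci_upper - rt$terms$ci_lower >
                    rn$terms$ci_upper - rn$terms$ci_lower))
})

test_that("placebo machinery reproduces the observed estimate under the identity map", {
  tab <- panel_fixture()
  res <- estimate_enso_effect(tab, model_spec())
  pl <- placebo_randomization(tab, model_spec(), n_perm = 100L, seed = 1L)
  expect_equal(pl$observed, unname(res$terms$estimate[1]), tolerance = 1e-8)
  expect_true(pl$p_value > 0 && pl$p_value <= 1)
  expect_length(pl$draws, 100L)
  expect_error(placebo_randomization(tab, n_perm = 50L), "at least 100")
})

test_that("a stratum equal to the full sample reproduces the pooled estimate", {
  tab <- panel_fixture()
  neg <- tab[pos_precip == 0L]
  spec_no_int <- model_spec(include_interaction = FALSE)
  pooled <- estimate_enso_effect(neg, spec_no_int)
  # all strata collapse to one when every interview is in the same decade
  tab_onedec <- data.table::copy(tab)
  tab_onedec[, int_year := 2000L + (int_year %% 10L)]
  tab_onedec[, tropical_year := 2000L + (tropical_year %% 10L)]
  strata <- subsample_effects(tab_onedec, model_spec(), by = "decade")
  expect_equal(nrow(strata), 1L)
  pooled2 <- estimate_enso_effect(tab_onedec[pos_precip == 0L], spec_no_int)
  expect_equal(strata$estimate, unname(pooled2$terms$estimate[1]),
               tolerance = 1e-10)
  expect_equal(strata$se, unname(pooled2$terms$se[1]), tolerance = 1e-10)
  # region strata cover the subsample
  by_region <- subsample_effects(tab, model_spec(), by = "region")
  expect_equal(sum(by_region$n), nrow(neg))
  expect_identical(pooled$terms$term[1], "nino")
})

test_that("Epanechnikov kernel has compact support and the curve tracks a linear truth", {
  expect_equal(epanechnikov(c(-1, 1, 1.5, -2)), rep(0, 4))
  expect_equal(epanechnikov(0), 0.75)
  u <- seq(-0.99, 0.99, by = 0.01)
  expect_true(all(epanechnikov(u) > 0))

  tab <- panel_fixture()
  spec <- model_spec()
  curve <- fwl_residual_curve(tab, spec, bandwidth = 0.7)
  expect_true(all(c("neg_neutral", "positive") %in% curve$subsample))
  hist <- attr(curve, "histogram")
  expect_true(sum(hist$count) > 0)
  # linear truth: central slope of the curve ~ the panel coefficient
  res <- estimate_enso_effect(tab, spec)
  cn <- curve[subsample == "neg_neutral"]
  mid <- cn[abs(x) < stats::sd(tab[pos_precip == 0L, nino]) * 1.5]
  slope <- stats::coef(stats::lm(fit ~ x, mid))[2]
  expect_lt(abs(slope - res$terms$estimate[1]), 0.02)
  expect_error(fwl_residual_curve(tab, spec, bandwidth = 0), "positive")
})

test_that("global weighted residual-on-residual regression equals beta_n exactly", {
  tab <- panel_fixture(n = 2500L)
  spec <- model_spec(include_interaction = FALSE)
  d <- build_design(tab, spec)
  fit <- fit_fe_wls(d)
  r <- fwl_residualize(d, exclude = "nino")
  slope <- sum(r$w * r$resid_x[, 1] * r$resid_y) /
    sum(r$w * r$resid_x[, 1]^2)
  expect_equal(slope, unname(fit$coef["nino"]), tolerance = 1e-10)
})

test_that("rank deficiency and insufficient clusters are caught", {
  tab <- panel_fixture(n = 500L)
  d <- build_design(tab, model_spec())
  d$cl1 <- rep("only", d$n)
  expect_error(twoway_cluster_se(fit_fe_wls(d)), "at least 2 clusters")
  # duplicated exposure column is pruned, not fatal
  tab2 <- data.table::copy(tab)[, mother_educ := mother_age_birth]
  d2 <- build_design(tab2, model_spec())
  expect_true(length(d2$dropped) > 0)
})

test_that("supplementary variants: lags, age interactions, unweighted, decade FEs", {
  cfg <- deterministic_config(beta_n = -0.03, beta_p = 0.02, alpha = -0.5)
  w <- simulate_world(cfg, tele = "truth")
  tab <- prepare_sample(w$children, w$nino, w$tele, outcome = "waz", lags = 1L)
  expect_true("nino_lag1" %in% names(tab))

  # lagged exposure has no planted effect: its coefficient is exactly zero
  # in the noise-free world while the contemporaneous slope stays exact
  fit_lag <- fit_fe_wls(build_design(tab, model_spec(lags = 1L)))
  expect_equal(unname(fit_lag$coef["nino"]), -0.03, tolerance = 1e-8)
  expect_lt(abs(fit_lag$coef["nino_lag1"]), 1e-8)

  # age-category interactions are exactly zero under the age-homogeneous DGP
  fit_age <- fit_fe_wls(build_design(tab, model_spec(age_categories = TRUE)))
  expect_equal(unname(fit_age$coef["nino"]), -0.03, tolerance = 1e-8)
  age_int <- fit_age$coef[grepl("^nino:agecat", names(fit_age$coef))]
  expect_length(age_int, 4L)
  expect_lt(max(abs(age_int)), 1e-8)

  # unweighted and decade-FE variants identify the same noise-free truth
  fit_uw <- fit_fe_wls(build_design(tab, model_spec(weighted = FALSE)))
  expect_equal(unname(fit_uw$coef["nino"]), -0.03, tolerance = 1e-8)
  expect_equal(unique(fit_uw$design$w), 1)
  fit_dec <- fit_fe_wls(build_design(tab, model_spec(trend = "decade_fe")))
  expect_equal(unname(fit_dec$coef["nino"]), -0.03, tolerance = 1e-8)
  expect_true(any(grepl("decade_region", colnames(fit_dec$design$X))))

  # lagged years preceding the record surface as NA, dropped with the rows
  expect_true(all(is.na(
    attach_exposure(w$children, w$nino, w$tele, lags = 30L)$nino_lag30)))
})
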