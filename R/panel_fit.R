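#' Model specification for the ENSO panel regression
#'
#' Describes one estimating equation: outcome, whether the exposure is
#' interacted with the admin1 positive-precipitation indicator, the
#' detrending scheme (region-specific linear trends in survey year, or
#' decade-by-region fixed effects), country-specific mother controls,
#' region-by-interview-month fixed effects, country-by-urban fixed-effect
#' cells, and the two clustering dimensions.
#'
#' @param outcome outcome column (`"waz"`, `"whz"`, `"bmiz"`,
#'   `"underweight"`, `"wasted"`).
#' @param include_interaction include `nino x pos_precip` (default TRUE).
#' @param trend `"region_linear"` or `"decade_fe"`.
#' @param controls numeric controls interacted by country.
#' @param clusters length-2 character: the two clustering columns.
#' @param se_adjust small-sample adjustment: `"CR1"` (G/(G-1)*(N-1)/(N-K)
#'   per clustering dimension) or `"none"`.
#' @param critical `"normal"` (CI = est +/- 1.96 SE, matching the reporting
#'   convention) or `"t"` (t with min(G1,G2)-1 df, more conservative).
#' @param lags integer vector of tropical-year lags: adds `nino_lag<k>`
#'   exposure terms (columns supplied by [attach_exposure()] with the same
#'   `lags`).
#' @param age_categories interact the exposure with child age bins
#'   0-5, 6-11, 12-23, 24-35, 36-59 months (reference 0-5); adds the bin
#'   main effects too.
#' @param weighted set `FALSE` for the unweighted variant (all observation
#'   weights one).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(outcome = "waz",
                       include_interaction = TRUE,
                       trend = c("region_linear", "decade_fe"),
                       controls = c("mother_educ", "mother_age_birth"),
                       clusters = c("tropical_year", "admin1"),
                       se_adjust = c("CR1", "none"),
                       critical = c("normal", "t"),
                       lags = integer(0),
                       age_categories = FALSE,
                       weighted = TRUE) {
  if (anyDuplicated(controls)) stop("a control appears twice in the spec")
  if (length(lags) && any(lags < 1L)) stop("lags must be positive integers")
  structure(list(outcome = outcome,
                 include_interaction = include_interaction,
                 trend = match.arg(trend),
                 controls = controls,
                 clusters = clusters,
                 se_adjust = match.arg(se_adjust),
                 critical = match.arg(critical),
                 lags = as.integer(lags),
                 age_categories = isTRUE(age_categories),
                 weighted = isTRUE(weighted)),
            class = "model_spec")
}

#' Build the sparse weighted design for the panel regression
#'
#' Expands the specification into a sparse design matrix: intercept,
#' exposure (`nino`) and optionally its interaction with `pos_precip`,
#' country-by-urban fixed-effect dummies, region-by-interview-month
#' dummies, country-interacted control slopes, and region-specific linear
#' survey-year trends (or decade-by-region dummies). Reference categories
#' are the first level by sorted id. Perfectly collinear columns (e.g. the
#' region identities implied by a full set of month-by-region dummies on
#' top of country dummies) are detected by sequential elimination on the
#' weighted Gram matrix and pruned, with the dropped names recorded;
#' exposure columns are ordered first and are never the ones pruned.
#'
#' @param table prepared child table (see [prepare_sample()]): needs the
#'   outcome, `nino`, `pos_precip`, `country`, `admin1`, `region`, `urban`,
#'   `int_year`, `int_month`, `tropical_year`, `weight`, and the controls.
#' @param spec a [model_spec()].
#' @return list of class `enso_design`: `X` (sparse, pruned), `y`, `w`,
#'   `cl1`, `cl2` (cluster id vectors), `dropped` (pruned column names),
#'   `spec`, `n`.
#' @export
build_design <- function(table, spec = model_spec()) {
  ch <- data.table::as.data.table(table)
  need <- unique(c(spec$outcome, "nino", "pos_precip", "country", "admin1",
                   "region", "urban", "int_year", "int_month", "weight",
                   spec$controls, spec$clusters,
                   if (length(spec$lags)) sprintf("nino_lag%d", spec$lags),
                   if (isTRUE(spec$age_categories)) "age_months"))
  miss <- setdiff(need, names(ch))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(ch[, need, with = FALSE])
  ch <- ch[ok]

  df <- data.frame(
    nino = ch$nino,
    fe_cr = factor(paste(ch$country, ifelse(ch$urban == 1, "urban", "rural"),
                         sep = ":")),
    month_region = factor(paste(ch$region, sprintf("m%02d", ch$int_month),
                                sep = ":")),
    country = factor(ch$country),
    region = factor(ch$region),
    tnorm = ch$int_year - min(ch$int_year))
  for (ctrl in spec$controls) df[[ctrl]] <- as.numeric(ch[[ctrl]])

  terms <- c("nino")
  if (spec$include_interaction) {
    df$nino_pos <- ch$nino * (ch$pos_precip == 1L)
    terms <- c(terms, "nino_pos")
  }
  for (k in spec$lags) {
    lag_col <- sprintf("nino_lag%d", k)
    if (!lag_col %in% names(ch))
      stop("spec requests lag ", k, " but column ", lag_col,
           " is missing; attach exposures with matching `lags`")
    df[[lag_col]] <- as.numeric(ch[[lag_col]])
    terms <- c(terms, lag_col)
  }
  if (spec$age_categories) {
    if (!"age_months" %in% names(ch))
      stop("age_categories requires an age_months column")
    df$agecat <- cut(ch$age_months, breaks = c(-1, 5, 11, 23, 35, 59),
                     labels = c("a00_05", "a06_11", "a12_23", "a24_35",
                                "a36_59"))
    terms <- c(terms, "agecat", "nino:agecat")
  }
  # single-level factors carry no information beyond the intercept: degrade
  # the affected term rather than tripping model.matrix contrasts
  multi <- function(fct) nlevels(fct) > 1L
  if (multi(df$fe_cr)) terms <- c(terms, "fe_cr")
  if (multi(df$month_region)) terms <- c(terms, "month_region")
  terms <- c(terms, vapply(spec$controls, function(ctrl)
    if (multi(df$country)) paste0(ctrl, ":country") else ctrl, character(1)))
  if (spec$trend == "region_linear") {
    terms <- c(terms, if (multi(df$region)) "tnorm:region" else "tnorm")
  } else {
    df$decade_region <- factor(paste(ch$region,
                                     10L * (ch$int_year %/% 10L), sep = ":"))
    if (multi(df$decade_region)) terms <- c(terms, "decade_region")
  }
  f <- stats::reformulate(terms, intercept = TRUE)
  X <- Matrix::sparse.model.matrix(f, data = df)

  w <- if (isTRUE(spec$weighted) || is.null(spec$weighted)) ch$weight else
    rep(1, nrow(ch))
  if (any(w <= 0)) stop("weights must be strictly positive")
  keep <- drop_collinear_cols(X, w)
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  X <- X[, keep, drop = FALSE]

  structure(list(X = X, y = as.numeric(ch[[spec$outcome]]), w = w,
                 cl1 = as.character(ch[[spec$clusters[1]]]),
                 cl2 = as.character(ch[[spec$clusters[2]]]),
                 dropped = dropped, spec = spec, n = nrow(ch),
                 table = ch),
            class = "enso_design")
}

# sequential (order-preserving) detection of collinear columns on the
# weighted Gram matrix; earlier columns win, and the design puts the
# intercept and exposure block first, so those are never the ones dropped.
drop_collinear_cols <- function(X, w, tol = 1e-9) {
  G <- as.matrix(Matrix::crossprod(X, X * w))
  p <- ncol(G)
  d0 <- diag(G)
  keep <- logical(p)
  A <- G
  for (j in seq_len(p)) {
    piv <- A[j, j]
    if (is.na(piv) || piv < tol * max(d0[j], 1)) {
      A[j, ] <- 0; A[, j] <- 0
      next
    }
    keep[j] <- TRUE
    if (j < p) {
      idx <- (j + 1L):p
      fac <- A[idx, j] / piv
      A[idx, idx] <- A[idx, idx] - tcrossprod(fac, A[j, idx])
      A[idx, j] <- 0; A[j, idx] <- 0
    }
  }
  which(keep)
}

#' Weighted least squares with high-dimensional fixed effects
#'
#' Solves the weighted normal equations on the sparse design from
#' [build_design()] via a Cholesky factorization of X'WX. Fixed effects
#' enter as explicit (sparse) dummies, which is numerically identical to
#' absorbing them by within-transformation; the sparse route keeps both the
#' estimates and the residuals exact. Reports the weighted R-squared and
#' the weighted outcome mean.
#'
#' @param design an `enso_design` from [build_design()].
#' @return list of class `enso_fit`: `coef`, `bread` (inverse weighted Gram
#'   matrix), `resid`, `r2`, `wmean`, `n`, `k`, plus the design.
#' @export
fit_fe_wls <- function(design) {
  stopifnot(inherits(design, "enso_design"))
  X <- design$X; y <- design$y; w <- design$w
  if (length(y) <= ncol(X))
    stop("fewer observations than identified parameters")
  XtWX <- as.matrix(Matrix::crossprod(X, X * w))
  XtWy <- as.numeric(Matrix::crossprod(X, y * w))
  ch <- tryCatch(chol(XtWX), error = function(e)
    stop("rank-deficient design after pruning; offending columns: ",
         paste(colnames(X)[diag(XtWX) < 1e-12], collapse = ", ")))
  coef <- backsolve(ch, forwardsolve(t(ch), XtWy))
  names(coef) <- colnames(X)
  fitted <- as.numeric(X %*% coef)
  resid <- y - fitted
  wmean <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * resid^2) / sum(w * (y - wmean)^2)
  bread <- chol2inv(ch)
  dimnames(bread) <- list(colnames(X), colnames(X))
  structure(list(coef = coef, bread = bread, resid = resid, r2 = r2,
                 wmean = wmean, n = length(y), k = ncol(X),
                 design = design),
            class = "enso_fit")
}

#' Two-way cluster-robust standard errors
#'
#' Cluster-robust sandwich variance combined over the two clustering
#' dimensions by inclusion-exclusion: V = V(dim1) + V(dim2) -
#' V(dim1 x dim2), each term a CR sandwich built from cluster-summed score
#' vectors, with an optional CR1 small-sample multiplier
#' G/(G-1) x (N-1)/(N-K) applied per dimension (including the
#' intersection). The inclusion-exclusion combination is not positive
#' semi-definite in general: if a reported exposure term draws a
#' non-positive combined variance the run aborts with a diagnostic rather
#' than silently truncating, while nuisance coefficients (fixed-effect and
#' control columns) with non-positive combined variance get `NA` standard
#' errors and are counted in `n_nonpos_nuisance`. With every observation
#' its own cluster in both dimensions the estimator reduces exactly to
#' HC1-type heteroskedasticity-robust variance.
#'
#' @param fit an `enso_fit`.
#' @param se_adjust `"CR1"` or `"none"`; defaults to the spec's choice.
#' @param critical `"normal"` or `"t"`; defaults to the spec's choice.
#' @return the fit, augmented with `vcov`, `se`, `p`, `ci_lower`,
#'   `ci_upper`, `g1`, `g2` and attribute `meats` (the three meat
#'   matrices, for verification against explicit constructions).
#' @export
twoway_cluster_se <- function(fit, se_adjust = NULL, critical = NULL) {
  stopifnot(inherits(fit, "enso_fit"))
  spec <- fit$design$spec
  se_adjust <- se_adjust %||% spec$se_adjust
  critical <- critical %||% spec$critical
  X <- fit$design$X; w <- fit$design$w; e <- fit$resid
  cl1 <- fit$design$cl1; cl2 <- fit$design$cl2
  if (length(unique(cl1)) < 2L || length(unique(cl2)) < 2L)
    stop("need at least 2 clusters in each dimension")
  cl12 <- paste(cl1, cl2, sep = "\r")

  meat <- function(cl) {
    f <- factor(cl)
    Ind <- Matrix::sparseMatrix(i = seq_along(cl), j = as.integer(f),
                                x = 1, dims = c(length(cl), nlevels(f)))
    S <- as.matrix(Matrix::crossprod(Ind, X * (w * e)))
    list(M = crossprod(S), G = nlevels(f))
  }
  m1 <- meat(cl1); m2 <- meat(cl2); m12 <- meat(cl12)
  adj <- function(G) if (se_adjust == "CR1")
    G / (G - 1) * (fit$n - 1) / (fit$n - fit$k) else 1
  V <- fit$bread %*% (adj(m1$G) * m1$M + adj(m2$G) * m2$M -
                      adj(m12$G) * m12$M) %*% fit$bread
  enforce <- intersect(c("nino", "nino_pos"), names(fit$coef))
  bad <- diag(V) <= 0
  if (any(bad[enforce]))
    stop("two-way combined variance has non-positive diagonal entries for ",
         "reported terms: ", paste(enforce[bad[enforce]], collapse = ", "),
         " (inclusion-exclusion not positive definite here)")
  se <- ifelse(bad, NA_real_, sqrt(pmax(diag(V), 0)))
  names(se) <- names(fit$coef)
  z <- fit$coef / se
  if (critical == "t") {
    dfree <- min(m1$G, m2$G) - 1L
    crit <- stats::qt(0.975, dfree)
    p <- 2 * stats::pt(-abs(z), dfree)
  } else {
    crit <- stats::qnorm(0.975)
    p <- 2 * stats::pnorm(-abs(z))
  }
  fit$vcov <- V
  fit$se <- se
  fit$p <- p
  fit$ci_lower <- fit$coef - crit * se
  fit$ci_upper <- fit$coef + crit * se
  fit$g1 <- m1$G; fit$g2 <- m2$G
  fit$n_nonpos_nuisance <- sum(bad)
  attr(fit, "meats") <- list(dim1 = m1$M, dim2 = m2$M, intersection = m12$M,
                             adj = c(adj(m1$G), adj(m2$G), adj(m12$G)))
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate the ENSO effect on a prepared sample
#'
#' One-call wrapper: build the design, fit by weighted least squares, and
#' attach two-way clustered standard errors. The result prints in the
#' conventional regression-table layout (coefficient, SE, p, 95% CI,
#' dependent-variable mean, N, R-squared).
#'
#' @param table prepared child table (see [prepare_sample()]).
#' @param spec a [model_spec()].
#' @return list of class `estimation_result`: `terms` (a `data.table` for
#'   the exposure terms), `fit` (the full `enso_fit`), `beta_p` (total
#'   slope in positive-precip areas with its SE, when the interaction is
#'   present), `n`, `r2`, `wmean`, `g_year`, `g_admin`.
#' @export
estimate_enso_effect <- function(table, spec = model_spec()) {
  fit <- twoway_cluster_se(fit_fe_wls(build_design(table, spec)))
  keep <- intersect(c("nino", if (spec$include_interaction) "nino_pos"),
                    names(fit$coef))
  terms <- data.table::data.table(
    term = keep,
    estimate = fit$coef[keep],
    se = fit$se[keep],
    p = fit$p[keep],
    ci_lower = fit$ci_lower[keep],
    ci_upper = fit$ci_upper[keep])
  beta_p <- NULL
  if (spec$include_interaction) {
    v <- fit$vcov[keep, keep]
    beta_p <- c(estimate = sum(fit$coef[keep]),
                se = sqrt(sum(v)))
  }
  structure(list(terms = terms, fit = fit, beta_p = beta_p,
                 n = fit$n, r2 = fit$r2, wmean = fit$wmean,
                 g_year = fit$g1, g_admin = fit$g2,
                 dropped = fit$design$dropped, spec = spec),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, digits = 4, ...) {
  cat(sprintf("ENSO panel estimate | outcome: %s | N = %s | R2 = %.3f | weighted mean = %.3f\n",
              x$spec$outcome, format(x$n, big.mark = ","), x$r2, x$wmean))
  cat(sprintf("clusters: %d years x %d admin1 units\n", x$g_year, x$g_admin))
  print(x$terms, digits = digits)
  if (!is.null(x$beta_p))
    cat(sprintf("total slope in positive-precip areas: %.4f (SE %.4f)\n",
                x$beta_p["estimate"], x$beta_p["se"]))
  if (length(x$dropped))
    cat("pruned collinear columns:", length(x$dropped), "\n")
  invisible(x)
}
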