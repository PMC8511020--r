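#' Residualize vectors on the control block of a design
#'
#' Weighted projection residuals with respect to every design column except
#' the exposure block, the Frisch-Waugh-Lovell partialling step. Returns a
#' reusable projector so many vectors (e.g. placebo exposure draws) can be
#' residualized at the cost of two sparse products each.
#'
#' @param design an `enso_design`.
#' @param exclude column names treated as the exposure block (default
#'   `"nino"` and, when present, `"nino_pos"`).
#' @return list: `resid_y`, `resid_x` (matrix, one column per excluded
#'   term), `w`, and `project(v)` returning the residual of any vector.
#' @export
fwl_residualize <- function(design, exclude = NULL) {
  stopifnot(inherits(design, "enso_design"))
  if (is.null(exclude))
    exclude <- intersect(c("nino", "nino_pos"), colnames(design$X))
  ci <- match(exclude, colnames(design$X))
  if (anyNA(ci)) stop("exclude names not in design columns")
  C <- design$X[, -ci, drop = FALSE]
  w <- design$w
  CtWC <- as.matrix(Matrix::crossprod(C, C * w))
  chC <- chol(CtWC)
  project <- function(v) {
    b <- backsolve(chC, forwardsolve(t(chC),
                                     as.numeric(Matrix::crossprod(C, v * w))))
    as.numeric(v - C %*% b)
  }
  rx <- vapply(ci, function(j) project(as.numeric(design$X[, j])),
               numeric(nrow(design$X)))
  colnames(rx) <- exclude
  list(resid_y = project(design$y), resid_x = rx, w = w, project = project)
}

#' Exposure coefficient via the Frisch-Waugh-Lovell route
#'
#' Partials all non-exposure columns out of the outcome and the exposure
#' block, then runs the small weighted regression of residual on residuals.
#' By the FWL theorem this reproduces the joint-fit exposure coefficients
#' exactly; it is exposed both as a numerical cross-check and as the fast
#' path for permutation refits.
#'
#' @param design an `enso_design`.
#' @return named vector of exposure coefficients.
#' @export
fwl_slope <- function(design) {
  r <- fwl_residualize(design)
  solve_wls(r$resid_x, r$resid_y, r$w)
}

# tiny dense WLS used on residualized blocks
solve_wls <- function(X, y, w) {
  X <- as.matrix(X)
  b <- solve(crossprod(X, X * w), crossprod(X, y * w))
  stats::setNames(as.numeric(b), colnames(X))
}

#' Placebo randomization test for the ENSO coefficient
#'
#' Permutes the tropical-year exposure assignment across years (every child
#' of a year receives the exposure of another year; all within-year
#' structure is preserved), refits the exposure block per permutation via
#' the FWL route (numerically identical to a full refit), and returns the
#' permutation distribution of the main coefficient with a rank-based
#' two-sided p-value for the observed estimate. The identity mapping
#' reproduces the observed estimate exactly.
#'
#' @param table prepared child table.
#' @param spec a [model_spec()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation draws.
#' @return list of class `placebo_result`: `observed`, `draws` (numeric
#'   vector of permuted beta_n estimates), `p_value`, `n_years`.
#' @export
placebo_randomization <- function(table, spec = model_spec(), n_perm = 200L,
                                  seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  design <- build_design(table, spec)
  ch <- design$table
  years <- sort(unique(ch$tropical_year))
  if (length(years) < 5L) stop("fewer than 5 distinct tropical years")
  expo_by_year <- ch[, .(nino = nino[1L]), by = tropical_year]
  data.table::setkey(expo_by_year, tropical_year)
  year_idx <- match(ch$tropical_year, expo_by_year$tropical_year)
  pos <- ch$pos_precip == 1L

  r <- fwl_residualize(design)
  with_int <- design$spec$include_interaction && any(pos) && !all(pos)
  beta_of <- function(xv) {
    xb <- cbind(nino = r$project(xv),
                if (with_int) r$project(xv * pos))
    unname(solve_wls(xb, r$resid_y, r$w)[1L])
  }
  observed <- beta_of(expo_by_year$nino[year_idx])

  set.seed(seed)
  draws <- vapply(seq_len(n_perm), function(i) {
    perm <- sample.int(nrow(expo_by_year))
    beta_of(expo_by_year$nino[perm][year_idx])
  }, numeric(1))
  p <- (1 + sum(abs(draws) >= abs(observed))) / (n_perm + 1)
  structure(list(observed = observed, draws = draws, p_value = p,
                 n_years = length(years)),
            class = "placebo_result")
}

#' @export
print.placebo_result <- function(x, ...) {
  cat(sprintf("placebo randomization: observed beta_n = %.4f, permutation p = %.4f (%d draws, %d years)\n",
              x$observed, x$p_value, length(x$draws), x$n_years))
  invisible(x)
}

#' Subsample estimates by decade or world region
#'
#' Refits the specification within each stratum of the non-positive-precip
#' subsample (the interaction term is dropped: the subsample has no
#' positive-precip variation). Strata without exposure variation are an
#' error.
#'
#' @param table prepared child table.
#' @param spec a [model_spec()].
#' @param by `"decade"` or `"region"`.
#' @return `data.table` (`stratum`, `estimate`, `se`, `p`, `ci_lower`,
#'   `ci_upper`, `n`).
#' @export
subsample_effects <- function(table, spec = model_spec(),
                              by = c("decade", "region")) {
  by <- match.arg(by)
  ch <- data.table::as.data.table(table)[pos_precip == 0L]
  if (nrow(ch) == 0L) stop("non-positive-precip subsample is empty")
  ch[, stratum := if (by == "decade")
    sprintf("%ds", 10L * (int_year %/% 10L)) else region]
  spec2 <- spec; spec2$include_interaction <- FALSE
  strata <- sort(unique(ch$stratum))
  out <- lapply(strata, function(st) {
    sub <- ch[stratum == st]
    if (data.table::uniqueN(sub$nino) < 2L)
      stop("stratum ", st, " has no exposure variation")
    est <- estimate_enso_effect(sub, spec2)
    data.table::data.table(stratum = st,
                           estimate = est$terms$estimate[1L],
                           se = est$terms$se[1L], p = est$terms$p[1L],
                           ci_lower = est$terms$ci_lower[1L],
                           ci_upper = est$terms$ci_upper[1L],
                           n = est$n)
  })
  data.table::rbindlist(out)
}

#' Epanechnikov local-polynomial curve of residualized outcome on exposure
#'
#' The Frisch-Waugh-Lovell visualization of the panel estimate: outcome and
#' exposure are residualized on the controls-only specification (no
#' exposure terms), separately for the negative/neutral and the
#' positive-precip subsamples, then the outcome residuals are smoothed on
#' the exposure residuals with an Epanechnikov kernel-weighted local
#' polynomial (default local linear), bandwidth in exposure-residual units.
#' Kernel weights are combined with the observation weights; pointwise 95%
#' confidence intervals use the local sandwich variance. Histogram counts
#' of the exposure residuals are attached for the conventional marginal
#' histogram.
#'
#' @param table prepared child table.
#' @param spec a [model_spec()].
#' @param bandwidth kernel half-width in exposure-residual units (> 0,
#'   default 0.7).
#' @param degree local polynomial degree (default 1, local linear).
#' @param n_grid evaluation points per subsample (default 50).
#' @param n_bins histogram bins per subsample (default 30).
#' @return `data.table` (`subsample`, `x`, `fit`, `se`, `ci_lower`,
#'   `ci_upper`, `n_local`), histogram as attribute `"histogram"`.
#' @export
fwl_residual_curve <- function(table, spec = model_spec(), bandwidth = 0.7,
                               degree = 1L, n_grid = 50L, n_bins = 30L) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  ch <- data.table::as.data.table(table)
  spec0 <- spec; spec0$include_interaction <- FALSE
  out <- list(); hists <- list()
  for (sub_name in c("neg_neutral", "positive")) {
    sub <- ch[pos_precip == (sub_name == "positive")]
    if (nrow(sub) == 0L) next
    design <- build_design(sub, spec0)
    r <- fwl_residualize(design, exclude = "nino")
    rx <- r$resid_x[, 1L]; ry <- r$resid_y; w <- r$w
    grid <- seq(stats::quantile(rx, 0.005), stats::quantile(rx, 0.995),
                length.out = n_grid)
    res <- t(vapply(grid, function(x0)
      local_poly_point(rx, ry, w, x0, bandwidth, degree), numeric(3)))
    out[[sub_name]] <- data.table::data.table(
      subsample = sub_name, x = grid, fit = res[, 1L], se = res[, 2L],
      ci_lower = res[, 1L] - 1.96 * res[, 2L],
      ci_upper = res[, 1L] + 1.96 * res[, 2L], n_local = res[, 3L])
    h <- graphics::hist(rx, breaks = n_bins, plot = FALSE)
    hists[[sub_name]] <- data.table::data.table(
      subsample = sub_name, mid = h$mids, count = h$counts)
  }
  curve <- data.table::rbindlist(out)
  data.table::setattr(curve, "histogram", data.table::rbindlist(hists))
  curve
}

#' Epanechnikov kernel weights
#'
#' `K(u) = 0.75 (1 - u^2)` on `|u| < 1` and exactly zero outside (compact
#' support).
#'
#' @param u scaled distances.
#' @return kernel weights.
#' @export
epanechnikov <- function(u) ifelse(abs(u) < 1, 0.75 * (1 - u^2), 0)

# local polynomial point estimate with sandwich CI; returns (fit, se, n_local)
local_poly_point <- function(rx, ry, w, x0, bandwidth, degree) {
  u <- (rx - x0) / bandwidth
  k <- epanechnikov(u)
  use <- k > 0
  if (sum(use) <= degree + 1L) return(c(NA_real_, NA_real_, sum(use)))
  ww <- w[use] * k[use]
  Z <- outer(rx[use] - x0, 0:degree, `^`)
  ZtWZ <- crossprod(Z, Z * ww)
  b <- tryCatch(solve(ZtWZ, crossprod(Z, ry[use] * ww)),
                error = function(e) NULL)
  if (is.null(b)) return(c(NA_real_, NA_real_, sum(use)))
  e <- ry[use] - Z %*% b
  meat <- crossprod(Z, Z * (ww * e[, 1L])^2)
  V <- solve(ZtWZ, t(solve(ZtWZ, meat)))
  c(b[1L], sqrt(V[1L, 1L]), sum(use))
}
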