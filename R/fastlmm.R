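# Spectral-transform mixed model machinery: weighted least squares at fixed
# heritability, one-dimensional likelihood profiling over h2, and the
# unified F statistic for genetic units of any degrees of freedom.
#
# Model: y = 1*mu + X*beta + a + eps, a ~ N(0, K sig_a^2),
# eps ~ N(0, I sig_e^2). With h2 = sig_a^2 / (sig_a^2 + sig_e^2),
# Var(y | beta) = (h2/(1-h2) K + I) sig_e^2. Rotating by the eigenvectors
# U of K = U S U' turns this into a diagonal-weight regression with
# weights w_i = (h2/(1-h2)) S_i + 1.

.fit_env <- new.env(parent = emptyenv())
.fit_env$count <- 0L

#' Instrumentation: count of weighted regression fits
#'
#' Every call to [wls_fit] increments an internal counter. This supports
#' the scan's cost accounting: a genome-wide scan in two-pass mode should
#' cost between one and two regression-scan equivalents, i.e.
#' fits / n_tests in (1, 2].
#'
#' @return `fit_count()` returns the current count; `reset_fit_count()`
#'   zeroes it (invisibly).
#' @export
fit_count <- function() .fit_env$count

#' @rdname fit_count
#' @export
reset_fit_count <- function() {
  .fit_env$count <- 0L
  invisible(NULL)
}

#' Rotate a phenotype into the eigenbasis of the kinship matrix
#'
#' Returns the transformed phenotype and intercept; unit design columns
#' are transformed lazily (or in one batch) by the scan.
#'
#' @param y a `phenotype_vector` or numeric vector.
#' @param eig an `eigen_system` from [spectral_decompose].
#' @return A `transformed_data` list: `y_t`, `intercept_t`, `S`
#'   (eigenvalues), `n`, and `y_raw` (original scale, for explained
#'   variance).
#' @export
transform_phenotype <- function(y, eig) {
  yv <- if (inherits(y, "phenotype_vector")) y$values else as.numeric(y)
  U <- eig$vectors
  if (length(yv) != nrow(U))
    stop("phenotype length (", length(yv), ") does not match the ",
         "eigen system dimension (", nrow(U), ")")
  structure(list(y_t = drop(crossprod(U, yv)),
                 intercept_t = drop(crossprod(U, rep(1, length(yv)))),
                 S = eig$values, n = length(yv), y_raw = yv),
            class = "transformed_data")
}

#' Weighted least squares at fixed heritability
#'
#' Solves the rotated model with diagonal weights
#' w_i = (h2/(1-h2)) S_i + 1 by whitening (y* = W^{-1/2} y~,
#' X* = W^{-1/2} X~) and an ordinary QR fit. Returns the coefficient
#' vector, weighted residual sum of squares, the residual variance with
#' the (n - 1) divisor used for reporting, and the profiled -2 log
#' likelihood n log(RSS_w / n) + sum(log w) (constants dropped: only
#' differences across fits are meaningful).
#'
#' @param td a `transformed_data`.
#' @param X_t transformed design, n x (1 + df_beta), intercept first.
#' @param h2 heritability in \[0, 1).
#' @return A `wls_fit` list: `beta`, `sigma2_eps`, `rss_weighted`, `h2`,
#'   `df_beta`, `neg2loglik`.
#' @export
wls_fit <- function(td, X_t, h2) {
  stopifnot(h2 >= 0, h2 < 1)
  .fit_env$count <- .fit_env$count + 1L
  w <- (h2 / (1 - h2)) * td$S + 1
  sw <- 1 / sqrt(w)
  fit <- .lm.fit(X_t * sw, td$y_t * sw)
  p <- ncol(X_t)
  if (fit$rank < p) {
    bad <- fit$pivot[fit$rank + 1L]
    stop("rank-deficient unit design after whitening (column ", bad,
         " aliased); degenerate unit", call. = FALSE)
  }
  beta <- fit$coefficients[order(fit$pivot)]
  rss <- sum(fit$residuals^2)
  n <- td$n
  structure(list(beta = beta, sigma2_eps = rss / (n - 1),
                 rss_weighted = rss, h2 = h2, df_beta = p - 1L,
                 neg2loglik = n * log(rss / n) + sum(log(w))),
            class = "wls_fit")
}

#' Profile the likelihood over heritability
#'
#' Minimises the -2 log likelihood of [wls_fit] over h2 by a coarse grid
#' (guarding against flat or multi-modal profiles) followed by Brent
#' refinement in the bracketing interval.
#'
#' @param td a `transformed_data`.
#' @param X_t transformed design.
#' @param bounds search interval (lo, hi), 0 <= lo < hi < 1.
#' @param tol absolute tolerance on h2 (default 1e-4).
#' @param grid_n coarse grid size (default 21); `grid_n = 0` skips the
#'   grid and runs Brent on the whole interval (used for the per-unit
#'   downward search, where the profile seeded at the null optimum is
#'   unimodal and a grid would dominate the scan cost).
#' @return list with `h2` (argmin), `fit` (the [wls_fit] there), and
#'   `boundary` (`TRUE` when the optimum sits at an interval endpoint).
#' @export
profile_h2 <- function(td, X_t, bounds = c(1e-6, 1 - 1e-6), tol = 1e-4,
                       grid_n = 21L) {
  lo <- bounds[1]; hi <- bounds[2]
  stopifnot(lo >= 0, lo < hi, hi < 1)
  obj <- function(h2) wls_fit(td, X_t, h2)$neg2loglik
  if (grid_n >= 3L) {
    grid <- seq(lo, hi, length.out = grid_n)
    vals <- vapply(grid, obj, numeric(1))
    k <- which.min(vals)
    blo <- grid[max(1L, k - 1L)]
    bhi <- grid[min(grid_n, k + 1L)]
  } else {
    blo <- lo; bhi <- hi
  }
  opt <- stats::optimize(obj, c(blo, bhi), tol = tol)
  h2_opt <- opt$minimum
  # Brent never returns an exact endpoint; snap when the edge is better.
  if (grid_n >= 3L) {
    edge <- c(lo, hi)
    ev <- c(vals[1], vals[grid_n])
    if (min(ev) < opt$objective) h2_opt <- edge[which.min(ev)]
  }
  boundary <- (h2_opt - lo) < 2 * tol || (hi - h2_opt) < 2 * tol
  list(h2 = h2_opt, fit = wls_fit(td, X_t, h2_opt), boundary = boundary)
}

#' Fit the null (no tested unit) mixed model
#'
#' Estimates the genomic heritability of the trait by profiling the
#' likelihood with an intercept-only design. This estimate both seeds the
#' per-unit downward search and serves as the fixed heritability of the
#' EMMAX screening pass.
#'
#' @param td a `transformed_data`.
#' @return A `null_model_fit`: `h2_genomic`, `neg2loglik`, `sigma2_eps`,
#'   `mu_hat`, `boundary`.
#' @export
fit_null <- function(td) {
  if (stats::var(td$y_raw) == 0) stop("constant phenotype")
  pr <- profile_h2(td, matrix(td$intercept_t, ncol = 1))
  structure(list(h2_genomic = pr$h2, neg2loglik = pr$fit$neg2loglik,
                 sigma2_eps = pr$fit$sigma2_eps, mu_hat = pr$fit$beta[1],
                 boundary = pr$boundary),
            class = "null_model_fit")
}

#' Unified F test for a genetic unit
#'
#' Nested-model F statistic in the whitened space, valid for units of any
#' degrees of freedom: F = ((RSS0 - RSS1)/df_beta) / (RSS1/df_eps) with
#' df_eps = n - df_beta - 1, where RSS0 is the weighted residual sum of
#' squares of the intercept-only model and RSS1 of the full model, both at
#' the same heritability. A SNP (df_beta = 1) recovers the squared t
#' test; a k-allele block is tested on k - 1 df at once.
#'
#' @param fit0 intercept-only [wls_fit] at the unit's h2.
#' @param fit1 full [wls_fit] at the same h2.
#' @param n sample size.
#' @param chisq also use the large-sample chi-square approximation
#'   (df_beta * F ~ chi2(df_beta)) for the p-value instead of the exact F
#'   reference.
#' @return list with `F`, `p`, `df_beta`, `df_eps`.
#' @export
unified_f_test <- function(fit0, fit1, n, chisq = FALSE) {
  if (!isTRUE(all.equal(fit0$h2, fit1$h2)))
    stop("null and full fits must be computed at the same h2")
  df_beta <- fit1$df_beta
  df_eps <- n - df_beta - 1L
  stopifnot(df_eps >= 1L)
  rss0 <- fit0$rss_weighted
  rss1 <- fit1$rss_weighted
  if (rss1 <= 0) {
    warning("perfect fit (zero residual); p-value degenerate")
    return(list(F = Inf, p = 0, df_beta = df_beta, df_eps = df_eps))
  }
  Fstat <- max(0, (rss0 - rss1) / df_beta / (rss1 / df_eps))
  p <- if (chisq)
    stats::pchisq(df_beta * Fstat, df_beta, lower.tail = FALSE)
  else
    stats::pf(Fstat, df_beta, df_eps, lower.tail = FALSE)
  list(F = Fstat, p = p, df_beta = df_beta, df_eps = df_eps)
}

#' Percentage of phenotypic variance explained by a fitted unit
#'
#' var(X beta_hat) / var(y) * 100 on the original (untransformed) scale,
#' clipped to \[0, 100\].
#'
#' @param beta_unit fitted unit effects (without the intercept).
#' @param unit a `unit_design`.
#' @param y original-scale phenotype values.
#' @return percentage in \[0, 100\].
#' @export
explained_variance <- function(beta_unit, unit, y) {
  g <- drop(unit$columns %*% beta_unit)
  pct <- 100 * stats::var(g) / stats::var(y)
  min(100, max(0, pct))
}

.transform_unit <- function(unit, eig) {
  crossprod(eig$vectors, unit$columns)
}

.make_result <- function(unit, ft, fit1, h2, ev_pct, mode, n) {
  list(unit_id = unit$unit_id, unit_kind = unit$unit_kind,
       chromosome = unit$chromosome,
       start_bp = unit$span_bp[1], end_bp = unit$span_bp[2],
       n_snps = if (is.null(unit$n_snps)) NA_integer_ else unit$n_snps,
       n_alleles = if (is.null(unit$n_alleles)) NA_integer_ else unit$n_alleles,
       df_beta = ft$df_beta, df_eps = ft$df_eps, F = ft$F, p = ft$p,
       neg_log10_p = -log10(ft$p), h2_used = h2,
       beta = if (ft$df_beta == 1L) fit1$beta[2] else NA_real_,
       explained_var_pct = ev_pct, mode = mode)
}

#' Test one genetic unit with per-unit heritability optimisation
#'
#' Transforms the unit's design columns into the eigenbasis, profiles the
#' likelihood over h2 searching downward from the genomic heritability
#' (units other than true QTLs leave the polygenic signal essentially
#' intact, so the optimum lies at or just below the null estimate), refits
#' the intercept-only model at the unit's optimal h2 and applies the
#' unified F test. If the optimum presses against the upper end of the
#' downward interval the interval is extended by 0.05 (capped below 1)
#' and the search repeated.
#'
#' @param td a `transformed_data`.
#' @param unit a `unit_design`.
#' @param eig the `eigen_system` (or `NULL` if `X_t_unit` is supplied).
#' @param h2_start the genomic heritability from [fit_null].
#' @param X_t_unit optional pre-transformed unit columns (batch rotation).
#' @param chisq use the chi-square approximation for p-values.
#' @param tol tolerance on h2.
#' @return A result record (list) with effect, F, p, optimised h2, and
#'   explained-variance percentage; `mode = "exact"`.
#' @export
test_unit_exact <- function(td, unit, eig = NULL, h2_start, X_t_unit = NULL,
                            chisq = FALSE, tol = 1e-4) {
  if (is.null(X_t_unit)) X_t_unit <- .transform_unit(unit, eig)
  X_t <- cbind(td$intercept_t, X_t_unit)
  hi <- max(h2_start, 2e-6)
  pr <- profile_h2(td, X_t, bounds = c(1e-6, hi), tol = tol, grid_n = 0L)
  if (pr$h2 > hi - 2 * tol && hi < 1 - 1e-6) {
    hi2 <- min(hi + 0.05, 1 - 1e-6)
    pr2 <- profile_h2(td, X_t, bounds = c(1e-6, hi2), tol = tol, grid_n = 0L)
    if (pr2$fit$neg2loglik < pr$fit$neg2loglik) pr <- pr2
  }
  fit0 <- wls_fit(td, matrix(td$intercept_t, ncol = 1), pr$h2)
  ft <- unified_f_test(fit0, pr$fit, td$n, chisq = chisq)
  ev <- explained_variance(pr$fit$beta[-1], unit, td$y_raw)
  .make_result(unit, ft, pr$fit, pr$h2, ev, "exact", td$n)
}

#' Test one genetic unit at fixed heritability (EMMAX screen)
#'
#' A single weighted regression at the genomic heritability; no
#' optimisation. `fit0` (the intercept-only fit at the same h2) can be
#' shared across all units of a scan.
#'
#' @inheritParams test_unit_exact
#' @param h2_fixed the fixed heritability (genomic heritability).
#' @param fit0 optional shared intercept-only [wls_fit] at `h2_fixed`.
#' @return A result record with `mode = "emmax"`.
#' @export
test_unit_emmax <- function(td, unit, eig = NULL, h2_fixed, X_t_unit = NULL,
                            fit0 = NULL, chisq = FALSE) {
  if (is.null(X_t_unit)) X_t_unit <- .transform_unit(unit, eig)
  if (is.null(fit0)) fit0 <- wls_fit(td, matrix(td$intercept_t, ncol = 1), h2_fixed)
  fit1 <- wls_fit(td, cbind(td$intercept_t, X_t_unit), h2_fixed)
  ft <- unified_f_test(fit0, fit1, td$n, chisq = chisq)
  ev <- explained_variance(fit1$beta[-1], unit, td$y_raw)
  .make_result(unit, ft, fit1, h2_fixed, ev, "emmax", td$n)
}
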