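test_that("eigenbasis rotation preserves norms and is invertible", {
  p <- sim_panel(n = 25, m = 200, seed = 21)
  y <- simulate_phenotype(p$G, p$spec, p$K)
  td <- transform_phenotype(y, p$eig)
  expect_equal(sqrt(sum(td$y_t^2)), sqrt(sum(y$values^2)), tolerance = 1e-8)
  expect_equal(drop(p$eig$vectors %*% td$y_t), y$values, tolerance = 1e-10)
  tdI <- transform_phenotype(y, identity_eig(25))
  expect_equal(tdI$y_t, y$values)
  expect_error(transform_phenotype(y$values[1:10], p$eig), "dimension")
})

test_that("weighted fit at h2 = 0 is ordinary least squares", {
  p <- sim_panel(n = 20, m = 100, seed = 22)
  y <- simulate_phenotype(p$G, p$spec, p$K)
  td <- transform_phenotype(y, p$eig)
  X <- cbind(1, rnorm(20))
  Xt <- crossprod(p$eig$vectors, X)
  f <- wls_fit(td, Xt, 0)
  ols <- lm.fit(Xt, td$y_t)
  expect_equal(unname(f$beta), unname(ols$coefficients), tolerance = 1e-10)
  expect_equal(f$rss_weighted, sum(ols$residuals^2), tolerance = 1e-10)
})

test_that("weighted fits agree with dense GLS on the original scale", {
  set.seed(23)
  for (rep in 1:12) {
    n <- sample(8:15, 1)
    p <- sim_panel(n = n, m = 50, seed = 100 + rep)
    y <- simulate_phenotype(p$G, p$spec, p$K)
    td <- transform_phenotype(y, p$eig)
    X <- cbind(1, rnorm(n), rnorm(n))
    Xt <- crossprod(p$eig$vectors, X)
    h2a <- runif(1, 0, 0.9); h2b <- runif(1, 0, 0.9)
    fa <- wls_fit(td, Xt, h2a); fb <- wls_fit(td, Xt, h2b)
    oa <- gls_oracle(y$values, X, p$K$K, h2a)
    ob <- gls_oracle(y$values, X, p$K$K, h2b)
    expect_equal(unname(fa$beta), oa$beta, tolerance = 1e-8)
    expect_equal(fa$rss_weighted, oa$rss, tolerance = 1e-8)
    # -2logL is defined up to a constant; differences must match
    expect_equal(fa$neg2loglik - fb$neg2loglik,
                 oa$neg2loglik - ob$neg2loglik, tolerance = 1e-8)
  }
})

test_that("a phenotype in the design span gives zero weighted residual", {
  p <- sim_panel(n = 15, m = 80, seed = 24)
  X <- cbind(1, rnorm(15))
  yv <- drop(X %*% c(2, 3))
  td <- transform_phenotype(yv, p$eig)
  f <- wls_fit(td, crossprod(p$eig$vectors, X), 0.4)
  expect_lt(f$rss_weighted, 1e-12)
})

test_that("rank-deficient designs fail with the offending column", {
  p <- sim_panel(n = 20, m = 100, seed = 25)
  y <- simulate_phenotype(p$G, p$spec, p$K)
  td <- transform_phenotype(y, p$eig)
  x <- rnorm(20)
  Xt <- crossprod(p$eig$vectors, cbind(1, x, x))
  expect_error(wls_fit(td, Xt, 0.3), "rank-deficient")
})

test_that("profiled h2 matches a dense grid search", {
  p <- sim_panel(n = 80, m = 400, seed = 26, h2 = 0.6)
  y <- simulate_phenotype(p$G, p$spec, p$K)
  td <- transform_phenotype(y, p$eig)
  Xt <- matrix(td$intercept_t, ncol = 1)
  pr <- profile_h2(td, Xt)
  grid <- seq(1e-6, 1 - 1e-6, length.out = 10001)
  nll <- vapply(grid, function(h) wls_fit(td, Xt, h)$neg2loglik, numeric(1))
  expect_equal(pr$h2, grid[which.min(nll)], tolerance = 2e-4)
  expect_lte(pr$fit$neg2loglik, min(nll) + 1e-8)
})

test_that("null model recovers zero heritability for pure noise", {
  p <- sim_panel(n = 150, m = 500, seed = 27)
  h2_hats <- vapply(1:40, function(i) {
    spec_i <- sim_spec(n_samples = 150, n_snps = 500, seed = 7000 + i,
                       h2_poly = 0)
    y <- simulate_phenotype(p$G, spec_i, p$K)
    td <- transform_phenotype(y, p$eig)
    fit_null(td)$h2_genomic
  }, numeric(1))
  expect_lt(median(h2_hats), 0.05)
  expect_error(fit_null(transform_phenotype(rep(1, 150), p$eig)), "constant")
})

test_that("unified F equals a classical nested F on the whitened variables", {
  set.seed(28)
  for (rep in 1:10) {
    n <- 40
    p <- sim_panel(n = n, m = 150, seed = 300 + rep)
    y <- simulate_phenotype(p$G, p$spec, p$K)
    td <- transform_phenotype(y, p$eig)
    df_b <- sample(1:4, 1)
    X <- random_category_design(n, df_b)
    Xt_unit <- crossprod(p$eig$vectors, X)
    h2 <- runif(1, 0.05, 0.8)
    fit0 <- wls_fit(td, matrix(td$intercept_t, ncol = 1), h2)
    fit1 <- wls_fit(td, cbind(td$intercept_t, Xt_unit), h2)
    ft <- unified_f_test(fit0, fit1, n)
    # independent route: whiten explicitly, use R's anova machinery
    w <- (h2 / (1 - h2)) * td$S + 1
    ys <- td$y_t / sqrt(w)
    int_s <- td$intercept_t / sqrt(w)
    Xs <- Xt_unit / sqrt(w)
    a <- anova(lm(ys ~ 0 + int_s), lm(ys ~ 0 + int_s + Xs))
    expect_equal(ft$F, a$F[2], tolerance = 1e-8)
    expect_equal(ft$p, a$`Pr(>F)`[2], tolerance = 1e-8)
    expect_equal(ft$df_eps, n - df_b - 1)
  }
})

test_that("with identity kinship the exact test collapses to plain regression", {
  set.seed(29)
  n <- 50
  G <- toy_geno(matrix(rbinom(n * 20, 1, 0.4), n, 20))
  yv <- rnorm(n) + 0.8 * G$calls[, 7]
  eig <- identity_eig(n)
  td <- transform_phenotype(yv, eig)
  units <- encode_units(G, NULL, "snp")
  for (j in c(3, 7, 12)) {
    r <- test_unit_exact(td, units[[j]], eig, h2_start = 0.5)
    a <- anova(lm(yv ~ G$calls[, j]))
    expect_equal(r$p, a$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("EMMAX and exact tests coincide when the optimum is the fixed h2", {
  # identity kinship makes the likelihood flat in h2, so any fixed value
  # is an optimum and the two modes must agree exactly
  set.seed(30)
  n <- 40
  G <- toy_geno(matrix(rbinom(n * 10, 1, 0.5), n, 10))
  yv <- rnorm(n)
  eig <- identity_eig(n)
  td <- transform_phenotype(yv, eig)
  u <- encode_units(G, NULL, "snp")[[4]]
  re <- test_unit_exact(td, u, eig, h2_start = 0.3)
  rm_ <- test_unit_emmax(td, u, eig, h2_fixed = 0.3)
  expect_equal(rm_$p, re$p, tolerance = 1e-10)
  expect_equal(rm_$F, re$F, tolerance = 1e-8)
})

test_that("EMMAX uses exactly one regression fit per unit", {
  p <- sim_panel(n = 30, m = 60, seed = 31)
  y <- simulate_phenotype(p$G, p$spec, p$K)
  td <- transform_phenotype(y, p$eig)
  units <- encode_units(p$G, NULL, "snp")
  fit0 <- wls_fit(td, matrix(td$intercept_t, ncol = 1), 0.4)
  ok <- which(apply(p$G$calls, 2, var) > 0)[1:10]
  reset_fit_count()
  for (j in ok) test_unit_emmax(td, units[[j]], p$eig, 0.4, fit0 = fit0)
  expect_equal(fit_count(), 10L)
})

test_that("explained variance: zero effect, exact fit, R-squared identity", {
  set.seed(32)
  n <- 60
  G <- toy_geno(matrix(rbinom(n * 5, 1, 0.5), n, 5))
  u <- encode_units(G, NULL, "snp")[[2]]
  yv <- rnorm(n)
  expect_equal(explained_variance(0, u, yv), 0)
  y_exact <- drop(u$columns %*% 2.5)
  expect_equal(explained_variance(2.5, u, y_exact), 100)
  b <- 1.3
  ev <- explained_variance(b, u, yv)
  expect_equal(ev, 100 * var(drop(u$columns %*% b)) / var(yv),
               tolerance = 1e-12)
})

test_that("null-unit p-values are uniform (KS) and median F is near 1", {
  p <- sim_panel(n = 120, m = 500, seed = 33, h2 = 0.4)
  y <- simulate_phenotype(p$G, p$spec, p$K)
  td <- transform_phenotype(y, p$eig)
  h2g <- fit_null(td)$h2_genomic
  fit0 <- wls_fit(td, matrix(td$intercept_t, ncol = 1), h2g)
  set.seed(34)
  res <- replicate(400, {
    X <- matrix(rbinom(120, 1, runif(1, 0.1, 0.5)), ncol = 1)
    u <- structure(list(unit_id = "u", unit_kind = "snp", columns = X,
                        df_beta = 1L, chromosome = "1", span_bp = c(1, 1)),
                   class = "unit_design")
    r <- test_unit_emmax(td, u, p$eig, h2g, fit0 = fit0)
    c(r$p, r$F)
  })
  expect_gt(ks.test(res[1, ], "punif")$p.value, 0.01)
  # null F(1, df_eps): median matches the theoretical null median and the
  # mean sits near df_eps / (df_eps - 2) ~ 1
  expect_lt(abs(median(res[2, ]) - qf(0.5, 1, 118)), 0.15)
  expect_lt(abs(mean(res[2, ]) - 1), 0.35)
})
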