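# build study_estimate-like inputs directly from aggregate numbers
fake_estimate <- function(g0, g1, v00 = 0.05, v01 = 0, v11 = 0.1) {
  structure(list(gamma0_hat = g0, gamma1_hat = g1,
                 cov = matrix(c(v00, v01, v01, v11), 2, 2),
                 corrected = FALSE, n_subjects = NA_integer_),
            class = "study_estimate")
}

test_that("DL pooling matches the hand-arithmetic oracle exactly", {
  est <- list(fake_estimate(0, 0.5, v11 = 0.1),
              fake_estimate(0, 0.0, v11 = 0.1),
              fake_estimate(0, 1.0, v11 = 0.1))
  fit <- pool_dl(est)
  # frozen from the arithmetic oracle: Q = 5, tau^2 = (5-2)/20 = 0.15,
  # beta = 0.5, SE = 1/sqrt(12)
  expect_equal(fit$tau1_sq_hat, 0.15, tolerance = 1e-10)
  expect_equal(fit$beta1_hat, 0.5, tolerance = 1e-10)
  expect_equal(fit$se_beta1, 1 / sqrt(12), tolerance = 1e-10)
  o <- oracle_dl(c(0.5, 0, 1), rep(0.1, 3))
  expect_equal(fit$beta1_hat, o$beta, tolerance = 1e-10)
  expect_equal(fit$tau1_sq_hat, o$tau2, tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("DL degenerates correctly and stays within the estimate range", {
  hom <- replicate(3, fake_estimate(0, 0.18, v11 = runif(1, 0.05, 0.3)),
                   simplify = FALSE)
  fit <- pool_dl(hom)
  expect_equal(fit$beta1_hat, 0.18, tolerance = 1e-12)
  expect_equal(fit$tau1_sq_hat, 0)   # truncated at zero

  dup <- replicate(6, fake_estimate(0.1, 0.42, v11 = 0.2), simplify = FALSE)
  fit <- pool_dl(dup)
  expect_equal(fit$beta1_hat, 0.42, tolerance = 1e-12)
  expect_equal(fit$tau1_sq_hat, 0)

  set.seed(21)
  for (i in 1:20) {
    yi <- rnorm(5, 0.2, 1)
    vi <- runif(5, 0.02, 0.5)
    est <- Map(function(y, v) fake_estimate(0, y, v11 = v), yi, vi)
    fit <- pool_dl(est)
    expect_gte(fit$beta1_hat, min(yi))
    expect_lte(fit$beta1_hat, max(yi))
    o <- oracle_dl(yi, vi)
    expect_equal(fit$beta1_hat, o$beta, tolerance = 1e-10)
    expect_equal(fit$se_beta1, o$se, tolerance = 1e-10)
  }
  expect_error(pool_dl(hom[1]), "2 studies")
})

test_that("DL agrees with metafor's implementation", {
  d <- make_dataset(31, 15, 500, "imbalanced")
  fs <- fit_all_studies(d)
  fit <- pool_dl(fs)
  yi <- vapply(fs, function(e) e$gamma1_hat, 0)
  vi <- vapply(fs, function(e) e$cov[2, 2], 0)
  ref <- metafor::rma(yi, vi, method = "DL")
  expect_equal(fit$beta1_hat, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(fit$tau1_sq_hat, ref$tau2, tolerance = 1e-10)
  expect_equal(fit$se_beta1, ref$se, tolerance = 1e-10)
})

test_that("bivariate REML collapses when studies are identical", {
  est <- replicate(8, fake_estimate(-0.8, 0.25, v00 = 1e-6, v01 = 0,
                                    v11 = 1e-6), simplify = FALSE)
  fit <- pool_bivariate_reml(est)
  expect_equal(fit$beta1_hat, 0.25, tolerance = 1e-4)
  expect_lt(fit$tau1_sq_hat, 1e-4)
  expect_lt(abs(fit$tau0_sq_hat), 1e-4)
})

test_that("bivariate REML recovers a known covariance at K = 200", {
  set.seed(22)
  k <- 200
  sigma <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  cj <- matrix(c(0.05, 0.01, 0.01, 0.08), 2, 2)
  y <- MASS::mvrnorm(k, c(-0.85, 0.18), sigma + cj)
  est <- lapply(seq_len(k), function(j)
    fake_estimate(y[j, 1], y[j, 2], v00 = cj[1, 1], v01 = cj[1, 2],
                  v11 = cj[2, 2]))
  fit <- pool_bivariate_reml(est)
  expect_true(fit$converged)
  # 3 approximate MC SEs: Var(tau1^2) ~ 2 (tau^2 + c)^2 / K
  se_t <- sqrt(2 * (1 + 0.08)^2 / k)
  expect_lt(abs(fit$tau1_sq_hat - 1), 3 * se_t)
  expect_lt(abs(fit$tau0_sq_hat - 1), 3 * se_t)
  expect_lt(abs(fit$beta1_hat - 0.18), 3 * sqrt((1 + 0.08) / k))
})

test_that("with fixed intercept variance the tau1^2 profile is univariate REML", {
  set.seed(23)
  k <- 12
  yi <- rnorm(k, 0.2, 1.2)
  vi <- runif(k, 0.05, 0.4)
  est <- Map(function(y, v) fake_estimate(rnorm(1), y, v00 = 0.2, v01 = 0,
                                          v11 = v), yi, vi)
  fit <- pool_bivariate_reml(est, fix_tau0_sq = 4, fix_tau01 = 0)
  oracle <- oracle_univ_reml_tau2(yi, vi)
  expect_equal(fit$tau1_sq_hat, oracle, tolerance = 1e-4)
})

test_that("bivariate REML matches metafor's rma.mv on real first stages", {
  d <- make_dataset(24, 15, 500, "imbalanced")
  fs <- fit_all_studies(d)
  fit <- pool_bivariate_reml(fs)
  k <- length(fs)
  dat <- data.frame(study = rep(seq_len(k), each = 2),
                    outcome = rep(c("int", "slope"), k),
                    yi = as.vector(vapply(fs, function(e)
                      c(e$gamma0_hat, e$gamma1_hat), numeric(2))))
  V <- metafor::bldiag(lapply(fs, function(e) e$cov))
  ref <- metafor::rma.mv(yi, V, mods = ~ 0 + outcome,
                         random = ~ outcome | study, struct = "UN",
                         data = dat, method = "REML",
                         control = list(rel.tol = 1e-10))
  expect_equal(fit$beta1_hat, as.numeric(ref$beta)[2], tolerance = 1e-5)
  expect_equal(fit$tau1_sq_hat, ref$tau2[2], tolerance = 1e-4)
  expect_equal(fit$se_beta1, ref$se[2], tolerance = 1e-5)
})

test_that("pooling is invariant to study order", {
  d <- make_dataset(25, 15, 500, "balanced")
  fs <- fit_all_studies(d)
  perm <- sample(seq_along(fs))
  f1 <- pool_bivariate_reml(fs)
  f2 <- pool_bivariate_reml(fs[perm])
  expect_equal(f1$beta1_hat, f2$beta1_hat, tolerance = 1e-8)
  expect_equal(f1$tau1_sq_hat, f2$tau1_sq_hat, tolerance = 1e-8)
  d1 <- pool_dl(fs); d2 <- pool_dl(fs[perm])
  expect_identical(d1$beta1_hat, d2$beta1_hat)
})
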