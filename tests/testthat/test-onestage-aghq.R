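test_that("one quadrature point reproduces the Laplace approximation", {
  d <- make_dataset(61, 3, 45, tau0_sq = 1, tau1_sq = 1, rho = 0.5)
  sigma <- matrix(c(0.8, 0.2, 0.2, 0.6), 2, 2)
  ll1 <- aghq_loglik_m3(d, gamma0 = -0.8, gamma1 = 0.2, sigma = sigma,
                        quad_points = 1)
  ll_lap <- oracle_laplace_ll_m3(d, -0.8, 0.2, sigma)
  expect_equal(ll1, ll_lap, tolerance = 1e-10)
})

test_that("AGHQ at 41 points matches dense 2-D grid integration", {
  d <- make_dataset(104, 3, 45, tau0_sq = 1, tau1_sq = 1, rho = 0.5)
  fit <- fit_aghq(d, glmm_spec("M3", "AGHQ", quad_points = 41))
  sigma_hat <- matrix(c(fit$tau0_sq_hat, fit$tau01_hat,
                        fit$tau01_hat, fit$tau1_sq_hat), 2, 2)
  # the rectangular oracle grid needs an interior, well-conditioned optimum
  expect_gt(min(eigen(sigma_hat)$values), 0.03)
  # evaluate both approximations of the integral at the fitted parameters
  ll_dense <- oracle_dense_ll_m3(d, fit$gamma0_hat, fit$beta1_hat, sigma_hat)
  expect_equal(fit$log_lik, ll_dense, tolerance = 1e-5)
})

test_that("the quadrature approximation stabilizes as points double", {
  for (seed in 63:82) {
    d <- make_dataset(seed, 3, 60, tau0_sq = 1, tau1_sq = 1, rho = 0.5)
    sigma <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
    lls <- vapply(c(5, 10, 20, 40), function(q)
      aghq_loglik_m3(d, -0.85, 0.18, sigma, q), 0)
    deltas <- abs(diff(lls))
    expect_true(all(diff(deltas) <= 1e-9),
                info = sprintf("seed %d: deltas %s", seed,
                               paste(signif(deltas, 3), collapse = ", ")))
  }
})

test_that("M4 with tau1^2 fixed at zero is the stratified logistic fit", {
  d <- make_dataset(83, 5, 250)
  fit <- fit_aghq(d, glmm_spec("M4", "AGHQ", fix_sigma = 0))
  ref <- glm(y ~ 0 + factor(study_id) + x, family = binomial(),
             data = d$data)
  expect_equal(fit$beta1_hat, unname(coef(ref)[["x"]]), tolerance = 1e-6)
  expect_equal(fit$study_intercepts, unname(coef(ref)[1:5]),
               tolerance = 1e-6)
})

test_that("M4 profile-likelihood fit matches lme4 with dense quadrature", {
  d <- make_dataset(84, 5, 300, tau0_sq = 1, tau1_sq = 1, rho = 0)
  fit <- fit_aghq(d, glmm_spec("M4", "AGHQ"))
  ref <- lme4::glmer(y ~ 0 + factor(study_id) + x + (0 + x | study_id),
                     family = binomial, data = d$data, nAGQ = 25)
  expect_lt(abs(fit$beta1_hat - lme4::fixef(ref)[["x"]]), 1e-3)
  expect_lt(abs(fit$tau1_sq_hat -
                  as.numeric(lme4::VarCorr(ref)$study_id)), 1e-3)
})

test_that("PQL and AGHQ coincide in an easy low-heterogeneity regime", {
  d <- make_dataset(85, 15, 3000, tau0_sq = 0.05, tau1_sq = 0.05, rho = 0)
  fp <- fit_pql(d, glmm_spec("M3", "PQL"))
  fa <- fit_aghq(d, glmm_spec("M3", "AGHQ"))
  expect_lt(abs(fp$beta1_hat - fa$beta1_hat), 0.1)
})

test_that("estimates are equivariant under exposure flip and study relabeling", {
  d <- make_dataset(86, 5, 400, tau0_sq = 1, tau1_sq = 1, rho = 0.5)
  fa <- fit_aghq(d, glmm_spec("M3", "AGHQ", quad_points = 10))
  fa_flip <- fit_aghq(flip_exposure(d), glmm_spec("M3", "AGHQ",
                                                  quad_points = 10))
  expect_equal(fa_flip$beta1_hat, -fa$beta1_hat, tolerance = 1e-4)

  d_rel <- d
  relabel <- c(3L, 5L, 1L, 2L, 4L)
  d_rel$data$study_id <- relabel[d$data$study_id]
  fa_rel <- fit_aghq(d_rel, glmm_spec("M3", "AGHQ", quad_points = 10))
  expect_equal(fa_rel$beta1_hat, fa$beta1_hat, tolerance = 1e-5)
  expect_equal(fa_rel$tau1_sq_hat, fa$tau1_sq_hat, tolerance = 1e-5)

  fp <- fit_pql(d, glmm_spec("M3", "PQL"))
  fp_flip <- fit_pql(flip_exposure(d), glmm_spec("M3", "PQL"))
  expect_equal(fp_flip$beta1_hat, -fp$beta1_hat, tolerance = 1e-6)
})
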