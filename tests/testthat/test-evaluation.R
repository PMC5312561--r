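test_that("bias and MSE follow the Monte-Carlo definitions", {
  r <- bias_mse(c(0.20, 0.10), 0.18)
  expect_equal(r$bias, -0.03)
  expect_equal(r$abs_bias, 0.03)
  expect_equal(r$mse, (0.0004 + 0.0064) / 2)
  expect_equal(r$rmse, sqrt(0.0034))

  perfect <- bias_mse(rep(0.18, 10), 0.18)
  expect_equal(unlist(perfect[c("bias", "abs_bias", "mse", "rmse")]),
               c(bias = 0, abs_bias = 0, mse = 0, rmse = 0))

  # shifting estimates shifts bias, leaves mse - bias^2 unchanged
  set.seed(1)
  est <- rnorm(50, 0.2, 0.1)
  a <- bias_mse(est, 0.18)
  b <- bias_mse(est + 0.07, 0.18)
  expect_equal(b$bias, a$bias + 0.07)
  expect_equal(b$mse - b$bias^2, a$mse - a$bias^2)
  expect_gte(a$rmse^2 - a$bias^2, 0)

  expect_error(bias_mse(c(NA, Inf), 0.18), "finite")
})

test_that("Wald coverage uses the 1.96 rule with an inclusive boundary", {
  expect_true(gaussian_coverage(0.18, 0.2, 0.18))
  expect_true(gaussian_coverage(1.96 * 0.5, 0.5, 0))  # exact boundary
  expect_false(gaussian_coverage(2 * 0.5, 0.5, 0))
  expect_error(gaussian_coverage(0.18, 0, 0.18), "> 0")
  expect_error(gaussian_coverage(0.18, -1, 0.18), "> 0")
})

test_that("the I^2 parameterization maps variances to heterogeneity", {
  expect_equal(i_squared(0), 0)
  expect_equal(i_squared(pi^2 / 3), 0.5)
  expect_equal(i_squared(1), 1 / (1 + pi^2 / 3))
  expect_equal(round(i_squared(c(0.05, 1, 4)), 2), c(0.01, 0.23, 0.55))
  expect_error(i_squared(-0.1), ">= 0")
})

test_that("the coverage machinery hits the nominal level on a normal toy", {
  set.seed(2)
  n_rep <- 10000
  theta <- 0.18
  se <- 0.25
  est <- rnorm(n_rep, theta, se)
  cov_pct <- mean(gaussian_coverage(est, rep(se, n_rep), theta))
  nominal <- 2 * pnorm(1.96) - 1
  mc_se <- sqrt(nominal * (1 - nominal) / n_rep)
  expect_lt(abs(cov_pct - nominal), 3 * mc_se)
})

test_that("summaries aggregate replicate fits correctly", {
  mk <- function(est, se, conv = TRUE, t1 = 0.9, t1se = NA_real_)
    ipdmasim:::new_pooled_fit("DL", beta1_hat = est, se_beta1 = se,
                              tau1_sq_hat = t1, se_tau1_sq = t1se,
                              converged = conv)
  sc <- scenario_config(5, 500, "balanced", beta1 = 0.18, tau1_sq = 1)
  fits <- c(lapply(1:977, function(i) mk(0.18, 0.1)),
            lapply(1:23, function(i) mk(0.25, 0.1, conv = FALSE)))
  s <- summarize_fits(fits, sc)
  expect_equal(s$convergence_pct, 97.7)
  expect_equal(s$n_converged, 977L)
  expect_equal(s$n_reps_attempted, 1000L)
  b <- s$stats[s$stats$parameter == "beta1", ]
  # non-converged replicates still contribute estimates
  expect_equal(b$bias, mean(c(rep(0.18, 977), rep(0.25, 23))) - 0.18)
  expect_equal(b$coverage_pct, 100)
  # DL reports no SE for tau1^2, so no coverage for it
  t <- s$stats[s$stats$parameter == "tau1_sq", ]
  expect_true(is.na(t$coverage_pct))

  # order invariance
  s2 <- summarize_fits(sample(fits), sc)
  expect_equal(s2$stats, s$stats)

  exact <- lapply(1:10, function(i) mk(0.18, 0.1))
  se_ <- summarize_fits(exact, sc)
  expect_equal(se_$stats$bias[1], 0)
  expect_equal(se_$stats$coverage_pct[1], 100)
  expect_equal(se_$convergence_pct, 100)

  mixed <- c(exact, list(ipdmasim:::new_pooled_fit("BIVREML")))
  expect_error(summarize_fits(mixed, sc), "mix")
})

test_that("summary cells format as median (p25, p75)", {
  expect_equal(format_cell(0.73, 0.35, 1.29), "0.73 (0.35, 1.29)")
})
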