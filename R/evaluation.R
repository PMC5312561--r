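#' Monte-Carlo bias and mean squared error
#'
#' Over the finite estimates, returns the mean bias
#' \eqn{\overline{\hat\theta} - \theta}, its absolute value, the mean
#' squared error \eqn{\mathrm{mean}((\hat\theta - \theta)^2)} and its square
#' root.
#'
#' @param estimates Numeric vector of replicate estimates; non-finite
#'   entries are dropped.
#' @param truth True parameter value.
#' @return Named list with `bias`, `abs_bias`, `mse`, `rmse`, and
#'   `n_finite`, the number of estimates used.
#' @examples
#' bias_mse(c(0.20, 0.10), 0.18)
#' @export
bias_mse <- function(estimates, truth) {
  est <- estimates[is.finite(estimates)]
  if (length(est) == 0) stop("no finite estimates", call. = FALSE)
  bias <- mean(est) - truth
  mse <- mean((est - truth)^2)
  list(bias = bias, abs_bias = abs(bias), mse = mse, rmse = sqrt(mse),
       n_finite = length(est))
}

#' Gaussian (Wald) coverage indicator
#'
#' The true value is covered when \eqn{|\hat\theta - \theta| \le 1.96 \,
#' \mathrm{SE}(\hat\theta)}; the boundary counts as covered.
#'
#' @param theta_hat Estimate(s).
#' @param se Standard error(s), all > 0.
#' @param theta True value.
#' @return Logical vector of coverage indicators.
#' @export
gaussian_coverage <- function(theta_hat, se, theta) {
  if (any(!is.finite(se)) || any(se <= 0))
    stop("standard errors must be finite and > 0", call. = FALSE)
  abs(theta_hat - theta) <= 1.96 * se
}

#' Heterogeneity fraction on the log-odds scale
#'
#' For a binary outcome analyzed as a log odds ratio, the fraction of total
#' variability attributable to between-study heterogeneity is
#' \eqn{I^2 = \tau^2 / (\tau^2 + \pi^2/3)}, where \eqn{\pi^2/3} is the
#' variance of the standard logistic distribution.
#'
#' @param tau_sq Between-study variance (>= 0), vectorized.
#' @return \eqn{I^2} values in \[0, 1).
#' @examples
#' i_squared(c(0.05, 1, 4))  # ~0.015, 0.233, 0.549
#' @export
i_squared <- function(tau_sq) {
  if (any(tau_sq < 0)) stop("tau_sq must be >= 0", call. = FALSE)
  tau_sq / (tau_sq + pi^2 / 3)
}

#' Summarize replicate fits for one scenario and method
#'
#' Aggregates a list of `pooled_fit` replicates into the Monte-Carlo
#' performance measures: the convergence rate (converged fits over
#' attempted), and for each target parameter — the pooled treatment effect
#' \eqn{\beta_1} always, the between-study variance \eqn{\tau_1^2} whenever
#' the method reports it — the mean bias, absolute mean bias, MSE, RMSE,
#' Wald coverage in percent, and the median and quartiles of the
#' per-replicate absolute error. Non-converged replicates contribute their
#' (finite) estimates to bias and MSE; non-finite estimates are dropped
#' with a logged count. Coverage of \eqn{\tau_1^2} is only computed for
#' methods that return a standard error for it (the method-of-moments
#' estimator does not).
#'
#' @param fits List of `pooled_fit` objects sharing one method.
#' @param scenario The generating [scenario_config()] (supplies the truth).
#' @return An object of class `"performance_summary"`: list with
#'   `scenario`, `method`, `n_reps_attempted`, `n_converged`,
#'   `convergence_pct`, `n_dropped_nonfinite`, and a `stats` data.frame
#'   with one row per parameter.
#' @export
summarize_fits <- function(fits, scenario) {
  stopifnot(length(fits) >= 1)
  methods <- vapply(fits, function(f) f$method, "")
  if (length(unique(methods)) != 1)
    stop("fits mix methods: ", paste(unique(methods), collapse = ", "),
         call. = FALSE)
  method <- methods[1]
  n_att <- length(fits)
  n_conv <- sum(vapply(fits, function(f) isTRUE(f$converged), TRUE))

  param_row <- function(est, se, truth, with_coverage) {
    ok <- is.finite(est)
    bm <- bias_mse(est[ok], truth)
    abs_err <- abs(est[ok] - truth)
    cov_pct <- NA_real_
    if (with_coverage) {
      use <- ok & is.finite(se) & se > 0
      if (any(use))
        cov_pct <- 100 * mean(gaussian_coverage(est[use], se[use], truth))
    }
    data.frame(bias = bm$bias, abs_bias = bm$abs_bias, mse = bm$mse,
               rmse = bm$rmse, coverage_pct = cov_pct,
               abs_err_median = median(abs_err),
               abs_err_p25 = unname(quantile(abs_err, 0.25)),
               abs_err_p75 = unname(quantile(abs_err, 0.75)),
               n_used = sum(ok))
  }

  b1 <- vapply(fits, function(f) f$beta1_hat, 0)
  b1_se <- vapply(fits, function(f) f$se_beta1, 0)
  t1 <- vapply(fits, function(f) f$tau1_sq_hat, 0)
  t1_se <- vapply(fits, function(f) f$se_tau1_sq, 0)
  tau_has_se <- any(is.finite(t1_se))

  stats <- rbind(
    cbind(parameter = "beta1",
          param_row(b1, b1_se, scenario$beta1, TRUE)),
    cbind(parameter = "tau1_sq",
          param_row(t1, t1_se, scenario$tau1_sq, tau_has_se)))
  structure(list(scenario = scenario, method = method,
                 n_reps_attempted = n_att, n_converged = n_conv,
                 convergence_pct = 100 * n_conv / n_att,
                 n_dropped_nonfinite = sum(!is.finite(b1)),
                 stats = stats),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("Performance [%s]: %d/%d converged (%.1f%%)\n", x$method,
              x$n_converged, x$n_reps_attempted, x$convergence_pct))
  print(x$stats, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Flatten performance summaries to a table
#'
#' One row per (scenario x method x parameter), with the scenario factors
#' as leading columns and cells formatted as in the published comparison
#' tables available via [format_cell()].
#'
#' @param summaries List of `performance_summary` objects.
#' @return A data.frame.
#' @export
performance_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    sc <- s$scenario
    cbind(data.frame(n_studies = sc$n_studies, total_size = sc$total_size,
                     size_scheme = sc$size_scheme, tau0_sq = sc$tau0_sq,
                     tau1_sq = sc$tau1_sq, rho = sc$rho,
                     generation_mode = sc$generation_mode,
                     method = s$method,
                     n_reps_attempted = s$n_reps_attempted,
                     n_converged = s$n_converged,
                     convergence_pct = s$convergence_pct),
          s$stats)
  }))
}

#' Format a "median (p25, p75)" table cell
#'
#' @param median,p25,p75 Summary values.
#' @param digits Decimal places.
#' @return A character scalar like `"0.73 (0.35, 1.29)"`.
#' @export
format_cell <- function(median, p25, p75, digits = 2) {
  sprintf("%.*f (%.*f, %.*f)", digits, median, digits, p25, digits, p75)
}
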