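#' Draw correlated study-level random effects
#'
#' K independent draws from a bivariate normal with mean zero and covariance
#' \deqn{\Sigma = \begin{pmatrix} \tau_0^2 & \rho\tau_0\tau_1 \\
#'       \rho\tau_0\tau_1 & \tau_1^2 \end{pmatrix}.}
#' Zero variances give exactly zero components.
#'
#' @inheritParams scenario_config
#' @param n_studies Number of draws K.
#' @return A `n_studies` x 2 matrix with columns `b0` (study effect) and
#'   `b1` (treatment effect).
#' @export
draw_random_effects <- function(tau0_sq, tau1_sq, rho, n_studies) {
  if (tau0_sq < 0 || tau1_sq < 0) stop("variances must be >= 0")
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  if (tau0_sq == 0 && tau1_sq == 0) {
    b <- matrix(0, n_studies, 2)
  } else {
    sigma <- matrix(c(tau0_sq, rho * sqrt(tau0_sq * tau1_sq),
                      rho * sqrt(tau0_sq * tau1_sq), tau1_sq), 2, 2)
    b <- MASS::mvrnorm(n_studies, mu = c(0, 0), Sigma = sigma, tol = 1e-8)
    b <- matrix(b, ncol = 2)  # mvrnorm drops to a vector when n_studies = 1
  }
  colnames(b) <- c("b0", "b1")
  b
}

#' Draw stratified study intercepts
#'
#' Independent uniform draws on \eqn{[\beta_0 - \tau_0\sqrt{3},\,
#' \beta_0 + \tau_0\sqrt{3}]}, so that the intercepts have mean \eqn{\beta_0}
#' and variance \eqn{\tau_0^2}, matching the variance of the random-intercept
#' generation mode.
#'
#' @inheritParams scenario_config
#' @param n_studies Number of draws K.
#' @return Numeric vector of K study intercepts.
#' @export
draw_stratified_intercepts <- function(beta0, tau0_sq, n_studies) {
  if (tau0_sq < 0) stop("tau0_sq must be >= 0")
  half_width <- sqrt(3 * tau0_sq)
  runif(n_studies, beta0 - half_width, beta0 + half_width)
}

#' Generate one two-level IPD meta-analysis dataset
#'
#' Subjects are assigned a binary exposure by a fair Bernoulli draw, recoded
#' to -1/2 (control) and +1/2 (treatment). The outcome probability follows
#' the random-study-effects logistic model
#' \deqn{\mathrm{logit}(\pi_{ij}) = (\beta_0 + b_{0j}) +
#'       (\beta_1 + b_{1j}) x_{ij}}
#' or, in stratified mode, \eqn{\mathrm{logit}(\pi_{ij}) = \beta_j +
#' (\beta_1 + b_{1j}) x_{ij}} with uniform \eqn{\beta_j}. Outcomes are
#' Bernoulli draws at those probabilities. The realized per-study true
#' effects are retained for later bias computations.
#'
#' @param scenario A [scenario_config()].
#' @return An object of class `"ipd_dataset"`: a list with `data` (a
#'   data.frame with columns `study_id`, `x`, `y`), `true_b0` and `true_b1`
#'   (length-K deviations from `beta0` and `beta1`), `sizes`, and the
#'   generating `scenario`.
#' @examples
#' set.seed(1)
#' d <- generate_dataset(scenario_config(5, 500, "balanced"))
#' head(d$data)
#' @export
generate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  sizes <- allocate_study_sizes(scenario$n_studies, scenario$total_size,
                                scenario$size_scheme)
  k <- scenario$n_studies
  if (scenario$generation_mode == "random_intercept") {
    b <- draw_random_effects(scenario$tau0_sq, scenario$tau1_sq,
                             scenario$rho, k)
    b0 <- b[, 1]
    b1 <- b[, 2]
  } else {
    # no bivariate structure: intercepts uniform, slopes normal, independent
    bj <- draw_stratified_intercepts(scenario$beta0, scenario$tau0_sq, k)
    b0 <- bj - scenario$beta0
    b1 <- rnorm(k, 0, sqrt(scenario$tau1_sq))
  }
  study_id <- rep.int(seq_len(k), sizes)
  n <- length(study_id)
  x <- rbinom(n, 1, 0.5) - 0.5
  eta <- (scenario$beta0 + b0[study_id]) + (scenario$beta1 + b1[study_id]) * x
  y <- rbinom(n, 1, plogis(eta))
  structure(list(data = data.frame(study_id = study_id, x = x, y = y),
                 true_b0 = b0, true_b1 = b1, sizes = sizes,
                 scenario = scenario),
            class = "ipd_dataset")
}

#' @export
print.ipd_dataset <- function(x, ...) {
  cat(sprintf("IPD-MA dataset: %d studies, %d subjects, outcome rate %.3f\n",
              x$scenario$n_studies, nrow(x$data), mean(x$data$y)))
  cat(sprintf("  generated by %s model (beta0 = %g, beta1 = %g)\n",
              x$scenario$generation_mode, x$scenario$beta0,
              x$scenario$beta1))
  invisible(x)
}

#' Write / read an IPD dataset as delimited text
#'
#' The subject-level table goes to `<path>` as tab-separated text with
#' columns `study_id`, `x`, `y`; the scenario and the realized true study
#' effects go to a YAML sidecar `<path>.meta.yaml`.
#'
#' @param dataset An `ipd_dataset`.
#' @param path Output file path.
#' @return `write_ipd_dataset` returns `path` invisibly; `read_ipd_dataset`
#'   returns the reconstructed `ipd_dataset`.
#' @export
write_ipd_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "ipd_dataset"))
  write.table(dataset$data, path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  meta <- list(scenario = unclass(dataset$scenario),
               true_b0 = dataset$true_b0, true_b1 = dataset$true_b1,
               sizes = dataset$sizes)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_ipd_dataset
#' @export
read_ipd_dataset <- function(path) {
  data <- read.table(path, header = TRUE, sep = "\t")
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  sc <- do.call(scenario_config, meta$scenario[
    setdiff(names(meta$scenario), character(0))])
  structure(list(data = data, true_b0 = unlist(meta$true_b0),
                 true_b1 = unlist(meta$true_b1),
                 sizes = as.integer(unlist(meta$sizes)), scenario = sc),
            class = "ipd_dataset")
}
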