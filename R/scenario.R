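#' Define one cell of the simulation grid
#'
#' A scenario bundles everything needed to generate one family of synthetic
#' IPD meta-analysis datasets: the number of studies, the average total sample
#' size and how it is split across studies, the true fixed effects on the
#' log-odds scale, the between-study variance components, and which
#' data-generating model is used (random study effects drawn from a bivariate
#' normal, or stratified study effects drawn from a uniform distribution).
#'
#' @param n_studies Number of studies K (>= 2).
#' @param total_size Average total number of subjects N across all studies
#'   (>= `n_studies`).
#' @param size_scheme `"balanced"` (all studies the same size) or
#'   `"imbalanced"` (25% of studies are large, with 10 times more subjects).
#' @param beta0 True mean log-odds of the outcome in the control condition
#'   (the study effect). The default -0.85 corresponds to a 30% outcome
#'   prevalence at the null.
#' @param beta1 True pooled treatment effect (log odds ratio).
#' @param tau0_sq Between-study variance of the study effect (>= 0).
#' @param tau1_sq Between-study variance of the treatment effect (>= 0).
#' @param rho Correlation between the random study and treatment effects,
#'   in \[-1, 1\]. Ignored when `generation_mode = "stratified_intercept"`,
#'   where no random study effect exists.
#' @param generation_mode `"random_intercept"`: study effects are the first
#'   component of a bivariate normal. `"stratified_intercept"`: each study's
#'   intercept is an independent uniform draw centred at `beta0`.
#' @param n_reps Number of Monte-Carlo repetitions for this scenario (>= 1).
#' @param seed Optional integer master seed for this scenario; `NA` means the
#'   harness supplies one.
#'
#' @return An object of class `"scenario_config"` (a named list).
#' @seealso [build_scenario_grid()], [generate_dataset()]
#' @examples
#' sc <- scenario_config(n_studies = 15, total_size = 500,
#'                       size_scheme = "imbalanced", tau0_sq = 1,
#'                       tau1_sq = 1, rho = 0.5)
#' sc
#' @export
scenario_config <- function(n_studies, total_size,
                            size_scheme = c("balanced", "imbalanced"),
                            beta0 = -0.85, beta1 = 0.18,
                            tau0_sq = 1, tau1_sq = 1, rho = 0.5,
                            generation_mode = c("random_intercept",
                                                "stratified_intercept"),
                            n_reps = 1000, seed = NA_integer_) {
  size_scheme <- match.arg(size_scheme)
  generation_mode <- match.arg(generation_mode)
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid scenario field '", field, "': ", msg,
                          call. = FALSE)
  }
  chk(is.numeric(n_studies) && length(n_studies) == 1 && n_studies >= 2,
      "n_studies", "need an integer >= 2")
  chk(is.numeric(total_size) && length(total_size) == 1 &&
        total_size >= n_studies,
      "total_size", "need an integer >= n_studies")
  chk(is.numeric(tau0_sq) && tau0_sq >= 0, "tau0_sq", "variance must be >= 0")
  chk(is.numeric(tau1_sq) && tau1_sq >= 0, "tau1_sq", "variance must be >= 0")
  chk(is.numeric(rho) && rho >= -1 && rho <= 1, "rho", "must lie in [-1, 1]")
  chk(is.numeric(beta0) && is.finite(beta0), "beta0", "must be finite")
  chk(is.numeric(beta1) && is.finite(beta1), "beta1", "must be finite")
  chk(is.numeric(n_reps) && n_reps >= 1, "n_reps", "need an integer >= 1")
  structure(list(n_studies = as.integer(n_studies),
                 total_size = as.integer(total_size),
                 size_scheme = size_scheme,
                 beta0 = beta0, beta1 = beta1,
                 tau0_sq = tau0_sq, tau1_sq = tau1_sq, rho = rho,
                 generation_mode = generation_mode,
                 n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("IPD-MA simulation scenario\n")
  cat(sprintf("  K = %d studies, N ~ %d subjects (%s)\n",
              x$n_studies, x$total_size, x$size_scheme))
  cat(sprintf("  beta0 = %g, beta1 = %g\n", x$beta0, x$beta1))
  cat(sprintf("  tau0^2 = %g, tau1^2 = %g, rho = %g\n",
              x$tau0_sq, x$tau1_sq, x$rho))
  cat(sprintf("  generation: %s, %d repetitions\n",
              x$generation_mode, x$n_reps))
  invisible(x)
}

#' Expand factor lists into the full scenario grid
#'
#' Forms the Cartesian product of the supplied factor lists, in deterministic
#' order: the size combination varies slowest, then `tau0_sq`, `tau1_sq`,
#' `rho`, and `generation_mode` fastest, each in the order given.
#'
#' @param sizes List of size combinations; each element is a list or vector
#'   with elements `n_studies`, `total_size`, `size_scheme` (in that order if
#'   unnamed).
#' @param tau0_sq,tau1_sq Numeric vectors of between-study variances.
#' @param rho Numeric vector of random-effect correlations.
#' @param generation_mode Character vector of generation modes.
#' @param beta0,beta1,n_reps Passed to every [scenario_config()].
#' @return A list of `scenario_config` objects.
#' @examples
#' grid <- build_scenario_grid(
#'   sizes = list(list(5, 500, "balanced"), list(15, 500, "imbalanced")),
#'   tau0_sq = c(1, 4), tau1_sq = c(1, 4), rho = 0.5,
#'   generation_mode = "random_intercept", n_reps = 10)
#' length(grid)  # 2 * 2 * 2 = 8
#' @export
build_scenario_grid <- function(sizes, tau0_sq, tau1_sq, rho,
                                generation_mode = c("random_intercept",
                                                    "stratified_intercept"),
                                beta0 = -0.85, beta1 = 0.18, n_reps = 1000) {
  for (nm in c("sizes", "tau0_sq", "tau1_sq", "rho", "generation_mode")) {
    if (length(get(nm)) == 0)
      stop("invalid scenario field '", nm, "': empty factor list",
           call. = FALSE)
  }
  grid <- list()
  for (sz in sizes) {
    sz <- unname(sz)
    for (t0 in tau0_sq) for (t1 in tau1_sq) for (r in rho)
      for (gm in generation_mode) {
        grid[[length(grid) + 1L]] <- scenario_config(
          n_studies = as.numeric(sz[[1]]), total_size = as.numeric(sz[[2]]),
          size_scheme = as.character(sz[[3]]),
          beta0 = beta0, beta1 = beta1,
          tau0_sq = t0, tau1_sq = t1, rho = r,
          generation_mode = gm, n_reps = n_reps)
      }
  }
  grid
}

#' The default simulation grid
#'
#' The six (K, N, scheme) size combinations crossed with variances
#' \eqn{\tau_0^2, \tau_1^2 \in \{0.05, 1, 4\}}, correlations
#' \eqn{\rho \in \{0, 0.5\}} and both generation modes: 216 scenarios.
#' The three imbalanced combinations reproduce large-study sizes of 357
#' (K = 5, N = 500), 98 (K = 15, N = 500) and 588 (K = 15, N = 3000).
#'
#' @param n_reps Monte-Carlo repetitions per scenario.
#' @return A list of `scenario_config` objects.
#' @export
default_scenario_grid <- function(n_reps = 1000) {
  build_scenario_grid(
    sizes = list(list(5, 500, "balanced"),
                 list(15, 500, "balanced"),
                 list(15, 3000, "balanced"),
                 list(5, 500, "imbalanced"),
                 list(15, 500, "imbalanced"),
                 list(15, 3000, "imbalanced")),
    tau0_sq = c(0.05, 1, 4), tau1_sq = c(0.05, 1, 4),
    rho = c(0, 0.5),
    generation_mode = c("random_intercept", "stratified_intercept"),
    n_reps = n_reps)
}

#' Read a scenario grid from a YAML configuration file
#'
#' The file holds the factor lists of [build_scenario_grid()]: a `sizes`
#' sequence of `[n_studies, total_size, size_scheme]` triples and scalar or
#' list entries for `tau0_sq`, `tau1_sq`, `rho`, `generation_mode`, plus
#' optional `beta0`, `beta1`, `n_reps`.
#'
#' @param path Path to the YAML file.
#' @return A list of `scenario_config` objects.
#' @examples
#' cfg <- system.file("extdata", "default-grid.yaml", package = "ipdmasim")
#' length(read_scenario_grid(cfg))  # 216
#' @export
read_scenario_grid <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("sizes", "tau0_sq", "tau1_sq", "rho", "generation_mode")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("scenario config file lacks field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  args <- cfg[intersect(names(cfg),
                        c(required, "beta0", "beta1", "n_reps"))]
  do.call(build_scenario_grid, args)
}

#' Allocate per-study sample sizes
#'
#' Balanced designs give every study `round(total_size / n_studies)` subjects.
#' Imbalanced designs make 25% of studies (rounded) "large" with ten times
#' more subjects than the rest: with \eqn{K_L = \mathrm{round}(0.25 K)} large
#' studies, the small-study size is \eqn{s = N / (K - K_L + 10 K_L)}; small
#' studies get `round(s)` subjects and large studies `round(10 s)`. Small
#' studies come first in the returned vector.
#'
#' @inheritParams scenario_config
#' @return Integer vector of `n_studies` per-study sizes.
#' @examples
#' allocate_study_sizes(5, 500, "imbalanced")   # 4 x 36 and one large 357
#' allocate_study_sizes(15, 3000, "imbalanced") # 11 x 59 and 4 x 588
#' @export
allocate_study_sizes <- function(n_studies, total_size,
                                 size_scheme = c("balanced", "imbalanced")) {
  size_scheme <- match.arg(size_scheme)
  if (n_studies < 2) stop("n_studies must be >= 2", call. = FALSE)
  if (total_size < n_studies)
    stop("total_size must be >= n_studies", call. = FALSE)
  if (size_scheme == "balanced") {
    sizes <- rep(round(total_size / n_studies), n_studies)
  } else {
    k_large <- round(0.25 * n_studies)
    k_small <- n_studies - k_large
    s <- total_size / (k_small + 10 * k_large)
    sizes <- c(rep(round(s), k_small), rep(round(10 * s), k_large))
  }
  if (any(sizes < 1))
    stop("infeasible scenario: allocation yields a study of size < 1",
         call. = FALSE)
  as.integer(sizes)
}
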