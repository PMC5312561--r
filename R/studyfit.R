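#' First-stage logistic regression for a single study
#'
#' Fits \eqn{\mathrm{logit}(p) = \gamma_0 + \gamma_1 x} by maximum
#' likelihood with the exposure coded -1/2 / +1/2, via iteratively
#' reweighted least squares on the study's 2x2 table. Because the model is
#' saturated for a binary exposure, the ML solution coincides with the
#' closed-form table estimate: \eqn{\hat\gamma_1} is the log odds ratio
#' \eqn{\log(ad/bc)} with variance \eqn{1/a + 1/b + 1/c + 1/d}, and
#' \eqn{\hat\gamma_0} is the mean of the two arm logits. If any cell of the
#' table is zero (separation), 0.5 is added to all four cells before fitting
#' (Haldane–Anscombe continuity correction) and the estimate is flagged.
#'
#' @param y Binary outcome vector (0/1).
#' @param x Exposure vector coded -1/2 (control) and +1/2 (treatment).
#' @return An object of class `"study_estimate"`: list with `gamma0_hat`,
#'   `gamma1_hat`, `cov` (2x2 within-study covariance of the estimates),
#'   `corrected` (logical), `n_subjects`, and the 2x2 `cells`
#'   (events/non-events per arm, after any correction).
#' @examples
#' y <- c(rep(1, 15), rep(0, 5), rep(1, 10), rep(0, 10))
#' x <- c(rep(0.5, 20), rep(-0.5, 20))
#' fit_study_logistic(y, x)$gamma1_hat  # log(3)
#' @export
fit_study_logistic <- function(y, x) {
  if (length(y) == 0) stop("empty study", call. = FALSE)
  if (length(y) != length(x)) stop("y and x lengths differ", call. = FALSE)
  treat <- x > 0
  if (all(treat) || all(!treat))
    stop("single-arm study: both exposure arms are required", call. = FALSE)
  a <- sum(y[treat])          # events, treated
  b <- sum(!y[treat])         # non-events, treated
  cc <- sum(y[!treat])        # events, control
  d <- sum(!y[!treat])        # non-events, control
  cells <- c(a, b, cc, d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5

  irls <- irls_2x2(cells)
  if (is.null(irls)) {
    est <- closed_form_2x2(cells)
  } else {
    est <- irls
  }
  structure(list(gamma0_hat = est$gamma0, gamma1_hat = est$gamma1,
                 cov = est$cov, corrected = corrected,
                 n_subjects = length(y),
                 cells = setNames(cells, c("a", "b", "c", "d"))),
            class = "study_estimate")
}

# Closed-form saturated-model estimate from (possibly corrected) cells
closed_form_2x2 <- function(cells) {
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  lt <- log(a / b)            # treated-arm logit
  lc <- log(cc / d)           # control-arm logit
  vt <- 1 / a + 1 / b
  vc <- 1 / cc + 1 / d
  # x = +-1/2: gamma0 = (lt + lc)/2, gamma1 = lt - lc; arms independent
  cov <- matrix(c((vt + vc) / 4, (vt - vc) / 2,
                  (vt - vc) / 2, vt + vc), 2, 2)
  list(gamma0 = (lt + lc) / 2, gamma1 = lt - lc, cov = cov)
}

# Newton/IRLS on the aggregated two-arm binomial likelihood; NULL on failure
irls_2x2 <- function(cells, tol = 1e-10, max_iter = 50) {
  n_arm <- c(cells[1] + cells[2], cells[3] + cells[4])  # treated, control
  events <- c(cells[1], cells[3])
  x_arm <- c(0.5, -0.5)
  X <- cbind(1, x_arm)
  beta <- c(0, 0)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- n_arm * mu * (1 - mu)
    z <- eta + (events / n_arm - mu) / (mu * (1 - mu))
    xtw <- t(X * w)
    beta_new <- tryCatch(solve(xtw %*% X, xtw %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) return(NULL)
    beta_new <- drop(beta_new)
    delta <- max(abs(beta_new - beta) / pmax(abs(beta), 1))
    beta <- beta_new
    if (delta < tol) {
      mu <- plogis(drop(X %*% beta))
      info <- t(X * (n_arm * mu * (1 - mu))) %*% X
      cov <- unname(solve(info))
      return(list(gamma0 = unname(beta[1]), gamma1 = unname(beta[2]),
                  cov = cov))
    }
  }
  NULL
}

#' First-stage estimates for every study of a dataset
#'
#' Studies in which every subject fell into the same exposure arm carry no
#' information about the within-study log odds ratio; with
#' `drop_single_arm = TRUE` (the default) they are excluded from the
#' second stage and their ids recorded in the `"dropped"` attribute,
#' otherwise they raise an error.
#'
#' @param dataset An `ipd_dataset` (see [generate_dataset()]).
#' @param drop_single_arm Drop single-arm studies instead of erroring.
#' @return A list of [fit_study_logistic()] results in study-id order,
#'   with attribute `"dropped"` (integer ids of excluded studies).
#' @export
fit_all_studies <- function(dataset, drop_single_arm = TRUE) {
  stopifnot(inherits(dataset, "ipd_dataset"))
  d <- dataset$data
  idx_by_study <- split(seq_len(nrow(d)), d$study_id)
  usable <- vapply(idx_by_study, function(idx) {
    !drop_single_arm || length(unique(d$x[idx])) == 2
  }, TRUE)
  out <- lapply(idx_by_study[usable],
                function(idx) fit_study_logistic(d$y[idx], d$x[idx]))
  attr(out, "dropped") <-
    as.integer(names(idx_by_study))[!usable]
  out
}

#' Export first-stage estimates as a data frame
#'
#' One row per study with the estimates, the three free elements of the
#' within-study covariance matrix, and the continuity-correction flag.
#'
#' @param estimates List of `study_estimate` objects.
#' @return A data.frame with columns `study_id`, `gamma0_hat`, `gamma1_hat`,
#'   `var00`, `var01`, `var11`, `corrected`.
#' @export
study_estimates_table <- function(estimates) {
  do.call(rbind, lapply(seq_along(estimates), function(j) {
    e <- estimates[[j]]
    data.frame(study_id = j, gamma0_hat = e$gamma0_hat,
               gamma1_hat = e$gamma1_hat,
               var00 = e$cov[1, 1], var01 = e$cov[1, 2],
               var11 = e$cov[2, 2], corrected = e$corrected)
  }))
}
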