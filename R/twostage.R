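#' @rdname pool_dl
#' @param method Method label.
#' @param ... Fields of the fit.
#' @keywords internal
new_pooled_fit <- function(method, ...) {
  fit <- list(method = method, beta1_hat = NA_real_, se_beta1 = NA_real_,
              tau1_sq_hat = NA_real_, se_tau1_sq = NA_real_,
              tau0_sq_hat = NA_real_, tau01_hat = NA_real_,
              study_intercepts = NULL, ci_beta1 = c(NA_real_, NA_real_),
              converged = FALSE, n_iter = 0L, messages = character())
  extra <- list(...)
  fit[names(extra)] <- extra
  class(fit) <- "pooled_fit"
  fit
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat(sprintf("Pooled IPD-MA fit [%s]%s\n", x$method,
              if (x$converged) "" else "  (did not converge)"))
  cat(sprintf("  log OR: %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$beta1_hat, x$se_beta1, x$ci_beta1[1], x$ci_beta1[2]))
  cat(sprintf("  tau1^2: %.4f%s\n", x$tau1_sq_hat,
              if (is.finite(x$se_tau1_sq))
                sprintf(" (SE %.4f)", x$se_tau1_sq) else ""))
  if (length(x$messages))
    cat("  notes:", paste(x$messages, collapse = "; "), "\n")
  invisible(x)
}

#' Second-stage DerSimonian–Laird pooling
#'
#' Univariate random-effects meta-analysis of the per-study log odds ratios
#' by the non-iterative inverse-variance method of moments. Cochran's Q with
#' fixed-effect weights \eqn{w_j = 1/\mathrm{var}(\hat\gamma_{1j})} gives
#' \deqn{\hat\tau_1^2 = \max\!\left(0,\;
#'   \frac{Q - (K-1)}{\sum w_j - \sum w_j^2 / \sum w_j}\right),}
#' and the pooled effect uses random-effects weights
#' \eqn{w_j^* = 1/(\mathrm{var}(\hat\gamma_{1j}) + \hat\tau_1^2)} with
#' \eqn{\mathrm{SE} = (\sum w_j^*)^{-1/2}} and a 95% Wald interval. The
#' method does not provide a standard error or interval for
#' \eqn{\hat\tau_1^2}.
#'
#' @param estimates List of `study_estimate` objects (>= 2), from
#'   [fit_all_studies()].
#' @return A `"pooled_fit"` with `method = "DL"`.
#' @export
pool_dl <- function(estimates) {
  if (length(estimates) < 2) stop("need at least 2 studies", call. = FALSE)
  yi <- vapply(estimates, function(e) e$gamma1_hat, 0)
  vi <- vapply(estimates, function(e) e$cov[2, 2], 0)
  if (!all(is.finite(yi)) || !all(is.finite(vi)) || any(vi <= 0))
    stop("non-finite or non-positive within-study variances", call. = FALSE)
  w <- 1 / vi
  ybar <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - ybar)^2)
  k <- length(yi)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau1_sq <- if (denom > 0) max(0, (q - (k - 1)) / denom) else 0
  wstar <- 1 / (vi + tau1_sq)
  beta1 <- sum(wstar * yi) / sum(wstar)
  se <- 1 / sqrt(sum(wstar))
  new_pooled_fit("DL", beta1_hat = beta1, se_beta1 = se,
                 tau1_sq_hat = tau1_sq,
                 ci_beta1 = beta1 + c(-1, 1) * 1.96 * se,
                 converged = TRUE, n_iter = 0L)
}

#' Second-stage bivariate random-effects meta-analysis by REML
#'
#' Jointly synthesizes the per-study intercepts and log odds ratios under
#' the marginal model
#' \deqn{(\hat\gamma_{0j}, \hat\gamma_{1j})^\top \sim
#'   N\!\big((\gamma_0, \gamma_1)^\top,\; \Sigma + C_j\big),}
#' where \eqn{C_j} is the known within-study covariance and \eqn{\Sigma} the
#' between-study covariance of the true effects. \eqn{\Sigma} is
#' parameterized by its Cholesky factor (guaranteeing positive
#' semidefiniteness) and estimated by restricted maximum likelihood with a
#' quasi-Newton optimizer from two starts (a small diagonal and a
#' method-of-moments start). The pooled effect and its standard error come
#' from generalized least squares at \eqn{\hat\Sigma}; the standard error of
#' \eqn{\hat\tau_1^2} from the numerically differentiated REML Hessian on
#' the variance scale.
#'
#' @param estimates List of `study_estimate` objects (>= 2).
#' @param fix_tau0_sq,fix_tau01 Optionally fix the intercept variance and
#'   the covariance at known values (both must be supplied together); the
#'   optimization is then over \eqn{\tau_1^2} alone. Used for diagnostics
#'   and degenerate comparisons against univariate REML.
#' @param max_iter Optimizer iteration cap.
#' @return A `"pooled_fit"` with `method = "BIVREML"`, carrying
#'   `tau0_sq_hat` and `tau01_hat` in addition to the common fields.
#' @export
pool_bivariate_reml <- function(estimates, fix_tau0_sq = NULL,
                                fix_tau01 = NULL, max_iter = 100) {
  if (length(estimates) < 2) stop("need at least 2 studies", call. = FALSE)
  y <- t(vapply(estimates, function(e) c(e$gamma0_hat, e$gamma1_hat),
                numeric(2)))
  clist <- lapply(estimates, function(e) e$cov)
  k <- nrow(y)
  msgs <- character()
  fixed <- !is.null(fix_tau0_sq)
  if (fixed != !is.null(fix_tau01))
    stop("fix_tau0_sq and fix_tau01 must be supplied together",
         call. = FALSE)

  sigma_of <- function(theta) {
    if (fixed) {
      matrix(c(fix_tau0_sq, fix_tau01, fix_tau01, theta[1]^2), 2, 2)
    } else {
      L <- matrix(c(theta[1], theta[2], 0, theta[3]), 2, 2)
      L %*% t(L)
    }
  }

  # negative REML log-likelihood (constants dropped), with GLS mean profile
  reml_nll_sigma <- function(sigma) {
    ldet <- 0
    sw <- matrix(0, 2, 2)   # sum of V_j^{-1}
    swy <- c(0, 0)
    vinv <- vector("list", k)
    for (j in seq_len(k)) {
      v <- sigma + clist[[j]]
      ch <- tryCatch(chol(v), error = function(e) NULL)
      if (is.null(ch)) {
        ch <- tryCatch(chol(v + diag(1e-10, 2)), error = function(e) NULL)
        if (is.null(ch)) return(NA_real_)
      }
      vinv[[j]] <- chol2inv(ch)
      ldet <- ldet + 2 * sum(log(diag(ch)))
      sw <- sw + vinv[[j]]
      swy <- swy + vinv[[j]] %*% y[j, ]
    }
    mu <- tryCatch(solve(sw, swy), error = function(e) NULL)
    if (is.null(mu)) return(NA_real_)
    quad <- 0
    for (j in seq_len(k)) {
      r <- y[j, ] - drop(mu)
      quad <- quad + drop(t(r) %*% vinv[[j]] %*% r)
    }
    0.5 * (ldet + determinant(sw, logarithm = TRUE)$modulus + quad)
  }
  obj <- function(theta) {
    val <- reml_nll_sigma(sigma_of(theta))
    if (!is.finite(val)) 1e10 else val
  }

  if (fixed) {
    starts <- list(sqrt(0.1), 1)
  } else {
    s_mom <- stats::cov(y) - Reduce(`+`, clist) / k
    es <- eigen(s_mom, symmetric = TRUE)
    s_mom <- es$vectors %*% diag(pmax(es$values, 1e-4)) %*% t(es$vectors)
    lm_ <- t(chol(s_mom + diag(1e-8, 2)))
    starts <- list(c(sqrt(0.1), 0, sqrt(0.1)),
                   c(lm_[1, 1], lm_[2, 1], lm_[2, 2]))
  }
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      nlminb(st, obj, control = list(iter.max = max_iter, eval.max = 1000,
                                     rel.tol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$objective < best$objective))
      best <- opt
  }
  if (is.null(best))
    return(new_pooled_fit("BIVREML", converged = FALSE,
                          messages = "REML optimization failed"))

  sigma_hat <- sigma_of(best$par)
  converged <- best$convergence == 0 && best$iterations < max_iter
  if (!converged)
    msgs <- c(msgs, paste0("optimizer: ", best$message))

  # GLS mean and its covariance at the REML solution
  sw <- matrix(0, 2, 2); swy <- c(0, 0)
  for (j in seq_len(k)) {
    vinv <- chol2inv(chol(sigma_hat + clist[[j]] + diag(1e-12, 2)))
    sw <- sw + vinv
    swy <- swy + vinv %*% y[j, ]
  }
  mu_cov <- solve(sw)
  mu <- drop(mu_cov %*% swy)

  # SE(tau1^2) from the REML curvature on the variance scale
  se_tau1_sq <- NA_real_
  hess_ok <- TRUE
  if (fixed) {
    vfun <- function(t1) reml_nll_sigma(sigma_of(sqrt(max(t1, 0))))
    h <- tryCatch(pracma::hessian(vfun, sigma_hat[2, 2]),
                  error = function(e) NA)
    if (is.finite(h) && h > 0) se_tau1_sq <- sqrt(1 / h) else hess_ok <- FALSE
  } else {
    vfun <- function(v) {
      reml_nll_sigma(matrix(c(v[1], v[2], v[2], v[3]), 2, 2))
    }
    vhat <- c(sigma_hat[1, 1], sigma_hat[1, 2], sigma_hat[2, 2])
    h <- tryCatch(pracma::hessian(vfun, vhat), error = function(e) NULL)
    hcov <- if (!is.null(h) && all(is.finite(h)))
      tryCatch(solve(h), error = function(e) NULL) else NULL
    if (!is.null(hcov) && hcov[3, 3] > 0) {
      se_tau1_sq <- sqrt(hcov[3, 3])
    } else {
      hess_ok <- FALSE
    }
  }
  if (!hess_ok) {
    msgs <- c(msgs, "REML Hessian not positive definite")
    converged <- FALSE
  }

  new_pooled_fit("BIVREML",
                 beta1_hat = mu[2], se_beta1 = sqrt(mu_cov[2, 2]),
                 tau1_sq_hat = sigma_hat[2, 2], se_tau1_sq = se_tau1_sq,
                 tau0_sq_hat = sigma_hat[1, 1], tau01_hat = sigma_hat[1, 2],
                 ci_beta1 = mu[2] + c(-1, 1) * 1.96 * sqrt(mu_cov[2, 2]),
                 converged = converged, n_iter = best$iterations,
                 messages = msgs)
}

#' Flatten pooled fits to a delimited-text-ready table
#'
#' One row per fit with a fixed column schema shared across all methods;
#' fields a method does not estimate are `NA`.
#'
#' @param fits List of `pooled_fit` objects.
#' @return A data.frame.
#' @export
pooled_fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(method = f$method, beta1_hat = f$beta1_hat,
               se_beta1 = f$se_beta1, tau1_sq_hat = f$tau1_sq_hat,
               se_tau1_sq = f$se_tau1_sq, tau0_sq_hat = f$tau0_sq_hat,
               tau01_hat = f$tau01_hat, converged = f$converged,
               n_iter = f$n_iter,
               messages = paste(f$messages, collapse = "; "))
  }))
}
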