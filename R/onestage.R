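#' Specify a one-stage GLMM fit
#'
#' @param model `"M3"` — random intercept and random treatment effect,
#'   allowed to be correlated; or `"M4"` — one fixed (stratified) intercept
#'   per study plus a random treatment effect.
#' @param engine `"PQL"` (penalized quasi-likelihood, Breslow–Clayton) or
#'   `"AGHQ"` (adaptive Gauss–Hermite quadrature maximum likelihood).
#' @param max_iter Iteration cap for the outer loop / optimizer.
#' @param param_tol Absolute parameter-change convergence criterion.
#' @param quad_points `"auto"` (start at 5 per dimension, double while the
#'   maximized log-likelihood changes by 1e-4 or more, cap 41) or a fixed
#'   integer; AGHQ only. One point reproduces the Laplace approximation.
#' @param fix_sigma Optionally hold the random-effects covariance fixed (a
#'   2x2 matrix for M3, a scalar variance for M4) instead of estimating it;
#'   zero collapses the GLMM to ordinary logistic regression. PQL accepts
#'   any positive-semidefinite value, AGHQ only zero. Used for diagnostics
#'   and known-variance fits.
#' @return An object of class `"glmm_spec"`.
#' @export
glmm_spec <- function(model = c("M3", "M4"), engine = c("PQL", "AGHQ"),
                      max_iter = 100, param_tol = 1e-8,
                      quad_points = "auto", fix_sigma = NULL) {
  model <- match.arg(model)
  engine <- match.arg(engine)
  stopifnot(param_tol > 0, max_iter >= 1)
  if (!identical(quad_points, "auto"))
    stopifnot(is.numeric(quad_points), quad_points >= 1)
  if (!is.null(fix_sigma)) {
    fix_sigma <- as.matrix(fix_sigma)
    ev <- eigen(fix_sigma, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-10))
      stop("fix_sigma must be positive semidefinite", call. = FALSE)
  }
  structure(list(model = model, engine = engine, max_iter = max_iter,
                 param_tol = param_tol, quad_points = quad_points,
                 fix_sigma = fix_sigma),
            class = "glmm_spec")
}

# Collapse subject-level data to per-(study, arm) binomial counts.
# The logistic GLMMs here depend on the data only through these counts.
aggregate_arms <- function(dataset) {
  d <- dataset$data
  agg <- aggregate(cbind(n = rep(1L, nrow(d)), e = d$y),
                   by = list(study = d$study_id, x = d$x), FUN = sum)
  agg <- agg[order(agg$study, agg$x), ]
  rownames(agg) <- NULL
  agg
}

chol_to_sigma <- function(theta) {
  L <- matrix(c(theta[1], theta[2], 0, theta[3]), 2, 2)
  L %*% t(L)
}

#' Fit a one-stage logistic GLMM by penalized quasi-likelihood
#'
#' Breslow–Clayton iteration: at the current linear predictor, form the
#' working response \eqn{z = \eta + (y - \mu)/(\mu(1-\mu))} and weights
#' \eqn{W = n\mu(1-\mu)}, fit the working linear mixed model
#' \eqn{z = X\beta + Zu + \epsilon}, \eqn{\epsilon \sim N(0, W^{-1})}, with
#' variance components estimated by REML (Cholesky-parameterized covariance,
#' quasi-Newton inner optimization), update \eqn{\eta} from the BLUPs, and
#' repeat until the largest absolute change across fixed effects and
#' variance components falls below `param_tol` (default 1e-8) or `max_iter`
#' (default 100) is reached. The standard error of the pooled effect comes
#' from the generalized-least-squares covariance at convergence; the
#' standard error of \eqn{\hat\tau_1^2} from the numerically differentiated
#' REML objective. The fit is flagged as non-converged when the iteration
#' cap is hit, the inner REML fails, or the estimated random-effects
#' covariance is not positive definite (smallest eigenvalue below 1e-8,
#' covering boundary estimates).
#'
#' @param dataset An `ipd_dataset`.
#' @param spec A [glmm_spec()] with `engine = "PQL"`.
#' @return A `"pooled_fit"` with method `"PQL_M3"` or `"PQL_M4"`.
#' @export
fit_pql <- function(dataset, spec = glmm_spec("M3", "PQL")) {
  stopifnot(inherits(dataset, "ipd_dataset"), spec$engine == "PQL")
  agg <- aggregate_arms(dataset)
  k <- dataset$scenario$n_studies
  msgs <- character()
  if (spec$model == "M3" && k < 2)
    stop("M3 needs at least 2 studies", call. = FALSE)
  one_armed <- k - length(unique(agg$study[duplicated(agg$study)]))
  if (spec$model == "M4" && one_armed > 0)
    msgs <- c(msgs, sprintf("%d stud(ies) contribute a single arm",
                            one_armed))

  nr <- nrow(agg)
  d_re <- if (spec$model == "M3") 2L else 1L
  X <- if (spec$model == "M3") {
    cbind(1, agg$x)
  } else {
    xm <- matrix(0, nr, k + 1)
    xm[cbind(seq_len(nr), agg$study)] <- 1
    xm[, k + 1] <- agg$x
    xm
  }
  beta1_col <- ncol(X)
  Z <- matrix(0, nr, k * d_re)
  for (i in seq_len(nr)) {
    j <- agg$study[i]
    if (d_re == 2) {
      Z[i, (j - 1) * 2 + 1:2] <- c(1, agg$x[i])
    } else {
      Z[i, j] <- agg$x[i]
    }
  }

  g_of <- function(theta) {
    sig <- if (d_re == 2) chol_to_sigma(theta) else matrix(theta[1]^2, 1, 1)
    kronecker(diag(k), sig)
  }

  # negative REML log-likelihood of the working LMM (constants dropped);
  # attributes carry the GLS solution so the caller avoids recomputation
  reml_pieces <- function(G, w, z) {
    V <- diag(1 / w, nr) + Z %*% G %*% t(Z)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    vinv <- chol2inv(ch)
    xtv <- crossprod(X, vinv)
    xtvx <- xtv %*% X
    beta <- tryCatch(solve(xtvx, xtv %*% z), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    r <- z - X %*% beta
    nll <- 0.5 * (2 * sum(log(diag(ch))) +
                    determinant(xtvx, logarithm = TRUE)$modulus +
                    drop(crossprod(r, vinv %*% r)))
    list(nll = as.numeric(nll), beta = drop(beta), vinv = vinv,
         xtvx = xtvx, r = drop(r), G = G)
  }

  fixed_g <- !is.null(spec$fix_sigma)
  g_fix <- if (fixed_g) {
    sig_fix <- as.matrix(spec$fix_sigma)
    stopifnot(nrow(sig_fix) == d_re)
    kronecker(diag(k), sig_fix)
  }
  theta <- if (d_re == 2) c(sqrt(0.3), 0, sqrt(0.3)) else sqrt(0.3)

  # starting linear predictor from the fixed-effects logistic fit
  fe <- glm(cbind(e, n - e) ~ 0 + X, family = binomial(), data = agg)
  eta <- drop(X %*% coef(fe))

  par_old <- rep(Inf, beta1_col + length(theta))
  converged_outer <- FALSE
  inner_ok <- TRUE
  pieces <- NULL
  w <- z <- NULL
  for (iter in seq_len(spec$max_iter)) {
    mu <- plogis(eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    w <- agg$n * mu * (1 - mu)
    z <- eta + (agg$e / agg$n - mu) / (mu * (1 - mu))
    if (fixed_g) {
      pieces <- reml_pieces(g_fix, w, z)
      if (is.null(pieces)) { inner_ok <- FALSE; break }
    } else {
      obj <- function(th) {
        p <- reml_pieces(g_of(th), w, z)
        if (is.null(p) || !is.finite(p$nll)) 1e10 else p$nll
      }
      opt <- tryCatch(nlminb(theta, obj,
                             control = list(iter.max = 200, eval.max = 1000,
                                            rel.tol = 1e-12)),
                      error = function(e) NULL)
      if (is.null(opt)) { inner_ok <- FALSE; break }
      theta <- opt$par
      pieces <- reml_pieces(g_of(theta), w, z)
      if (is.null(pieces)) { inner_ok <- FALSE; break }
    }
    u <- pieces$G %*% crossprod(Z, pieces$vinv %*% pieces$r)
    eta <- drop(X %*% pieces$beta + Z %*% u)
    sig_now <- if (d_re == 2) chol_to_sigma(theta) else
      matrix(theta[1]^2, 1, 1)
    par_new <- c(pieces$beta, sig_now[upper.tri(sig_now, diag = TRUE)])
    if (max(abs(par_new - par_old)) < spec$param_tol) {
      converged_outer <- TRUE
      break
    }
    par_old <- par_new
  }

  if (is.null(pieces))
    return(new_pooled_fit(paste0("PQL_", spec$model), converged = FALSE,
                          n_iter = iter,
                          messages = c(msgs, "inner REML failed")))

  sigma_hat <- if (fixed_g) {
    sig_fix
  } else if (d_re == 2) chol_to_sigma(theta) else matrix(theta[1]^2, 1, 1)
  beta <- pieces$beta
  beta_cov <- tryCatch(solve(pieces$xtvx), error = function(e) NULL)
  se_beta1 <- if (is.null(beta_cov)) NA_real_ else
    sqrt(beta_cov[beta1_col, beta1_col])
  tau1_sq <- sigma_hat[d_re, d_re]

  # curvature of the inner REML objective on the variance scale at the
  # final working response
  se_tau1_sq <- NA_real_
  if (!fixed_g) {
    if (d_re == 2) {
      vfun <- function(v) {
        G <- kronecker(diag(k), matrix(c(v[1], v[2], v[2], v[3]), 2, 2))
        p <- reml_pieces(G, w, z)
        if (is.null(p)) NA_real_ else p$nll
      }
      vhat <- c(sigma_hat[1, 1], sigma_hat[1, 2], sigma_hat[2, 2])
      h <- tryCatch(pracma::hessian(vfun, vhat), error = function(e) NULL)
      hc <- if (!is.null(h) && all(is.finite(h)))
        tryCatch(solve(h), error = function(e) NULL) else NULL
      if (!is.null(hc) && hc[3, 3] > 0) se_tau1_sq <- sqrt(hc[3, 3])
    } else {
      vfun <- function(v) {
        p <- reml_pieces(kronecker(diag(k), matrix(max(v, 0), 1, 1)), w, z)
        if (is.null(p)) NA_real_ else p$nll
      }
      h <- tryCatch(pracma::hessian(vfun, tau1_sq), error = function(e) NA)
      if (is.finite(h) && h > 0) se_tau1_sq <- sqrt(1 / h)
    }
    if (!is.finite(se_tau1_sq))
      msgs <- c(msgs, "REML curvature for tau1^2 not positive definite")
  }

  pd_ok <- fixed_g || min(eigen(sigma_hat, symmetric = TRUE,
                                only.values = TRUE)$values) >= 1e-8
  if (!pd_ok)
    msgs <- c(msgs,
              "random-effects covariance not positive definite (boundary)")
  if (!converged_outer) msgs <- c(msgs, "iteration cap reached")
  if (!inner_ok) msgs <- c(msgs, "inner REML failed")
  converged <- converged_outer && inner_ok && pd_ok

  new_pooled_fit(paste0("PQL_", spec$model),
                 beta1_hat = beta[beta1_col], se_beta1 = se_beta1,
                 tau1_sq_hat = tau1_sq, se_tau1_sq = se_tau1_sq,
                 tau0_sq_hat = if (d_re == 2) sigma_hat[1, 1] else NA_real_,
                 tau01_hat = if (d_re == 2) sigma_hat[1, 2] else NA_real_,
                 study_intercepts = if (spec$model == "M4")
                   beta[seq_len(k)] else NULL,
                 ci_beta1 = beta[beta1_col] + c(-1, 1) * 1.96 * se_beta1,
                 converged = converged, n_iter = iter, messages = msgs)
}

# ---- adaptive Gauss-Hermite machinery ----------------------------------

# binomial log-likelihood pieces for one study's arms at linear predictor eta
binll <- function(eta, n, e) {
  mu <- plogis(eta)
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  sum(e * log(mu) + (n - e) * log(1 - mu))
}

# Precompute the tensor-product Hermite grid for d dimensions:
# standardized nodes, log-weights, and the |z|^2 adjustment.
make_gh_grid <- function(quad_points, d) {
  gh <- if (quad_points == 1) {
    list(x = 0, w = sqrt(pi))  # one node at the origin: the Laplace limit
  } else {
    pracma::gaussHermite(quad_points)
  }
  if (d == 1) {
    znodes <- matrix(gh$x, ncol = 1)
    logw <- log(gh$w)
  } else {
    znodes <- as.matrix(expand.grid(gh$x, gh$x))
    logw <- as.vector(outer(log(gh$w), log(gh$w), `+`))
  }
  list(znodes = znodes, adj = logw + rowSums(znodes^2), d = d)
}

# log of one study's marginal likelihood integral by AGHQ.
# eta_fixed: fixed-effect part per arm; zre: per-arm random-effect design
# (n_arm x d); sig_inv, log_det_sig for the random-effect density;
# grid: a make_gh_grid() result; u_start: warm start for the mode search.
aghq_study <- function(eta_fixed, zre, n, e, sig_inv, log_det_sig, grid,
                       u_start = NULL) {
  d <- grid$d
  u <- if (is.null(u_start)) rep(0, d) else u_start
  const <- -0.5 * (d * log(2 * pi) + log_det_sig)
  h_of <- function(u) {
    binll(eta_fixed + drop(zre %*% u), n, e) -
      0.5 * drop(t(u) %*% sig_inv %*% u) + const
  }
  h_cur <- h_of(u)
  ok <- FALSE
  for (it in 1:50) {
    mu <- plogis(eta_fixed + drop(zre %*% u))
    g <- drop(crossprod(zre, e - n * mu)) - drop(sig_inv %*% u)
    H <- -crossprod(zre * (n * mu * (1 - mu)), zre) - sig_inv
    step <- tryCatch(solve(-H, g), error = function(x) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      u_new <- u + lambda * step
      h_new <- h_of(u_new)
      if (is.finite(h_new) && h_new >= h_cur - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    moved <- max(abs(u_new - u))
    u <- u_new
    h_cur <- h_new
    if (max(abs(g)) < 1e-11 || moved < 1e-13) { ok <- TRUE; break }
  }
  mu <- plogis(eta_fixed + drop(zre %*% u))
  H <- -crossprod(zre * (n * mu * (1 - mu)), zre) - sig_inv
  A <- tryCatch(solve(-H), error = function(x) NULL)
  if (is.null(A)) return(list(log_lik = NA_real_, mode = u, ok = FALSE))
  chA <- tryCatch(chol(A), error = function(x) NULL)
  if (is.null(chA)) return(list(log_lik = NA_real_, mode = u, ok = FALSE))
  L <- t(chA)
  unodes <- sweep(grid$znodes %*% t(L) * sqrt(2), 2, u, `+`)
  eta_nodes <- matrix(eta_fixed, length(eta_fixed), nrow(unodes)) +
    zre %*% t(unodes)
  mu_nodes <- pmin(pmax(plogis(eta_nodes), 1e-12), 1 - 1e-12)
  ll_nodes <- colSums(e * log(mu_nodes) + (n - e) * log(1 - mu_nodes))
  pen <- 0.5 * rowSums((unodes %*% sig_inv) * unodes)
  terms <- ll_nodes - pen + const + grid$adj
  m <- max(terms)
  log_lik <- (d / 2) * log(2) + sum(log(diag(L))) +
    m + log(sum(exp(terms - m)))
  list(log_lik = log_lik, mode = u, ok = ok)
}

#' Fit a one-stage logistic GLMM by adaptive Gauss–Hermite quadrature
#'
#' The marginal log-likelihood factorizes over studies; each study's
#' integral over its random effects (two-dimensional for M3, one-dimensional
#' for M4) is approximated by adaptive Gauss–Hermite quadrature: the
#' integrand's conditional mode and curvature recenter and rescale a
#' tensor-product Hermite grid. The likelihood is maximized by quasi-Newton
#' over the fixed effects and the Cholesky factor of the random-effects
#' covariance; for M4 the K stratified intercepts are profiled out with an
#' inner per-study Newton search, keeping the outer problem two-dimensional.
#' With `quad_points = "auto"` the fit starts at 5 points per dimension and
#' doubles (5, 10, 20, 40) until the maximized log-likelihood changes by
#' less than 1e-4. Standard errors come from the inverse numerical Hessian
#' of the (profile) log-likelihood with a delta-method transformation to
#' the variance scale. Non-convergence is flagged on the iteration cap, a
#' non-positive-definite Hessian, failed mode-finding at the optimum, or a
#' boundary covariance estimate (smallest eigenvalue below 1e-8).
#'
#' @param dataset An `ipd_dataset`.
#' @param spec A [glmm_spec()] with `engine = "AGHQ"`.
#' @return A `"pooled_fit"` with method `"AGHQ_M3"` or `"AGHQ_M4"`.
#' @export
fit_aghq <- function(dataset, spec = glmm_spec("M3", "AGHQ")) {
  stopifnot(inherits(dataset, "ipd_dataset"), spec$engine == "AGHQ")
  agg <- aggregate_arms(dataset)
  k <- dataset$scenario$n_studies
  msgs <- character()
  if (spec$model == "M3" && k < 2)
    stop("M3 needs at least 2 studies", call. = FALSE)
  by_study <- split(agg, agg$study)

  if (!is.null(spec$fix_sigma)) {
    if (any(spec$fix_sigma != 0))
      stop("fit_aghq supports fix_sigma = 0 only", call. = FALSE)
    return(aghq_fixed_zero(dataset, spec, agg, k))
  }

  d_re <- if (spec$model == "M3") 2L else 1L
  mode_cache <- new.env(parent = emptyenv())
  mode_cache$u <- replicate(k, rep(0, d_re), simplify = FALSE)
  mode_cache$gamma <- vapply(by_study, function(s) {
    e <- sum(s$e) + 0.5
    n <- sum(s$n) + 1
    qlogis(e / n)
  }, 0)
  mode_cache$fails <- 0L

  sig_parts <- function(theta_v) {
    if (d_re == 2) {
      sig <- chol_to_sigma(theta_v)
    } else {
      sig <- matrix(theta_v[1]^2, 1, 1)
    }
    ch <- tryCatch(chol(sig), error = function(x) NULL)
    if (is.null(ch)) return(NULL)
    list(inv = chol2inv(ch), ldet = 2 * sum(log(diag(ch))))
  }

  neg_ll <- function(theta, grid) {
    nfix <- 2L  # (gamma0, gamma1) for M3; (gamma1, ell) packed for M4
    if (spec$model == "M3") {
      sp <- sig_parts(theta[3:5])
      if (is.null(sp)) return(1e10)
      total <- 0
      fails <- 0L
      for (j in seq_len(k)) {
        s <- by_study[[j]]
        res <- aghq_study(theta[1] + theta[2] * s$x,
                          cbind(1, s$x), s$n, s$e,
                          sp$inv, sp$ldet, grid, mode_cache$u[[j]])
        if (!is.finite(res$log_lik)) return(1e10)
        mode_cache$u[[j]] <- res$mode
        if (!res$ok) fails <- fails + 1L
        total <- total + res$log_lik
      }
      mode_cache$fails <- fails
      -total
    } else {
      sp <- sig_parts(theta[2])
      if (is.null(sp)) return(1e10)
      total <- 0
      fails <- 0L
      for (j in seq_len(k)) {
        s <- by_study[[j]]
        study_ll <- function(gam) {
          res <- aghq_study(gam + theta[1] * s$x, matrix(s$x, ncol = 1),
                            s$n, s$e, sp$inv, sp$ldet, grid,
                            mode_cache$u[[j]])
          res
        }
        # profile the study intercept by 1-D Newton on numerical derivatives
        gam <- mode_cache$gamma[j]
        res <- study_ll(gam)
        if (!is.finite(res$log_lik)) return(1e10)
        hstep <- 1e-5
        for (nit in 1:30) {
          lp <- study_ll(gam + hstep)$log_lik
          lm <- study_ll(gam - hstep)$log_lik
          g1 <- (lp - lm) / (2 * hstep)
          g2 <- (lp - 2 * res$log_lik + lm) / hstep^2
          if (!is.finite(g1) || !is.finite(g2) || g2 >= 0) break
          step <- -g1 / g2
          step <- max(min(step, 2), -2)
          gam_new <- gam + step
          res_new <- study_ll(gam_new)
          if (!is.finite(res_new$log_lik) ||
                res_new$log_lik < res$log_lik - 1e-10) {
            gam_new <- gam + step / 2
            res_new <- study_ll(gam_new)
            if (!is.finite(res_new$log_lik) ||
                  res_new$log_lik < res$log_lik - 1e-10) break
          }
          conv <- abs(gam_new - gam) < 1e-9
          gam <- gam_new
          res <- res_new
          if (conv) break
        }
        mode_cache$gamma[j] <- gam
        mode_cache$u[[j]] <- res$mode
        if (!res$ok) fails <- fails + 1L
        total <- total + res$log_lik
      }
      mode_cache$fails <- fails
      -total
    }
  }

  # starting values: fixed-effects logistic fit, moderate heterogeneity
  fe <- glm(cbind(e, n - e) ~ x, family = binomial(), data = agg)
  if (spec$model == "M3") {
    theta <- c(coef(fe), sqrt(0.3), 0, sqrt(0.3))
    lower <- c(-Inf, -Inf, 1e-4, -Inf, 1e-4)
  } else {
    theta <- c(coef(fe)[2], sqrt(0.3))
    lower <- c(-Inf, 1e-4)
  }

  qs <- if (identical(spec$quad_points, "auto")) c(5L, 10L, 20L, 40L)
        else as.integer(spec$quad_points)
  ll_prev <- NA_real_
  opt <- NULL
  q_used <- qs[1]
  n_iter_total <- 0L
  for (qi in seq_along(qs)) {
    grid <- make_gh_grid(qs[qi], d_re)
    opt_try <- tryCatch(
      nlminb(theta, neg_ll, grid = grid, lower = lower,
             control = list(iter.max = spec$max_iter, eval.max = 2000,
                            rel.tol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt_try)) {
      msgs <- c(msgs, sprintf("optimization failed at %d points", qs[qi]))
      break
    }
    opt <- opt_try
    theta <- opt$par
    q_used <- qs[qi]
    n_iter_total <- n_iter_total + opt$iterations
    if (!is.na(ll_prev) && abs(-opt$objective - ll_prev) < 1e-4) break
    ll_prev <- -opt$objective
  }
  if (is.null(opt))
    return(new_pooled_fit(paste0("AGHQ_", spec$model), converged = FALSE,
                          messages = c(msgs, "AGHQ optimization failed")))

  grid <- make_gh_grid(q_used, d_re)
  final_nll <- neg_ll(theta, grid)
  mode_fails <- mode_cache$fails
  opt_ok <- opt$convergence == 0 && opt$iterations < spec$max_iter

  if (spec$model == "M3") {
    sigma_hat <- chol_to_sigma(theta[3:5])
    beta1 <- theta[2]
    study_int <- NULL
  } else {
    sigma_hat <- matrix(theta[2]^2, 1, 1)
    beta1 <- theta[1]
    study_int <- mode_cache$gamma
  }
  tau1_sq <- sigma_hat[d_re, d_re]

  h <- tryCatch(pracma::hessian(function(p) neg_ll(p, grid), theta),
                error = function(e) NULL)
  se_beta1 <- NA_real_
  se_tau1_sq <- NA_real_
  hess_ok <- FALSE
  if (!is.null(h) && all(is.finite(h))) {
    hc <- tryCatch(solve(h), error = function(e) NULL)
    if (!is.null(hc)) {
      if (spec$model == "M3") {
        jac_b <- c(0, 1, 0, 0, 0)
        jac_t <- c(0, 0, 0, 2 * theta[4], 2 * theta[5])
      } else {
        jac_b <- c(1, 0)
        jac_t <- c(0, 2 * theta[2])
      }
      vb <- drop(t(jac_b) %*% hc %*% jac_b)
      vt <- drop(t(jac_t) %*% hc %*% jac_t)
      if (vb > 0) se_beta1 <- sqrt(vb)
      if (vt > 0) se_tau1_sq <- sqrt(vt)
      hess_ok <- vb > 0
    }
  }
  if (!hess_ok) msgs <- c(msgs, "log-likelihood Hessian not positive definite")

  pd_ok <- min(eigen(sigma_hat, symmetric = TRUE,
                     only.values = TRUE)$values) >= 1e-8
  if (!pd_ok)
    msgs <- c(msgs,
              "random-effects covariance not positive definite (boundary)")
  if (mode_fails > 0)
    msgs <- c(msgs, sprintf("mode finding failed in %d stud(ies)",
                            mode_fails))
  if (!opt_ok) msgs <- c(msgs, paste0("optimizer: ", opt$message))
  converged <- opt_ok && hess_ok && pd_ok && mode_fails == 0

  new_pooled_fit(paste0("AGHQ_", spec$model),
                 beta1_hat = beta1, se_beta1 = se_beta1,
                 gamma0_hat = if (spec$model == "M3") theta[1] else NA_real_,
                 tau1_sq_hat = tau1_sq, se_tau1_sq = se_tau1_sq,
                 tau0_sq_hat = if (d_re == 2) sigma_hat[1, 1] else NA_real_,
                 tau01_hat = if (d_re == 2) sigma_hat[1, 2] else NA_real_,
                 study_intercepts = study_int,
                 ci_beta1 = beta1 + c(-1, 1) * 1.96 * se_beta1,
                 converged = converged, n_iter = n_iter_total,
                 messages = msgs, log_lik = -final_nll,
                 quad_points = q_used)
}

# With the random-effects covariance fixed at zero the marginal likelihood
# is an ordinary logistic likelihood; fit it directly.
aghq_fixed_zero <- function(dataset, spec, agg, k) {
  if (spec$model == "M3") {
    fe <- glm(cbind(e, n - e) ~ x, family = binomial(), data = agg)
    beta1 <- coef(fe)[["x"]]
    study_int <- NULL
  } else {
    agg$study_f <- factor(agg$study, levels = seq_len(k))
    fe <- glm(cbind(e, n - e) ~ 0 + study_f + x, family = binomial(),
              data = agg)
    beta1 <- coef(fe)[["x"]]
    study_int <- unname(coef(fe)[seq_len(k)])
  }
  se <- sqrt(vcov(fe)["x", "x"])
  new_pooled_fit(paste0("AGHQ_", spec$model),
                 beta1_hat = beta1, se_beta1 = se,
                 tau1_sq_hat = 0, study_intercepts = study_int,
                 ci_beta1 = beta1 + c(-1, 1) * 1.96 * se,
                 converged = TRUE, n_iter = fe$iter,
                 log_lik = as.numeric(stats::logLik(fe)))
}

#' Evaluate the AGHQ marginal log-likelihood at fixed parameters
#'
#' Exposed for diagnostics and quadrature-stability checks: returns the
#' adaptive Gauss–Hermite approximation of the M3 marginal log-likelihood
#' at the supplied parameter values and number of quadrature points.
#'
#' @param dataset An `ipd_dataset`.
#' @param gamma0,gamma1 Fixed effects.
#' @param sigma 2x2 random-effects covariance (positive definite).
#' @param quad_points Points per dimension.
#' @return The log-likelihood value.
#' @export
aghq_loglik_m3 <- function(dataset, gamma0, gamma1, sigma, quad_points) {
  agg <- aggregate_arms(dataset)
  by_study <- split(agg, agg$study)
  ch <- chol(sigma)
  sig_inv <- chol2inv(ch)
  ldet <- 2 * sum(log(diag(ch)))
  grid <- make_gh_grid(quad_points, 2)
  sum(vapply(by_study, function(s) {
    aghq_study(gamma0 + gamma1 * s$x, cbind(1, s$x), s$n, s$e,
               sig_inv, ldet, grid)$log_lik
  }, 0))
}

#' Fit one estimator to one dataset
#'
#' Dispatch helper mapping a method label to the corresponding fit: `"DL"`
#' and `"BIVREML"` run the two-stage pipeline (per-study logistic fits then
#' pooling), `"PQL_M3"`, `"PQL_M4"`, `"AGHQ_M3"`, `"AGHQ_M4"` the one-stage
#' GLMMs.
#'
#' @param dataset An `ipd_dataset`.
#' @param method One of `"DL"`, `"BIVREML"`, `"PQL_M3"`, `"PQL_M4"`,
#'   `"AGHQ_M3"`, `"AGHQ_M4"`.
#' @param first_stage Optional precomputed [fit_all_studies()] result, so
#'   the two-stage methods can share one first stage.
#' @return A `"pooled_fit"`.
#' @export
fit_method <- function(dataset, method, first_stage = NULL) {
  method <- match.arg(method, c("DL", "BIVREML", "PQL_M3", "PQL_M4",
                                "AGHQ_M3", "AGHQ_M4"))
  if (method %in% c("DL", "BIVREML")) {
    if (is.null(first_stage)) first_stage <- fit_all_studies(dataset)
    if (method == "DL") return(pool_dl(first_stage))
    return(pool_bivariate_reml(first_stage))
  }
  model <- if (endsWith(method, "M3")) "M3" else "M4"
  engine <- if (startsWith(method, "PQL")) "PQL" else "AGHQ"
  spec <- glmm_spec(model, engine)
  if (engine == "PQL") fit_pql(dataset, spec) else fit_aghq(dataset, spec)
}
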