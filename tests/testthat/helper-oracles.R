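# Independent oracles used to validate the estimators. These deliberately
# share no code with the package: closed forms, grid searches, brute-force
# optimization and dense numerical integration only.

# closed-form 2x2 table estimate with exposure coded +-1/2
oracle_2x2 <- function(a, b, c, d) {
  lt <- log(a / b)
  lc <- log(c / d)
  list(gamma0 = (lt + lc) / 2, gamma1 = lt - lc,
       var_gamma1 = 1 / a + 1 / b + 1 / c + 1 / d)
}

# DerSimonian-Laird by spreadsheet-style arithmetic
oracle_dl <- function(yi, vi) {
  w <- 1 / vi
  ybar <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - ybar)^2)
  tau2 <- max(0, (q - (length(yi) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (vi + tau2)
  list(q = q, tau2 = tau2, beta = sum(ws * yi) / sum(ws),
       se = 1 / sqrt(sum(ws)))
}

# univariate random-effects REML by two-pass grid search over tau^2
oracle_univ_reml_tau2 <- function(yi, vi, hi = 8) {
  nll <- function(t2) {
    w <- 1 / (vi + t2)
    mu <- sum(w * yi) / sum(w)
    0.5 * (sum(log(vi + t2)) + log(sum(w)) + sum(w * (yi - mu)^2))
  }
  ts <- seq(0, hi, by = 1e-3)
  t0 <- ts[which.min(vapply(ts, nll, 0))]
  ts2 <- seq(max(0, t0 - 2e-3), t0 + 2e-3, by = 1e-6)
  ts2[which.min(vapply(ts2, nll, 0))]
}

# Laplace approximation of the random-intercept/random-slope marginal
# log-likelihood, with the conditional mode found by BFGS and the exact
# analytic curvature at that mode
oracle_laplace_ll_m3 <- function(dataset, gamma0, gamma1, sigma) {
  d <- dataset$data
  sig_inv <- solve(sigma)
  log_det <- as.numeric(determinant(sigma, logarithm = TRUE)$modulus)
  total <- 0
  for (j in sort(unique(d$study_id))) {
    rows <- d[d$study_id == j, ]
    h <- function(u) {
      eta <- gamma0 + u[1] + (gamma1 + u[2]) * rows$x
      sum(rows$y * eta - log1p(exp(eta))) -
        0.5 * drop(t(u) %*% sig_inv %*% u) - log(2 * pi) - 0.5 * log_det
    }
    grad_h <- function(u) {
      mu <- plogis(gamma0 + u[1] + (gamma1 + u[2]) * rows$x)
      c(sum(rows$y - mu), sum((rows$y - mu) * rows$x)) -
        drop(sig_inv %*% u)
    }
    opt <- optim(c(0, 0), function(u) -h(u), function(u) -grad_h(u),
                 method = "BFGS",
                 control = list(reltol = 1e-16, maxit = 1000))
    u <- opt$par
    # polish to machine precision with Newton on a finite-difference Hessian
    for (it in 1:20) {
      g <- grad_h(u)
      if (max(abs(g)) < 1e-12) break
      u <- u - solve(pracma::hessian(h, u), g)
    }
    mu <- plogis(gamma0 + u[1] + (gamma1 + u[2]) * rows$x)
    zmat <- cbind(1, rows$x)
    neg_hess <- crossprod(zmat * (mu * (1 - mu)), zmat) + sig_inv
    total <- total + h(u) + log(2 * pi) -
      0.5 * as.numeric(determinant(neg_hess, logarithm = TRUE)$modulus)
  }
  total
}

# dense 2-D trapezoid integration of each study's marginal likelihood over
# +-`width` prior standard deviations, on an npts x npts grid
oracle_dense_ll_m3 <- function(dataset, gamma0, gamma1, sigma,
                               npts = 201, width = 6) {
  d <- dataset$data
  sig_inv <- solve(sigma)
  log_det <- as.numeric(determinant(sigma, logarithm = TRUE)$modulus)
  u1 <- seq(-width * sqrt(sigma[1, 1]), width * sqrt(sigma[1, 1]),
            length.out = npts)
  u2 <- seq(-width * sqrt(sigma[2, 2]), width * sqrt(sigma[2, 2]),
            length.out = npts)
  wt <- function(n) c(0.5, rep(1, n - 2), 0.5)  # trapezoid weights
  w2 <- outer(wt(npts), wt(npts)) * diff(u1)[1] * diff(u2)[1]
  grid <- as.matrix(expand.grid(u1 = u1, u2 = u2))
  pen <- 0.5 * rowSums((grid %*% sig_inv) * grid)
  total <- 0
  for (j in sort(unique(d$study_id))) {
    rows <- d[d$study_id == j, ]
    ll_u <- vapply(seq_len(nrow(grid)), function(i) {
      eta <- gamma0 + grid[i, 1] + (gamma1 + grid[i, 2]) * rows$x
      sum(rows$y * eta - log1p(exp(eta)))
    }, 0)
    log_f <- ll_u - pen - log(2 * pi) - 0.5 * log_det
    m <- max(log_f)
    total <- total + m + log(sum(exp(log_f - m) * as.vector(w2)))
  }
  total
}

# brute-force nested optimization of the Laplace-type penalized likelihood:
# outer Nelder-Mead over fixed effects and an unconstrained covariance
# parameterization, inner per-study mode search inside the oracle above
oracle_nested_ml_m3 <- function(dataset) {
  obj <- function(p) {
    sd0 <- exp(p[3]); sd1 <- exp(p[4]); rho <- tanh(p[5])
    sigma <- matrix(c(sd0^2, rho * sd0 * sd1,
                      rho * sd0 * sd1, sd1^2), 2, 2)
    -oracle_laplace_ll_m3(dataset, p[1], p[2], sigma)
  }
  opt <- optim(c(-0.8, 0.2, log(0.7), log(0.7), 0), obj,
               method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  list(gamma0 = opt$par[1], beta1 = opt$par[2],
       tau0_sq = exp(opt$par[3])^2, tau1_sq = exp(opt$par[4])^2,
       rho = tanh(opt$par[5]), log_lik = -opt$value)
}

# small seeded dataset factory
make_dataset <- function(seed, n_studies, total_size,
                         size_scheme = "balanced", tau0_sq = 1,
                         tau1_sq = 1, rho = 0.5, beta0 = -0.85,
                         beta1 = 0.18,
                         generation_mode = "random_intercept") {
  sc <- scenario_config(n_studies, total_size, size_scheme,
                        beta0 = beta0, beta1 = beta1, tau0_sq = tau0_sq,
                        tau1_sq = tau1_sq, rho = rho,
                        generation_mode = generation_mode, n_reps = 1)
  set.seed(seed)
  generate_dataset(sc)
}

# reverse the exposure coding of a dataset
flip_exposure <- function(dataset) {
  dataset$data$x <- -dataset$data$x
  dataset
}
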