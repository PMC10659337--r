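# Independent scalar-LMM oracle: direct REML maximization over a dense
# covariance parameterization, sharing no code with the package's engine
# (which delegates to lme4). Supports y ~ x + (1|g) and y ~ x + (x|g).
oracle_reml_criterion <- function(y, X, Zg, Gf, sigma2) {
  L <- length(y)
  V <- sigma2 * diag(L) + Zg %*% Gf %*% t(Zg)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vinv <- chol2inv(ch)
  XtVX <- t(X) %*% Vinv %*% X
  beta <- solve(XtVX, t(X) %*% Vinv %*% y)
  r <- y - X %*% beta
  -0.5 * (2 * sum(log(diag(ch))) + determinant(XtVX, logarithm = TRUE)$modulus +
            as.numeric(t(r) %*% Vinv %*% r) +
            (L - ncol(X)) * log(2 * pi))
}

oracle_build_Z <- function(g, Tmat) {
  g <- factor(g)
  nlev <- nlevels(g); q <- ncol(Tmat)
  Zg <- matrix(0, length(g), nlev * q)
  for (j in seq_len(nlev)) {
    rows <- which(as.integer(g) == j)
    Zg[rows, (j - 1) * q + seq_len(q)] <- Tmat[rows, , drop = FALSE]
  }
  Zg
}

oracle_Gf <- function(G, nlev) {
  q <- ncol(G)
  Gf <- matrix(0, nlev * q, nlev * q)
  for (j in seq_len(nlev)) {
    idx <- (j - 1) * q + seq_len(q)
    Gf[idx, idx] <- G
  }
  Gf
}

# REML fit by Nelder-Mead over a log-Cholesky parameterization
oracle_lmm <- function(y, x = NULL, g, random_slope = !is.null(x)) {
  X <- if (is.null(x)) matrix(1, length(y)) else cbind(1, x)
  Tmat <- if (random_slope) cbind(1, x) else matrix(1, length(y))
  q <- ncol(Tmat)
  nlev <- nlevels(factor(g))
  Zg <- oracle_build_Z(g, Tmat)
  par2cov <- function(par) {
    Lc <- matrix(0, q, q)
    diag(Lc) <- exp(par[seq_len(q)])
    if (q == 2) Lc[2, 1] <- par[3]
    G <- Lc %*% t(Lc)
    sigma2 <- exp(par[length(par)])
    list(G = G, sigma2 = sigma2)
  }
  npar <- q + ifelse(q == 2, 1, 0) + 1
  obj <- function(par) {
    cc <- par2cov(par)
    -oracle_reml_criterion(y, X, Zg, oracle_Gf(cc$G, nlev), cc$sigma2)
  }
  best <- NULL
  for (start in list(rep(0, npar), c(rep(-2, npar - 1), log(stats::var(y))),
                     rep(-1, npar))) {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  cc <- par2cov(best$par)
  V <- cc$sigma2 * diag(length(y)) + Zg %*% oracle_Gf(cc$G, nlev) %*% t(Zg)
  Vinv <- chol2inv(chol(V))
  XtVX <- t(X) %*% Vinv %*% X
  beta <- solve(XtVX, t(X) %*% Vinv %*% y)
  list(beta = as.vector(beta), cov_beta = solve(XtVX), G = cc$G,
       sigma2 = cc$sigma2, reml = -best$value,
       criterion = function(G, sigma2)
         oracle_reml_criterion(y, X, Zg, oracle_Gf(G, nlev), sigma2))
}

# closed-form balanced one-way random-intercept components
oracle_oneway <- function(y, g) {
  g <- factor(g)
  m <- length(y) / nlevels(g)
  gm <- tapply(y, g, mean)
  msb <- m * sum((gm - mean(y))^2) / (nlevels(g) - 1)
  msw <- sum((y - gm[g])^2) / (length(y) - nlevels(g))
  list(between = max((msb - msw) / m, 0), within = msw)
}

# small nested functional dataset with known structure, for fast tests
tiny_truth <- function(n_subjects = 4, n_sessions = 2, trials = 6,
                       n_points = 12, effect = 0.4, condition = "session") {
  grid <- time_grid(start = -0.3, rate = 15, n = n_points)
  t <- as.numeric(grid)
  sq <- function(s, l) default_covariance(grid, "sqexp", scale = s, lengthscale = l)
  sim_truth(grid,
            beta0 = 0.8 * exp(-(t - 0.1)^2 / 0.02),
            beta1 = effect * exp(-(t - 0.15)^2 / 0.01),
            Sigma_g0 = sq(0.09, 0.3), Sigma_g1 = sq(0.01, 0.3),
            Sigma_eps_base = lapply(1:3, function(m) sq(0.08 + 0.02 * m, 0.1) +
                                      diag(0.01, n_points)),
            eps_scale = 5, n_subjects = n_subjects, n_sessions = n_sessions,
            trials_per_session = trials, condition = condition)
}

tiny_dataset <- function(seed = 1, ...) generate_functional(tiny_truth(...), seed)$dataset

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(max(abs(y)), 1e-12), tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
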