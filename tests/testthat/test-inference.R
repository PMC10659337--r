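test_that("no-random-effects homoskedastic model: near-diagonal raw covariance", {
  # independent columns: cross-covariances should vanish, diagonal should
  # match the model-based pointwise variance up to finite-sample factors
  set.seed(10)
  S <- 10; L <- 120
  tr <- data.frame(subject = rep(c("a", "b", "c"), each = L / 3),
                   session = 1, trial = rep(seq_len(L / 3), 3))
  tr$x <- round(runif(L, -1, 1), 3)
  R <- 60
  offs <- matrix(NA_real_, R, 2); diags <- matrix(NA_real_, R, S)
  model_diag <- matrix(NA_real_, R, S)
  for (r in 1:R) {
    set.seed(300 + r)
    Y <- sapply(1:S, function(s) 0.5 * tr$x + rnorm(L, 0, 0.7))
    ds <- functional_dataset(Y, time_grid(start = 0, rate = 15, n = S), tr)
    design <- build_design(flmm_formula("y ~ x"), tr, center = FALSE)
    pw <- fit_pointwise(ds, design)
    ident <- lapply(1:2, function(k) diag(S))
    cv <- estimate_beta_covariance(pw, ident, design)
    offs[r, ] <- c(cv$raw[[2]][2, 7], cv$raw[[2]][1, 9])
    diags[r, ] <- diag(cv$raw[[2]])
    model_diag[r, ] <- pw$cov_beta[2, 2, ]
  }
  mc_se <- apply(offs, 2, sd) / sqrt(R)
  expect_true(all(abs(colMeans(offs)) <= 3 * mc_se))
  expect_equal(mean(diags), mean(model_diag), tolerance = 0.05)
})

test_that("a constant subject random intercept induces positive long-range correlation", {
  # intercept estimator: corr between distant time-points implied by the
  # variance ratio  G / (G + sig2/m_per_subject ... ) computed empirically
  set.seed(20)
  S <- 8; n <- 6; m <- 25; L <- n * m
  G <- 0.3^2; s2 <- 0.5^2
  tr <- data.frame(subject = rep(sprintf("s%d", 1:n), each = m),
                   session = 1, trial = rep(1:m, n))
  design <- build_design(flmm_formula("y ~ 1 + (1 | subject)"), tr)
  R <- 40
  est_cor <- numeric(R); b1 <- matrix(NA_real_, R, 2)
  for (r in 1:R) {
    set.seed(400 + r)
    g0 <- rnorm(n, 0, sqrt(G))
    i <- rep(1:n, each = m)
    Y <- sapply(1:S, function(s) g0[i] + rnorm(L, 0, sqrt(s2)))
    ds <- functional_dataset(Y, time_grid(start = 0, rate = 15, n = S), tr)
    pw <- fit_pointwise(ds, design)
    cv <- estimate_beta_covariance(pw, list(diag(S)), design)
    C <- cv$raw[[1]]
    est_cor[r] <- C[1, S] / sqrt(C[1, 1] * C[S, S])
    b1[r, ] <- pw$beta_raw[c(1, S), 1]
  }
  # empirical correlation of the estimator across distant columns
  emp <- cor(b1[, 1], b1[, 2])
  expect_gt(mean(est_cor), 0)
  expect_lt(abs(mean(est_cor) - emp), 3 * (sd(est_cor) / sqrt(R) + 0.12))
})

test_that("assembled covariances are exactly symmetric and PSD after projection", {
  ds <- tiny_dataset(seed = 3)
  fit <- flmm(photometry ~ delay + (1 | id), ds, n_sim_joint = 1000,
              random_curves = FALSE)
  for (b in fit$bands) {
    C <- b$cov_full
    expect_identical(max(abs(C - t(C))), 0)
    expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
    expect_equal(unname(diag(C)), unname(b$se^2), tolerance = 1e-8)
  }
})

test_that("the joint multiplier matches closed forms", {
  # one point: the pointwise normal quantile
  expect_equal(joint_multiplier(matrix(1), 0.95, n_sim = 1e5, seed = 1),
               qnorm(0.975), tolerance = 0.02)
  # perfect correlation: max of identical variables is one variable
  C1 <- matrix(1, 10, 10)
  expect_equal(joint_multiplier(C1, 0.95, n_sim = 1e5, seed = 2),
               qnorm(0.975), tolerance = 0.02)
  # independence: closed-form quantile of the max of 10 iid |N(0,1)|
  C2 <- diag(10)
  q10 <- qnorm((1 + 0.95^(1 / 10)) / 2)
  expect_equal(joint_multiplier(C2, 0.95, n_sim = 1e5, seed = 3), q10,
               tolerance = 0.03)
  # invariance to rescaling the covariance
  set.seed(4)
  A <- crossprod(matrix(rnorm(100), 10))
  expect_equal(joint_multiplier(A, seed = 5), joint_multiplier(7.3 * A, seed = 5),
               tolerance = 1e-12)
  # zero-variance points are excluded with a warning
  A0 <- A; A0[1, ] <- 0; A0[, 1] <- 0
  expect_warning(q0 <- joint_multiplier(A0, seed = 6), "zero variance")
  expect_gte(q0, qnorm(0.975))
  # a finite df widens the multiplier
  expect_gt(joint_multiplier(A, seed = 7, df = 8), joint_multiplier(A, seed = 7))
})

test_that("band construction arithmetic and degeneracy flags", {
  est <- rep(0, 5); C <- diag(5)
  b <- build_bands(est, C, level = 0.95, q_joint = 2.5, time = 1:5)
  expect_equal(unname(b$joint_bounds[, 1]), rep(-2.5, 5))
  expect_equal(unname(b$joint_bounds[, 2]), rep(2.5, 5))
  w_ratio <- (b$joint_bounds[, 2] - b$joint_bounds[, 1]) /
    (b$pw_bounds[, 2] - b$pw_bounds[, 1])
  expect_equal(unname(w_ratio), rep(2.5 / qnorm(0.975), 5), tolerance = 1e-10)
  Cz <- diag(c(1, 0, 1, 1, 1))
  bz <- build_bands(est, Cz, q_joint = 2.5, time = 1:5)
  expect_equal(bz$degenerate, 2L)
  expect_equal(unname(bz$joint_bounds[2, ]), c(0, 0))
})

test_that("significant-interval extraction returns maximal runs in time order", {
  t <- seq(0, 2, by = 0.1)
  est <- rep(0, 21); se <- rep(1, 21)
  b <- build_bands(est, diag(21), q_joint = 2, time = t)
  expect_equal(nrow(significant_intervals(b)), 0)
  est2 <- c(rep(0, 5), rep(5, 5), rep(0, 4), rep(-5, 3), rep(0, 4))
  b2 <- build_bands(est2, diag(21), q_joint = 2, time = t)
  si <- significant_intervals(b2, "joint")
  expect_equal(nrow(si), 2)
  expect_equal(si$start, c(t[6], t[15]))
  expect_equal(si$end, c(t[10], t[17]))
  expect_equal(si$sign, c("positive", "negative"))
})

test_that("every fitted joint band contains its pointwise band", {
  for (seed in 1:3) {
    ds <- tiny_dataset(seed = seed)
    fit <- flmm(photometry ~ delay + (delay | id), ds, n_sim_joint = 1000,
                random_curves = FALSE)
    for (b in fit$bands) {
      expect_true(all(b$joint_bounds[, 1] <= b$pw_bounds[, 1] + 1e-12))
      expect_true(all(b$pw_bounds[, 2] <= b$joint_bounds[, 2] + 1e-12))
      expect_gte(b$q_joint, qnorm(0.975))
    }
  }
})

test_that("the cluster bootstrap validates inputs, is seeded, and tracks the analytic band", {
  truth <- tiny_truth(n_subjects = 10, n_sessions = 1, trials = 8, n_points = 10,
                      condition = "trial")
  ds <- generate_functional(truth, seed = 12)$dataset
  expect_error(cluster_bootstrap_bands(ds, photometry ~ delay, B = 2), "at least 200")
  b1 <- cluster_bootstrap_bands(ds, photometry ~ delay + (1 | id), B = 200, seed = 5)
  b2 <- cluster_bootstrap_bands(ds, photometry ~ delay + (1 | id), B = 200, seed = 5)
  expect_equal(b1$delay$pw_bounds, b2$delay$pw_bounds, tolerance = 1e-12)
  fit <- flmm(photometry ~ delay + (1 | id), ds, n_sim_joint = 1000,
              random_curves = FALSE)
  wb <- mean(b1$delay$pw_bounds[, 2] - b1$delay$pw_bounds[, 1])
  wa <- mean(fit$bands$delay$pw_bounds[, 2] - fit$bands$delay$pw_bounds[, 1])
  expect_lt(abs(wb - wa) / wa, 0.15)
})

test_that("fitting with nested random effects runs end to end", {
  truth <- tiny_truth(n_subjects = 5, n_sessions = 3, trials = 8, n_points = 10)
  truth$Sigma_g0_session <- default_covariance(truth$grid, "sqexp",
                                               scale = 0.04, lengthscale = 0.3)
  ds <- generate_functional(truth, seed = 9)$dataset
  fit <- flmm(photometry ~ delay + (1 | id/session), ds, n_sim_joint = 1000)
  expect_length(fit$bands, 2)
  expect_true(is.finite(fit$info$aic))
  expect_named(fit$random_curves, c("id", "id:session"))
  expect_equal(dim(fit$random_curves[["id:session"]]), c(15, 10, 1))
})
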