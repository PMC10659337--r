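test_that("covariance families: white-noise limit, symmetry, eigenvalues", {
  g <- time_grid(start = 0, rate = 15, n = 20)
  C <- default_covariance(g, "sqexp", scale = 2, lengthscale = 0.3)
  expect_identical(C, t(C))
  expect_equal(unname(diag(C / 2)), rep(1, 20))
  expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  # lengthscale far below the grid spacing: essentially scale * identity
  Cw <- default_covariance(g, "sqexp", scale = 2, lengthscale = (1 / 15) / 100)
  expect_lt(max(abs(Cw - 2 * diag(20))), 1e-6)
  Ca <- default_covariance(g, "ar1", scale = 1, lengthscale = 0.2)
  expect_equal(Ca[1, 2], exp(-(1 / 15) / 0.2), tolerance = 1e-12)
  expect_error(default_covariance(g, scale = -1), "scale")
})

test_that("the noiseless limit reproduces the mean model exactly", {
  truth <- tiny_truth(n_subjects = 3, trials = 4, n_points = 8)
  eps <- 1e-14
  truth$Sigma_g0 <- diag(eps, 8); truth$Sigma_g1 <- diag(eps, 8)
  truth$Sigma_eps_base <- list(diag(eps, 8))
  g <- generate_functional(truth, seed = 1)
  mu <- outer(rep(1, nrow(g$dataset$Y)), truth$beta0) +
    g$dataset$trials$delay * outer(rep(1, nrow(g$dataset$Y)), truth$beta1)
  expect_lt(max(abs(g$dataset$Y - mu)), 1e-5)
})

test_that("generated random curves have the requested covariance", {
  truth <- tiny_truth(n_subjects = 2000, n_sessions = 1, trials = 1, n_points = 6)
  g <- generate_functional(truth, seed = 42)
  emp <- cov(g$latent$gamma1)
  tru <- truth$Sigma_g1
  # entrywise within 3 MC standard errors (normal fourth-moment formula)
  se <- sqrt((outer(diag(tru), diag(tru)) + tru^2) / 2000)
  expect_true(all(abs(emp - tru) <= 3 * se + 1e-12))
})

test_that("base error-matrix assignment follows the identity-then-draw rule", {
  truth <- delay_template(n_subjects = 10, trials_per_session = 2)
  idx <- generate_functional(truth, seed = 3)$latent$base_index
  expect_equal(idx[1:7], 1:7)
  expect_true(all(idx[8:10] %in% 1:7))
  expect_false(anyDuplicated(idx[8:10]) > 0)
  truth5 <- delay_template(n_subjects = 5, trials_per_session = 2)
  idx5 <- generate_functional(truth5, seed = 4)$latent$base_index
  expect_length(unique(idx5), 5)
  expect_true(all(idx5 %in% 1:7))
})

test_that("the error covariance used is eps_scale times the base covariance", {
  truth <- delay_template(n_subjects = 7, trials_per_session = 1)
  expect_equal(truth$eps_scale, 5)
  # trace ratio of the drawing covariance to the base is exactly eps_scale
  base <- truth$Sigma_eps_base[[3]]
  expect_equal(sum(diag(truth$eps_scale * base)) / sum(diag(base)), 5)
  # empirical check on draws from a single subject/base matrix
  truth1 <- tiny_truth(n_subjects = 1, n_sessions = 1, trials = 4000, n_points = 5)
  truth1$Sigma_g0 <- diag(1e-14, 5); truth1$Sigma_g1 <- diag(1e-14, 5)
  g <- generate_functional(truth1, seed = 6)
  emp <- cov(g$latent$eps)
  tru <- truth1$eps_scale * truth1$Sigma_eps_base[[g$latent$base_index]]
  expect_lt(max(abs(emp - tru)) / max(tru), 0.12)
})

test_that("trial events: reward numbering, exponential IRIs, determinism", {
  tab <- generate_trial_events(event_config(), n_sessions = 3,
                               trials_per_session = 100, seed = 11)
  expect_equal(tab$reward_number, 1:300)
  expect_equal(tab$trial_number, rep(1:100, 3))
  expect_equal(tab$session_number, rep(1:3, each = 100))
  tab2 <- generate_trial_events(event_config(), 3, 100, seed = 11)
  expect_identical(tab, tab2)
  big <- generate_trial_events(event_config(), 1, 1e5, seed = 12)
  expect_lt(abs(mean(big$iri) - 14), 3 * 14 / sqrt(1e5))
  expect_true(all(big$lick_latency > 0))
})

test_that("generation is seed-deterministic and seed-sensitive, shapes fixed", {
  truth <- tiny_truth()
  a <- generate_functional(truth, seed = 7)
  b <- generate_functional(truth, seed = 7)
  c <- generate_functional(truth, seed = 8)
  expect_identical(a$dataset$Y, b$dataset$Y)
  expect_false(identical(a$dataset$Y, c$dataset$Y))
  expect_identical(dim(a$dataset$Y), dim(c$dataset$Y))
  expect_identical(a$dataset$trials, c$dataset$trials)
})

test_that("averaging many trials recovers the mean curves (law of large numbers)", {
  truth <- tiny_truth(n_subjects = 40, n_sessions = 2, trials = 10, n_points = 8)
  g <- generate_functional(truth, seed = 13)
  Y <- g$dataset$Y; d <- g$dataset$trials$delay
  m0 <- colMeans(Y[d == 0, ]); m1 <- colMeans(Y[d == 1, ])
  se0 <- apply(Y[d == 0, ], 2, sd) / sqrt(sum(d == 0))
  se1 <- apply(Y[d == 1, ], 2, sd) / sqrt(sum(d == 1))
  expect_true(all(abs(m0 - truth$beta0) <= 4 * se0))
  expect_true(all(abs((m1 - m0) - truth$beta1) <= 4 * sqrt(se0^2 + se1^2)))
})

test_that("effect recovery improves with more subjects", {
  ise <- sapply(c(4, 7, 14), function(n) {
    truth <- delay_template(n_subjects = n, trials_per_session = 8)
    mean(sapply(1:6, function(r) {
      ds <- generate_functional(truth, seed = 500 + 13 * n + r)$dataset
      fit <- flmm(photometry ~ delay + (delay | id), ds, n_sim_joint = 1000,
                  random_curves = FALSE)
      sum((fit$bands$delay$estimate - truth$beta1)^2) / grid_rate(truth$grid)
    }))
  })
  expect_gt(ise[1], ise[2])
  expect_gt(ise[2], ise[3])
})

test_that("the Simpson fixture reverses sign between pooled and within-session fits", {
  pooled_pos <- 0; within_neg <- 0
  for (r in 1:100) {
    sim <- simpsons_template(seed = 700 + r)
    auc <- compute_auc(sim$dataset, window_spec(attr(sim, "cue_window")))
    sw <- suppressWarnings(sessionwise_regression(auc, sim$dataset$trials))
    pooled_pos <- pooled_pos + (sw$pooled_slope > 0)
    within_neg <- within_neg + (median(sw$sessions$slope) < 0)
  }
  expect_gte(pooled_pos / 100, 0.95)
  expect_gte(within_neg / 100, 0.95)
})
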