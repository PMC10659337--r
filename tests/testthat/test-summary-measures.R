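ramp_dataset <- function() {
  g <- time_grid(start = 0, rate = 15, n = 31) # 0 ... 2 s
  t <- as.numeric(g)
  Y <- rbind(t, t, t, t)
  tr <- data.frame(subject = c("a", "a", "b", "b"), session = 1, trial = rep(1:2, 2))
  functional_dataset(Y, g, tr)
}

test_that("windowed summaries: cancellation, closed-form integral, ramp mean", {
  ds <- ramp_dataset()
  const <- functional_dataset(matrix(3, 4, 31), ds$grid, ds$trials)
  expect_equal(compute_auc(const, window_spec(c(0.5, 1.5), baseline = c(0, 0.5),
                                              mode = "mean")),
               rep(0, 4))
  expect_equal(compute_auc(ds, window_spec(c(0, 2), mode = "integral")),
               rep(2, 4), tolerance = 1e-6)
  expect_equal(compute_auc(ds, window_spec(c(0, 2), mode = "mean")),
               rep(1, 4), tolerance = 1e-6)
  expect_error(compute_auc(ds, window_spec(c(5, 6))), "no grid points")
})

test_that("summaries are linear in the signal and stable under rate refinement", {
  g1 <- time_grid(start = 0, rate = 15, n = 31)
  g2 <- time_grid(start = 0, rate = 150, n = 301)
  # one-second period: the two-second window spans whole cycles, so the
  # sample mean is rate-stable (non-commensurate periods are not)
  f <- function(t) sin(2 * pi * t)
  tr1 <- data.frame(subject = "a", session = 1, trial = 1)
  d1 <- functional_dataset(matrix(f(as.numeric(g1)), 1), g1, tr1)
  d2 <- functional_dataset(matrix(f(as.numeric(g2)), 1), g2, tr1)
  w <- window_spec(c(0, 2), mode = "mean")
  expect_equal(compute_auc(d1, w), compute_auc(d2, w), tolerance = 1e-3)
  ds <- ramp_dataset()
  a <- compute_auc(ds, w)
  ds2 <- functional_dataset(2 * ds$Y + 1, ds$grid, ds$trials)
  expect_equal(compute_auc(ds2, w), 2 * a + 1, tolerance = 1e-12)
})

make_auc_data <- function(n = 6, m = 8, sd_subj = 0, sd_eps = 0.3,
                          effect = 0.5, seed = 1) {
  set.seed(seed)
  tr <- expand.grid(trial = 1:m, cond = 0:1, subject = sprintf("s%d", 1:n),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tr <- data.frame(subject = tr$subject, session = tr$cond + 1, trial = tr$trial,
                   cond = tr$cond)
  g0 <- rnorm(n, 0, sd_subj)
  auc <- g0[match(tr$subject, sprintf("s%d", 1:n))] + effect * tr$cond +
    rnorm(nrow(tr), 0, sd_eps)
  list(auc = auc, trials = tr)
}

test_that("scalar baselines: null identity, OLS collapse, df bookkeeping", {
  # identical condition means per subject: mirror the trial values across
  # conditions so every paired difference is exactly zero
  d <- make_auc_data(effect = 0.5, sd_eps = 0.4, seed = 2)
  ord <- order(d$trials$subject, d$trials$cond, d$trials$trial)
  auc <- d$auc
  for (s in unique(d$trials$subject)) {
    i0 <- which(d$trials$subject == s & d$trials$cond == 0)
    i1 <- which(d$trials$subject == s & d$trials$cond == 1)
    auc[i1] <- auc[i0]
  }
  r0 <- scalar_baselines(auc, d$trials, "cond")
  expect_equal(r0$t_test$statistic, 0)
  expect_equal(r0$t_test$p_value, 1)
  d1 <- make_auc_data(effect = 0.5, sd_subj = 0, seed = 3)
  r1 <- scalar_baselines(d1$auc, d1$trials, "cond")
  m1 <- tapply(d1$auc, d1$trials$cond, mean)
  expect_equal(r1$lmm$estimate, unname(m1[2] - m1[1]), tolerance = 1e-6)
  d2 <- make_auc_data(n = 2, seed = 4)
  r2 <- scalar_baselines(d2$auc, d2$trials, "cond")
  expect_equal(r2$t_test$df, 1)
  expect_equal(r2$t_test$n_pairs, 2)
})

test_that("a subject observed in one condition only is excluded with a warning", {
  d <- make_auc_data(seed = 5)
  keep <- !(d$trials$subject == "s1" & d$trials$cond == 1)
  expect_warning(r <- scalar_baselines(d$auc[keep], d$trials[keep, ], "cond"),
                 "one condition only")
  expect_equal(r$t_test$n_pairs, 5)
})

test_that("session-wise regression parameterizes first-trial intercepts", {
  tr <- data.frame(subject = rep("a", 10), session = rep(1:2, each = 5),
                   trial = rep(1:5, 2))
  auc <- c(2 + 0.5 * (0:4), 4 - 0.25 * (0:4)) # exactly linear per session
  sw <- sessionwise_regression(auc, tr)
  expect_equal(sw$sessions$intercept, c(2, 4), tolerance = 1e-10)
  expect_equal(sw$sessions$slope, c(0.5, -0.25), tolerance = 1e-10)
  # constant single session: zero slope, intercept = constant
  tr1 <- tr[1:5, ]
  sw1 <- sessionwise_regression(rep(3, 5), tr1)
  expect_equal(sw1$sessions$slope, 0, tolerance = 1e-12)
  expect_equal(sw1$sessions$intercept, 3, tolerance = 1e-12)
  # singleton sessions are skipped with a warning
  tr2 <- rbind(tr, data.frame(subject = "a", session = 3, trial = 1))
  expect_warning(sw2 <- sessionwise_regression(c(auc, 9), tr2), "singleton")
  expect_equal(nrow(sw2$sessions), 2)
})
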