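test_that("a single-point fit matches an independently coded REML optimizer", {
  # uncentered so both implementations see the same design
  set.seed(4)
  n <- 5; m <- 12
  tr <- data.frame(subject = rep(sprintf("s%d", 1:n), each = m),
                   session = 1, trial = rep(1:m, n))
  tr$x <- round(runif(n * m, -1, 1), 3)
  i <- rep(1:n, each = m)
  y <- 1 + rnorm(n, 0, 0.6)[i] + tr$x * (0.5 + rnorm(n, 0, 0.3)[i]) +
    rnorm(n * m, 0, 0.4)
  ds <- functional_dataset(cbind(y, y), time_grid(start = 0, rate = 15, n = 2), tr)
  design <- build_design(flmm_formula("y ~ x + (x | subject)"), tr, center = FALSE)
  fit <- fit_single(ds, design, 1)
  ora <- oracle_lmm(y, tr$x, tr$subject)
  expect_rel_equal(unname(fit$beta), ora$beta, 1e-4)
  expect_rel_equal(unname(fit$cov_beta), unname(ora$cov_beta), 1e-4)
  # local optimality of the reported variance components under the
  # oracle's REML criterion
  base <- ora$criterion(fit$varcomps$subject, fit$sigma2)
  for (fac in c(0.9, 1.1)) {
    expect_gte(base + 1e-6,
               ora$criterion(fit$varcomps$subject * fac, fit$sigma2))
    expect_gte(base + 1e-6,
               ora$criterion(fit$varcomps$subject, fit$sigma2 * fac))
  }
})

test_that("zero between-group variability collapses to ordinary least squares", {
  set.seed(2)
  m <- 15; n <- 4
  tr <- data.frame(subject = rep(sprintf("s%d", 1:n), each = m),
                   session = 1, trial = rep(1:m, n))
  tr$x <- rep(seq(-1, 1, length.out = m), n)
  y <- 0.3 + 0.8 * tr$x + rnorm(n * m, 0, 0.3) # identical group structure
  ds <- functional_dataset(cbind(y, y), time_grid(start = 0, rate = 15, n = 2), tr)
  design <- build_design(flmm_formula("y ~ x + (1 | subject)"), tr, center = FALSE)
  fit <- fit_single(ds, design, 1)
  ols <- unname(qr.coef(qr(cbind(1, tr$x)), y))
  expect_lt(max(abs(unname(fit$beta) - ols)), 1e-6)
})

test_that("balanced one-way variance components match the ANOVA closed form", {
  set.seed(11)
  g <- rep(sprintf("g%d", 1:8), each = 12)
  y <- rnorm(8, 0, 0.7)[factor(g)] + rnorm(96, 0, 0.5)
  tr <- data.frame(subject = g, session = 1, trial = rep(1:12, 8))
  ds <- functional_dataset(cbind(y, y), time_grid(start = 0, rate = 15, n = 2), tr)
  fit <- fit_single(ds, build_design(flmm_formula("y ~ 1 + (1 | subject)"), tr), 1)
  cf <- oracle_oneway(y, g)
  expect_equal(unname(fit$varcomps$subject[1, 1]), cf$between, tolerance = 1e-4)
  expect_equal(fit$sigma2, cf$within, tolerance = 1e-4)
})

test_that("fit_all is deterministic, order-invariant and worker-invariant", {
  ds <- tiny_dataset(seed = 5)
  design <- build_design(flmm_formula("photometry ~ delay + (1 | id)"), ds$trials)
  pw1 <- fit_pointwise(ds, design, workers = 1)
  pw2 <- fit_pointwise(ds, design, workers = 2)
  expect_identical(pw1$beta_raw, pw2$beta_raw)
  # permuting trials leaves estimates unchanged
  set.seed(9); ord <- sample(nrow(ds$Y))
  ds2 <- functional_dataset(ds$Y[ord, ], ds$grid, ds$trials[ord, ])
  pw3 <- fit_pointwise(ds2, build_design(flmm_formula("photometry ~ delay + (1 | id)"),
                                         ds2$trials))
  expect_lt(max(abs(pw1$beta_raw - pw3$beta_raw)), 1e-10)
})

test_that("column-wise fits agree with fit_single; intercept-only OLS moments", {
  ds <- tiny_dataset(seed = 6)
  design <- build_design(flmm_formula("photometry ~ delay + (1 | id)"), ds$trials)
  one <- fit_single(ds, design, 1)
  all1 <- fit_pointwise(ds, design)
  expect_equal(all1$beta_raw[1, ], one$beta[colnames(design$X)], tolerance = 1e-10)

  # no-random-effects intercept-only: mean and var/L
  dn <- build_design(flmm_formula("photometry ~ 1"), ds$trials)
  pw <- fit_pointwise(ds, dn)
  expect_equal(unname(pw$beta_raw[, 1]), unname(colMeans(ds$Y)), tolerance = 1e-10)
  L <- nrow(ds$Y)
  expect_equal(unname(pw$cov_beta[1, 1, ]), unname(apply(ds$Y, 2, var) / L),
               tolerance = 1e-10)
})

test_that("missing samples are dropped per column without poisoning the fit", {
  ds <- tiny_dataset(seed = 7)
  Y <- ds$Y
  Y[3, 5] <- NA
  dsm <- functional_dataset(Y, ds$grid, ds$trials, allow_missing = TRUE)
  design <- build_design(flmm_formula("photometry ~ delay + (1 | id)"), ds$trials)
  pw_full <- fit_pointwise(ds, design)
  pw_miss <- fit_pointwise(dsm, design)
  # untouched columns agree exactly; the affected column differs but is finite
  expect_equal(pw_miss$beta_raw[-5, ], pw_full$beta_raw[-5, ], tolerance = 1e-8)
  expect_true(all(is.finite(pw_miss$beta_raw[5, ])))
  expect_equal(sum(is.na(pw_miss$columns[[5]]$resid)), 1)
})

test_that("aggregate information sums per-column ML criteria and guards comparisons", {
  ds <- tiny_dataset(seed = 8)
  dn <- build_design(flmm_formula("photometry ~ delay"), ds$trials)
  pw <- fit_pointwise(ds, dn)
  info <- model_information(pw)
  expect_equal(info$aic, sum(vapply(pw$columns, `[[`, numeric(1), "aic")))
  expect_true(is.finite(info$bic))
  # a single column: aggregate equals the scalar criterion
  expect_equal(model_information(pw)$n_columns, ncol(ds$Y))

  # adding a pure-noise covariate increases BIC in most replicates
  worse <- 0
  for (r in 1:60) {
    set.seed(100 + r)
    tr <- ds$trials
    tr$noise <- rnorm(nrow(tr))
    pw0 <- fit_pointwise(ds, build_design(flmm_formula("photometry ~ delay"), tr))
    pw1 <- fit_pointwise(ds, build_design(flmm_formula("photometry ~ delay + noise"), tr))
    cmp <- compare_models(model_information(pw1), model_information(pw0))
    worse <- worse + (cmp$delta_bic > 0)
  }
  expect_gte(worse / 60, 0.9)

  # refusal on differing column sets
  i1 <- model_information(pw)
  i2 <- i1; i2$columns <- i1$columns[-1]
  class(i2) <- class(i1)
  expect_error(compare_models(i1, i2), "different column sets")
})
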