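replicate_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

mc_se <- function(p, n) sqrt(p * (1 - p) / n)

set_n_subjects <- function(truth, n) {
  truth$n_subjects <- n
  truth
}

#' Coverage experiment for the functional confidence bands
#'
#' Repeatedly generates data from a known truth, fits the functional mixed
#' model, and records (a) whether the joint band for the condition effect
#' covers the entire true coefficient function, (b) per-time-point pointwise
#' coverage averaged over a window, and (c) whether the joint band excludes
#' zero anywhere (the rejection indicator — the Type-I rate when the true
#' effect is identically zero). All rates carry binomial Monte-Carlo
#' standard errors; the run is fully determined by `seed`.
#'
#' @param truth A [sim_truth()], e.g. [delay_template()].
#' @param replicates Number of simulation replicates (>= 100 recommended;
#'   fewer sets a small-sample warning flag).
#' @param seed Integer master seed; per-replicate seeds are derived from it.
#' @param formula Model formula fitted per replicate.
#' @param coefficient Name of the coefficient whose bands are assessed.
#' @param window Window (seconds) for pointwise-coverage averaging; default
#'   the truth's cue window, else the whole grid.
#' @param sample_sizes Optional vector of subject counts; one report row per
#'   size (default: the truth's).
#' @param level,n_sim_joint,smoother Passed to [flmm()].
#' @return Data frame of class `flmm_experiment_report`, one row per sample
#'   size: coverage rates, rejection rate, MC standard errors, replicate
#'   counts and the seed.
#' @export
run_coverage_experiment <- function(truth, replicates = 500, seed = 1,
                                    formula = photometry ~ delay + (delay | id),
                                    coefficient = "delay",
                                    window = NULL, sample_sizes = NULL,
                                    level = 0.95, n_sim_joint = 10000,
                                    smoother = smoother_spec()) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(window)) window <- attr(truth, "cue_window")
  if (is.null(window)) window <- range(as.numeric(truth$grid))
  if (is.null(sample_sizes)) sample_sizes <- truth$n_subjects
  widx <- window_index(truth$grid, window)
  rows <- list()
  for (n in sample_sizes) {
    tr <- set_n_subjects(truth, n)
    seeds <- replicate_seeds(seed + n, replicates)
    joint_cov <- pw_cov <- reject <- rep(NA, replicates)
    failed <- 0L
    for (r in seq_len(replicates)) {
      ds <- generate_functional(tr, seed = seeds[r])$dataset
      fit <- tryCatch(
        flmm(formula, ds, level = level, n_sim_joint = n_sim_joint,
             seed = seeds[r], smoother = smoother, random_curves = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) { failed <- failed + 1L; next }
      b <- fit$bands[[coefficient]]
      joint_cov[r] <- all(b$joint_bounds[, 1] <= tr$beta1 &
                            tr$beta1 <= b$joint_bounds[, 2])
      pw_cov[r] <- mean(b$pw_bounds[widx, 1] <= tr$beta1[widx] &
                          tr$beta1[widx] <= b$pw_bounds[widx, 2])
      si <- significant_intervals(b, "joint")
      reject[r] <- nrow(si) > 0
    }
    used <- sum(!is.na(joint_cov))
    jc <- mean(joint_cov, na.rm = TRUE)
    pc <- mean(pw_cov, na.rm = TRUE)
    rj <- mean(reject, na.rm = TRUE)
    rows[[as.character(n)]] <- data.frame(
      method = "flmm", n_subjects = n, replicates = replicates,
      replicates_used = used, failed = failed,
      joint_coverage = jc, joint_coverage_se = mc_se(jc, used),
      pointwise_coverage = pc, pointwise_coverage_se = mc_se(pc, used),
      rejection_rate = rj, rejection_rate_se = mc_se(rj, used),
      small_R_flag = replicates < 100, seed = seed)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("flmm_experiment_report", class(out))
  out
}

#' Power experiment: functional bands versus summary-measure tests
#'
#' Per replicate, generates data from a truth with a nonzero condition
#' effect and records rejections for three methods: the functional model
#' (joint band excludes zero somewhere in the window, and separately the
#' average fraction of window points that are pointwise-significant), a
#' paired t-test on the window mean-amplitude summary, and a scalar LMM on
#' the same summary. A window-perturbation sweep (endpoints shifted by one
#' grid step) shows the sensitivity of the summary-measure tests to the
#' window choice.
#'
#' @inheritParams run_coverage_experiment
#' @param window Analysis window (seconds); default the truth's cue window.
#' @param alpha Test size for the scalar methods (default 0.05).
#' @param perturb If `TRUE`, also run the t-test with the window endpoints
#'   shifted by plus/minus one grid step.
#' @return Data frame of class `flmm_experiment_report`: one row per method
#'   (and per perturbed window), with rejection rates and MC SEs.
#' @export
run_power_experiment <- function(truth, window = NULL, replicates = 200,
                                 seed = 1,
                                 formula = photometry ~ delay + (delay | id),
                                 coefficient = "delay", sample_sizes = NULL,
                                 level = 0.95, alpha = 0.05,
                                 n_sim_joint = 10000,
                                 smoother = smoother_spec(), perturb = TRUE) {
  stopifnot(inherits(truth, "sim_truth"))
  if (is.null(window)) window <- attr(truth, "cue_window")
  if (is.null(window)) window <- range(as.numeric(truth$grid))
  if (is.null(sample_sizes)) sample_sizes <- truth$n_subjects
  h <- 1 / grid_rate(truth$grid)
  windows <- list(main = window)
  if (perturb) windows <- c(windows, list(minus = window - h, plus = window + h))
  gridrange <- range(as.numeric(truth$grid))
  windows <- lapply(windows, function(w) pmin(pmax(w, gridrange[1]), gridrange[2]))
  rows <- list()
  for (n in sample_sizes) {
    tr <- set_n_subjects(truth, n)
    seeds <- replicate_seeds(seed + n, replicates)
    rej <- list(flmm = rep(NA, replicates), pw_frac = rep(NA, replicates),
                lmm = rep(NA, replicates))
    ttest <- lapply(windows, function(w) rep(NA, replicates))
    failed <- 0L
    for (r in seq_len(replicates)) {
      ds <- generate_functional(tr, seed = seeds[r])$dataset
      widx <- window_index(ds$grid, window)
      fit <- tryCatch(
        flmm(formula, ds, level = level, n_sim_joint = n_sim_joint,
             seed = seeds[r], smoother = smoother, random_curves = FALSE),
        error = function(e) NULL)
      if (!is.null(fit)) {
        b <- fit$bands[[coefficient]]
        sig_joint <- b$joint_bounds[, 1] > 0 | b$joint_bounds[, 2] < 0
        sig_pw <- b$pw_bounds[, 1] > 0 | b$pw_bounds[, 2] < 0
        rej$flmm[r] <- any(sig_joint[widx])
        rej$pw_frac[r] <- mean(sig_pw[widx])
      } else failed <- failed + 1L
      for (wn in names(windows)) {
        auc <- compute_auc(ds, window_spec(windows[[wn]], mode = "mean"))
        bl <- tryCatch(scalar_baselines(auc, ds$trials, "delay", level = level),
                       error = function(e) NULL)
        if (is.null(bl)) next
        ttest[[wn]][r] <- bl$t_test$p_value < alpha
        if (wn == "main") rej$lmm[r] <- bl$lmm$p_value < alpha
      }
    }
    mk <- function(method, x, win = window) {
      p <- mean(x, na.rm = TRUE); u <- sum(!is.na(x))
      data.frame(method = method, n_subjects = n, window_lo = win[1],
                 window_hi = win[2], replicates = replicates,
                 replicates_used = u, failed = failed, power = p,
                 power_se = mc_se(p, u), small_R_flag = replicates < 100,
                 seed = seed)
    }
    rows <- c(rows, list(
      mk("flmm_joint", rej$flmm), mk("flmm_pointwise_avg", rej$pw_frac),
      mk("auc_t_test", ttest$main), mk("auc_lmm", rej$lmm)))
    if (perturb)
      rows <- c(rows, list(mk("auc_t_test_window_minus", ttest$minus, windows$minus),
                           mk("auc_t_test_window_plus", ttest$plus, windows$plus)))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("flmm_experiment_report", class(out))
  out
}
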