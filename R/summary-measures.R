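#' Describe a trial summary window
#'
#' @param main Closed interval `c(a, b)` in seconds relative to the
#'   alignment event.
#' @param baseline Optional baseline interval; the baseline summary is
#'   subtracted from the main-window summary.
#' @param mode `"mean"` (average signal amplitude, the default — windows of
#'   unequal length stay comparable) or `"integral"` (trapezoidal area).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(main, baseline = NULL, mode = c("mean", "integral")) {
  mode <- match.arg(mode)
  stopifnot(length(main) == 2, main[1] < main[2])
  if (!is.null(baseline)) stopifnot(length(baseline) == 2, baseline[1] < baseline[2])
  structure(list(main = as.numeric(main), baseline = baseline, mode = mode),
            class = "window_spec")
}

window_index <- function(grid, win) {
  t <- as.numeric(grid)
  tol <- 1e-9 * max(1, diff(range(t)))
  idx <- which(t >= win[1] - tol & t <= win[2] + tol)
  if (!length(idx))
    stop(sprintf("window [%g, %g] contains no grid points", win[1], win[2]),
         call. = FALSE)
  idx
}

window_summary <- function(Y, t, idx, mode) {
  if (mode == "mean") return(unname(rowMeans(Y[, idx, drop = FALSE])))
  unname(apply(Y[, idx, drop = FALSE], 1, function(y) pracma::trapz(t[idx], y)))
}

#' Per-trial windowed summary (AUC) of a functional dataset
#'
#' Mean-amplitude or trapezoidal-integral summary over a closed time window,
#' optionally baseline-subtracted (same mode in both windows). Window
#' membership uses closed endpoints at grid resolution.
#'
#' @param dataset A [functional_dataset()].
#' @param spec A [window_spec()].
#' @return Numeric vector, one value per trial, in trial-table row order.
#' @export
compute_auc <- function(dataset, spec) {
  stopifnot(inherits(dataset, "functional_dataset"), inherits(spec, "window_spec"))
  t <- as.numeric(dataset$grid)
  out <- window_summary(dataset$Y, t, window_index(dataset$grid, spec$main),
                        spec$mode)
  if (!is.null(spec$baseline))
    out <- out - window_summary(dataset$Y, t,
                                window_index(dataset$grid, spec$baseline),
                                spec$mode)
  out
}

#' Scalar summary-measure baselines: paired t-test and scalar LMM
#'
#' The two standard comparators for a binary condition applied to a trial
#' summary: a paired t-test on subject-by-condition means, and a scalar
#' linear mixed model with a random intercept and condition slope per
#' subject (`auc ~ condition + (condition | subject)`), with a normal
#' approximation for the fixed-effect p-value.
#'
#' @param auc Per-trial summary vector (e.g. from [compute_auc()]).
#' @param trials The matching trial table.
#' @param condition Name of a binary condition column (0/1 or two-level).
#' @param level Confidence level (default 0.95).
#' @return List with `t_test` (estimate, statistic, df, p_value, conf_int,
#'   n_pairs) and `lmm` (estimate, se, statistic, p_value, conf_int).
#' @export
scalar_baselines <- function(auc, trials, condition, level = 0.95) {
  trials <- validate_trial_table(trials)
  stopifnot(length(auc) == nrow(trials))
  cond <- trials[[condition]]
  if (is.null(cond)) stop("no column '", condition, "' in the trial table", call. = FALSE)
  if (is.factor(cond) || is.character(cond)) {
    cond <- relevel_first_observed(cond)
    if (nlevels(cond) != 2) stop("condition must be binary", call. = FALSE)
    cond <- as.integer(cond) - 1L
  }
  if (!all(cond %in% c(0, 1))) stop("condition must be binary (0/1)", call. = FALSE)
  if (nlevels(trials$subject) < 2) stop("need at least 2 subjects", call. = FALSE)

  m <- tapply(auc, list(trials$subject, cond), mean)
  paired <- stats::complete.cases(m)
  if (any(!paired))
    warning(sum(!paired), " subject(s) observed in one condition only, ",
            "excluded from the paired test")
  d <- m[paired, 2] - m[paired, 1]
  n <- length(d)
  if (stats::sd(d) == 0) {
    # identical condition means per subject: the null identity t = 0, p = 1
    tt <- list(estimate = mean(d), statistic = if (mean(d) == 0) 0 else Inf,
               parameter = n - 1, p.value = as.numeric(mean(d) == 0),
               conf.int = c(mean(d), mean(d)))
  } else {
    tt <- stats::t.test(m[paired, 2], m[paired, 1], paired = TRUE,
                        conf.level = level)
  }
  df <- data.frame(auc = auc, cond = cond, subject = trials$subject)
  fit <- suppressMessages(lme4::lmer(auc ~ cond + (cond | subject), data = df,
                                     control = lmer_ctrl()))
  est <- lme4::fixef(fit)[["cond"]]
  se <- sqrt(as.matrix(stats::vcov(fit))["cond", "cond"])
  z <- est / se
  zc <- stats::qnorm(1 - (1 - level) / 2)
  list(t_test = list(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p_value = tt$p.value,
                     conf_int = as.numeric(tt$conf.int), n_pairs = n),
       lmm = list(estimate = est, se = se, statistic = z,
                  p_value = 2 * stats::pnorm(-abs(z)),
                  conf_int = c(est - zc * se, est + zc * se)))
}

#' Session-wise and pooled regressions of a trial summary
#'
#' Per (subject, session), an OLS regression of the summary on
#' `trial_number - 1`, so the intercept is the expected value on the first
#' trial of that session; plus a pooled OLS of the summary on Reward Number
#' (cumulative trials across sessions). The pair exposes Simpson's-paradox
#' reversals between within-session and pooled trends.
#'
#' @param auc Per-trial summary vector.
#' @param trials The matching trial table; `reward_number` is derived from
#'   (session, trial) if absent.
#' @return List with `sessions` (data frame: subject, session, intercept,
#'   slope, n_trials), `pooled_slope`, `pooled_intercept`.
#' @export
sessionwise_regression <- function(auc, trials) {
  trials <- validate_trial_table(trials)
  stopifnot(length(auc) == nrow(trials))
  tn <- if (!is.null(trials$trial_number)) trials$trial_number else trials$trial
  rn <- if (!is.null(trials$reward_number)) trials$reward_number
  else (trials$session - 1L) * max(trials$trial) + trials$trial
  key <- interaction(trials$subject, trials$session, drop = TRUE)
  singleton <- names(which(table(key) < 2))
  if (length(singleton))
    warning(length(singleton), " singleton session(s) skipped")
  rows <- list()
  for (k in setdiff(levels(key), singleton)) {
    w <- which(key == k)
    fit <- stats::lm.fit(cbind(1, tn[w] - 1), auc[w])
    rows[[k]] <- data.frame(subject = as.character(trials$subject[w[1]]),
                            session = trials$session[w[1]],
                            intercept = fit$coefficients[1],
                            slope = fit$coefficients[2], n_trials = length(w))
  }
  sessions <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  pooled <- stats::lm.fit(cbind(1, rn), auc)$coefficients
  list(sessions = sessions[order(sessions$subject, sessions$session), ],
       pooled_intercept = unname(pooled[1]), pooled_slope = unname(pooled[2]))
}
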