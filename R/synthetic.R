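#' Stationary covariance families on a time grid
#'
#' Parametric stand-ins for covariance matrices estimated from real data:
#' a squared-exponential kernel `scale * exp(-(ti-tj)^2 / (2 l^2))` or an
#' AR(1)-type kernel `scale * exp(-|ti-tj| / l)`. Both are positive
#' semi-definite by construction.
#'
#' @param grid A [time_grid()] or numeric vector of times (seconds).
#' @param family `"sqexp"` or `"ar1"`.
#' @param scale Marginal variance (> 0).
#' @param lengthscale Correlation length in seconds (> 0).
#' @param nugget Fraction of `scale` added to the diagonal (default 0).
#' @return An S x S covariance matrix.
#' @export
default_covariance <- function(grid, family = c("sqexp", "ar1"), scale = 1,
                               lengthscale = 0.5, nugget = 0) {
  family <- match.arg(family)
  stopifnot(scale > 0, lengthscale > 0, nugget >= 0)
  t <- as.numeric(grid)
  d <- abs(outer(t, t, "-"))
  C <- switch(family,
              sqexp = scale * exp(-d^2 / (2 * lengthscale^2)),
              ar1 = scale * exp(-d / lengthscale))
  C + diag(nugget * scale, length(t))
}

gauss_bump <- function(t, amplitude, center, width) {
  amplitude * exp(-(t - center)^2 / (2 * width^2))
}

#' Event-structure configuration for simulated sessions
#'
#' @param iri_mean Mean of the exponential inter-reward-interval law,
#'   seconds (default 14).
#' @param delay_short,delay_long Cue-to-reward delays in seconds for the
#'   delay-change experiment template. The source experiment is described
#'   with both a 3 s / 9 s and a 2 s / 8 s pairing in different places; the
#'   default here is 3 / 9 and both are accepted.
#' @param lick_latency Parameters of the lognormal first-lick-latency law
#'   (list with `meanlog`, `sdlog`).
#' @return An object of class `event_config`.
#' @export
event_config <- function(iri_mean = 14, delay_short = 3, delay_long = 9,
                         lick_latency = list(meanlog = -1, sdlog = 0.5)) {
  stopifnot(iri_mean > 0, delay_short >= 0, delay_long >= 0)
  structure(list(iri_mean = iri_mean, delay_short = delay_short,
                 delay_long = delay_long, lick_latency = lick_latency),
            class = "event_config")
}

#' Generative truth for a nested longitudinal functional experiment
#'
#' Describes the simulation model
#' `Y_ijl(s) = beta0(s) + gamma0_i(s) + delay_il * (beta1(s) + gamma1_i(s))
#'  [+ gamma0_il(s)] + eps_ijl(s)`
#' with subject-level random curves drawn once per subject from
#' `N(0, Sigma_g0)` / `N(0, Sigma_g1)`, an optional session-level random
#' intercept curve (nested), and error curves drawn independently per trial
#' from `N(0, eps_scale * Sigma_eps_base[[m(i)]])`, where the base-matrix
#' index `m(i)` follows the assignment rule: for `n <= M` subjects the
#' indices are drawn uniformly without replacement from `{1..M}`; for
#' `n > M` the first `M` subjects take indices `1..M` and the remainder are
#' drawn without replacement.
#'
#' @param grid A [time_grid()].
#' @param beta0,beta1 True coefficient functions evaluated on the grid.
#' @param Sigma_g0,Sigma_g1 S x S random-effect covariances (PSD).
#' @param Sigma_eps_base List of S x S base error covariances (the M base
#'   matrices; default M = 7).
#' @param eps_scale Positive scalar multiplying the base error covariance
#'   (default 5).
#' @param Sigma_g0_session Optional S x S covariance of a session-level
#'   random intercept curve, nested within subject.
#' @param n_subjects,n_sessions,trials_per_session Design sizes (defaults
#'   2 sessions of 100 trials).
#' @param condition `"session"` (default): the condition indicator `delay`
#'   is 0 on the first half of sessions and 1 on the rest (the delay-change
#'   design); `"trial"`: iid Bernoulli(1/2) per trial.
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(grid, beta0, beta1, Sigma_g0, Sigma_g1,
                      Sigma_eps_base, eps_scale = 5,
                      Sigma_g0_session = NULL,
                      n_subjects = 7, n_sessions = 2,
                      trials_per_session = 100,
                      condition = c("session", "trial")) {
  condition <- match.arg(condition)
  S <- length(grid)
  stopifnot(length(beta0) == S, length(beta1) == S,
            eps_scale > 0, trials_per_session >= 1, n_sessions >= 1,
            n_subjects >= 1)
  chk_psd <- function(C, nm) {
    if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8)))
      stop(nm, " is not symmetric", call. = FALSE)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      stop(nm, " is not positive semi-definite", call. = FALSE)
  }
  chk_psd(Sigma_g0, "Sigma_g0"); chk_psd(Sigma_g1, "Sigma_g1")
  if (!is.list(Sigma_eps_base)) Sigma_eps_base <- list(Sigma_eps_base)
  for (i in seq_along(Sigma_eps_base))
    chk_psd(Sigma_eps_base[[i]], sprintf("Sigma_eps_base[[%d]]", i))
  if (!is.null(Sigma_g0_session)) chk_psd(Sigma_g0_session, "Sigma_g0_session")
  structure(list(grid = grid, beta0 = beta0, beta1 = beta1,
                 Sigma_g0 = Sigma_g0, Sigma_g1 = Sigma_g1,
                 Sigma_g0_session = Sigma_g0_session,
                 Sigma_eps_base = Sigma_eps_base, eps_scale = eps_scale,
                 n_subjects = n_subjects, n_sessions = n_sessions,
                 trials_per_session = trials_per_session,
                 condition = condition),
            class = "sim_truth")
}

# base-matrix assignment: uniform without replacement for n <= M; identity
# for the first M then without-replacement draws for the rest
assign_base_indices <- function(n, M) {
  if (n <= M) return(sample.int(M, n, replace = FALSE))
  idx <- seq_len(M)
  rest <- n - M
  while (rest > 0) {
    take <- min(rest, M)
    idx <- c(idx, sample.int(M, take, replace = FALSE))
    rest <- rest - take
  }
  idx
}

rmvn_chol <- function(n, R) {
  # R: upper-triangular Cholesky factor (t(R) %*% R = Sigma)
  matrix(stats::rnorm(n * ncol(R)), n) %*% R
}

safe_chol <- function(C) {
  S <- nrow(C)
  if (max(abs(C)) == 0) return(matrix(0, S, S)) # exact zero-noise limit
  jit <- 0
  for (i in 1:7) {
    R <- tryCatch(chol(C + diag(jit, S)), error = function(e) NULL)
    if (!is.null(R)) return(R)
    jit <- max(jit * 100, 1e-12 * max(diag(C)))
  }
  stop("covariance is too far from positive definite", call. = FALSE)
}

#' Generate a functional dataset from a generative truth
#'
#' @param truth A [sim_truth()].
#' @param seed Integer seed; all draws are deterministic given it.
#' @return List with `dataset` (a [functional_dataset()] whose trial table
#'   carries the `delay` condition indicator) and `latent` (the per-subject
#'   random curves `gamma0`, `gamma1`, session curves if any, the base-matrix
#'   indices `base_index`, and the error draws), for oracle tests.
#' @export
generate_functional <- function(truth, seed) {
  stopifnot(inherits(truth, "sim_truth"))
  S <- length(truth$grid)
  n <- truth$n_subjects; J <- truth$n_sessions; Tn <- truth$trials_per_session
  L <- n * J * Tn
  M <- length(truth$Sigma_eps_base)
  R0 <- safe_chol(truth$Sigma_g0)
  R1 <- safe_chol(truth$Sigma_g1)
  Rs <- if (!is.null(truth$Sigma_g0_session)) safe_chol(truth$Sigma_g0_session)
  Re <- lapply(truth$Sigma_eps_base,
               function(C) safe_chol(truth$eps_scale * C))
  with_seed(seed, {
    base_index <- assign_base_indices(n, M)
    g0 <- rmvn_chol(n, R0)
    g1 <- rmvn_chol(n, R1)
    gs <- if (!is.null(Rs)) rmvn_chol(n * J, Rs)
    trials <- expand.grid(trial = seq_len(Tn), session = seq_len(J),
                          subject = sprintf("s%02d", seq_len(n)),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    trials <- trials[, c("subject", "session", "trial")]
    delay <- if (truth$condition == "session")
      as.integer(trials$session > J / 2)
    else stats::rbinom(L, 1, 0.5)
    trials$delay <- delay
    i_of <- match(trials$subject, sprintf("s%02d", seq_len(n)))
    sess_of <- (i_of - 1) * J + trials$session
    eps <- matrix(NA_real_, L, S)
    for (i in seq_len(n)) {
      rows <- which(i_of == i)
      eps[rows, ] <- rmvn_chol(length(rows), Re[[base_index[i]]])
    }
    Y <- matrix(rep(truth$beta0, each = L), L, S) +
      g0[i_of, , drop = FALSE] +
      delay * (matrix(rep(truth$beta1, each = L), L, S) +
                 g1[i_of, , drop = FALSE]) +
      eps
    if (!is.null(Rs)) Y <- Y + gs[sess_of, , drop = FALSE]
    ds <- functional_dataset(Y, truth$grid, trials)
    list(dataset = ds,
         latent = list(gamma0 = g0, gamma1 = g1,
                       gamma0_session = if (!is.null(Rs)) gs,
                       base_index = base_index, eps = eps))
  })
}

#' Generate trial event covariates (IRI, trial/session/reward numbers)
#'
#' Inter-reward intervals are iid exponential with mean `iri_mean`; Reward
#' Number is the cumulative trial count pooled across sessions within
#' subject; Trial Number resets each session; first-lick latency follows the
#' configured lognormal law.
#'
#' @param config An [event_config()].
#' @param n_sessions,trials_per_session Design sizes.
#' @param seed Integer seed.
#' @param n_subjects Number of subjects (default 1).
#' @return A trial table (data frame) with columns `subject`, `session`,
#'   `trial`, `iri`, `trial_number`, `session_number`, `reward_number`,
#'   `lick_latency`.
#' @export
generate_trial_events <- function(config = event_config(), n_sessions,
                                  trials_per_session, seed, n_subjects = 1) {
  stopifnot(inherits(config, "event_config"))
  with_seed(seed, {
    tab <- expand.grid(trial = seq_len(trials_per_session),
                       session = seq_len(n_sessions),
                       subject = sprintf("s%02d", seq_len(n_subjects)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tab <- tab[, c("subject", "session", "trial")]
    nL <- nrow(tab)
    tab$iri <- stats::rexp(nL, rate = 1 / config$iri_mean)
    tab$trial_number <- tab$trial
    tab$session_number <- tab$session
    tab$reward_number <- (tab$session - 1L) * trials_per_session + tab$trial
    tab$lick_latency <- stats::rlnorm(nL, config$lick_latency$meanlog,
                                      config$lick_latency$sdlog)
    tab
  })
}

# M base error covariances with animal-to-animal heterogeneity in both
# magnitude and correlation length; multiplied by eps_scale at draw time.
# Magnitudes are set so that single-trial noise (after the x5 scale) is
# comparable to the mean transient, as in real photometry trials.
default_eps_bases <- function(grid, M = 7) {
  lapply(seq_len(M), function(m) {
    v <- 0.15 + 0.03 * (m - 1)
    l <- 0.10 + 0.05 * (m - 1)
    default_covariance(grid, "sqexp", scale = 0.95 * v, lengthscale = l) +
      diag(0.05 * v, length(grid))
  })
}

#' Generative truth for the delay-change experiment template
#'
#' The packaged synthetic truth mimicking a delay-length change experiment:
#' a condition indicator `delay` that switches between sessions, a
#' bump-shaped functional intercept (the cue-elicited transient), and a
#' biphasic condition effect (a positive lobe followed by a smaller negative
#' lobe), with subject-level random intercept and slope curves and
#' subject-specific error covariances (`eps_scale` times one of M = 7 base
#' matrices). The cue-period window used by summary-measure comparisons is
#' attached as attribute `"cue_window"`.
#'
#' @param n_subjects,n_sessions,trials_per_session Design sizes (defaults
#'   7, 2, 100).
#' @param effect_size Amplitude of the positive lobe of the condition effect
#'   (default 0.5; 0 gives a null truth).
#' @param biphasic If `TRUE` (default) the condition effect has a negative
#'   second lobe of 25% the main amplitude.
#' @param n_points,rate,time_start Grid layout (default 45 points at 15 Hz
#'   starting 1 s before the alignment event).
#' @return A [sim_truth()].
#' @export
delay_template <- function(n_subjects = 7, n_sessions = 2,
                           trials_per_session = 100, effect_size = 0.75,
                           biphasic = TRUE, n_points = 45, rate = 15,
                           time_start = -1) {
  grid <- time_grid(start = time_start, rate = rate, n = n_points)
  t <- as.numeric(grid)
  beta0 <- gauss_bump(t, 2, 0.25, 0.35)
  beta1 <- gauss_bump(t, effect_size, 0.35, 0.18)
  if (biphasic) beta1 <- beta1 - gauss_bump(t, 0.25 * effect_size, 1.3, 0.25)
  truth <- sim_truth(
    grid, beta0, beta1,
    Sigma_g0 = default_covariance(grid, "sqexp", scale = 0.25, lengthscale = 0.4),
    Sigma_g1 = default_covariance(grid, "sqexp", scale = 0.0225, lengthscale = 0.4),
    Sigma_eps_base = default_eps_bases(grid, 7),
    eps_scale = 5,
    n_subjects = n_subjects, n_sessions = n_sessions,
    trials_per_session = trials_per_session, condition = "session")
  attr(truth, "cue_window") <- c(0, min(1.9, max(t)))
  truth
}

#' Simpson's-paradox fixture: opposing between- and within-session trends
#'
#' Generates data in which the expected signal amplitude increases across
#' sessions (positive `between_slope` per session) while decreasing across
#' trials within a session (negative `within_slope` per trial), both acting
#' on a bump-shaped response curve. Pooled regression of a window summary on
#' Reward Number then recovers a positive slope, while a functional model
#' with separate Session Number and Trial Number covariates recovers the
#' (+, -) sign pair.
#'
#' @param n_subjects,n_sessions,trials_per_session Design sizes (defaults
#'   7, 4, 20).
#' @param between_slope Change in bump amplitude per session (> 0).
#' @param within_slope Change in bump amplitude per trial (< 0).
#' @param seed Integer seed.
#' @param n_points,rate,time_start Grid layout.
#' @return List with `dataset` (trial table columns include `session_number`,
#'   `trial_number`, `reward_number`), `truth` (the true coefficient
#'   functions `beta_session`, `beta_trial` and shape), and the cue window
#'   as attribute `"cue_window"`.
#' @export
simpsons_template <- function(n_subjects = 7, n_sessions = 4,
                              trials_per_session = 20, between_slope = 1.5,
                              within_slope = -0.04, seed = 1, n_points = 45,
                              rate = 15, time_start = -1) {
  stopifnot(between_slope >= 0, within_slope <= 0)
  if (between_slope > 0 && within_slope < 0 &&
      between_slope <= abs(within_slope) * (trials_per_session - 1))
    warning("between-session gain does not dominate the within-session drift; ",
            "the pooled slope may not be positive")
  grid <- time_grid(start = time_start, rate = rate, n = n_points)
  t <- as.numeric(grid)
  shape <- gauss_bump(t, 1, 0.25, 0.35)
  Sg0 <- default_covariance(grid, "sqexp", scale = 0.25, lengthscale = 0.4)
  bases <- default_eps_bases(grid, 7)
  n <- n_subjects; J <- n_sessions; Tn <- trials_per_session
  R0 <- safe_chol(Sg0)
  Re <- lapply(bases, function(C) safe_chol(5 * C))
  with_seed(seed, {
    base_index <- assign_base_indices(n, length(bases))
    g0 <- rmvn_chol(n, R0)
    tab <- expand.grid(trial = seq_len(Tn), session = seq_len(J),
                       subject = sprintf("s%02d", seq_len(n)),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tab <- tab[, c("subject", "session", "trial")]
    tab$session_number <- tab$session
    tab$trial_number <- tab$trial
    tab$reward_number <- (tab$session - 1L) * Tn + tab$trial
    i_of <- match(tab$subject, sprintf("s%02d", seq_len(n)))
    L <- nrow(tab)
    amp <- between_slope * (tab$session_number - 1) +
      within_slope * (tab$trial_number - 1)
    eps <- matrix(NA_real_, L, length(t))
    for (i in seq_len(n)) {
      rows <- which(i_of == i)
      eps[rows, ] <- rmvn_chol(length(rows), Re[[base_index[i]]])
    }
    Y <- matrix(rep(shape, each = L), L) +
      outer(amp, shape) + g0[i_of, , drop = FALSE] + eps
    ds <- functional_dataset(Y, grid, tab)
    out <- list(dataset = ds,
                truth = list(shape = shape,
                             beta_session = between_slope * shape,
                             beta_trial = within_slope * shape,
                             gamma0 = g0, base_index = base_index))
    attr(out, "cue_window") <- c(0, min(1.9, max(t)))
    out
  })
}
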