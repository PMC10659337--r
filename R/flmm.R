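#' Fit a functional linear mixed model
#'
#' The full pipeline for trial-structured functional outcomes: build the
#' design from the mixed-model formula, fit an independent Gaussian LMM at
#' every time-point, smooth the raw coefficient functions with penalized
#' B-splines, estimate the cross-time-point covariance of the smoothed
#' estimators by method of moments, and construct pointwise and joint
#' (simultaneous) confidence bands per coefficient.
#'
#' @param formula Model formula in the supported lme4-style sublanguage,
#'   e.g. `photometry ~ delay + (delay | id)` or
#'   `photometry ~ IRI + (lick_latency | id/session)`. The response name is
#'   symbolic — the outcome is always the signal matrix of `data`.
#' @param data A [functional_dataset()].
#' @param method `"REML"` (default) or `"ML"` for the per-column fits.
#' @param smoother A [smoother_spec()].
#' @param level Nominal level of both bands (default 0.95).
#' @param n_sim_joint Monte-Carlo draws for the joint multiplier.
#' @param seed Seed for the joint-multiplier simulation (recorded in the
#'   output; default 12345).
#' @param center Covariate centering policy, see [build_design()].
#' @param workers Worker processes for the pointwise fits.
#' @param random_curves If `TRUE` (default), also smooth the per-level BLUP
#'   functions for reporting.
#' @param small_sample If `TRUE` (default), widen the bands by the
#'   Satterthwaite t/z ratio at the effective degrees of freedom of the
#'   variance estimate (matters when few grouping levels dominate the
#'   estimator variance; leaves the band correlation unchanged).
#' @return An object of class `flmm`: list with `bands` (one
#'   [coefficient_band] per fixed-effect coefficient), `random_curves`
#'   (per random group: array levels x time x terms of smoothed BLUP
#'   functions), `smoothed`, `pointwise`, `design`, `grid` and `info`
#'   (formula, AIC/BIC, multipliers, lambda, seed, convergence log).
#' @examples
#' \donttest{
#' truth <- delay_template(n_subjects = 4, trials_per_session = 10, n_points = 20)
#' ds <- generate_functional(truth, seed = 1)$dataset
#' fit <- flmm(photometry ~ delay + (delay | id), ds, n_sim_joint = 1000)
#' print(fit)
#' }
#' @export
flmm <- function(formula, data, method = c("REML", "ML"),
                 smoother = smoother_spec(), level = 0.95,
                 n_sim_joint = 10000, seed = 12345, center = "default",
                 workers = 1L, random_curves = TRUE, small_sample = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(data, "functional_dataset"))
  formula <- if (inherits(formula, "flmm_formula")) formula else flmm_formula(formula)
  design <- build_design(formula, data$trials, center = center)
  pw <- fit_pointwise(data, design, method = method, workers = workers)
  sm <- smooth_coefficients(pw$beta_raw, data$grid, smoother)
  covs <- estimate_beta_covariance(pw, sm$smoothers, design)
  p <- ncol(pw$beta_raw)
  bands <- vector("list", p)
  for (k in seq_len(p)) {
    Ck <- covs$cov[[k]]
    # the joint band is what variance-estimation noise hurts (it shifts the
    # distribution of the maximum); studentize its multiplier at the
    # jackknife effective df, keeping the pointwise bands Gaussian
    df_k <- if (small_sample) covs$df_common[k] else Inf
    qk <- joint_multiplier(Ck, level = level, n_sim = n_sim_joint,
                           seed = seed + k, df = df_k)
    bands[[k]] <- build_bands(sm$smoothed[, k], Ck, level, qk,
                              name = colnames(pw$beta_raw)[k],
                              time = as.numeric(data$grid))
    bands[[k]]$df <- covs$df[[k]]
  }
  names(bands) <- colnames(pw$beta_raw)

  rc <- NULL
  if (random_curves && length(design$groups)) {
    rc <- list()
    S <- length(data$grid)
    for (nm in names(design$groups)) {
      g <- design$groups[[nm]]
      nlev <- length(g$levels)
      arr <- array(NA_real_, c(nlev, S, g$q),
                   dimnames = list(g$levels, NULL, g$terms))
      for (s in which(pw$converged))
        arr[, s, ] <- pw$columns[[s]]$blups[[nm]]
      for (i in seq_len(nlev)) for (a in seq_len(g$q)) {
        y <- arr[i, , a]
        okc <- is.finite(y)
        if (sum(okc) < 4) next
        arr[i, okc, a] <- smooth_coefficients(
          matrix(y[okc]), data$grid[okc], smoother)$smoothed[, 1]
      }
      rc[[nm]] <- arr
    }
  }

  mi <- model_information(pw)
  info <- list(formula = format(formula), method = method,
               likelihood = "ML criterion evaluated at the REML/ML fitted components",
               aic = mi$aic, bic = mi$bic, n_columns = mi$n_columns,
               lambda = sm$lambda, K = sm$K,
               smoother = sprintf("cubic P-spline, K=%d, diff order %d, GCV",
                                  sm$K, smoother$penalty_order),
               multipliers = vapply(bands, function(b) b$q_joint, numeric(1)),
               n_sim_joint = n_sim_joint, seed = seed,
               n_nonconverged = sum(!pw$converged),
               centers = design$centers)
  structure(list(bands = bands, random_curves = rc, smoothed = sm$smoothed,
                 pointwise = pw, design = design, grid = data$grid,
                 info = info, model_information = mi),
            class = "flmm")
}

#' @export
print.flmm <- function(x, ...) {
  cat("Functional linear mixed model\n")
  cat("  ", x$info$formula, "\n", sep = "")
  cat(sprintf("  %d time-points (%.3g to %.3g s), %d trials\n",
              length(x$grid), min(x$grid), max(x$grid), nrow(x$design$X)))
  cat(sprintf("  AIC %.1f  BIC %.1f  (summed over %d converged columns)\n",
              x$info$aic, x$info$bic, x$info$n_columns))
  for (b in x$bands) {
    si <- significant_intervals(b, "joint")
    lab <- if (nrow(si))
      paste(sprintf("[%.2f, %.2f]%s", si$start, si$end,
                    ifelse(si$sign == "positive", "+", "-")), collapse = " ")
    else "none"
    cat(sprintf("  %-14s q_joint %.3f  joint-significant: %s\n",
                b$name, b$q_joint, lab))
  }
  invisible(x)
}

#' Coefficient-function plot with pointwise and joint bands
#'
#' One panel in the style of the framework's output: smoothed coefficient
#' estimate, dark pointwise band, light joint band, zero reference, the
#' alignment event at t = 0, and bars marking jointly significant periods.
#'
#' @param band A [coefficient_band].
#' @param out Optional file path; the extension selects the device
#'   (`.png`, `.pdf`, `.svg`).
#' @param width,height Device size in inches.
#' @return The ggplot object, invisibly if written to file.
#' @export
plot_coefficient <- function(band, out = NULL, width = 5, height = 3.5) {
  df <- data.frame(time = band$time, estimate = band$estimate,
                   pw_lo = band$pw_bounds[, 1], pw_hi = band$pw_bounds[, 2],
                   jt_lo = band$joint_bounds[, 1], jt_hi = band$joint_bounds[, 2])
  si <- significant_intervals(band, "joint")
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$jt_lo, ymax = .data$jt_hi),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pw_lo, ymax = .data$pw_hi),
                         fill = "grey60") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate), color = "#b8860b",
                       linewidth = 0.8) +
    ggplot2::labs(x = "time from alignment event (s)",
                  y = bquote(hat(beta)(s)), title = band$name) +
    ggplot2::theme_minimal(base_size = 10)
  if (nrow(si)) {
    ymin <- min(df$jt_lo); yr <- diff(range(df$jt_hi, df$jt_lo))
    gg <- gg + ggplot2::annotate("segment", x = si$start, xend = si$end,
                                 y = ymin - 0.03 * yr, yend = ymin - 0.03 * yr,
                                 linewidth = 2, color = "#8b0000")
  }
  if (!is.null(out)) {
    ggplot2::ggsave(out, gg, width = width, height = height)
    return(invisible(gg))
  }
  gg
}

#' @param x An `flmm` fit.
#' @param coef Coefficient name(s) to plot; default all.
#' @param ... Unused.
#' @rdname plot_coefficient
#' @export
plot.flmm <- function(x, coef = NULL, ...) {
  bands <- if (is.null(coef)) x$bands else x$bands[coef]
  plots <- lapply(bands, plot_coefficient)
  if (length(plots) == 1L) return(plots[[1]])
  plots
}
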