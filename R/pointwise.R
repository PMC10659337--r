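lmer_ctrl <- function() {
  lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4),
    check.nobs.vs.nRE = "ignore")
}

# GLS quantities at fitted variance components, via the Woodbury identity:
# V = sigma2 I + Z Gf Z'  with Gf = bdiag over groups of I_{n_k} (x) G_k.
# Returns the weight matrix M = (X'V^-1 X)^-1 X'V^-1 (so beta = M y), the
# model-based covariance (X'V^-1 X)^-1, and a function applying V^-1.
gls_weights <- function(X, Zlist, Glist, sigma2, nlev) {
  p <- ncol(X)
  if (!length(Zlist)) {
    XtXi <- solve(crossprod(X))
    M <- XtXi %*% t(X)
    return(list(M = sigma2 * 0 + M, cov_beta = sigma2 * XtXi,
                vinv = function(B) B / sigma2,
                logdetV = nrow(X) * log(sigma2)))
  }
  Zg <- as.matrix(do.call(cbind, Zlist))
  q <- ncol(Zg)
  Gf <- matrix(0, q, q)
  off <- 0
  for (k in seq_along(Zlist)) {
    qk <- ncol(Glist[[k]])
    for (j in seq_len(nlev[k])) {
      idx <- off + (j - 1) * qk + seq_len(qk)
      Gf[idx, idx] <- Glist[[k]]
    }
    off <- off + nlev[k] * qk
  }
  core <- sigma2 * diag(q) + crossprod(Zg) %*% Gf
  core_lu <- qr(core)
  vinv <- function(B) {
    ZtB <- crossprod(Zg, B)
    (B - Zg %*% (Gf %*% qr.coef(core_lu, ZtB))) / sigma2
  }
  Xv <- vinv(X)
  cov_beta <- solve(crossprod(X, Xv))
  cov_beta <- (cov_beta + t(cov_beta)) / 2
  M <- cov_beta %*% t(Xv)
  ld <- determinant(core, logarithm = TRUE)
  logdetV <- nrow(X) * log(sigma2) + as.numeric(ld$modulus) - q * log(sigma2)
  list(M = M, cov_beta = cov_beta, vinv = vinv, logdetV = logdetV)
}

ml_loglik <- function(y, X, beta, gls) {
  r <- y - as.vector(X %*% beta)
  quad <- sum(r * as.vector(as.matrix(gls$vinv(matrix(r)))))
  -0.5 * (length(y) * log(2 * pi) + gls$logdetV + quad)
}

extract_fit <- function(fit, design, ok, y) {
  gvars <- vapply(design$groups, function(g) g$var, character(1))
  beta <- lme4::fixef(fit)
  vc <- lme4::VarCorr(fit)
  sigma2 <- stats::sigma(fit)^2
  Glist <- list(); blups <- list()
  re <- lme4::ranef(fit, condVar = FALSE)
  for (nm in names(design$groups)) {
    g <- design$groups[[nm]]
    Gm <- matrix(as.numeric(vc[[g$var]]), g$q, g$q)
    dimnames(Gm) <- list(g$terms, g$terms)
    Glist[[nm]] <- Gm
    B <- as.matrix(re[[g$var]])
    B <- B[match(g$levels, rownames(B)), , drop = FALSE]
    blups[[nm]] <- B
  }
  Zl <- lapply(names(design$groups), function(nm) design$Z[[nm]][ok, , drop = FALSE])
  nlev <- vapply(design$groups, function(g) length(g$levels), integer(1))
  gls <- gls_weights(design$X[ok, , drop = FALSE], Zl, Glist, sigma2, nlev)
  ll <- ml_loglik(y[ok], design$X[ok, , drop = FALSE], beta, gls)
  k <- length(beta) + sum(vapply(design$groups, function(g) g$q * (g$q + 1) / 2,
                                 numeric(1))) + 1
  rc <- rep(NA_real_, length(y))
  rc[ok] <- stats::residuals(fit)
  mr <- rep(NA_real_, length(y))
  mr[ok] <- y[ok] - as.vector(design$X[ok, , drop = FALSE] %*%
                                beta[colnames(design$X)])
  list(beta = beta, cov_beta = as.matrix(gls$cov_beta), sigma2 = sigma2,
       varcomps = Glist, blups = blups, resid = rc, mresid = mr,
       M = as.matrix(gls$M), ok = ok,
       loglik = ll, aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(sum(ok)),
       converged = TRUE)
}

extract_lm <- function(y, X, ok) {
  Xo <- X[ok, , drop = FALSE]; yo <- y[ok]
  qrX <- qr(Xo)
  beta <- qr.coef(qrX, yo)
  r <- yo - as.vector(Xo %*% beta)
  n <- length(yo); p <- ncol(Xo)
  sigma2 <- sum(r^2) / (n - p)
  XtXi <- chol2inv(qr.R(qrX))
  cov_beta <- sigma2 * XtXi
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  M <- XtXi %*% t(Xo)
  sig2_ml <- sum(r^2) / n
  ll <- -0.5 * n * (log(2 * pi * sig2_ml) + 1)
  k <- p + 1
  rc <- rep(NA_real_, length(y)); rc[ok] <- r
  list(beta = stats::setNames(beta, colnames(X)), cov_beta = cov_beta,
       sigma2 = sigma2, varcomps = list(), blups = list(), resid = rc,
       mresid = rc,
       M = M, ok = ok, loglik = ll, aic = -2 * ll + 2 * k,
       bic = -2 * ll + k * log(n), converged = TRUE)
}

fit_one_column <- function(y, design, method, template = NULL) {
  ok <- is.finite(y)
  p <- ncol(design$X)
  qtot <- sum(vapply(design$groups, function(g) g$q * length(g$levels), numeric(1)))
  if (sum(ok) < p + max(1, qtot) && sum(ok) < p + 1)
    stop("too few complete observations at this time-point", call. = FALSE)
  if (!length(design$Z))
    return(extract_lm(y, design$X, ok))
  df <- design$frame
  use_refit <- !is.null(template) && all(ok)
  fml <- stats::as.formula(design$lmer_formula)
  fit <- NULL
  try_fit <- function(expr) tryCatch(suppressMessages(expr),
                                     error = function(e) NULL)
  if (use_refit) {
    fit <- try_fit(lme4::refit(template, y))
  } else {
    df$.y <- y
    fit <- try_fit(lme4::lmer(fml, data = df[ok, , drop = FALSE],
                              REML = (method == "REML"), control = lmer_ctrl()))
  }
  conv_ok <- function(f) !is.null(f) && isTRUE(f@optinfo$conv$opt == 0)
  if (!conv_ok(fit)) {
    # deterministic restarts from rescaled variance components
    base <- if (!is.null(template)) lme4::getME(template, "theta") else NULL
    for (fac in c(0.1, 10)) {
      df$.y <- y
      f2 <- try_fit(lme4::lmer(fml, data = df[ok, , drop = FALSE],
                               REML = (method == "REML"), control = lmer_ctrl(),
                               start = if (!is.null(base)) base * fac else NULL))
      if (conv_ok(f2)) { fit <- f2; break }
    }
  }
  if (!conv_ok(fit)) {
    if (is.null(fit)) return(list(converged = FALSE))
    out <- extract_fit(fit, design, ok, y)
    out$converged <- FALSE
    return(out)
  }
  extract_fit(fit, design, ok, y)
}

#' Fit a linear mixed model at a single time-point
#'
#' The per-column engine of the functional fit: a Gaussian LMM (REML by
#' default) for the signal at grid position `s_index` as outcome, with the
#' design from [build_design()].
#'
#' @param dataset A [functional_dataset()].
#' @param design An [flmm_design] built against `dataset$trials`.
#' @param s_index Grid position (1-based column of `Y`).
#' @param method `"REML"` (default) or `"ML"`.
#' @return A list with `beta` (raw fixed-effect estimates), `cov_beta`
#'   (model-based covariance), `sigma2`, `varcomps` (one covariance matrix
#'   per random group), `blups` (predicted random effects per grouping
#'   level), `resid` (conditional residuals, NA for rows dropped at this
#'   time-point), `loglik`/`aic`/`bic` (ML criterion evaluated at the fitted
#'   components) and `converged`.
#' @export
fit_single <- function(dataset, design, s_index, method = c("REML", "ML")) {
  method <- match.arg(method)
  stopifnot(s_index >= 1, s_index <= ncol(dataset$Y))
  out <- fit_one_column(dataset$Y[, s_index], design, method)
  out$s_index <- s_index
  out
}

#' Fit the pointwise linear mixed models at every time-point
#'
#' Runs the massively univariate step: one independent Gaussian LMM per grid
#' column. Rows with a missing sample are dropped only at the affected
#' columns. Columns that fail to converge after deterministic restarts are
#' flagged; their raw coefficients and covariances are linearly interpolated
#' from the nearest converged neighbours for smoothing, and excluded from
#' covariance estimation.
#'
#' @inheritParams fit_single
#' @param workers Number of worker processes (results are identical for any
#'   worker count; forking is used when `workers > 1`).
#' @return An object of class `flmm_pointwise`: list with `beta_raw`
#'   (S x p), `cov_beta` (p x p x S array), `columns` (per-column extracts as
#'   in [fit_single()]), `converged`, `interpolated`, `design`, `method`.
#' @export
fit_pointwise <- function(dataset, design, method = c("REML", "ML"),
                          workers = 1L) {
  method <- match.arg(method)
  Y <- dataset$Y
  S <- ncol(Y)
  template <- NULL
  if (length(design$Z)) {
    full <- which(colSums(!is.finite(Y)) == 0)
    if (length(full)) {
      df <- design$frame
      df$.y <- Y[, full[1]]
      template <- tryCatch(suppressMessages(
        lme4::lmer(stats::as.formula(design$lmer_formula), data = df,
                   REML = (method == "REML"), control = lmer_ctrl())),
        error = function(e) NULL)
    }
  }
  run <- function(s) fit_one_column(Y[, s], design, method, template)
  cols <- if (workers > 1L) {
    parallel::mclapply(seq_len(S), run, mc.cores = workers)
  } else {
    lapply(seq_len(S), run)
  }
  converged <- vapply(cols, function(x) isTRUE(x$converged), logical(1))
  if (mean(!converged) > 0.2)
    stop(sprintf("%d of %d time-points failed to converge; simplify the model",
                 sum(!converged), S), call. = FALSE)
  p <- ncol(design$X)
  beta_raw <- matrix(NA_real_, S, p, dimnames = list(NULL, colnames(design$X)))
  cov_beta <- array(NA_real_, c(p, p, S))
  for (s in which(converged)) {
    beta_raw[s, ] <- cols[[s]]$beta[colnames(design$X)]
    cov_beta[, , s] <- cols[[s]]$cov_beta
  }
  interpolated <- which(!converged)
  for (s in interpolated) {
    lo <- max(which(converged[seq_len(s)]), -Inf)
    hi_set <- which(converged) ; hi_set <- hi_set[hi_set > s]
    hi <- if (length(hi_set)) min(hi_set) else -Inf
    if (is.infinite(lo)) { beta_raw[s, ] <- beta_raw[hi, ]; cov_beta[, , s] <- cov_beta[, , hi] }
    else if (is.infinite(hi)) { beta_raw[s, ] <- beta_raw[lo, ]; cov_beta[, , s] <- cov_beta[, , lo] }
    else {
      w <- (s - lo) / (hi - lo)
      beta_raw[s, ] <- (1 - w) * beta_raw[lo, ] + w * beta_raw[hi, ]
      cov_beta[, , s] <- (1 - w) * cov_beta[, , lo] + w * cov_beta[, , hi]
    }
  }
  structure(list(beta_raw = beta_raw, cov_beta = cov_beta, columns = cols,
                 converged = converged, interpolated = interpolated,
                 design = design, method = method, grid = dataset$grid),
            class = "flmm_pointwise")
}

#' @export
print.flmm_pointwise <- function(x, ...) {
  cat(sprintf("<flmm_pointwise> %d time-points, %d coefficients, %d converged\n",
              nrow(x$beta_raw), ncol(x$beta_raw), sum(x$converged)))
  invisible(x)
}

#' Aggregate fit information across time-points
#'
#' Sums the per-column AIC and BIC (ML criterion evaluated at the fitted
#' variance components) over converged columns, recording the column set so
#' that models are only compared on identical sets — see [compare_models()].
#'
#' @param fits An `flmm_pointwise` object.
#' @return A list with `aic`, `bic`, `n_columns`, `columns`.
#' @export
model_information <- function(fits) {
  stopifnot(inherits(fits, "flmm_pointwise"))
  idx <- which(fits$converged)
  structure(list(
    aic = sum(vapply(fits$columns[idx], `[[`, numeric(1), "aic")),
    bic = sum(vapply(fits$columns[idx], `[[`, numeric(1), "bic")),
    n_columns = length(idx), columns = idx), class = "flmm_information")
}

#' Compare fit information of two models
#'
#' Refuses the comparison unless both models converged on the same column
#' set, since summed criteria are only comparable on identical data.
#'
#' @param a,b Results of [model_information()].
#' @return A data frame with the AIC/BIC differences (a minus b).
#' @export
compare_models <- function(a, b) {
  stopifnot(inherits(a, "flmm_information"), inherits(b, "flmm_information"))
  if (!identical(a$columns, b$columns))
    stop("models converged on different column sets; ",
         "refit on a common set before comparing criteria", call. = FALSE)
  data.frame(delta_aic = a$aic - b$aic, delta_bic = b$bic * 0 + a$bic - b$bic,
             n_columns = a$n_columns)
}
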