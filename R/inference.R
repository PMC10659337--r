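# Pairwise-complete cross-products of a column-partial matrix: crossprod
# divided by the count of complete pairs (no small-sample correction).
pairwise_crossprod <- function(E) {
  obs <- is.finite(E)
  E0 <- E; E0[!obs] <- 0
  cnt <- crossprod(obs * 1)
  cp <- crossprod(E0)
  cp / pmax(cnt, 1)
}

# Hat-adjusted moment estimator. Marginal residuals satisfy (with the OLS
# hat H as a proxy for the per-column GLS hat)
#   E[e(s1) e(s2)'] = (I - H) V(s1,s2) (I - H)',
#   V(s1,s2) = sum_k Z_k (I (x) G_k(s1,s2)) Z_k' + sig(s1,s2) I,
# which stays linear in the unknown G/sigma coordinates with known basis
# matrices (I-H) B_u (I-H)'. Least squares over all L^2 index pairs gives
# every coordinate, for every (s1, s2) at once, from factored quantities
# A Z_u = (I-H) Z_u (L x nlev) and A E (L x S) without forming any L x L
# matrix; unbiased by construction (no shrinkage, no ad hoc df factor).
moment_fit <- function(design, E0) {
  X <- design$X
  L <- nrow(X)
  qrX <- qr(X)
  XtXi_Xt <- function(B) qr.coef(qrX, B) # (X'X)^-1 X' B
  gs <- design$groups
  AZ <- list(); labels_az <- character(0)
  for (k in seq_along(gs)) {
    g <- gs[[k]]
    Zk <- design$Z[[names(gs)[k]]]
    for (a in seq_len(g$q)) {
      Za <- as.matrix(Zk[, seq(a, ncol(Zk), by = g$q), drop = FALSE])
      AZ <- c(AZ, list(Za - X %*% XtXi_Xt(Za)))
      labels_az <- c(labels_az, sprintf("z%d.%d", k, a))
    }
  }
  AE <- E0 - X %*% XtXi_Xt(E0)
  # unknown coordinates: per group k all (a, b), then sigma
  terms <- list(); labels <- character(0)
  for (k in seq_along(gs)) for (a in seq_len(gs[[k]]$q))
    for (b in seq_len(gs[[k]]$q)) {
      terms <- c(terms, list(c(k, a, b)))
      labels <- c(labels, sprintf("g%d.%d.%d", k, a, b))
    }
  u <- length(terms) + 1
  az_of <- function(k, a) AZ[[which(labels_az == sprintf("z%d.%d", k, a))]]
  # normal matrix via traces of products of the small cross-Gram matrices
  N <- matrix(0, u, u)
  for (i in seq_along(terms)) {
    ka <- terms[[i]]
    Za <- az_of(ka[1], ka[2]); Zb <- az_of(ka[1], ka[3])
    for (j in seq_along(terms)) {
      kc <- terms[[j]]
      Zc <- az_of(kc[1], kc[2]); Zd <- az_of(kc[1], kc[3])
      N[i, j] <- sum(crossprod(Za, Zc) * crossprod(Zb, Zd))
    }
    N[i, u] <- N[u, i] <- sum(Za * Zb)
  }
  N[u, u] <- L - qrX$rank
  rhs <- vector("list", u)
  for (i in seq_along(terms)) {
    ka <- terms[[i]]
    rhs[[i]] <- crossprod(crossprod(az_of(ka[1], ka[2]), E0),
                          crossprod(az_of(ka[1], ka[3]), E0))
  }
  rhs[[u]] <- crossprod(AE, E0)
  Ninv <- tryCatch(solve(N), error = function(e) {
    sv <- svd(N); pos <- sv$d > max(sv$d) * 1e-10
    sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  })
  Cmom <- lapply(seq_len(u), function(i)
    Reduce(`+`, Map(`*`, rhs, Ninv[i, ])))
  names(Cmom) <- c(labels, "sigma")
  Cmom
}

# Smooth a (possibly asymmetric) covariance surface along its lag-diagonals:
# each diagonal C[s, s+k] is a smooth function of s under the model, so
# 1-D penalized-spline smoothing per lag removes moment-estimation noise
# without blurring the short-range ridge across lags.
smooth_surface_lagwise <- function(C, min_len = 8, lambdas = NULL,
                                   cache = new.env(parent = emptyenv())) {
  S <- nrow(C)
  lambda_grid <- 10^seq(-2, 6, length.out = 17)
  used <- matrix(NA_real_, 2, S) # row 1: upper lags, row 2: lower lags
  smooth_vec <- function(v, fixed_lam) {
    len <- length(v)
    if (len < min_len || stats::sd(v) == 0)
      return(list(v = v, lam = NA_real_))
    key <- as.character(len)
    cmp <- cache[[key]]
    if (is.null(cmp)) {
      K <- max(4L, min(ceiling(len / 2), 10L))
      cmp <- smoother_components(seq_len(len), smoother_spec(K = K))
      cache[[key]] <- cmp
    }
    lam <- fixed_lam
    if (is.null(lam) || is.na(lam)) {
      gcv <- gcv_curve(cmp, v, lambda_grid)
      lam <- lambda_grid[max(which(gcv <= min(gcv) * (1 + 1e-10)))]
    }
    w <- 1 / (1 + lam * cmp$d)
    list(v = as.vector(cmp$Tm %*% (w * as.vector(crossprod(cmp$Tm, v)))),
         lam = lam)
  }
  out <- C
  for (k in 0:(S - 1)) {
    iu <- cbind(seq_len(S - k), seq_len(S - k) + k)
    r <- smooth_vec(C[iu], if (!is.null(lambdas)) lambdas[1, k + 1])
    out[iu] <- r$v; used[1, k + 1] <- r$lam
    if (k > 0) {
      il <- cbind(seq_len(S - k) + k, seq_len(S - k))
      r <- smooth_vec(C[il], if (!is.null(lambdas)) lambdas[2, k + 1])
      out[il] <- r$v; used[2, k + 1] <- r$lam
    }
  }
  attr(out, "lambdas") <- used
  out
}

project_psd <- function(C) {
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  C2 <- e$vectors %*% (pos * t(e$vectors))
  (C2 + t(C2)) / 2
}

#' Method-of-moments covariance of the smoothed coefficient functions
#'
#' Assembles, for every pair of time-points (s1, s2), the cross-covariance of
#' the raw per-column GLS estimators via the sandwich implied by the
#' per-column GLS weight matrices:
#'
#' `Cov(b(s1), b(s2)) = sum_k M(s1) Z_k Ghat_k(s1,s2) Z_k' M(s2)' +
#'  sighat_eps(s1,s2) M(s1) M(s2)'`
#'
#' where the cross-time-point variance components `Ghat_k(s1,s2)` (per
#' random group, including nested levels) and `sighat_eps(s1,s2)` are
#' estimated by method of moments: least squares of pairwise cross-products
#' of marginal residuals `e_l(s1) e_m(s2)` on their known expectation
#' structure over all within-group index pairs. Unlike plug-in BLUP
#' cross-products, these moment estimates are free of shrinkage bias; no
#' small-sample correction is applied. The same-time-point diagonal uses the
#' model-based covariance from the pointwise fit. The raw S x S surface per
#' coefficient is then pre/post-multiplied by that coefficient's smoother
#' matrix, symmetrized, and projected to the nearest positive semi-definite
#' matrix by eigenvalue truncation at zero; the projected diagonal defines
#' the squared pointwise standard errors.
#'
#' @param fits An `flmm_pointwise` object from [fit_pointwise()].
#' @param smoothers List of per-coefficient S x S smoother matrices from
#'   [smooth_coefficients()].
#' @param design The [flmm_design] used for the fits.
#' @return List with `cov` (per-coefficient smoothed S x S covariance,
#'   PSD-projected), `raw` (per-coefficient raw estimator covariance), and
#'   `df` (per-coefficient effective degrees of freedom of the variance
#'   estimate at each time-point, from a delete-one-cluster jackknife of
#'   the moment step; used for small-sample band widening).
#' @export
estimate_beta_covariance <- function(fits, smoothers, design) {
  stopifnot(inherits(fits, "flmm_pointwise"))
  cols <- fits$columns
  S <- nrow(fits$beta_raw)
  p <- ncol(fits$beta_raw)
  L <- nrow(design$X)
  conv <- fits$converged
  if (!any(conv)) stop("no converged time-points", call. = FALSE)

  # marginal residual matrix (L x S); zero outside converged columns and
  # for rows excluded at a column (their GLS weight is zero too)
  E0 <- matrix(0, L, S)
  for (s in which(conv)) {
    e <- cols[[s]]$mresid
    e[!is.finite(e)] <- 0
    E0[, s] <- e
  }
  if (any(!is.finite(E0)))
    stop("non-finite residual cross-products", call. = FALSE)

  # moment-equation estimates of G_k(s1,s2) and sig_eps(s1,s2), all pairs,
  # denoised by smoothing along lag-diagonals (each lag curve is smooth
  # under the model; the ridge across lags is untouched)
  Cmom <- moment_fit(design, E0)
  lag_lambdas <- NULL
  lag_cache <- new.env(parent = emptyenv())
  if (sum(conv) == S) {
    Cmom <- lapply(Cmom, smooth_surface_lagwise, cache = lag_cache)
    lag_lambdas <- lapply(Cmom, attr, "lambdas")
  }

  # full-length GLS weight rows per coefficient: Mk is S x L (zero for rows
  # excluded at a column)
  Mk_list <- lapply(seq_len(p), function(k) matrix(0, S, L))
  for (s in which(conv)) {
    ok <- cols[[s]]$ok
    M <- cols[[s]]$M
    for (k in seq_len(p)) Mk_list[[k]][s, ok] <- M[k, ]
  }

  # sandwich weights per coefficient and moment coordinate:
  # Cov(b(s1), b(s2))[k,k] = sum_u P[[k]][[u]](s1,s2) * Cmom[[u]](s1,s2)
  gs <- design$groups
  Plist <- lapply(seq_len(p), function(k) {
    out <- list(sigma = Mk_list[[k]] %*% t(Mk_list[[k]]))
    for (ki in seq_along(gs)) {
      g <- gs[[ki]]
      q <- g$q; nlev <- length(g$levels)
      BZ <- as.matrix(Mk_list[[k]] %*% design$Z[[names(gs)[ki]]])
      for (a in seq_len(q)) for (b in seq_len(q)) {
        Wa <- BZ[, seq(a, nlev * q, by = q), drop = FALSE]
        Wb <- BZ[, seq(b, nlev * q, by = q), drop = FALSE]
        out[[sprintf("g%d.%d.%d", ki, a, b)]] <- Wa %*% t(Wb)
      }
    }
    out
  })
  assemble <- function(k, Cm)
    Reduce(`+`, lapply(names(Plist[[k]]), function(u) Plist[[k]][[u]] * Cm[[u]]))
  craw <- lapply(seq_len(p), function(k) assemble(k, Cmom))

  # Effective df of the variance estimate by delete-one-cluster jackknife
  # of the moment step (smoother and sandwich weights held fixed): drives
  # the small-sample widening applied by flmm().
  dfs <- lapply(seq_len(p), function(k) rep(Inf, S))
  var_rel <- vector("list", p)
  df_common <- rep(Inf, p)
  if (length(gs)) {
    nlevs <- vapply(gs, function(g) length(g$levels), integer(1))
    jg <- gs[[which.min(nlevs)]]
    units <- levels(jg$factor)
    J <- length(units)
    if (J >= 3) {
      vjack <- lapply(seq_len(p), function(k) matrix(NA_real_, J, S))
      for (j in seq_len(J)) {
        keep <- jg$factor != units[j]
        sub <- list(X = design$X[keep, , drop = FALSE],
                    Z = lapply(design$Z, function(z) z[keep, , drop = FALSE]),
                    groups = gs)
        Cj <- tryCatch(moment_fit(sub, E0[keep, , drop = FALSE]),
                       error = function(e) NULL)
        if (is.null(Cj)) next
        if (!is.null(lag_lambdas))
          Cj <- lapply(names(Cj), function(u) {
            smooth_surface_lagwise(Cj[[u]], lambdas = lag_lambdas[[u]],
                                   cache = lag_cache)
          }) |> stats::setNames(names(lag_lambdas))
        for (k in seq_len(p)) {
          cj <- assemble(k, Cj)
          vjack[[k]][j, ] <- rowSums((smoothers[[k]] %*% cj) * smoothers[[k]])
        }
      }
      for (k in seq_len(p)) {
        vj <- vjack[[k]][stats::complete.cases(vjack[[k]]), , drop = FALSE]
        if (nrow(vj) >= 3) {
          vfull <- pmax(rowSums((smoothers[[k]] %*% craw[[k]]) * smoothers[[k]]),
                        .Machine$double.eps)
          ctr <- sweep(vj, 2, colMeans(vj))
          fac <- (nrow(vj) - 1) / nrow(vj)
          varv <- fac * colSums(ctr^2)
          dfs[[k]] <- pmax(ifelse(varv > 0, 2 * vfull^2 / varv, Inf), 3)
          var_rel[[k]] <- (fac * crossprod(ctr)) / outer(vfull, vfull)
          # df of the integrated variance: per-point jackknife noise cancels
          # in the sum, leaving the component shared across time-points —
          # the scale the studentized joint multiplier needs
          vtot <- fac * sum(rowSums(ctr)^2)
          df_common[k] <- if (vtot > 0) max(2 * sum(vfull)^2 / vtot, 3) else Inf
        }
      }
    }
  }

  # same-time-point diagonal: the model-based per-column variance, denoised
  # by smoothing log-variance along the grid (the variance function is
  # smooth under the model; per-column estimation noise is independent)
  for (k in seq_len(p)) {
    v <- fits$cov_beta[k, k, ]
    if (all(conv) && all(v > 0) && S >= 8) {
      lv <- log(v)
      cmp <- smoother_components(seq_len(S),
                                 smoother_spec(K = max(4L, min(ceiling(S / 2), 10L))))
      lambda_grid <- 10^seq(-2, 6, length.out = 17)
      gcv <- gcv_curve(cmp, lv, lambda_grid)
      lam <- lambda_grid[max(which(gcv <= min(gcv) * (1 + 1e-10)))]
      w <- 1 / (1 + lam * cmp$d)
      v <- exp(as.vector(cmp$Tm %*% (w * as.vector(crossprod(cmp$Tm, lv)))))
    }
    diag(craw[[k]])[conv] <- v[conv]
    craw[[k]] <- (craw[[k]] + t(craw[[k]])) / 2
  }

  # columns excluded from estimation: fill their rows/columns by linear
  # interpolation between the nearest converged neighbours
  if (any(!conv)) {
    idx <- which(conv)
    fill <- function(C) {
      for (s in which(!conv)) {
        lo <- suppressWarnings(max(idx[idx < s])); hi <- suppressWarnings(min(idx[idx > s]))
        src <- if (!is.finite(lo)) c(hi, hi) else if (!is.finite(hi)) c(lo, lo) else c(lo, hi)
        w <- if (diff(src) == 0) 0.5 else (s - src[1]) / diff(src)
        C[s, ] <- (1 - w) * C[src[1], ] + w * C[src[2], ]
        C[, s] <- C[s, ]
        C[s, s] <- (1 - w) * C[src[1], src[1]] + w * C[src[2], src[2]]
      }
      C
    }
    craw <- lapply(craw, fill)
  }

  covs <- lapply(seq_len(p), function(k)
    project_psd(smoothers[[k]] %*% craw[[k]] %*% t(smoothers[[k]])))
  names(covs) <- colnames(fits$beta_raw)
  names(craw) <- colnames(fits$beta_raw)
  names(dfs) <- colnames(fits$beta_raw)
  names(var_rel) <- colnames(fits$beta_raw)
  names(df_common) <- colnames(fits$beta_raw)
  list(cov = covs, raw = craw, df = dfs, var_rel = var_rel,
       df_common = df_common)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulation-based joint (simultaneous) band multiplier
#'
#' The multiplier replacing the pointwise normal quantile in a simultaneous
#' band: the empirical `level` quantile of `max_s |Z_s| / sd_s` over
#' `n_sim` draws `Z ~ N(0, cov)`, never below the pointwise critical value.
#' Time-points with zero variance are excluded with a warning. Deterministic
#' given `seed` (R's default Mersenne-Twister generator).
#'
#' @param cov S x S positive semi-definite covariance of the smoothed
#'   coefficient estimator.
#' @param level Nominal simultaneous level (default 0.95).
#' @param n_sim Number of Monte-Carlo draws (>= 1000; default 10000).
#' @param seed Integer seed.
#' @param df Effective degrees of freedom of the variance estimate. The
#'   default `Inf` gives the Gaussian multiplier; a finite value studentizes
#'   the max draws with a common chi-square scale, widening the multiplier
#'   to account for variance-estimation noise shared across time-points.
#' @param var_rel Optional S x S relative covariance of the variance
#'   estimate (e.g. the jackknife covariance of the variance field divided
#'   by the outer product of the variances). When supplied, each draw's
#'   standardized deviations are divided by a correlated variance-noise
#'   field with this covariance, a finer-grained studentization than `df`.
#' @return The multiplier `q_joint`.
#' @export
joint_multiplier <- function(cov, level = 0.95, n_sim = 10000, seed = 12345,
                             df = Inf, var_rel = NULL) {
  stopifnot(level > 0, level < 1, n_sim >= 1000, df > 0)
  v <- diag(cov)
  keep <- v > 0
  if (!any(keep)) stop("all time-points have zero variance", call. = FALSE)
  if (!all(keep))
    warning(sum(!keep), " time-point(s) with zero variance excluded from the multiplier")
  Cr <- cov[keep, keep, drop = FALSE] / sqrt(outer(v[keep], v[keep]))
  Cr <- (Cr + t(Cr)) / 2
  e <- eigen(Cr, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = ncol(Cr))
  Ar <- NULL
  if (!is.null(var_rel)) {
    R <- var_rel[keep, keep, drop = FALSE]
    R <- (R + t(R)) / 2
    er <- eigen(R, symmetric = TRUE)
    Ar <- er$vectors %*% diag(sqrt(pmax(er$values, 0)), nrow = ncol(R))
  }
  sims <- with_seed(seed, {
    d <- matrix(stats::rnorm(n_sim * ncol(Cr)), n_sim)
    w <- if (is.null(Ar) && is.finite(df))
      sqrt(stats::rchisq(n_sim, df) / df) else rep(1, n_sim)
    eta <- if (!is.null(Ar)) matrix(stats::rnorm(n_sim * ncol(Cr)), n_sim)
    list(d = d, w = w, eta = eta)
  })
  Zs <- sims$d %*% t(A)
  if (!is.null(Ar)) {
    # correlated variance-noise field: se_hat^2 ~ se^2 (1 + eta)
    scl <- sqrt(pmax(1 + sims$eta %*% t(Ar), 0.04))
    mx <- apply(abs(Zs) / scl, 1, max)
  } else {
    mx <- apply(abs(Zs), 1, max) / sims$w
  }
  q <- as.numeric(stats::quantile(mx, level, type = 7))
  max(q, stats::qnorm(1 - (1 - level) / 2))
}

#' Construct pointwise and joint confidence bands for one coefficient
#'
#' @param estimate S-vector of smoothed coefficient values.
#' @param cov S x S covariance of the estimator (PSD).
#' @param level Nominal level for both bands (default 0.95).
#' @param q_joint Joint multiplier, e.g. from [joint_multiplier()].
#' @param name Coefficient label.
#' @param time Time grid (seconds).
#' @return An object of class `coefficient_band` with `estimate`, `se`,
#'   `pw_bounds`, `joint_bounds` (S x 2 each), `q_joint`, `cov_full` and the
#'   indices of degenerate (zero-se) points in `degenerate`.
#' @export
build_bands <- function(estimate, cov, level = 0.95, q_joint, name = "beta",
                        time = seq_along(estimate)) {
  se <- sqrt(pmax(diag(cov), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  pw <- cbind(lower = estimate - z * se, upper = estimate + z * se)
  jt <- cbind(lower = estimate - q_joint * se, upper = estimate + q_joint * se)
  structure(list(name = name, time = as.numeric(time), estimate = estimate,
                 se = se, pw_level = level, joint_level = level,
                 q_joint = q_joint, pw_bounds = pw, joint_bounds = jt,
                 cov_full = cov, degenerate = which(se == 0)),
            class = "coefficient_band")
}

#' @export
print.coefficient_band <- function(x, ...) {
  cat(sprintf("<coefficient_band> %s: %d points, q_joint = %.3f\n",
              x$name, length(x$estimate), x$q_joint))
  si <- significant_intervals(x, "joint")
  if (nrow(si)) {
    cat("jointly significant:\n")
    for (i in seq_len(nrow(si)))
      cat(sprintf("  [%.3f, %.3f] s (%s)\n", si$start[i], si$end[i], si$sign[i]))
  } else cat("no jointly significant period\n")
  invisible(x)
}

#' Extract maximal significant time intervals from a band
#'
#' Maximal runs of consecutive grid points whose chosen band excludes zero,
#' reported as closed intervals in seconds.
#'
#' @param band A [coefficient_band].
#' @param which `"joint"` (default) or `"pointwise"`.
#' @return Data frame with columns `start`, `end`, `sign` (one row per
#'   interval, time order); zero rows if the band contains 0 everywhere.
#' @export
significant_intervals <- function(band, which = c("joint", "pointwise")) {
  which <- match.arg(which)
  b <- if (which == "joint") band$joint_bounds else band$pw_bounds
  pos <- b[, 1] > 0
  neg <- b[, 2] < 0
  sig <- pos | neg
  out <- data.frame(start = numeric(0), end = numeric(0), sign = character(0))
  if (!any(sig)) return(out)
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (i in which(r$values)) {
    seg <- starts[i]:ends[i]
    out <- rbind(out, data.frame(
      start = band$time[starts[i]], end = band$time[ends[i]],
      sign = if (all(pos[seg])) "positive" else if (all(neg[seg])) "negative" else "mixed"))
  }
  out
}

#' Cluster bootstrap confidence bands
#'
#' Resamples subjects with replacement (each carrying all its trials),
#' refits the full pipeline per replicate, and builds percentile pointwise
#' bands plus a joint band from the quantile of the maximum standardized
#' deviation across replicates. Intended for outcomes where the Gaussian
#' analytic bands are suspect.
#'
#' @param dataset A [functional_dataset()] with at least 3 subjects.
#' @param formula Model formula (see [flmm_formula()]).
#' @param B Number of bootstrap replicates (minimum 200).
#' @param seed Integer seed; the procedure is deterministic given it.
#' @param level Nominal level (default 0.95).
#' @param smoother A [smoother_spec()].
#' @return List of [coefficient_band] objects (one per fixed-effect
#'   coefficient), with the redraw count in attribute `"redraws"`.
#' @export
cluster_bootstrap_bands <- function(dataset, formula, B = 200, seed = 1,
                                    level = 0.95, smoother = smoother_spec()) {
  if (B < 200) stop("B must be at least 200", call. = FALSE)
  subj <- levels(dataset$trials$subject)
  if (length(subj) < 3) stop("need at least 3 subjects", call. = FALSE)
  fit0 <- flmm_point_estimate(formula, dataset, smoother)
  S <- nrow(fit0$smoothed); p <- ncol(fit0$smoothed)
  arr <- array(NA_real_, c(B, S, p))
  redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        pick <- sample(subj, length(subj), replace = TRUE)
        if (length(unique(pick)) > 1) break
        redraws <- redraws + 1L
      }
      rows <- unlist(lapply(seq_along(pick), function(i) {
        w <- which(dataset$trials$subject == pick[i])
        names(w) <- NULL
        w
      }))
      relabel <- rep(sprintf("bs%d", seq_along(pick)),
                     vapply(pick, function(s) sum(dataset$trials$subject == s),
                            integer(1)))
      tr <- dataset$trials[rows, , drop = FALSE]
      tr$subject <- relabel
      rownames(tr) <- NULL
      ds <- functional_dataset(dataset$Y[rows, , drop = FALSE], dataset$grid, tr,
                               allow_missing = TRUE)
      fb <- tryCatch(flmm_point_estimate(formula, ds, smoother),
                     error = function(e) NULL)
      if (!is.null(fb)) arr[b, , ] <- fb$smoothed
    }
  })
  alpha <- 1 - level
  bands <- vector("list", p)
  for (k in seq_len(p)) {
    bk <- arr[, , k]
    keep <- stats::complete.cases(bk)
    bk <- bk[keep, , drop = FALSE]
    lo <- apply(bk, 2, stats::quantile, alpha / 2)
    hi <- apply(bk, 2, stats::quantile, 1 - alpha / 2)
    se <- apply(bk, 2, stats::sd)
    est <- fit0$smoothed[, k]
    dev <- sweep(abs(sweep(bk, 2, est)), 2, pmax(se, .Machine$double.eps), "/")
    qb <- as.numeric(stats::quantile(apply(dev, 1, max), level))
    band <- build_bands(est, diag(se^2, S), level, qb,
                        name = colnames(fit0$smoothed)[k],
                        time = as.numeric(dataset$grid))
    band$pw_bounds <- cbind(lower = lo, upper = hi)
    bands[[k]] <- band
  }
  names(bands) <- colnames(fit0$smoothed)
  attr(bands, "redraws") <- redraws
  attr(bands, "B_used") <- sum(stats::complete.cases(arr[, , 1]))
  bands
}

# design + pointwise + smoothing only (shared by bootstrap replicates)
flmm_point_estimate <- function(formula, dataset, smoother) {
  design <- build_design(formula, dataset$trials)
  pw <- fit_pointwise(dataset, design)
  sm <- smooth_coefficients(pw$beta_raw, dataset$grid, smoother)
  list(pointwise = pw, smoothed = sm$smoothed, smoothers = sm$smoothers,
       lambda = sm$lambda, design = design)
}
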