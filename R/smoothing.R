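#' Describe a penalized B-spline smoother
#'
#' Cubic B-splines on an equally spaced knot sequence with a second-order
#' difference penalty (a P-spline); the penalty null space (linear
#' functions) is reproduced exactly for any lambda. The default smoothing
#' is the pure basis projection (`lambda = 0` with
#' `K = min(ceiling(S/2), 30)` functions): smoothing through the basis
#' dimension keeps the smoother independent of the realized noise, which
#' the confidence bands require — data-driven GCV selection
#' (`lambda = "auto"`) is available but its selection optimism measurably
#' inflates the bands' error rates at small subject counts.
#'
#' @param K Number of basis functions; `NULL` picks the default from the
#'   grid length at smoothing time.
#' @param degree Spline degree (3 = cubic).
#' @param penalty_order Order of the difference penalty.
#' @param lambda A fixed nonnegative penalty weight (default 0: basis
#'   projection) or `"auto"` for GCV over `lambda_grid`.
#' @param lambda_grid Logarithmic search grid for GCV.
#' @return An object of class `smoother_spec`.
#' @export
smoother_spec <- function(K = NULL, degree = 3, penalty_order = 2,
                          lambda = 0,
                          lambda_grid = 10^seq(-4, 8, length.out = 49)) {
  if (!identical(lambda, "auto")) {
    lambda <- as.numeric(lambda)
    stopifnot(length(lambda) == 1, lambda >= 0)
  }
  structure(list(K = K, degree = degree, penalty_order = penalty_order,
                 lambda = lambda, lambda_grid = sort(lambda_grid)),
            class = "smoother_spec")
}

default_K <- function(S) min(ceiling(S / 2), 30L)

pspline_basis <- function(x, K, degree = 3) {
  x <- as.numeric(x)
  S <- length(x)
  if (K > S)
    stop(sprintf("K = %d basis functions exceed the %d grid points; reduce the basis",
                 K, S), call. = FALSE)
  if (K < max(4L, degree + 1L))
    stop("need at least max(4, degree + 1) basis functions", call. = FALSE)
  lo <- min(x); hi <- max(x)
  dx <- (hi - lo) / (K - degree)
  knots <- seq(lo - degree * dx, hi + degree * dx, by = dx)
  B <- splines::splineDesign(knots, x, ord = degree + 1, outer.ok = TRUE)
  stopifnot(ncol(B) == K)
  B
}

# Demmler-Reinsch-style decomposition: with C = B'B = R'R and
# A = R^-T P R^-1 = U diag(d) U', the hat matrix is
# H(lambda) = T diag(1/(1 + lambda d)) T' with orthonormal T = B R^-1 U,
# so GCV is O(K) per lambda.
smoother_components <- function(grid, spec) {
  S <- length(grid)
  K <- if (is.null(spec$K)) default_K(S) else spec$K
  B <- pspline_basis(grid, K, spec$degree)
  D <- diff(diag(K), differences = spec$penalty_order)
  R <- chol(crossprod(B))
  A <- backsolve(R, t(backsolve(R, crossprod(D), transpose = TRUE)),
                 transpose = TRUE)
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  d <- pmax(e$values, 0)
  Tm <- B %*% backsolve(R, e$vectors)
  list(B = B, Tm = Tm, d = d, K = K)
}

hat_matrix <- function(cmp, lambda) {
  w <- 1 / (1 + lambda * cmp$d)
  cmp$Tm %*% (w * t(cmp$Tm))
}

gcv_curve <- function(cmp, y, lambdas) {
  cy <- as.vector(crossprod(cmp$Tm, y))
  yy <- sum(y^2)
  S <- nrow(cmp$Tm)
  vapply(lambdas, function(lam) {
    w <- 1 / (1 + lam * cmp$d)
    rss <- max(yy - sum(cy^2 * (2 * w - w^2)), 0)
    edf <- sum(w)
    S * rss / (S - edf)^2
  }, numeric(1))
}

#' Select the penalty weight by generalized cross-validation
#'
#' Minimizes `GCV(lambda) = S * RSS(lambda) / (S - edf(lambda))^2` over the
#' spec's logarithmic grid; deterministic given the inputs. Near-ties
#' (within 1e-10 relative) resolve to the larger lambda. A degenerate
#' (constant) input returns the largest grid value with a warning — the
#' smoother is exact for constants at any lambda.
#'
#' @param raw Numeric vector to be smoothed (one raw coefficient function).
#' @param grid A [time_grid()] (or numeric vector of sample times).
#' @param spec A [smoother_spec()].
#' @return The selected lambda, with the GCV curve attached as attribute
#'   `"criterion"`.
#' @export
select_lambda <- function(raw, grid, spec = smoother_spec()) {
  S <- length(raw)
  stopifnot(length(grid) == S)
  if (stats::sd(raw) == 0) {
    warning("degenerate (constant) input; returning the largest grid lambda")
    lam <- max(spec$lambda_grid)
    attr(lam, "criterion") <- rep(0, length(spec$lambda_grid))
    return(lam)
  }
  cmp <- smoother_components(as.numeric(grid), spec)
  gcv <- gcv_curve(cmp, raw, spec$lambda_grid)
  best <- min(gcv)
  idx <- max(which(gcv <= best * (1 + 1e-10)))
  lam <- spec$lambda_grid[idx]
  attr(lam, "criterion") <- gcv
  lam
}

#' Smooth raw coefficient functions and expose the smoother matrices
#'
#' Applies an independent penalized B-spline smoother to each column of a
#' raw coefficient matrix (one lambda per coefficient, selected by GCV when
#' `spec$lambda == "auto"`), and returns the exact linear smoother matrices
#' so that variance propagation through the smoother is valid:
#' `smoothed[, k] = smoothers[[k]] %*% raw[, k]`.
#'
#' @param raw S x p matrix of raw per-time-point coefficient estimates.
#' @param grid A [time_grid()] of length S.
#' @param spec A [smoother_spec()].
#' @return List with `smoothed` (S x p), `smoothers` (list of S x S
#'   matrices), `lambda` (named vector).
#' @export
smooth_coefficients <- function(raw, grid, spec = smoother_spec()) {
  raw <- as.matrix(raw)
  S <- nrow(raw)
  cmp <- smoother_components(as.numeric(grid), spec)
  p <- ncol(raw)
  smoothed <- raw
  smoothers <- vector("list", p)
  lambda <- numeric(p)
  for (k in seq_len(p)) {
    lam <- if (identical(spec$lambda, "auto")) {
      if (stats::sd(raw[, k]) == 0) max(spec$lambda_grid)
      else {
        gcv <- gcv_curve(cmp, raw[, k], spec$lambda_grid)
        spec$lambda_grid[max(which(gcv <= min(gcv) * (1 + 1e-10)))]
      }
    } else spec$lambda
    H <- hat_matrix(cmp, lam)
    smoothers[[k]] <- H
    smoothed[, k] <- as.vector(H %*% raw[, k])
    lambda[k] <- lam
  }
  names(lambda) <- colnames(raw)
  names(smoothers) <- colnames(raw)
  list(smoothed = smoothed, smoothers = smoothers, lambda = lambda, K = cmp$K)
}
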