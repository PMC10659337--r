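#' Construct a common time grid
#'
#' A time grid describes the functional domain of a trial-structured signal:
#' equally spaced sample times in seconds, relative to the alignment event
#' (time 0), together with the sampling rate.
#'
#' @param points Numeric vector of sample times in seconds. Either `points`
#'   or (`start`, `rate`, `n`) must be given.
#' @param start First sample time in seconds relative to the alignment event.
#' @param rate Sampling rate in samples per second.
#' @param n Number of samples.
#' @return An object of class `time_grid`: a numeric vector of sample times
#'   with a `rate` attribute.
#' @examples
#' g <- time_grid(start = -1, rate = 15, n = 45)
#' range(g)
#' @export
time_grid <- function(points = NULL, start = NULL, rate = NULL, n = NULL) {
  if (is.null(points)) {
    if (is.null(start) || is.null(rate) || is.null(n))
      stop("supply either `points` or all of `start`, `rate`, `n`", call. = FALSE)
    points <- start + (seq_len(n) - 1) / rate
  }
  points <- as.numeric(points)
  if (length(points) < 2L)
    stop("a time grid needs at least 2 points", call. = FALSE)
  d <- diff(points)
  if (any(d <= 0))
    stop("time grid must be strictly increasing", call. = FALSE)
  if (max(d) - min(d) > 1e-8 * max(abs(d)))
    stop("time grid must be equally spaced (relative tolerance 1e-8)", call. = FALSE)
  spacing <- mean(d)
  if (is.null(rate)) rate <- 1 / spacing
  if (abs(rate * spacing - 1) > 1e-6)
    stop("`rate` is inconsistent with the grid spacing", call. = FALSE)
  structure(points, rate = rate, class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> %d points, %.6g to %.6g s, %.6g Hz\n",
              length(x), x[1], x[length(x)], attr(x, "rate")))
  invisible(x)
}

#' Sampling rate of a time grid
#' @param grid A [time_grid()].
#' @return Samples per second.
#' @export
grid_rate <- function(grid) attr(grid, "rate")

validate_trial_table <- function(trials) {
  if (!is.data.frame(trials)) stop("`trials` must be a data.frame", call. = FALSE)
  need <- c("subject", "session", "trial")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(trials$subject))
    stop("trial table has missing `subject` values", call. = FALSE)
  if (any(!is.finite(trials$session)) || any(trials$session < 1) ||
      any(trials$session != round(trials$session)))
    stop("`session` must be integers >= 1", call. = FALSE)
  if (any(!is.finite(trials$trial)) || any(trials$trial < 1) ||
      any(trials$trial != round(trials$trial)))
    stop("`trial` must be integers >= 1", call. = FALSE)
  key <- paste(trials$subject, trials$session, trials$trial, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- trials[duplicated(key), need, drop = FALSE]
    stop("duplicate (subject, session, trial) rows: ",
         paste(utils::head(apply(dup, 1, paste, collapse = "/"), 5), collapse = ", "),
         call. = FALSE)
  }
  trials$subject <- factor(trials$subject)
  trials
}

#' Bundle a signal matrix, time grid and trial table
#'
#' The central data container: one row of `Y` per trial (in arbitrary order),
#' one column per time-point of `grid`, and a trial-level covariate table
#' aligned row-for-row with `Y`. The table must carry `subject`, `session`
#' and `trial` identifier columns; any further columns are scalar covariates.
#'
#' @param Y Numeric matrix, trials by time-points.
#' @param grid A [time_grid()] whose length equals `ncol(Y)`.
#' @param trials Data frame with one row per row of `Y`.
#' @param allow_missing If `FALSE` (default) any non-finite entry of `Y` is an
#'   error; if `TRUE`, rows containing missing samples are flagged and handled
#'   by per-column case deletion during fitting.
#' @return An object of class `functional_dataset` with elements `Y`, `grid`,
#'   `trials`.
#' @export
functional_dataset <- function(Y, grid, trials, allow_missing = FALSE) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (!inherits(grid, "time_grid")) grid <- time_grid(points = grid)
  trials <- validate_trial_table(trials)
  if (nrow(Y) != nrow(trials))
    stop(sprintf("Y has %d rows but the trial table has %d", nrow(Y), nrow(trials)),
         call. = FALSE)
  if (ncol(Y) != length(grid))
    stop(sprintf("Y has %d columns but the grid has %d points", ncol(Y), length(grid)),
         call. = FALSE)
  bad <- !is.finite(Y)
  if (any(bad)) {
    rows <- which(rowSums(bad) > 0)
    if (!allow_missing) {
      lab <- paste(trials$subject[rows], trials$session[rows], trials$trial[rows],
                   sep = "/")
      stop("non-finite signal values in rows (subject/session/trial): ",
           paste(utils::head(lab, 5), collapse = ", "), call. = FALSE)
    }
    Y[bad] <- NA_real_
  }
  structure(list(Y = Y, grid = grid, trials = trials),
            class = "functional_dataset")
}

#' @export
print.functional_dataset <- function(x, ...) {
  cat(sprintf("<functional_dataset> %d trials x %d time-points, %d subject(s)\n",
              nrow(x$Y), ncol(x$Y), nlevels(x$trials$subject)))
  covs <- setdiff(names(x$trials), c("subject", "session", "trial"))
  if (length(covs)) cat("covariates:", paste(covs, collapse = ", "), "\n")
  print(x$grid)
  invisible(x)
}

#' @export
dim.functional_dataset <- function(x) dim(x$Y)

#' Read a wide-format CSV of trial-structured signals
#'
#' Expects a UTF-8 comma-separated file with a header row, identifier columns
#' `subject`, `session`, `trial`, optional covariate columns, and consecutively
#' numbered signal columns `<signal_prefix>0 ... <signal_prefix>{S-1}`
#' (zero-based). The time grid is reconstructed as `time_start + k / rate`.
#'
#' @param path File path.
#' @param signal_prefix Prefix of the signal columns (default `"sig"`).
#' @param time_start Time of the first sample, seconds relative to the
#'   alignment event.
#' @param rate Sampling rate, samples per second.
#' @param allow_missing Passed to [functional_dataset()].
#' @return A [functional_dataset()].
#' @export
read_wide_csv <- function(path, signal_prefix = "sig", time_start, rate,
                          allow_missing = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  sig_re <- paste0("^", signal_prefix, "([0-9]+)$")
  sig_cols <- grep(sig_re, names(df), value = TRUE)
  if (!length(sig_cols))
    stop("no signal columns with prefix '", signal_prefix, "' found", call. = FALSE)
  k <- as.integer(sub(sig_re, "\\1", sig_cols))
  ord <- order(k)
  sig_cols <- sig_cols[ord]; k <- k[ord]
  if (!identical(k, 0:(length(k) - 1L)))
    stop("signal columns must be consecutively numbered ", signal_prefix, "0...",
         signal_prefix, length(k) - 1L, "; found gaps", call. = FALSE)
  Y <- as.matrix(df[sig_cols])
  trials <- df[setdiff(names(df), sig_cols)]
  grid <- time_grid(start = time_start, rate = rate, n = length(sig_cols))
  functional_dataset(Y, grid, trials, allow_missing = allow_missing)
}

#' Read a long-format CSV and pivot to the wide internal representation
#'
#' Expects columns `subject`, `session`, `trial`, `time`, `value` plus any
#' covariate columns (constant within trial). Wide is the canonical internal
#' form; this is a convenience reader.
#'
#' @inheritParams read_wide_csv
#' @return A [functional_dataset()].
#' @export
read_long_csv <- function(path, allow_missing = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject", "session", "trial", "time", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("long CSV is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  times <- sort(unique(df$time))
  grid <- time_grid(points = times)
  key <- paste(df$subject, df$session, df$trial, sep = "\r")
  ukey <- unique(key)
  tidx <- match(df$time, times)
  ridx <- match(key, ukey)
  Y <- matrix(NA_real_, length(ukey), length(times))
  if (anyDuplicated(cbind(ridx, tidx)))
    stop("duplicate (subject, session, trial, time) rows in long CSV", call. = FALSE)
  Y[cbind(ridx, tidx)] <- df$value
  first <- match(ukey, key)
  trials <- df[first, setdiff(names(df), c("time", "value")), drop = FALSE]
  rownames(trials) <- NULL
  functional_dataset(Y, grid, trials, allow_missing = allow_missing)
}

#' Write fitted coefficient tables and a JSON sidecar
#'
#' Writes one CSV per coefficient with columns `time`, `estimate`, `se`,
#' `pw_lower`, `pw_upper`, `joint_lower`, `joint_upper`, plus a
#' `flmm_fit.json` sidecar recording the model formula, joint multipliers,
#' fit information, seed and package version.
#'
#' @param result An [flmm()] fit.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_result_tables <- function(result, dir) {
  stopifnot(inherits(result, "flmm"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (band in result$bands) {
    tab <- data.frame(time = as.numeric(band$time),
                      estimate = band$estimate,
                      se = band$se,
                      pw_lower = band$pw_bounds[, 1],
                      pw_upper = band$pw_bounds[, 2],
                      joint_lower = band$joint_bounds[, 1],
                      joint_upper = band$joint_bounds[, 2])
    safe <- gsub("[^A-Za-z0-9_.-]", "_", band$name)
    p <- file.path(dir, paste0("coef_", safe, ".csv"))
    utils::write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  side <- list(formula = result$info$formula,
               multipliers = lapply(result$bands, function(b) b$q_joint),
               pw_level = result$bands[[1]]$pw_level,
               joint_level = result$bands[[1]]$joint_level,
               aic = result$info$aic, bic = result$info$bic,
               n_columns = result$info$n_columns,
               lambda = result$info$lambda,
               smoother = result$info$smoother,
               likelihood = result$info$likelihood,
               seed = result$info$seed,
               package_version = as.character(utils::packageVersion("flmm")))
  pj <- file.path(dir, "flmm_fit.json")
  jsonlite::write_json(side, pj, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(paths, pj))
}
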