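split_plus <- function(e) {
  if (is.call(e) && identical(e[[1]], as.name("+")) && length(e) == 3L)
    c(split_plus(e[[2]]), list(e[[3]]))
  else if (is.call(e) && identical(e[[1]], as.name("-")) && length(e) == 3L)
    c(split_plus(e[[2]]), list(call("-", e[[3]])))
  else list(e)
}

is_zero_term <- function(e) {
  (is.numeric(e) && length(e) == 1L && e == 0) ||
    (is.call(e) && identical(e[[1]], as.name("-")) &&
       is.numeric(e[[2]]) && e[[2]] == 1)
}

check_fixed_term <- function(e, text) {
  if (is.name(e)) return(deparse1(e))
  if (is.call(e) && identical(e[[1]], as.name(":")))
    return(paste(check_fixed_term(e[[2]], text), check_fixed_term(e[[3]], text),
                 sep = ":"))
  stop(flmm_parse_error(text, e,
    "unsupported term (only `+`-separated names, `:` interactions and `(terms | group)` blocks are allowed)"))
}

flmm_parse_error <- function(text, e, msg) {
  frag <- deparse1(e)
  pos <- regexpr(frag, text, fixed = TRUE)
  where <- if (pos > 0) sprintf(" at position %d", as.integer(pos)) else ""
  structure(class = c("flmm_parse_error", "error", "condition"),
            list(message = sprintf("in '%s'%s: %s ('%s')", text, where, msg, frag),
                 call = NULL))
}

parse_terms <- function(parts, text) {
  intercept <- TRUE
  terms <- character(0)
  for (e in parts) {
    if (is_zero_term(e)) { intercept <- FALSE; next }
    if (is.numeric(e) && length(e) == 1L && e == 1) { intercept <- TRUE; next }
    terms <- c(terms, check_fixed_term(e, text))
  }
  list(intercept = intercept, terms = terms)
}

#' Parse a mixed-model formula for functional outcomes
#'
#' Supports a deliberate subset of the lme4 grammar: a response, `+`-separated
#' fixed terms (with `:` interactions), and random-effect blocks
#' `(terms | group)` where `group` is a single factor, a nested pair `a/b`,
#' or an explicit interaction `a:b`. A nested pair expands to two random
#' groups, `(terms | a)` and `(terms | a:b)`. Each block includes a random
#' intercept unless suppressed with `0 +`.
#'
#' @param x A formula or a character string such as
#'   `"photometry ~ IRI + (lick_latency | id/session)"`.
#' @return An object of class `flmm_formula` with elements `response`,
#'   `fixed` (list with `intercept`, `terms`) and `random` (list of groups,
#'   each with `intercept`, `terms`, `group` — a character vector of one or
#'   two factor names, two meaning their interaction).
#' @examples
#' f <- flmm_formula("photometry ~ IRI + (lick_latency | id/session)")
#' print(f)
#' @export
flmm_formula <- function(x) {
  text <- if (is.character(x)) x else deparse1(x)
  f <- tryCatch(stats::as.formula(x, env = globalenv()),
                error = function(e) stop(flmm_parse_error(text, as.name("~"),
                                                          conditionMessage(e))))
  if (length(f) != 3L)
    stop(flmm_parse_error(text, f, "formula must have a response"))
  if (!is.name(f[[2]]))
    stop(flmm_parse_error(text, f[[2]], "response must be a single column name"))
  response <- deparse1(f[[2]])
  parts <- split_plus(f[[3]])
  fixed_parts <- list()
  random <- list()
  for (e in parts) {
    if (is.call(e) && identical(e[[1]], as.name("(")) && length(e) == 2L &&
        is.call(e[[2]]) && identical(e[[2]][[1]], as.name("|"))) {
      bar <- e[[2]]
      lhs <- parse_terms(split_plus(bar[[2]]), text)
      grp <- bar[[3]]
      if (is.name(grp)) {
        groups <- list(deparse1(grp))
      } else if (is.call(grp) && identical(grp[[1]], as.name("/")) &&
                 is.name(grp[[2]]) && is.name(grp[[3]])) {
        a <- deparse1(grp[[2]]); b <- deparse1(grp[[3]])
        groups <- list(a, c(a, b))
      } else if (is.call(grp) && identical(grp[[1]], as.name(":")) &&
                 is.name(grp[[2]]) && is.name(grp[[3]])) {
        groups <- list(c(deparse1(grp[[2]]), deparse1(grp[[3]])))
      } else {
        stop(flmm_parse_error(text, grp,
          "grouping must be a factor name, `a/b`, or `a:b`"))
      }
      if (any(grepl("[*]", deparse1(bar[[2]]))))
        stop(flmm_parse_error(text, bar[[2]], "`*` is not allowed in random terms"))
      for (g in groups)
        random <- c(random, list(list(intercept = lhs$intercept,
                                      terms = lhs$terms, group = g)))
    } else if (is.call(e) && identical(e[[1]], as.name("|"))) {
      stop(flmm_parse_error(text, e, "random term must be parenthesized"))
    } else if (is.call(e) && identical(e[[1]], as.name("*"))) {
      stop(flmm_parse_error(text, e,
        "`*` interactions are not supported; expand with `:` explicitly"))
    } else {
      fixed_parts <- c(fixed_parts, list(e))
    }
  }
  fixed <- parse_terms(fixed_parts, text)
  if (!fixed$intercept && !length(fixed$terms))
    stop(flmm_parse_error(text, f[[3]], "model has no fixed effects at all"))
  structure(list(response = response, fixed = fixed, random = random),
            class = "flmm_formula")
}

group_label <- function(group) paste(group, collapse = ":")

term_text <- function(intercept, terms) {
  parts <- c(if (!intercept) "0", terms)
  if (!length(parts)) parts <- "1"
  paste(parts, collapse = " + ")
}

#' @export
format.flmm_formula <- function(x, ...) {
  rhs <- term_text(x$fixed$intercept, x$fixed$terms)
  for (r in x$random)
    rhs <- paste0(rhs, " + (", term_text(r$intercept, r$terms), " | ",
                  group_label(r$group), ")")
  paste(x$response, "~", rhs)
}

#' @export
print.flmm_formula <- function(x, ...) {
  cat("<flmm_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

# first-observed level becomes the reference for dummy coding
relevel_first_observed <- function(x) {
  if (is.character(x)) factor(x, levels = unique(x))
  else if (is.factor(x)) factor(x, levels = unique(as.character(x)))
  else x
}

#' Build fixed- and random-effect design matrices
#'
#' Expands a parsed [flmm_formula()] against a trial table into a dense fixed
#' design `X` and one sparse random-effect block per random group. Numeric
#' covariates are mean-centered under the default policy ("center numeric,
#' never center 0/1 indicators"); categorical covariates are dummy-coded
#' against their first-observed level.
#'
#' @param formula An [flmm_formula()] (or something coercible to one).
#' @param trials A trial table (data frame with `subject`, `session`, `trial`
#'   and covariate columns).
#' @param center `"default"` for the policy above, `TRUE`/`FALSE` to force
#'   centering of all/no numeric covariates, or a character vector naming the
#'   columns to center.
#' @return An object of class `flmm_design`: list with `X`, `Z` (list of
#'   sparse blocks, one per random group, columns ordered level-major),
#'   `groups` (per group: factor, levels, term names), `centers` (named
#'   vector of subtracted means), `frame` (the transformed model frame) and
#'   `lmer_formula` (the equivalent single-column lme4 formula).
#' @export
build_design <- function(formula, trials, center = "default") {
  if (!inherits(formula, "flmm_formula")) formula <- flmm_formula(formula)
  trials <- validate_trial_table(trials)
  # conventional alias: `id` means the subject factor
  if (!("id" %in% names(trials))) trials$id <- trials$subject
  used <- unique(c(formula$fixed$terms,
                   unlist(lapply(formula$random, function(r) c(r$terms, r$group)))))
  used <- unique(unlist(strsplit(used, ":", fixed = TRUE)))
  miss <- setdiff(used, names(trials))
  if (length(miss))
    stop("formula refers to column(s) not in the trial table: ",
         paste(miss, collapse = ", "), call. = FALSE)

  df <- trials
  for (v in used) df[[v]] <- relevel_first_observed(df[[v]])
  for (v in used) {
    if (is.factor(df[[v]]) && nlevels(droplevels(df[[v]])) < 2 &&
        v %in% unlist(strsplit(formula$fixed$terms, ":", fixed = TRUE)))
      stop("categorical covariate '", v, "' has fewer than 2 observed levels",
           call. = FALSE)
  }

  is_indicator <- function(x) is.numeric(x) && all(x %in% c(0, 1))
  if (identical(center, "default")) {
    to_center <- used[vapply(used, function(v)
      is.numeric(df[[v]]) && !is_indicator(df[[v]]), logical(1))]
  } else if (isTRUE(center)) {
    to_center <- used[vapply(used, function(v) is.numeric(df[[v]]), logical(1))]
  } else if (isFALSE(center)) {
    to_center <- character(0)
  } else {
    to_center <- intersect(as.character(center), used)
  }
  grp_vars <- unique(unlist(lapply(formula$random, function(r) r$group)))
  to_center <- setdiff(to_center, grp_vars)
  centers <- numeric(0)
  for (v in to_center) {
    m <- mean(df[[v]], na.rm = TRUE)
    df[[v]] <- df[[v]] - m
    centers[v] <- m
  }

  fx <- stats::as.formula(paste("~", term_text(formula$fixed$intercept,
                                               formula$fixed$terms)))
  X <- stats::model.matrix(fx, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("fixed design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  Z <- list(); groups <- list()
  lmer_rhs <- term_text(formula$fixed$intercept, formula$fixed$terms)
  for (r in formula$random) {
    if (length(r$group) == 1L) {
      f <- relevel_first_observed(df[[r$group]])
      gvar <- r$group
    } else {
      f <- interaction(df[[r$group[1]]], df[[r$group[2]]], drop = TRUE,
                       sep = ":", lex.order = TRUE)
      gvar <- paste0(".grp_", paste(r$group, collapse = "_"))
      df[[gvar]] <- f
    }
    f <- droplevels(factor(f))
    if (nlevels(f) < 2)
      stop("grouping factor '", group_label(r$group),
           "' has a single level", call. = FALSE)
    Tmat <- stats::model.matrix(
      stats::as.formula(paste("~", term_text(r$intercept, r$terms))), df)
    q <- ncol(Tmat); nlev <- nlevels(f); L <- nrow(df)
    j <- (as.integer(f) - 1L) * q
    Zi <- Matrix::sparseMatrix(
      i = rep(seq_len(L), each = q),
      j = as.vector(t(outer(j, seq_len(q), `+`))),
      x = as.vector(t(Tmat)),
      dims = c(L, nlev * q))
    colnames(Zi) <- paste(rep(levels(f), each = q), rep(colnames(Tmat), nlev),
                          sep = "|")
    label <- group_label(r$group)
    Z[[label]] <- Zi
    groups[[label]] <- list(group = r$group, var = gvar, factor = f,
                            levels = levels(f), terms = colnames(Tmat), q = q,
                            Tmat = Tmat)
    lmer_rhs <- paste0(lmer_rhs, " + (", term_text(r$intercept, r$terms),
                       " | ", gvar, ")")
  }

  structure(list(X = X, Z = Z, groups = groups, centers = centers,
                 frame = df, formula = formula,
                 lmer_formula = paste(".y ~", lmer_rhs)),
            class = "flmm_design")
}

#' @export
print.flmm_design <- function(x, ...) {
  cat("<flmm_design> ", format(x$formula), "\n", sep = "")
  cat(sprintf("  X: %d x %d (%s)\n", nrow(x$X), ncol(x$X),
              paste(colnames(x$X), collapse = ", ")))
  for (nm in names(x$Z))
    cat(sprintf("  Z[%s]: %d x %d (%d levels x %d terms)\n", nm,
                nrow(x$Z[[nm]]), ncol(x$Z[[nm]]),
                length(x$groups[[nm]]$levels), x$groups[[nm]]$q))
  if (length(x$centers))
    cat("  centered:", paste(sprintf("%s (-%.4g)", names(x$centers), x$centers),
                             collapse = ", "), "\n")
  invisible(x)
}
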