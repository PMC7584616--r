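#' Fit the AR(1) dichotomized-process model to CGM data
#'
#' The central estimator of the package. Each subject's glucose trace is
#' dichotomized against a glycemic range (TBR by default), the
#' hypoglycemia probability is estimated by the whole-trace fraction
#' `p_hat = t(N)`, and the autocovariance decay `alpha_hat` is estimated
#' by fitting `alpha^tau` to the normalized sample autocovariance with
#' weighted nonlinear least squares ([sample_autocov()], [fit_alpha()]).
#' Subject-level estimates are aggregated into population parameters:
#' by default the mean of `p_hat` and the 95th percentile of `alpha_hat`
#' (the most correlated traces dominate the population error decay, so a
#' high quantile of `alpha` is the conservative population choice).
#'
#' @param x one of: a numeric glucose vector (mg/dL), a [cgm_trace()], a
#'   list of either (a cohort), a data frame with a glucose column and
#'   optional subject column, or — with `range = NULL` — 0/1 indicator
#'   data (vector, list of vectors, or matrix with one trace per column,
#'   e.g. from [simulate_binary()]).
#' @param range a [glycemic_range()] or preset name (`"tbr"`, `"l2h"`,
#'   `"tir"`, `"tar"`); `NULL` means `x` is already dichotomized.
#' @param period_seconds CGM sampling period in seconds (default 300).
#' @param max_lag largest autocovariance lag used in the `alpha` fit
#'   (default 50, about 4 h at 5-min sampling; capped per subject at the
#'   longest contiguous segment minus 2).
#' @param weights weighting scheme for the fit, see [fit_alpha()].
#' @param p_rule,alpha_rule aggregation rules for the population
#'   parameters: a function of a numeric vector, or the defaults `"mean"`
#'   and `"q95"` (95th percentile, linear interpolation between order
#'   statistics).
#' @return an object of class `tbr_ar1` with components `subjects`
#'   (per-subject data frame: `subject`, `n_obs`, `p_hat`, `alpha_hat`,
#'   `sigma2_hat`, `rss`, `degenerate`, `flat`), `autocov` (per-subject
#'   [sample_autocov()] results), `p_h` and `alpha` (population values),
#'   and the settings used. Subjects whose trace never (or always) enters
#'   the range are flagged degenerate — `alpha` is undefined there — and
#'   are excluded from the population aggregation.
#' @examples
#' h <- simulate_binary(0.1, 0.8, N = 5000, nsim = 3, seed = 1)
#' fit <- tbr_ar1(h, range = NULL)
#' coef(fit)
#' predict(fit, days = c(14, 30))
#' @seealso [sd_error()], [predict.tbr_ar1()], [simulate.tbr_ar1()]
#' @export
tbr_ar1 <- function(x, range = "tbr", period_seconds = 300, max_lag = 50,
                    weights = "pairs", p_rule = "mean", alpha_rule = "q95") {
  cl <- match.call()
  range <- if (is.null(range)) NULL else glycemic_range(range)
  cohort <- as_bit_cohort(x, range, period_seconds)
  fits <- lapply(names(cohort), function(id) {
    bits <- cohort[[id]]
    p_hat <- mean(bits)
    n_obs <- length(bits)
    if (p_hat %in% c(0, 1))
      return(list(row = data.frame(subject = id, n_obs = n_obs,
                                   p_hat = p_hat, alpha_hat = NA_real_,
                                   sigma2_hat = 0, rss = NA_real_,
                                   degenerate = TRUE, flat = FALSE),
                  acv = NULL))
    segs <- attr(bits, "segments") %||% n_obs
    ml <- min(max_lag, max(segs) - 2L)
    acv <- sample_autocov(bits, ml)
    fa <- fit_alpha(acv, weights)
    list(row = data.frame(subject = id, n_obs = n_obs, p_hat = p_hat,
                          alpha_hat = fa$alpha,
                          sigma2_hat = p_hat * (1 - p_hat),
                          rss = fa$rss, degenerate = FALSE,
                          flat = fa$flat),
         acv = acv)
  })
  subjects <- do.call(rbind, lapply(fits, `[[`, "row"))
  rownames(subjects) <- NULL
  autocov <- stats::setNames(lapply(fits, `[[`, "acv"), subjects$subject)
  pop <- population_params(subjects$p_hat[!subjects$degenerate],
                           subjects$alpha_hat[!subjects$degenerate],
                           p_rule, alpha_rule)
  structure(list(subjects = subjects, autocov = autocov,
                 p_h = pop[["p_h"]], alpha = pop[["alpha"]],
                 range = range, period_seconds = period_seconds,
                 max_lag = max_lag, weights = weights, call = cl),
            class = "tbr_ar1")
}

#' Aggregate subject-level estimates into population parameters
#'
#' @param p_hats,alphas numeric vectors of non-degenerate subject
#'   estimates (equal length, at least 1).
#' @param p_rule,alpha_rule see [tbr_ar1()].
#' @return named numeric vector `c(p_h, alpha)`.
#' @examples
#' population_params(c(0.02, 0.06), c(0.8, 0.9))  # 0.04, 0.895
#' @export
population_params <- function(p_hats, alphas, p_rule = "mean",
                              alpha_rule = "q95") {
  if (length(p_hats) == 0L || length(p_hats) != length(alphas))
    stop("need at least one non-degenerate subject fit", call. = FALSE)
  pf <- if (is.function(p_rule)) p_rule else
    switch(p_rule, mean = mean, median = stats::median,
           stop("unknown p_rule '", p_rule, "'", call. = FALSE))
  af <- if (is.function(alpha_rule)) alpha_rule else
    switch(alpha_rule,
           q95 = function(a) stats::quantile(a, 0.95, type = 7, names = FALSE),
           mean = mean, median = stats::median,
           stop("unknown alpha_rule '", alpha_rule, "'", call. = FALSE))
  c(p_h = pf(p_hats), alpha = af(alphas))
}

# Normalize the many accepted input shapes to a named list of 0/1 vectors
# (with segments attributes where available).
as_bit_cohort <- function(x, range, period_seconds) {
  dichot <- function(tr) {
    if (is.null(range)) {
      bits <- check_bits(if (inherits(tr, "cgm_trace")) tr$values else tr)
      if (inherits(tr, "cgm_trace")) attr(bits, "segments") <- tr$segments
      bits
    } else {
      dichotomize(tr, range)
    }
  }
  if (is.matrix(x)) {
    if (!is.null(range))
      stop("matrix input is for dichotomized traces; use range = NULL",
           call. = FALSE)
    cohort <- lapply(seq_len(ncol(x)), function(j) check_bits(x[, j]))
    names(cohort) <- colnames(x) %||% sprintf("trace%d", seq_len(ncol(x)))
    return(cohort)
  }
  if (is.data.frame(x)) {
    if (!"glucose" %in% names(x))
      stop("data frame input requires a 'glucose' column", call. = FALSE)
    traces <- if ("subject_id" %in% names(x))
      lapply(split(x$glucose, factor(x$subject_id, levels = unique(x$subject_id))),
             identity)
    else list(subject = x$glucose)
    return(stats::setNames(
      lapply(seq_along(traces), function(i) dichot(traces[[i]])),
      names(traces)))
  }
  if (inherits(x, "cgm_trace")) x <- list(x)
  if (is.numeric(x)) x <- list(x)
  if (!is.list(x) || length(x) == 0L)
    stop("unsupported input type for 'x'", call. = FALSE)
  nm <- names(x)
  if (is.null(nm)) {
    nm <- vapply(seq_along(x), function(i) {
      tr <- x[[i]]
      if (inherits(tr, "cgm_trace")) tr$subject else sprintf("trace%d", i)
    }, character(1))
  }
  stats::setNames(lapply(x, dichot), make.unique(nm))
}

#' @export
print.tbr_ar1 <- function(x, ...) {
  ns <- nrow(x$subjects)
  nd <- sum(x$subjects$degenerate)
  cat("AR(1) dichotomized-process fit",
      if (!is.null(x$range)) sprintf(" (%s)", x$range$label) else "", "\n",
      sep = "")
  cat(sprintf("  subjects: %d (%d degenerate)\n", ns, nd))
  cat(sprintf("  population p_h = %.4g, alpha = %.4g\n", x$p_h, x$alpha))
  cat(sprintf("  sd[e(n)] at 14 days: %.2f%%\n",
              100 * sd_error(round(14 * samples_per_day(x$period_seconds)),
                             x$p_h, x$alpha)))
  invisible(x)
}

#' @export
coef.tbr_ar1 <- function(object, ...) {
  c(p_h = object$p_h, alpha = object$alpha)
}

#' Summarize an AR(1) TBR fit
#'
#' @param object a [tbr_ar1()] fit.
#' @param days trial durations (days) for the planning table.
#' @param ... unused.
#' @return an object of class `summary.tbr_ar1`.
#' @export
summary.tbr_ar1 <- function(object, days = c(7, 14, 30, 60, 120), ...) {
  ok <- !object$subjects$degenerate
  structure(list(
    subjects = object$subjects,
    population = coef(object),
    p_quantiles = stats::quantile(object$subjects$p_hat[ok],
                                  c(0.05, 0.5, 0.95), names = TRUE),
    alpha_quantiles = if (any(ok))
      stats::quantile(object$subjects$alpha_hat[ok],
                      c(0.05, 0.5, 0.95), names = TRUE) else NULL,
    planning = uncertainty_table(days, object$p_h, object$alpha,
                                 object$period_seconds)),
    class = "summary.tbr_ar1")
}

#' @export
print.summary.tbr_ar1 <- function(x, ...) {
  cat("Subjects:\n")
  print(x$subjects, digits = 4)
  cat(sprintf("\nPopulation parameters: p_h = %.4g, alpha = %.4g\n",
              x$population[["p_h"]], x$population[["alpha"]]))
  cat("\nPlanning table (error SD of the time-in-metric estimate):\n")
  tab <- x$planning
  tab$sd_pct <- sprintf("%.1f", tab$sd_pct)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Predict estimation-error uncertainty from a fitted model
#'
#' Evaluates the closed-form error SD at the fit's population parameters
#' for the requested window lengths, optionally with the finite-trial
#' (tail-effect) correction when the full-trial length `N` is given.
#'
#' @param object a [tbr_ar1()] fit.
#' @param days trial durations in days (default `c(7, 14, 30, 60, 120)`);
#'   ignored when `n` is given.
#' @param n window lengths in samples (overrides `days`).
#' @param N optional full-trial length in samples; adds the
#'   tail-affected SD and the relative discrepancy.
#' @param ... unused.
#' @return a data frame with columns `n`, `days`, `sd`, `sd_pct` and,
#'   when `N` is supplied, `sd_vs_full`, `rd`.
#' @export
predict.tbr_ar1 <- function(object, days = c(7, 14, 30, 60, 120), n = NULL,
                            N = NULL, ...) {
  spd <- samples_per_day(object$period_seconds)
  if (is.null(n)) n <- as.integer(round(days * spd))
  out <- data.frame(n = n, days = n / spd,
                    sd = sd_error(n, object$p_h, object$alpha))
  out$sd_pct <- 100 * out$sd
  if (!is.null(N)) {
    out$sd_vs_full <- sd_error_vs_full(n, N, object$p_h, object$alpha)
    out$rd <- relative_discrepancy(n, N, object$p_h, object$alpha)
  }
  out
}

#' Simulate binary hypoglycemia traces from a fitted model
#'
#' Draws stationary correlated Bernoulli traces at the fit's population
#' parameters via the two-state Markov chain (see [simulate_binary()]).
#'
#' @param object a [tbr_ar1()] fit.
#' @param nsim number of traces.
#' @param seed optional master seed.
#' @param N trace length in samples (default 14 days at the fit's
#'   sampling period).
#' @param ... unused.
#' @return an `N x nsim` 0/1 matrix.
#' @export
simulate.tbr_ar1 <- function(object, nsim = 1, seed = NULL,
                             N = round(14 * samples_per_day(object$period_seconds)),
                             ...) {
  simulate_binary(object$p_h, object$alpha, N = N, nsim = nsim, seed = seed)
}

#' Autocovariance-fit residuals
#'
#' Residuals of the exponential decay fit: normalized sample
#' autocovariance minus `alpha_hat^tau`, per subject.
#'
#' @param object a [tbr_ar1()] fit.
#' @param ... unused.
#' @return a named list of per-subject residual vectors (degenerate
#'   subjects yield `NULL`), or the bare vector for a single subject.
#' @export
residuals.tbr_ar1 <- function(object, ...) {
  res <- lapply(seq_len(nrow(object$subjects)), function(i) {
    acv <- object$autocov[[i]]
    if (is.null(acv)) return(NULL)
    acv$ncov - object$subjects$alpha_hat[i]^acv$lag
  })
  names(res) <- object$subjects$subject
  if (length(res) == 1L) res[[1]] else res
}

#' Plot an AR(1) TBR fit
#'
#' `which = 1` shows the normalized sample autocovariance of each subject
#' with the fitted exponential decay; `which = 2` shows the predicted
#' error-SD curve on log-log axes.
#'
#' @param x a [tbr_ar1()] fit.
#' @param which subset of `1:2`.
#' @param max_days largest duration (days) for the error curve.
#' @param ... passed to the underlying plot calls.
#' @return invisibly, `x`.
#' @export
plot.tbr_ar1 <- function(x, which = 1:2, max_days = 120, ...) {
  ok <- which(!x$subjects$degenerate)
  if (1 %in% which && length(ok)) {
    acv1 <- x$autocov[[ok[1]]]
    graphics::plot(acv1$lag, acv1$ncov, pch = 16, col = "grey40",
                   xlab = "lag (samples)",
                   ylab = "normalized autocovariance",
                   main = "Autocovariance and fitted AR(1) decay", ...)
    for (i in ok) {
      acv <- x$autocov[[i]]
      graphics::points(acv$lag, acv$ncov, pch = 16,
                       col = grDevices::grey(0.7, alpha = 0.5))
      graphics::lines(acv$lag, x$subjects$alpha_hat[i]^acv$lag,
                      col = "steelblue")
    }
  }
  if (2 %in% which) {
    spd <- samples_per_day(x$period_seconds)
    n <- unique(round(exp(seq(log(1), log(max_days * spd), length.out = 200))))
    graphics::plot(n, sd_error(n, x$p_h, x$alpha), type = "l", log = "xy",
                   col = "steelblue", lwd = 2,
                   xlab = "window length n (samples)",
                   ylab = "sd[e(n)]",
                   main = "Predicted estimation-error SD", ...)
  }
  invisible(x)
}
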