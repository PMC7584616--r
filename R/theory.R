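#' Validate AR(1) process parameters
#'
#' @param p_h hypoglycemia probability, in `[0, 1]`.
#' @param alpha autocovariance decay parameter, in `[0, 1)`.
#' @return invisibly, `c(p_h, alpha)`.
#' @keywords internal
check_ar1 <- function(p_h, alpha) {
  if (!is.numeric(p_h) || length(p_h) != 1L || is.na(p_h) ||
      p_h < 0 || p_h > 1)
    stop("'p_h' must be a single probability in [0, 1]", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha >= 1)
    stop("'alpha' must be a single value in [0, 1); got ",
         format(alpha), call. = FALSE)
  invisible(c(p_h = p_h, alpha = alpha))
}

# alpha^n without spurious NaN for alpha = 0; underflow to 0 is the correct
# asymptote for large n.
alpha_pow <- function(alpha, n) {
  if (alpha == 0) return(ifelse(n == 0, 1, 0))
  exp(n * log(alpha))
}

#' Standard deviation of the time-in-metric estimation error
#'
#' For a stationary binary process `h_k` with success probability `p_h` and
#' AR(1) autocovariance `cov[h_k, h_l] = alpha^|l-k| p_h (1 - p_h)`, the
#' prefix-mean estimator `t(n)` of `p_h` has estimation error
#' `e(n) = t(n) - p_h` with standard deviation
#' \deqn{sd[e(n)] = \sqrt{\frac{p_h(1-p_h)}{n}\Big(1 + \frac{2\alpha}{1-\alpha}
#'   + \frac{2\alpha}{n}\frac{\alpha^n - 1}{(1-\alpha)^2}\Big)}.}
#' For `alpha = 0` this reduces to the binomial standard error
#' `sqrt(p_h (1 - p_h) / n)`.
#'
#' @param n number of samples in the estimation window (vectorized,
#'   positive integers).
#' @inheritParams check_ar1
#' @return numeric vector of standard deviations (dimensionless fractions,
#'   not percent), one per element of `n`.
#' @examples
#' sd_error(4032, p_h = 0.043, alpha = 0.917)  # 14 days at 5-min sampling
#' sd_error(100, 0.5, 0)                       # binomial: 0.05
#' @seealso [sd_error_vs_full()] for the finite-trial version,
#'   [min_duration()] for planning.
#' @export
sd_error <- function(n, p_h, alpha) {
  check_ar1(p_h, alpha)
  if (any(!is.finite(n)) || any(n < 1) || any(n != floor(n)))
    stop("'n' must contain positive integers", call. = FALSE)
  sigma2 <- p_h * (1 - p_h)
  if (sigma2 == 0) return(rep(0, length(n)))
  bracket <- 1 + 2 * alpha / (1 - alpha) +
    (2 * alpha / n) * (alpha_pow(alpha, n) - 1) / (1 - alpha)^2
  sqrt(pmax(sigma2 / n * bracket, 0))
}

#' Error standard deviation when the truth is replaced by the full-trial mean
#'
#' On real data the true `p_h` is unknown and is approximated by the
#' whole-trial estimate `t(N)`, so what is actually measured is
#' `e(n; N) = t(n) - t(N)`. Its standard deviation,
#' \deqn{sd[t(n)-t(N)] = \sqrt{var[t(N)] + \frac{N-2n}{N} var[t(n)]
#'   - \frac{2\sigma^2\alpha}{nN}\frac{(1-\alpha^n)(1-\alpha^{N-n})}{(1-\alpha)^2}},}
#' decreases faster than the true `sd[e(n)]` as `n` approaches `N` and is
#' exactly zero at `n = N` — the "tail effect". As `N` grows with `n` fixed
#' it converges to [sd_error()].
#'
#' @param n estimation-window length in samples (vectorized).
#' @param N full-trial length in samples, `n <= N`.
#' @inheritParams check_ar1
#' @return numeric vector of standard deviations (fractions). Tiny negative
#'   radicands arising from floating-point cancellation near `n = N` are
#'   clamped to zero.
#' @examples
#' sd_error_vs_full(8640, 54000, 0.043, 0.917)
#' sd_error_vs_full(1000, 1000, 0.043, 0.917)  # 0 at n = N
#' @export
sd_error_vs_full <- function(n, N, p_h, alpha) {
  check_ar1(p_h, alpha)
  if (length(N) != 1L || !is.finite(N) || N < 1 || N != floor(N))
    stop("'N' must be a single positive integer", call. = FALSE)
  if (any(n > N))
    stop("'n' must not exceed the full-trial length 'N'", call. = FALSE)
  sigma2 <- p_h * (1 - p_h)
  if (sigma2 == 0) return(rep(0, length(n)))
  var_n <- sd_error(n, p_h, alpha)^2
  var_N <- sd_error(N, p_h, alpha)^2
  cross <- 2 * sigma2 * (alpha / (n * N)) *
    (1 - alpha_pow(alpha, n)) * (1 - alpha_pow(alpha, N - n)) /
    (1 - alpha)^2
  v <- var_N + (N - 2 * n) / N * var_n - cross
  sqrt(pmax(v, 0))
}

#' Relative discrepancy caused by the tail effect
#'
#' The signed ratio `RD = (sd[e(n;N)] - sd[e(n)]) / sd[e(n)]` quantifying how
#' much the finite-trial error SD underestimates the true error SD. It is
#' never positive for valid AR(1) parameters and equals `-1` at `n = N`.
#'
#' @inheritParams sd_error_vs_full
#' @return numeric vector of signed dimensionless ratios in `[-1, 0]`.
#' @examples
#' relative_discrepancy(8640, 54000, 0.043, 0.917)  # about -0.0835
#' @export
relative_discrepancy <- function(n, N, p_h, alpha) {
  denom <- sd_error(n, p_h, alpha)
  if (any(denom == 0))
    stop("relative discrepancy undefined: sd_error is zero at these parameters",
         call. = FALSE)
  (sd_error_vs_full(n, N, p_h, alpha) - denom) / denom
}

#' Minimum recording duration achieving a target uncertainty
#'
#' Finds the smallest window length `n` (and the corresponding number of
#' days) such that the TBR estimation-error standard deviation
#' [sd_error()] does not exceed `target_sd`. The search brackets the target
#' by doubling, bisects on it, then verifies the returned `n` by a local
#' linear scan; the correction term in the error formula makes the curve
#' non-monotone at very small `n`, so the candidate is always checked
#' against its neighbours.
#'
#' @param target_sd desired error standard deviation, as a dimensionless
#'   fraction in `(0, sqrt(p_h(1-p_h))]`.
#' @inheritParams check_ar1
#' @param period_seconds CGM sampling period in seconds (default 300,
#'   i.e. 5 minutes, 288 samples per day).
#' @return a list with components `n` (samples) and `days`.
#' @examples
#' min_duration(0.015, p_h = 0.043, alpha = 0.917)
#' @export
min_duration <- function(target_sd, p_h, alpha, period_seconds = 300) {
  check_ar1(p_h, alpha)
  if (!is.numeric(target_sd) || length(target_sd) != 1L || target_sd <= 0)
    stop("'target_sd' must be a single positive fraction", call. = FALSE)
  spd <- samples_per_day(period_seconds)
  if (sd_error(1, p_h, alpha) <= target_sd)
    return(list(n = 1L, days = 1 / spd))
  # exponential bracketing: find hi with sd <= target
  hi <- 2L
  while (sd_error(hi, p_h, alpha) > target_sd) {
    hi <- hi * 2L
    if (hi > .Machine$integer.max / 2)
      stop("target uncertainty unreachable within integer range", call. = FALSE)
  }
  lo <- hi %/% 2L
  # bisection: invariant sd(lo) > target >= sd(hi)
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (sd_error(mid, p_h, alpha) > target_sd) lo <- mid else hi <- mid
  }
  # local verification against non-monotonicity
  cand <- hi
  while (cand > 1L && sd_error(cand - 1L, p_h, alpha) <= target_sd)
    cand <- cand - 1L
  stopifnot(sd_error(cand, p_h, alpha) <= target_sd)
  list(n = cand, days = cand / spd)
}

samples_per_day <- function(period_seconds) {
  if (!is.numeric(period_seconds) || length(period_seconds) != 1L ||
      period_seconds <= 0)
    stop("'period_seconds' must be a single positive number", call. = FALSE)
  86400 / period_seconds
}

#' Uncertainty of the TBR estimate for a set of trial durations
#'
#' Tabulates the estimation-error standard deviation for monitoring periods
#' expressed in days, the usual planning view: each duration is converted to
#' a sample count `n` and the error SD is reported in percent.
#'
#' @param days numeric vector of trial durations in days.
#' @inheritParams min_duration
#' @return a data frame with columns `days`, `n` (samples, rounded to the
#'   nearest integer) and `sd_pct` (`100 *` [sd_error()]).
#' @examples
#' uncertainty_table(c(14, 30, 60, 120), p_h = 0.043, alpha = 0.917)
#' @export
uncertainty_table <- function(days, p_h, alpha, period_seconds = 300) {
  check_ar1(p_h, alpha)
  if (length(days) == 0L)
    return(data.frame(days = numeric(), n = integer(), sd_pct = numeric()))
  if (any(!is.finite(days)) || any(days <= 0))
    stop("'days' must be positive and finite", call. = FALSE)
  n <- as.integer(round(days * samples_per_day(period_seconds)))
  data.frame(days = days, n = n,
             sd_pct = 100 * sd_error(n, p_h, alpha))
}
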