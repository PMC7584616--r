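#' Sliding-window estimation errors of a single trace
#'
#' On real data the true `p_h` is unknown, so the error of a length-`n`
#' window is measured against the whole-trace estimate:
#' `e(n; i) = t(n; i) - t(N)`, where `t(n; i)` is the mean of the window
#' starting at sample `i`. All `M = N - n + 1` overlapping windows
#' (stride 1) are used; window means are computed from prefix sums, which
#' is value-identical to the naive loop at O(N) cost.
#'
#' @param bits 0/1 indicator vector of length `N`.
#' @param n window length, `1 <= n <= N`.
#' @return numeric vector of `N - n + 1` window errors.
#' @examples
#' window_errors(c(1, 0, 0, 1), 2)  # 0 -0.5 0
#' @export
window_errors <- function(bits, n) {
  bits <- check_bits(bits)
  N <- length(bits)
  if (length(n) != 1L || n < 1 || n > N || n != floor(n))
    stop("'n' must be an integer in [1, N]", call. = FALSE)
  csum <- c(0, cumsum(bits))
  wmeans <- (csum[(n + 1):(N + 1)] - csum[1:(N - n + 1)]) / n
  wmeans - mean(bits)
}

#' Pooled empirical error curve over a cohort
#'
#' For each window length `n`, pools the sliding-window errors
#' [window_errors()] of every trace (each trace uses its own whole-trace
#' mean) and summarizes them with the root-mean-square about zero,
#' `SD[e(n)] = sqrt(sum_i e(n;i)^2 / (M - 1))`, where
#' `M = sum_subjects (N_subject - n + 1)`. The SD is deliberately *not*
#' centered about the pooled sample mean — the mean error is reported
#' separately and should be near zero for an unbiased estimator. When
#' `p_h`/`alpha` are supplied, the analytic predictions are attached: the
#' true error SD ([sd_error()]) and, for cohorts of equal trace length,
#' the tail-effect-corrected SD ([sd_error_vs_full()]).
#'
#' @param cohort a list of 0/1 vectors, or a matrix with one trace per
#'   column (e.g. from [simulate_binary()]).
#' @param n_values window lengths, each at most the shortest trace.
#' @inheritParams check_ar1
#' @param stride window stride in samples (default 1 = all overlapping
#'   windows; larger strides subsample windows for speed).
#' @return a data frame of class `error_curve` with columns `n`, `M`,
#'   `mean_error`, `sd` and, when parameters are given, `theorem1_sd` and
#'   `theorem2_sd`.
#' @examples
#' h <- simulate_binary(0.3, 0.5, N = 500, nsim = 20, seed = 1)
#' cohort_error_curve(h, c(1, 10, 50), p_h = 0.3, alpha = 0.5)
#' @export
cohort_error_curve <- function(cohort, n_values, p_h = NULL, alpha = NULL,
                               stride = 1) {
  if (is.matrix(cohort))
    cohort <- lapply(seq_len(ncol(cohort)), function(j) cohort[, j])
  if (!is.list(cohort) || length(cohort) == 0L)
    stop("'cohort' must be a non-empty list of 0/1 traces or a matrix",
         call. = FALSE)
  lens <- vapply(cohort, length, integer(1))
  n_values <- sort(unique(as.integer(n_values)))
  if (any(n_values < 1) || any(n_values > min(lens)))
    stop("'n_values' must lie in [1, shortest trace length]", call. = FALSE)
  if (stride < 1 || stride != floor(stride))
    stop("'stride' must be a positive integer", call. = FALSE)
  rows <- lapply(n_values, function(n) {
    errs <- unlist(lapply(cohort, function(b) {
      e <- window_errors(b, n)
      e[seq(1, length(e), by = stride)]
    }), use.names = FALSE)
    M <- length(errs)
    data.frame(n = n, M = M,
               mean_error = mean(errs),
               sd = if (M >= 2) sqrt(sum(errs^2) / (M - 1)) else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (!is.null(p_h) && !is.null(alpha)) {
    out$theorem1_sd <- sd_error(out$n, p_h, alpha)
    out$theorem2_sd <- if (length(unique(lens)) == 1L)
      sd_error_vs_full(out$n, lens[1], p_h, alpha) else NA_real_
  }
  structure(out, class = c("error_curve", "data.frame"),
            source = "empirical", n_subjects = length(cohort))
}

#' Largest window keeping the tail-effect bias within budget
#'
#' The tail effect systematically shrinks the measured error SD as `n`
#' approaches the trial length `N`. Given an acceptable relative
#' underestimation `rd_budget` (e.g. 0.11), returns the largest `n` such
#' that `|relative_discrepancy(n, N)| <= rd_budget`. For the population
#' parameters of a typical CGM cohort this lands near `n = 0.2 N` at an
#' 11% budget.
#'
#' @param N trial length in samples.
#' @param rd_budget acceptable discrepancy magnitude, positive fraction.
#' @inheritParams check_ar1
#' @return the largest admissible `n` (integer); `0` with attribute
#'   `unreachable = TRUE` when even `n = 1` exceeds the budget.
#' @examples
#' max_window_fraction(43200, 0.11, 0.043, 0.917) / 43200  # about 0.2
#' @export
max_window_fraction <- function(N, rd_budget, p_h, alpha) {
  check_ar1(p_h, alpha)
  if (rd_budget <= 0) stop("'rd_budget' must be positive", call. = FALSE)
  ok <- function(n) abs(relative_discrepancy(n, N, p_h, alpha)) <= rd_budget
  if (!ok(1)) return(structure(0L, unreachable = TRUE))
  if (ok(N)) return(as.integer(N))
  # |RD| grows with n; bisect the boundary, then verify linearly
  lo <- 1L; hi <- as.integer(N)          # ok(lo), !ok(hi)
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (ok(mid)) lo <- mid else hi <- mid
  }
  while (lo < N && ok(lo + 1L)) lo <- lo + 1L
  lo
}
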