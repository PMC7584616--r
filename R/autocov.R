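#' Sample autocovariance of a dichotomized trace
#'
#' Computes, for lags `tau = 0..max_lag`,
#' \deqn{COV_h(\tau) = \frac{1}{N-\tau-1}\sum_{k=1}^{N-\tau}
#'   (h_k - \bar h)(h_{k+\tau} - \bar h)}
#' with the global mean subtracted in both factors, so that `COV_h(0)` is
#' the usual `(N-1)`-denominator sample variance. When the input carries a
#' `segments` attribute (contiguous runs separated by recording gaps), the
#' cross-product sums are accumulated per segment with the pooled mean —
#' lags never bridge a gap — and the denominator generalizes to
#' `sum_s (N_s - tau) - 1`.
#'
#' @param bits 0/1 indicator vector, optionally with a `segments`
#'   attribute of contiguous-run lengths summing to `length(bits)`.
#' @param max_lag largest lag, must satisfy `max_lag < N - 1` in the
#'   longest segment.
#' @return an object of class `cgm_autocov`: a data frame with columns
#'   `lag`, `cov` and `ncov` (normalized by `cov[1]` at lag 0), with
#'   attributes `n_obs`, `mean` and `npairs` (contributing pairs per lag,
#'   used as default weights by [fit_alpha()]).
#' @examples
#' sample_autocov(c(1, 0, 0, 1), max_lag = 1)
#' @export
sample_autocov <- function(bits, max_lag) {
  segments <- attr(bits, "segments")
  bits <- check_bits(bits)
  N <- length(bits)
  if (is.null(segments)) segments <- N
  if (sum(segments) != N || any(segments < 1))
    stop("'segments' must be positive run lengths summing to length(bits)",
         call. = FALSE)
  if (length(max_lag) != 1L || max_lag < 0 || max_lag != floor(max_lag))
    stop("'max_lag' must be a non-negative integer", call. = FALSE)
  if (max_lag >= max(segments) - 1)
    stop("'max_lag' must be smaller than the longest segment minus 1",
         call. = FALSE)
  m <- mean(bits)
  centered <- bits - m
  starts <- cumsum(c(1L, segments[-length(segments)]))
  lags <- 0:max_lag
  sums <- numeric(max_lag + 1L)
  npairs <- numeric(max_lag + 1L)
  for (s in seq_along(segments)) {
    seg <- centered[starts[s]:(starts[s] + segments[s] - 1L)]
    Ns <- length(seg)
    for (tau in lags) {
      if (Ns - tau < 1L) next
      idx <- seq_len(Ns - tau)
      sums[tau + 1L] <- sums[tau + 1L] + sum(seg[idx] * seg[idx + tau])
      npairs[tau + 1L] <- npairs[tau + 1L] + (Ns - tau)
    }
  }
  cov <- sums / (npairs - 1)
  if (cov[1] <= 0)
    stop("degenerate series: zero variance, autocovariance normalization undefined",
         call. = FALSE)
  out <- data.frame(lag = lags, cov = cov, ncov = cov / cov[1])
  structure(out, class = c("cgm_autocov", "data.frame"),
            n_obs = N, mean = m, npairs = npairs)
}

#' Fit the AR(1) decay parameter to a normalized autocovariance
#'
#' Estimates `alpha` by weighted nonlinear least squares: minimizes
#' `sum_tau w_tau (alpha^tau - ncov_tau)^2` over `alpha` in
#' `[0, 0.999999]`. Default weights are the number of contributing pairs
#' at each lag (`N - tau` for a gap-free trace), reflecting the growing
#' variance of the autocovariance estimate at long lags; `"equal"` weights
#' are available. The objective is minimized by a deterministic coarse
#' grid search refined with [stats::optimize()], so the fit is bounded and
#' reproducible.
#'
#' @param acv a `cgm_autocov` from [sample_autocov()], or a data frame
#'   with columns `lag` and `ncov`.
#' @param weights `"pairs"` (default) or `"equal"`, or a numeric vector of
#'   per-lag weights.
#' @return a list with components `alpha`, `rss` (weighted residual sum of
#'   squares), `lags` (lags used) and `flat` (`TRUE` when every normalized
#'   covariance at `tau >= 1` is non-positive, in which case `alpha = 0`
#'   is returned with a warning).
#' @examples
#' acv <- data.frame(lag = 0:50, ncov = 0.86^(0:50))
#' fit_alpha(acv)$alpha
#' @export
fit_alpha <- function(acv, weights = c("pairs", "equal")) {
  if (!is.data.frame(acv) || !all(c("lag", "ncov") %in% names(acv)))
    stop("'acv' must have columns 'lag' and 'ncov'", call. = FALSE)
  lags <- acv$lag
  y <- acv$ncov
  if (length(lags) < 3L)
    stop("need at least 3 lags to fit alpha", call. = FALSE)
  if (is.numeric(weights)) {
    if (length(weights) != length(lags))
      stop("numeric 'weights' must match the number of lags", call. = FALSE)
    w <- weights
  } else {
    weights <- match.arg(weights)
    w <- if (weights == "pairs") {
      np <- attr(acv, "npairs")
      if (is.null(np)) attr(acv, "n_obs") %||% max(lags) + 1 - lags else np
    } else rep(1, length(lags))
  }
  if (all(y[lags >= 1] <= 0)) {
    warning("no positive autocovariance beyond lag 0; returning alpha = 0",
            call. = FALSE)
    return(list(alpha = 0, rss = sum(w * (ifelse(lags == 0, 1, 0) - y)^2),
                lags = lags, flat = TRUE))
  }
  obj <- function(a) sum(w * (a^lags - y)^2)
  upper <- 0.999999
  grid <- seq(0, upper, length.out = 2001L)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(obj, lower = lo, upper = hi, tol = 1e-12)
  # keep the better of the grid point and the refined optimum
  if (vals[i] < opt$objective) {
    alpha <- grid[i]; rss <- vals[i]
  } else {
    alpha <- opt$minimum; rss <- opt$objective
  }
  list(alpha = alpha, rss = rss, lags = lags, flat = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
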