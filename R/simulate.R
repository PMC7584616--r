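#' Stationary parameters of a two-state hypoglycemia Markov chain
#'
#' For the time-homogeneous chain with stay probabilities `p00` (state 0,
#' no hypoglycemia) and `p11` (state 1, hypoglycemia), the stationary
#' probability of state 1 and the lag-1 autocovariance decay of the
#' resulting binary process are
#' `p_h = (p00 - 1) / (p00 + p11 - 2)` and `alpha = p00 + p11 - 1`
#' (the two-term closed form `p11 (p00 + p11 - 2)/(p11 - 1) -
#' (p00 - 1)/(p11 - 1)` reduces algebraically to this and is singular at
#' `p11 = 1`, so the reduced form is used).
#'
#' @param p00 probability of staying in state 0, in `[0, 1]`.
#' @param p11 probability of staying in state 1, in `[0, 1]`.
#' @return named numeric vector `c(p_h, alpha)`.
#' @examples
#' stationary_params(0.5, 0.5)  # p_h = 0.5, alpha = 0
#' stationary_params(1, 0)      # p_h = 0
#' @export
stationary_params <- function(p00, p11) {
  check_chain(p00, p11)
  if (p00 == 1 && p11 == 1)
    stop("degenerate chain: p00 = p11 = 1 has no unique stationary law",
         call. = FALSE)
  c(p_h = (p00 - 1) / (p00 + p11 - 2), alpha = p00 + p11 - 1)
}

check_chain <- function(p00, p11) {
  for (p in list(p00 = p00, p11 = p11))
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("transition probabilities must be single values in [0, 1]",
           call. = FALSE)
  invisible(NULL)
}

#' Markov-chain transition probabilities realizing target (p_h, alpha)
#'
#' Inverts the stationary relations of [stationary_params()]:
#' `p00 = 1 - p_h (1 - alpha)` and `p11 = alpha + p_h (1 - alpha)`.
#' Only non-negative correlation is representable here (`alpha` in
#' `[0, 1)`), matching the AR(1) structure assumed for dichotomized CGM.
#'
#' @inheritParams check_ar1
#' @return named numeric vector `c(p00, p11)` satisfying the round-trip
#'   identity `stationary_params(chain_from_targets(p_h, alpha)) ==
#'   c(p_h, alpha)` to machine precision.
#' @examples
#' chain_from_targets(0.043, 0.917)
#' @export
chain_from_targets <- function(p_h, alpha) {
  check_ar1(p_h, alpha)
  c(p00 = 1 - p_h * (1 - alpha), p11 = alpha + p_h * (1 - alpha))
}

#' Simulate correlated Bernoulli hypoglycemia processes
#'
#' Generates stationary binary traces with exact target success
#' probability `p_h` and AR(1) autocovariance decay `alpha`, via the
#' two-state Markov chain of [chain_from_targets()]. The initial state of
#' each trace is drawn from the stationary distribution, so the process is
#' stationary from the first sample and no burn-in is needed (an optional
#' `burn_in` discards leading samples anyway). Replicates use independent
#' substreams spawned from the master seed, so trace `i` does not depend
#' on how many replicates are requested before it.
#'
#' @inheritParams check_ar1
#' @param N trace length in samples.
#' @param nsim number of replicate traces.
#' @param seed optional integer master seed; identical seeds give
#'   identical output.
#' @param burn_in leading samples to simulate and discard (default 0).
#' @return an `N x nsim` integer matrix of 0/1 values, one replicate per
#'   column.
#' @examples
#' h <- simulate_binary(0.3, 0.8, N = 1000, nsim = 5, seed = 1)
#' colMeans(h)
#' @export
simulate_binary <- function(p_h, alpha, N, nsim = 1, seed = NULL,
                            burn_in = 0) {
  check_ar1(p_h, alpha)
  if (length(N) != 1L || N < 1 || N != floor(N))
    stop("'N' must be a single positive integer", call. = FALSE)
  if (length(nsim) != 1L || nsim < 1 || nsim != floor(nsim))
    stop("'nsim' must be a single positive integer", call. = FALSE)
  if (burn_in < 0) stop("'burn_in' must be non-negative", call. = FALSE)
  ch <- chain_from_targets(p_h, alpha)
  if (!is.null(seed)) set.seed(seed)
  substreams <- sample.int(.Machine$integer.max, nsim)
  total <- N + burn_in
  out <- matrix(0L, nrow = N, ncol = nsim)
  for (i in seq_len(nsim)) {
    set.seed(substreams[i])
    s <- chain_scan(ch[["p00"]], ch[["p11"]], p_h, total)
    out[, i] <- s[(burn_in + 1L):total]
  }
  out
}

# One chain trajectory of length N, vectorized.
# With alpha >= 0 the transition thresholds nest (1 - p00 <= p11), so for a
# shared uniform u_k: the move-to-1 event a_k = {u_k < 1 - p00} forces state
# 1, u_k >= p11 forces state 0, and the band between carries the previous
# state forward. The trajectory is then a[j_k] where j_k is the most recent
# non-carry position, computable with cummax.
chain_scan <- function(p00, p11, p_h, N) {
  s1 <- as.integer(stats::runif(1) < p_h)
  if (N == 1L) return(s1)
  u <- stats::runif(N - 1L)
  a <- u < (1 - p00)          # forced 1
  carry <- !a & (u < p11)     # keep previous state
  j <- cummax(ifelse(carry, 0L, seq_len(N - 1L)))
  tail_states <- ifelse(j == 0L, s1, as.integer(a[pmax(j, 1L)]))
  c(s1, tail_states)
}

#' Monte-Carlo standard deviation of the estimation error
#'
#' Replicated simulation of the error curve: generates `nsim` traces of
#' length `N` at the target parameters, computes the prefix-mean estimate
#' `t(n; i)` and error `e(n; i) = t(n; i) - p_h` against the *known*
#' `p_h`, and summarizes each window length by
#' \deqn{SD[e(n)] = \sqrt{\frac{1}{N_{rep}-1}\sum_i e(n;i)^2}.}
#'
#' @inheritParams simulate_binary
#' @param n_values window lengths to evaluate, each `<= N`.
#' @return a data frame of class `error_curve` with columns `n` and `sd`,
#'   and attributes `source = "monte_carlo"`, `p_h`, `alpha`, `nsim`.
#' @examples
#' monte_carlo_sd_curve(0.3, 0.5, N = 200, nsim = 100,
#'                      n_values = c(1, 10, 100), seed = 1)
#' @export
monte_carlo_sd_curve <- function(p_h, alpha, N, nsim, n_values,
                                 seed = NULL) {
  if (nsim < 2)
    stop("'nsim' must be at least 2 (SD denominator is nsim - 1)",
         call. = FALSE)
  n_values <- sort(unique(as.integer(n_values)))
  if (any(n_values < 1) || any(n_values > N))
    stop("'n_values' must lie in [1, N]", call. = FALSE)
  h <- simulate_binary(p_h, alpha, N = N, nsim = nsim, seed = seed)
  csum <- matrix(apply(h, 2, cumsum), nrow = N)  # N x nsim prefix sums
  sd <- vapply(n_values, function(n) {
    e <- csum[n, ] / n - p_h
    sqrt(sum(e^2) / (nsim - 1))
  }, numeric(1))
  structure(data.frame(n = n_values, sd = sd),
            class = c("error_curve", "data.frame"),
            source = "monte_carlo", p_h = p_h, alpha = alpha, nsim = nsim)
}
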