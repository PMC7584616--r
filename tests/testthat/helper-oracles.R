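# Independent oracles: brute-force expansions of the covariance structure,
# naive reimplementations of the sliding-window and autocovariance
# estimators, and the two-term closed form of the chain's decay parameter.

# var[t(n)] as the full double sum over the n x n AR(1) covariance matrix
oracle_sd_error <- function(n, p_h, alpha) {
  s2 <- p_h * (1 - p_h)
  K <- outer(1:n, 1:n, function(k, l) s2 * alpha^abs(k - l))
  sqrt(sum(K) / n^2)
}

# var[t(n) - t(N)] as a quadratic form w'Kw with w the contrast of the two
# prefix means over the N x N covariance matrix
oracle_sd_vs_full <- function(n, N, p_h, alpha) {
  s2 <- p_h * (1 - p_h)
  K <- outer(1:N, 1:N, function(k, l) s2 * alpha^abs(k - l))
  w <- rep(-1 / N, N)
  w[1:n] <- w[1:n] + 1 / n
  sqrt(max(drop(t(w) %*% K %*% w), 0))
}

# sliding-window errors by explicit loop
naive_window_errors <- function(bits, n) {
  N <- length(bits)
  p_hat <- mean(bits)
  vapply(1:(N - n + 1), function(i) mean(bits[i:(i + n - 1)]) - p_hat,
         numeric(1))
}

# sample autocovariance exactly as printed: global mean in both factors,
# denominator N - tau - 1
naive_autocov <- function(bits, max_lag) {
  N <- length(bits)
  m <- mean(bits)
  vapply(0:max_lag, function(tau) {
    sum((bits[1:(N - tau)] - m) * (bits[(1 + tau):N] - m)) / (N - tau - 1)
  }, numeric(1))
}

# the paper's two-term closed form for the chain's decay parameter
# (singular at p11 = 1)
alpha_printed <- function(p00, p11) {
  p11 * (p00 + p11 - 2) / (p11 - 1) - (p00 - 1) / (p11 - 1)
}

ar1_param_grid <- expand.grid(p_h = c(0.1, 0.3, 0.5),
                              alpha = c(0, 0.3, 0.8, 0.95))
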