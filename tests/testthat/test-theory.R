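test_that("error-SD formula matches the brute-force covariance double sum", {
  for (r in seq_len(nrow(ar1_param_grid))) {
    p <- ar1_param_grid$p_h[r]
    a <- ar1_param_grid$alpha[r]
    for (n in c(1:10, 20, 35, 50)) {
      expect_equal(sd_error(n, p, a), oracle_sd_error(n, p, a),
                   tolerance = 1e-10,
                   info = sprintf("n=%d p=%g a=%g", n, p, a))
    }
  }
})

test_that("error-SD formula has the right limits and degenerate behaviour", {
  # single sample: bracket collapses, sd = sqrt(p(1-p)) exactly
  expect_equal(sd_error(1, 0.3, 0.8), sqrt(0.21))
  # no correlation: binomial standard error
  n <- c(1, 10, 100, 1e4)
  expect_equal(sd_error(n, 0.2, 0), sqrt(0.2 * 0.8 / n))
  # degenerate probabilities give a zero-error process
  expect_identical(sd_error(c(5, 50), 0, 0.9), c(0, 0))
  expect_identical(sd_error(10, 1, 0.5), 0)
  # huge n: no overflow/NaN, alpha^n underflow is the correct asymptote
  big <- sd_error(10^(3:6), 0.043, 0.917)
  expect_true(all(is.finite(big)))
  expect_true(all(diff(big) < 0))
  expect_lt(big[4], 1e-3)
  # eventually non-increasing and vanishing
  curve <- sd_error(10:5000, 0.3, 0.95)
  expect_true(all(diff(curve) <= 0))
})

test_that("invalid parameters are rejected", {
  expect_error(sd_error(10, 0.3, 1), "alpha")
  expect_error(sd_error(10, 0.3, -0.2), "alpha")
  expect_error(sd_error(10, 1.4, 0.5), "p_h")
  expect_error(sd_error(0, 0.3, 0.5), "positive integers")
  expect_error(sd_error_vs_full(10, 5, 0.3, 0.5), "must not exceed")
})

test_that("finite-trial error SD matches the quadratic-form oracle", {
  Ns <- c(1, 2, 3, 4, 5, 8, 13, 21, 30, 40)
  for (r in seq_len(nrow(ar1_param_grid))) {
    p <- ar1_param_grid$p_h[r]
    a <- ar1_param_grid$alpha[r]
    for (N in Ns) for (n in 1:N) {
      got <- sd_error_vs_full(n, N, p, a)
      want <- oracle_sd_vs_full(n, N, p, a)
      if (want > 1e-12) {
        expect_equal(got, want, tolerance = 1e-10,
                     info = sprintf("n=%d N=%d p=%g a=%g", n, N, p, a))
      } else {
        expect_lt(got, 1e-7)
      }
    }
  }
})

test_that("finite-trial SD vanishes at n = N and converges to the true SD", {
  expect_equal(sd_error_vs_full(1000, 1000, 0.043, 0.917), 0)
  expect_equal(sd_error_vs_full(7, 7, 0.3, 0.5), 0)
  # N -> infinity with n fixed recovers the known-truth formula
  n <- 10
  gap <- abs(sd_error_vs_full(n, 1e4 * n, 0.3, 0.8) / sd_error(n, 0.3, 0.8) - 1)
  expect_lt(gap, 1e-3)
})

test_that("relative discrepancy is a systematic underestimation", {
  for (r in seq_len(nrow(ar1_param_grid))) {
    p <- ar1_param_grid$p_h[r]
    a <- ar1_param_grid$alpha[r]
    N <- 300
    rd <- relative_discrepancy(c(1, 10, 60, 150, 300), N, p, a)
    expect_true(all(rd <= 1e-12))
    expect_equal(rd[5], -1)
  }
  # ratio of the two small brute-force sums
  expect_equal(relative_discrepancy(2, 4, 0.3, 0.5),
               (oracle_sd_vs_full(2, 4, 0.3, 0.5) -
                  oracle_sd_error(2, 0.3, 0.5)) / oracle_sd_error(2, 0.3, 0.5),
               tolerance = 1e-10)
  expect_error(relative_discrepancy(2, 4, 0, 0.5), "undefined")
})

test_that("the discrepancy magnitude depends on n/N, not on N", {
  Ns <- c(8640, 34560, 69120, 103680)
  rd <- vapply(Ns, function(N)
    abs(relative_discrepancy(round(0.2 * N), N, 0.043, 0.917)), numeric(1))
  expect_lt(max(rd) - min(rd), 0.005)
  expect_true(all(rd <= 0.11))
})

test_that("minimum-duration search is exact against a linear scan", {
  # boundary: target met already by a single sample
  # (p_h = 0.5, alpha = 0: sd_error(1) = 0.5 exactly in floating point)
  expect_identical(min_duration(0.5, 0.5, 0)$n, 1L)
  expect_identical(min_duration(sqrt(0.1 * 0.9), 0.1, 0.5)$n, 1L)
  # population parameters, 1.5% target
  res <- min_duration(0.015, 0.043, 0.917)
  expect_gt(sd_error(res$n - 1, 0.043, 0.917), 0.015)
  expect_lte(sd_error(res$n, 0.043, 0.917), 0.015)
  expect_equal(res$days, res$n / 288)
  # small case: agree with an exhaustive scan
  scan <- which(sd_error(1:500, 0.3, 0.5) <= 0.05)[1]
  expect_identical(min_duration(0.05, 0.3, 0.5)$n, as.integer(scan))
  expect_error(min_duration(0, 0.3, 0.5), "positive")
  expect_error(min_duration(-0.1, 0.3, 0.5), "positive")
})

test_that("uncertainty table is a percent view of the error-SD formula", {
  tab <- uncertainty_table(c(7, 14, 30, 60, 120), 0.043, 0.917)
  expect_equal(tab$n, as.integer(c(7, 14, 30, 60, 120) * 288))
  expect_equal(tab$sd_pct, 100 * sd_error(tab$n, 0.043, 0.917))
  # one-sample duration: binomial SD of a single Bernoulli draw
  one <- uncertainty_table(1 / 288, 0.043, 0.917)
  expect_equal(one$n, 1L)
  expect_equal(one$sd_pct, 100 * sqrt(0.043 * 0.957))
  expect_equal(nrow(uncertainty_table(numeric(), 0.3, 0.5)), 0L)
  expect_error(uncertainty_table(-3, 0.3, 0.5), "positive")
})
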