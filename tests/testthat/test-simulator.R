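test_that("stationary law of the two-state chain matches the closed forms", {
  expect_equal(stationary_params(0.5, 0.5), c(p_h = 0.5, alpha = 0))
  expect_equal(stationary_params(1, 0)[["p_h"]], 0)
  expect_equal(stationary_params(0, 1)[["p_h"]], 1)
  expect_error(stationary_params(1, 1), "degenerate")
  expect_error(stationary_params(1.2, 0.5), "\\[0, 1\\]")
})

test_that("the reduced decay formula agrees with the two-term closed form", {
  grid <- seq(0.025, 0.975, length.out = 20)  # p11 = 1 is singular there
  for (p00 in grid) for (p11 in grid) {
    expect_equal(stationary_params(p00, p11)[["alpha"]],
                 alpha_printed(p00, p11), tolerance = 1e-12)
  }
})

test_that("target inversion round-trips through the stationary law", {
  expect_equal(chain_from_targets(0.5, 0), c(p00 = 0.5, p11 = 0.5))
  expect_equal(chain_from_targets(0.043, 0.917),
               c(p00 = 0.996431, p11 = 0.920569), tolerance = 1e-9)
  expect_equal(chain_from_targets(0, 0.6), c(p00 = 1, p11 = 0.6))
  for (p in c(0.01, 0.043, 0.3, 0.5, 0.9)) {
    for (a in c(0, 0.3, 0.86, 0.917, 0.99)) {
      ch <- chain_from_targets(p, a)
      expect_equal(stationary_params(ch[["p00"]], ch[["p11"]]),
                   c(p_h = p, alpha = a), tolerance = 1e-12)
    }
  }
  expect_error(chain_from_targets(0.5, 1), "alpha")
  expect_error(chain_from_targets(-0.1, 0.5), "p_h")
})

test_that("simulation is reproducible and respects degenerate targets", {
  h1 <- simulate_binary(0.3, 0.8, N = 500, nsim = 4, seed = 99)
  h2 <- simulate_binary(0.3, 0.8, N = 500, nsim = 4, seed = 99)
  expect_identical(h1, h2)
  expect_identical(dim(h1), c(500L, 4L))
  expect_true(all(h1 %in% 0:1))
  # replicate substreams: trace i does not depend on how many come after
  h3 <- simulate_binary(0.3, 0.8, N = 500, nsim = 1, seed = 99)
  expect_identical(h1[, 1], h3[, 1])
  # degenerate chains
  expect_true(all(simulate_binary(0, 0.7, N = 200, nsim = 3, seed = 1) == 0L))
  expect_true(all(simulate_binary(1, 0.7, N = 200, nsim = 3, seed = 1) == 1L))
})

test_that("simulated traces have the target stationary moments", {
  N <- 1e5
  # iid limit
  h0 <- simulate_binary(0.3, 0, N = N, nsim = 1, seed = 7)[, 1]
  r0 <- stats::cor(h0[-N], h0[-1])
  expect_lt(abs(r0), 3 / sqrt(N))
  # correlated chain: mean and lag-tau autocorrelation
  p <- 0.3; a <- 0.8
  h <- simulate_binary(p, a, N = N, nsim = 1, seed = 7)[, 1]
  se_mean <- sqrt(p * (1 - p) * (1 + 2 * a / (1 - a)) / N)
  expect_lt(abs(mean(h) - p), 3 * se_mean)
  for (tau in c(1, 2, 5)) {
    r <- stats::cor(h[1:(N - tau)], h[(1 + tau):N])
    expect_lt(abs(r - a^tau), 3 * tau * sqrt((1 - a^2) / N))
  }
})

test_that("Monte-Carlo error curve matches its definition and edge cases", {
  # zero-probability process: identically zero curve
  mc0 <- monte_carlo_sd_curve(0, 0.5, N = 100, nsim = 50,
                              n_values = c(1, 10, 100), seed = 1)
  expect_equal(mc0$sd, rep(0, 3))
  expect_error(monte_carlo_sd_curve(0.3, 0.5, N = 10, nsim = 1,
                                    n_values = 1), "at least 2")
  expect_error(monte_carlo_sd_curve(0.3, 0.5, N = 10, nsim = 5,
                                    n_values = 20), "\\[1, N\\]")
  # definition check against a direct computation on the same traces
  h <- simulate_binary(0.2, 0.5, N = 50, nsim = 40, seed = 5)
  mc <- monte_carlo_sd_curve(0.2, 0.5, N = 50, nsim = 40,
                             n_values = c(1, 7, 50), seed = 5)
  for (k in seq_along(mc$n)) {
    n <- mc$n[k]
    e <- colMeans(h[1:n, , drop = FALSE]) - 0.2
    expect_equal(mc$sd[k], sqrt(sum(e^2) / 39))
  }
})

test_that("Monte-Carlo curve converges to the analytic curve as replicates grow", {
  n_values <- c(1, 10, 100, 1000)
  p <- 0.3; a <- 0.6
  th <- sd_error(n_values, p, a)
  gap <- function(nsim) {
    mc <- monte_carlo_sd_curve(p, a, N = 1000, nsim = nsim,
                               n_values = n_values, seed = 101)
    max(abs(mc$sd / th - 1))
  }
  g250 <- gap(250)
  g1000 <- gap(1000)
  expect_lt(g1000, g250)
  expect_lt(g1000, 0.10)
})
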