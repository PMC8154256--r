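test_that("the selected bandwidth is the root found by dense residual scanning", {
  fx <- generate_fixture("gaussian", 50, seed = 5)
  g <- make_grid(fx$values, 256)
  b <- bin_samples(fx$values, g)
  bw <- select_bandwidth(b)
  expect_true(bw$converged)
  expect_lt(abs(bw$residual), 1e-10)

  # brute-force oracle: scan the residual on a dense log grid, then refine
  # the bracketing interval by plain bisection (independent of uniroot)
  a <- kdentropy:::dct2(b$bin_mass / b$total_weight)
  tg <- 10^seq(-12, -1, length.out = 1e5)
  gv <- fixed_point_residual(tg, b$n_effective, a)
  i <- which(gv[-1] * gv[-length(gv)] <= 0)[1]
  lo <- tg[i]; hi <- tg[i + 1]
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (fixed_point_residual(mid, b$n_effective, a) *
        fixed_point_residual(lo, b$n_effective, a) <= 0) hi <- mid else lo <- mid
  }
  expect_equal(bw$t_unit, (lo + hi) / 2, tolerance = 1e-6)
})

test_that("the residual recursion matches an independent re-derivation", {
  # independent evaluation: same mathematics, written from the definition
  # with double factorials via (2s)! / (2^s s!) and explicit loops
  residual_ref <- function(t, N, p) {
    n <- length(p)
    a <- dct2_naive(p)
    a2 <- (a[-1] / 2)^2
    I <- as.numeric(seq_len(n - 1))^2
    f <- 2 * pi^14 * sum(I^7 * a2 * exp(-I * pi^2 * t))
    for (s in 6:2) {
      dfact <- factorial(2 * s) / (2^s * factorial(s))
      K0 <- dfact / sqrt(2 * pi)
      const <- (1 + 2^(-s - 0.5)) / 3
      ts <- (2 * const * K0 / (N * f))^(2 / (3 + 2 * s))
      f <- 2 * pi^(2 * s) * sum(I^s * a2 * exp(-I * pi^2 * ts))
    }
    t - (2 * N * sqrt(pi) * f)^(-0.4)
  }
  p <- c(0.05, 0.1, 0.3, 0.25, 0.15, 0.1, 0.04, 0.01)  # 8-bin toy histogram
  a <- kdentropy:::dct2(p)
  for (t in c(0.001, 0.01, 0.05))
    expect_equal(fixed_point_residual(t, 200, a), residual_ref(t, 200, p),
                 tolerance = 1e-12)
})

test_that("the residual is continuous in t", {
  fx <- generate_fixture("gaussian", 200, seed = 2)
  b <- bin_samples(fx$values, make_grid(fx$values, 128))
  a <- kdentropy:::dct2(b$bin_mass / b$total_weight)
  t0 <- 0.005
  deltas <- 10^seq(-3, -9, by = -1)
  jumps <- abs(fixed_point_residual(t0 + deltas, 200, a) -
                 fixed_point_residual(t0, 200, a))
  expect_true(all(diff(jumps) < 0))
  expect_lt(jumps[length(jumps)], 1e-7)
})

test_that("Gaussian samples recover the normal-reference bandwidth within 15%", {
  fx <- generate_fixture("gaussian", 1e4, seed = 7)
  d <- estimate_pdf(fx$values)
  ref <- 1.06 * stats::sd(fx$values) * 1e4^(-1 / 5)
  expect_lt(abs(d$bandwidth$h - ref) / ref, 0.15)
})

test_that("bandwidth scales with the data and shrinks with sample size", {
  fx <- generate_fixture("gaussian", 400, seed = 9)
  t1 <- estimate_pdf(fx$values, resolution = 256)$bandwidth$t_data
  t2 <- estimate_pdf(3.7 * fx$values + 11, resolution = 256)$bandwidth$t_data
  expect_equal(t2, 3.7^2 * t1, tolerance = 1e-8)

  hs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    f <- generate_fixture("gaussian", n, seed = 3)
    estimate_pdf(f$values)$bandwidth$h
  }, numeric(1))
  expect_true(all(diff(hs) < 0))
  # h * n^(1/5) stabilizes near the Gaussian-optimal constant
  scaled <- hs * c(1e3, 1e4, 1e5)^(1 / 5)
  expect_true(all(abs(scaled - 1.06) / 1.06 < 0.15))
})

test_that("degenerate inputs are rejected", {
  g <- make_grid(c(0, 1), 64)
  b <- bin_samples(rep(0.5, 100), g)
  expect_error(select_bandwidth(b), "single bin")
  b2 <- bin_samples(c(0.2, 0.8), g)
  expect_error(select_bandwidth(b2, n_used = 1), "n_used")
  expect_error(fixed_point_residual(0.01, 100, numeric(0)), "length")
  expect_error(fixed_point_residual(-1, 100, c(1, 0.5)), "positive")
})
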