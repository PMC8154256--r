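test_that("resolution rules give powers of two in range, with the dihedral default", {
  # large dihedral datasets use the 4096-bin default
  expect_identical(choose_resolution(2e5, "dihedral"), 4096L)
  expect_identical(choose_resolution(1e4, "dihedral"), 4096L)
  # halving schedule below 1e4 frames, floored at 512
  expect_identical(choose_resolution(5000, "dihedral"), 2048L)
  expect_identical(choose_resolution(300, "dihedral"), 512L)
  # generic auto = Rice rounded up to a power of two, clamped
  expect_identical(choose_resolution(1e6, rule = "rice"), 256L)  # ceil(2e2) -> 256
  expect_identical(choose_resolution(1, rule = "auto"), 32L)     # clamp floor
  expect_identical(choose_resolution(1e4, rule = "sqrt"), 128L)
  for (n in c(1, 10, 1e3, 1e6))
    for (rule in c("auto", "sturges", "rice", "sqrt")) {
      r <- choose_resolution(n, rule = rule)
      expect_true(r >= 32L && r <= 8192L && bitwAnd(r, r - 1L) == 0L)
    }
})

test_that("resolution is monotone in sample size for each rule and kind", {
  ns <- c(1, 5, 50, 500, 5e3, 5e4, 5e5)
  for (kind in c("generic", "dihedral"))
    for (rule in c("auto", "sturges", "rice", "sqrt")) {
      rs <- vapply(ns, choose_resolution, integer(1),
                   data_kind = kind, rule = rule)
      expect_true(all(diff(rs) >= 0L),
                  info = paste(kind, rule))
    }
})

test_that("invalid resolution requests are rejected", {
  expect_error(choose_resolution(0), "n_samples")
  expect_error(choose_resolution(100, rule = "fixed"), "fixed_value")
  expect_error(choose_resolution(100, rule = "fixed", fixed_value = 100),
               "power of two")
  expect_identical(choose_resolution(100, rule = "fixed", fixed_value = 1024),
                   1024L)
})

test_that("grids pad generic data and pin dihedral bounds", {
  g <- make_grid(c(0, 3, 10), 64)
  expect_equal(g$lower, -1)
  expect_equal(g$upper, 11)
  expect_equal(g$spacing, 12 / 64)
  expect_equal(g$centers[1], -1 + 0.5 * 12 / 64)

  gd <- make_grid(c(-500, 720), 512, "dihedral")
  expect_equal(gd$lower, -180)
  expect_equal(gd$upper, 180)

  expect_error(make_grid(rep(5, 10), 64), "identical")
  expect_warning(g2 <- make_grid(c(0, 1), 100), "power of two")
  expect_identical(g2$resolution, 128L)
})

test_that("binning conserves mass and honors the half-open edge convention", {
  g <- make_grid(c(0, 4), 4, pad_fraction = 0)
  b <- bin_samples(c(0.5, 1.5, 2.5, 3.5), g)
  expect_equal(sum(b$bin_mass), 4)
  expect_equal(b$n_effective, 4)

  # interior edge goes to the right-hand bin
  edge <- bin_samples(1, g)
  expect_equal(edge$bin_mass, c(0, 1, 0, 0))
  # the final bin is closed at the top
  top <- bin_samples(4, g)
  expect_equal(top$bin_mass, c(0, 0, 0, 1))

  # weighted example with Kish effective sample size
  bw <- bin_samples(c(1, 1, 3), g, weights = c(0.5, 0.5, 2))
  expect_equal(bw$bin_mass, c(0, 1, 0, 2))
  expect_equal(bw$total_weight, 3)
  expect_equal(bw$n_effective, 2)

  expect_error(bin_samples(c(0.5, 7), g), "outside the grid")
})

test_that("mass conservation holds to 1e-12 relative on random weighted samples", {
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(500)
    w <- rexp(500) + 0.01
    g <- make_grid(x, 128)
    b <- bin_samples(x, g, w)
    expect_lt(abs(sum(b$bin_mass) - sum(w)) / sum(w), 1e-12)
    expect_equal(b$n_effective, sum(w)^2 / sum(w^2))
  }
})

test_that("degree wrapping maps into [-180, 180) and is idempotent", {
  expect_equal(wrap_degrees(180), -180)
  expect_equal(wrap_degrees(-180), -180)
  expect_equal(wrap_degrees(540), 180 - 360)
  set.seed(1)
  x <- runif(1000, -1000, 1000)
  w1 <- wrap_degrees(x)
  expect_true(all(w1 >= -180 & w1 < 180))
  expect_identical(wrap_degrees(w1), w1)
})
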