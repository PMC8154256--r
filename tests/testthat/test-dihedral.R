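test_that("uniform circular data approach the circular-uniform entropy", {
  # flat circular data defeat the curvature-based plug-in (the fixed point
  # latches onto bin-count noise), so the estimate carries a small negative
  # noise bias that shrinks with n; at 1e5 frames it is close to the truth
  set.seed(3)
  th <- runif(1e5, -180, 180)
  s <- dihedral_entropy(th)$value
  truth <- R_GAS * log(2 * pi)
  expect_lt(abs(s - truth) / truth, 0.02)
})

test_that("the periodic density is normalized over the central window", {
  fx <- generate_fixture("von_mises", 5e3, seed = 19, mu = -60, kappa = 4)
  d <- dihedral_density(fx$values)
  expect_lt(abs(riemann_mass(d) - 1), 1e-9)
  expect_equal(d$grid$lower, -180)
  expect_equal(d$grid$upper, 180)
})

test_that("dihedral entropy is invariant under circular shifts", {
  fx <- generate_fixture("von_mises", 1e4, seed = 5, mu = -60, kappa = 4)
  s0 <- dihedral_entropy(fx$values)$value
  # 90 degrees is a whole number of bins: invariance is almost exact
  s90 <- dihedral_entropy(wrap_degrees(fx$values + 90))$value
  expect_lt(abs(s90 - s0), 1e-3)
  # arbitrary shifts realign samples against bin edges, adding a sub-bin
  # aliasing term on top
  for (shift in c(37.5, -120.2)) {
    s1 <- dihedral_entropy(wrap_degrees(fx$values + shift))$value
    expect_lt(abs(s1 - s0), 5e-3)
  }
})

test_that("the spectral periodic estimate matches a periodic kernel sum", {
  fx <- generate_fixture("von_mises", 5e3, seed = 31, kappa = 20)
  d <- dihedral_density(fx$values)
  r <- d$grid$resolution
  gc <- kdentropy:::new_grid(-180, 180, r, kind = "dihedral")
  bwc <- manual_bandwidth(gc, t_data = d$bandwidth$t_data)
  # kernels summed over images at x and x +/- 360, then renormalized on the window
  xs <- c(fx$values - 360, fx$values, fx$values + 360)
  ds <- direct_sum_density(xs, gc, bwc)
  pdfd <- ds$pdf / (sum(ds$pdf) * gc$spacing)
  s_direct <- -R_GAS * sum(ifelse(pdfd > 0, pdfd * log(pdfd * 180 / pi), 0)) *
    gc$spacing
  s_spec <- dihedral_entropy(fx$values)$value
  expect_lt(abs(s_spec - s_direct) / abs(s_direct), 0.005)
})

test_that("entropy stabilizes as the number of frames grows", {
  fx <- generate_fixture("von_mises", 4e4, seed = 12, kappa = 4)
  ns <- c(5e3, 1e4, 2e4, 4e4)
  s <- vapply(ns, function(n) dihedral_entropy(fx$values[1:n])$value, numeric(1))
  d <- abs(diff(s))
  expect_lt(d[length(d)], d[1])
})

test_that("residuewise entropies group, order and sum correctly", {
  fx1 <- generate_fixture("von_mises", 2000, seed = 41, mu = -70, kappa = 6)
  fx2 <- generate_fixture("von_mises", 2000, seed = 42, mu = 50, kappa = 3)
  tbl <- dplyr::bind_rows(
    tibble::tibble(frame = 1:2000, dihedral = "phi", residue_index = 2L,
                   residue_name = NA_character_, angle = fx1$values),
    tibble::tibble(frame = 1:2000, dihedral = "psi", residue_index = 2L,
                   residue_name = NA_character_, angle = fx2$values),
    tibble::tibble(frame = 1:2000, dihedral = "phi", residue_index = 1L,
                   residue_name = NA_character_, angle = fx2$values))
  out <- residuewise_entropy(tbl, resolution = 512)
  expect_identical(out$residue_index, c(1L, 2L))
  s_phi1 <- dihedral_entropy(fx1$values, resolution = 512)$value
  s_psi2 <- dihedral_entropy(fx2$values, resolution = 512)$value
  expect_equal(out$phi[2], s_phi1)
  expect_equal(out$combined[2], out$phi[2] + out$psi[2], tolerance = 1e-12)
  # single series in a residue: combined equals that entropy
  expect_equal(out$combined[1], s_psi2)

  # two identical series under different names double the combined value
  tbl2 <- dplyr::bind_rows(
    tibble::tibble(frame = 1:2000, dihedral = "phi", residue_index = 1L,
                   residue_name = NA_character_, angle = fx1$values),
    tibble::tibble(frame = 1:2000, dihedral = "chi1", residue_index = 1L,
                   residue_name = NA_character_, angle = fx1$values))
  out2 <- residuewise_entropy(tbl2, resolution = 512)
  expect_equal(out2$combined, 2 * s_phi1, tolerance = 1e-12)

  # duplicate dihedral name within one residue is rejected
  tbl3 <- dplyr::bind_rows(
    tibble::tibble(frame = 1:100, dihedral = "phi", residue_index = 1L,
                   residue_name = NA_character_, angle = fx1$values[1:100]),
    tibble::tibble(frame = 1:100, dihedral = "phi", residue_index = 1L,
                   residue_name = NA_character_, angle = fx2$values[1:100]))
  expect_error(residuewise_entropy(tbl3), "duplicate")
})

test_that("empty or mismatched dihedral input is rejected", {
  expect_error(dihedral_entropy(numeric(0)), "non-empty")
  expect_error(dihedral_entropy(runif(100, -180, 180), weights = rep(1, 50)),
               "length")
})
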