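# Extracellular potassium transport: conservation, closed forms,
# electromigration consistency.

test_that("uniform Ko with zero currents and no wash-out is unchanged", {
  ko <- rep(6, 41); vo <- rep(0, 41)
  out <- step_k_transport(ko, vo, dt = 0.5, dx = 0.025)
  expect_equal(out, ko)
})

test_that("wash-out relaxation matches the closed form", {
  p <- cell_params()
  ko <- rep(9, 5); vo <- rep(0, 5)
  dt <- 1
  nstep <- 30000
  for (i in seq_len(nstep))
    ko <- step_k_transport(ko, vo, dt = dt, dx = 0.025, DK = 0,
                           tau_wo = 15000, params = p)
  expected <- 5.4 + (9 - 5.4) * exp(-nstep * dt / 15000)
  expect_lt(max(abs(ko - expected)) / 5.4, 1e-3)
  expect_equal(ko[1], expected, tolerance = 1e-3)
})

test_that("transport conserves total potassium with zero-flux ends", {
  set.seed(7)
  n <- 61
  ko <- 5.4 + cumsum(rnorm(n, 0, 0.2))
  ko <- pmax(ko, 0.5)
  vo <- 10 * sin(seq(0, 3, length.out = n))
  dkc <- 1.5e-6   # exaggerated DK to make transport visible
  tot0 <- sum(ko)
  for (i in 1:2000)
    ko <- step_k_transport(ko, vo, dt = 0.1, dx = 0.025, DK = dkc)
  expect_equal(sum(ko), tot0, tolerance = 1e-12)
  # diffusion smooths the profile
  expect_lt(diff(range(ko)), 6)
})

test_that("electromigration vanishes for uniform Vo and for uniform Ko with linear Vo", {
  n <- 41
  ko <- 5.4 + 3 * exp(-((seq_len(n) - 21) / 6)^2)
  vo_flat <- rep(2, n)
  a <- step_k_transport(ko, vo_flat, dt = 0.1, dx = 0.025, DK = 1.5e-6)
  b <- step_k_transport(ko, rep(0, n), dt = 0.1, dx = 0.025, DK = 1.5e-6)
  expect_equal(a, b, tolerance = 1e-14)
  # uniform Ko + linear Vo: drift flux is constant, divergence zero at
  # interior nodes; boundary nodes see the no-flux walls
  ko_u <- rep(5.4, n)
  vo_lin <- seq(0, 20, length.out = n)
  out <- step_k_transport(ko_u, vo_lin, dt = 0.1, dx = 0.025, DK = 1.5e-6)
  expect_equal(out[2:(n - 1)], ko_u[2:(n - 1)], tolerance = 1e-12)
})

test_that("local transport rate sign follows the curvature", {
  n <- 41
  x <- seq_len(n)
  # a dip at the center: positive curvature -> local potassium gain
  ko <- 5.4 - 2 * exp(-((x - 21) / 4)^2)
  vo <- rep(0, n)
  out <- step_k_transport(ko, vo, dt = 0.1, dx = 0.025, DK = 1.5e-6)
  expect_gt(out[21], ko[21])
  # a bump: negative curvature -> local loss
  ko2 <- 5.4 + 2 * exp(-((x - 21) / 4)^2)
  out2 <- step_k_transport(ko2, vo, dt = 0.1, dx = 0.025, DK = 1.5e-6)
  expect_lt(out2[21], ko2[21])
})

test_that("negative concentrations abort with a diagnostic", {
  ko <- c(0.001, 5, 5); vo <- rep(0, 3)
  expect_error(step_k_transport(ko, vo, sumikx = c(-500, 0, 0), dt = 1,
                                dx = 0.025, DK = 0),
               "negative")
})
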