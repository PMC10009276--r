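# 1D cable: stability guard, diffusion conservation, extracellular
# potential recovery, injury current, short propagation runs.

test_that("grid construction enforces the explicit stability bound", {
  g <- cable_grid(4, 0.025, 0.02, 0.0026)
  expect_equal(g$n, 161)
  expect_error(cable_grid(4, 0.025, 0.2, 0.0026), "stability")
})

test_that("uniform cable stays uniform and conserves the spatial mean", {
  # all conductances off, no stimulus: diffusion must do nothing on a
  # uniform profile and conserve the mean on a perturbed one
  p <- cell_params()
  p$current_scale[] <- 0
  scn <- scenario("unif", "1D", duration_min = 100 / 60000,
                  normoxia_min = Inf, bpm = 0, dx_cm = 0.1,
                  snapshot_dt = 100, probe_dt = 100)
  init <- matrix(rep(as.numeric(cell_init_state()), each = 41), nrow = 41)
  r1 <- run_cable(scn, params = p, init = init)
  vm_end <- r1$snapshots$Vm[nrow(r1$snapshots$Vm), ]
  expect_lt(diff(range(vm_end)), 1e-9)
  # perturbed profile: the discrete zero-flux integral (trapezoidal mean,
  # half-weighted end cells) is conserved to round-off by diffusion
  init2 <- init
  init2[, 1] <- init2[, 1] + sin(seq(0, pi, length.out = 41)) * 5
  r2 <- run_cable(scn, params = p, init = init2)
  vm2 <- r2$snapshots$Vm[nrow(r2$snapshots$Vm), ]
  trapz_mean <- function(v) (sum(v) - v[1] / 2 - v[length(v)] / 2) /
    (length(v) - 1)
  expect_equal(trapz_mean(vm2), trapz_mean(init2[, 1]), tolerance = 1e-10)
})

test_that("extracellular potential matches the closed form -Vm/(1+lambda)+c", {
  set.seed(42)
  # a smooth zero-flux profile: sum of cosines (zero-gradient at both ends)
  x <- seq(0, 1, length.out = 81)
  vm <- -85 + 40 * cos(pi * x) + 10 * cos(2 * pi * x)
  lam <- 3.647
  vo_cf <- extracellular_potential(vm, lam)
  vo_ps <- extracellular_potential(vm, lam, method = "poisson")
  # both routes agree, and Vo + Vm/(1+lambda) is constant across nodes
  expect_lt(max(abs(vo_cf - vo_ps)), 1e-8 * diff(range(vm)))
  resid <- vo_cf + vm / (1 + lam)
  expect_lt(diff(range(resid)), 1e-8 * diff(range(vm)))
  # peak-to-peak attenuation by 1/(1+lambda)
  expect_equal(diff(range(vo_cf)), diff(range(vm)) / (1 + lam))
  # uniform Vm gives uniform Vo; gauge fixes the constant
  expect_equal(extracellular_potential(rep(-80, 11), lam),
               rep(0, 11))
  expect_equal(extracellular_potential(rep(-80, 11), lam, gauge = "zero-left"),
               rep(0, 11))
})

test_that("injury current: zero on uniform Vm, exact on quadratic Vm", {
  expect_equal(injury_current(rep(-80, 21)), rep(0, 21))
  vm <- make_fixture("quadratic-vm", n = 41, a = 2, dx = 0.025)
  iinj <- injury_current(vm, dx_cm = 0.025, DV = 0.0026)
  interior <- 2:40
  expect_equal(iinj[interior], rep(2 * 2 * 0.0026, 39), tolerance = 1e-9)
})

test_that("a paced normoxic cable propagates with a physiological CV", {
  run <- cv_run_fine()
  cv <- measure_cv(run, 1.0, 1.5)
  expect_gt(cv, 55); expect_lt(cv, 85)
  # reducing DV reduces CV
  run40 <- cached("cv_short_dv04", {
    scn <- scenario("cv40", "1D", duration_min = 2100 / 60000,
                    normoxia_min = Inf, probe_x_cm = c(1.0, 1.5),
                    snapshot_dt = 2100, n_stim_nodes = 3, dv_factor = 0.4)
    run_cable(scn)
  })
  expect_lt(measure_cv(run40, 1.0, 1.5), cv)
})

test_that("splitting-order effects are bounded: CV insensitive to probe beat", {
  run <- cv_run_fine()
  cv2 <- measure_cv(run, 1.0, 1.5, beat = 2)
  cv3 <- measure_cv(run, 1.0, 1.5, beat = 3)
  expect_lt(abs(cv2 - cv3) / cv3, 0.01)
})

test_that("electrogram of normoxic tissue has an isoelectric ST segment", {
  run <- cv_run_fine()
  eg <- electrogram_at(run, 1.0)
  # after full repolarization of the whole strand (~360 ms APD + ~60 ms
  # activation delay) the tissue is uniform -> Vo flat at baseline
  st <- run$stim_times[2]
  sel <- eg$t > st + 620 & eg$t < st + 950
  expect_lt(max(abs(eg$Vo[sel])), 0.35)
})
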