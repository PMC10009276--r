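# Ischemia factor curves and the cell right-hand side.

test_that("IKatp vanishes at the K+ Nernst potential and in normoxia", {
  ki <- 143.8
  ek <- 8314 * 310 / 96485 * log(5.4 / ki)
  expect_equal(ikatp_current(ek, 5.4, 2, 100, ki = ki), 0)
  # normoxic metabolic state: almost non-existent current
  i_nx <- ikatp_current(-20, 5.4, 10, 15, ki = ki)
  expect_lt(abs(i_nx), 0.05)
})

test_that("IKatp magnitude grows as ATP falls and as ADP rises", {
  ki <- 143.8
  sweep_atp <- sapply(c(10, 5, 2, 1),
                      function(a) ikatp_current(0, 5.4, a, 100, ki = ki))
  expect_true(all(diff(sweep_atp) > 0))  # outward current at Vm=0 increases
  sweep_adp <- sapply(c(15, 50, 100, 200),
                      function(d) ikatp_current(0, 5.4, 5, d, ki = ki))
  expect_true(all(diff(sweep_adp) > 0))
  expect_error(ikatp_current(0, -1, 5, 100), "Ko")
  expect_error(ikatp_current(0, 5.4, 0, 100), "ATP")
})

test_that("pump scaling is anchored at normoxia and monotone in ATP", {
  f0 <- pump_scaling(10, 15)
  expect_true(all(abs(f0 - 1) < 0.01))
  expect_true(all(f0 <= 1 & f0 > 0))
  for (adp in c(15, 60, 120)) {
    f5 <- pump_scaling(5, adp)
    f2 <- pump_scaling(2, adp)
    expect_true(all(f5 >= f2))
  }
  # 30-min metabolic state: NaK reduced by more than 50%
  m30 <- metabolites_at(30)
  expect_lt(pump_scaling(m30$ATPi, m30$ADPi)[["fNaK"]], 0.5)
  expect_error(pump_scaling(-1, 15), "ATP")
})

test_that("acidosis scaling is 1 at normoxic pH and monotone non-increasing", {
  f0 <- acidosis_scaling(7.2, 7.4)
  expect_true(all(f0 == 1))
  m30 <- metabolites_at(30)
  f30 <- acidosis_scaling(m30$pHi, m30$pHo)
  expect_true(all(f30 < 1))
  f65 <- acidosis_scaling(6.5, 6.7)
  f70 <- acidosis_scaling(7.0, 7.2)
  expect_true(all(f65 <= f70))
  expect_error(acidosis_scaling(4.0, 7.4), "range")
})

test_that("LPC scaling is anchored at 2 umol/L and grows with LPC", {
  expect_true(all(lpc_scaling(2) == 1))
  f10 <- lpc_scaling(10); f20 <- lpc_scaling(20)
  expect_true(all(abs(f20 - 1) >= abs(f10 - 1)))
  expect_true(any(lpc_scaling(20) != 1))
  expect_error(lpc_scaling(-1), "LPC")
})

test_that("currents record satisfies the SumIKx identity", {
  r <- cell_rhs(cell_init_state(), normoxic_metab(), 0)
  cc <- r$currents
  expect_equal(cc[["SumIKx"]],
               cc[["IKr"]] + cc[["IKs"]] + cc[["Ito"]] + cc[["IK1"]] +
                 cc[["IKatp"]] + cc[["IKb"]] + cc[["ICaK"]] - 2 * cc[["INaK"]],
               tolerance = 1e-15)
})

test_that("with all conductances zeroed dVm/dt = Istm/Cm and dKo/dt is wash-out only", {
  p <- cell_params()
  p$current_scale[] <- 0
  s <- cell_init_state()
  s["Ko"] <- 6.0
  r <- cell_rhs(s, normoxic_metab(), istm = 3, params = p)
  expect_equal(r$deriv[["V"]], 3, tolerance = 1e-12)
  expect_equal(r$deriv[["Ko"]], (5.4 - 6.0) / 15000, tolerance = 1e-12)
  # and with infinite tau_wo the Ko derivative vanishes entirely
  p$tau_wo <- Inf
  r2 <- cell_rhs(s, normoxic_metab(), istm = 0, params = p)
  expect_equal(r2$deriv[["Ko"]], 0)
})

test_that("non-finite state is rejected with a diagnostic", {
  s <- cell_init_state()
  s["Nai"] <- NaN
  expect_error(cell_rhs(s), "non-finite")
})

test_that("gating variables stay inside [0,1] and concentrations positive", {
  run <- normoxic_run()
  fs <- run$final_state
  gates <- fs[c("m", "h", "j", "mL", "hL", "a", "iF", "iS", "d", "ff",
                "fs", "fcaf", "fcas", "jca", "xrf", "xrs", "xs1", "xs2",
                "xk1")]
  expect_true(all(gates >= 0 & gates <= 1))
  conc <- fs[c("Nai", "Ki", "Cai", "Cansr", "Cajsr", "Ko")]
  expect_true(all(conc > 0))
  expect_true(all(run$trace$Ko > 0))
})

test_that("cleft potassium bookkeeping matches the quadrature of SumIKx", {
  # tau_wo = Inf: Delta Ko over any window equals alpha * integral(SumIKx)
  run <- ischemia_run()
  m <- run$macro
  i0 <- which(m$t == 240000); i1 <- which(m$t == 600000)
  dint <- m$int_SumIKx[i1] - m$int_SumIKx[i0]   # uA/uF * ms, solver-resolution
  dko <- m$Ko[i1] - m$Ko[i0]
  expect_equal(dko, run$params$alpha * dint, tolerance = 1e-6)
})

test_that("with membrane currents disabled Ko relaxes to bulk as exp(-t/tau)", {
  p <- cell_params()
  p$current_scale[] <- 0
  s <- cell_init_state()
  s["Ko"] <- 9.0
  r <- .run_cell_raw(as.numeric(s), p, duration = 30000, dt = 0.02,
                     trace_dt = 100, macro_dt = 30000)
  tr <- r$trace[seq_len(r$n_trace), ]
  expected <- 5.4 + (9.0 - 5.4) * exp(-tr[, 1] / 15000)
  expect_lt(max(abs(tr[, 3] - expected) / expected), 1e-3)
})

test_that("fixed-step trajectory agrees with an independent stiff solve", {
  skip_if_not_installed("deSolve")
  # one paced beat: integrate the same RHS with deSolve's LSODA and compare
  p <- cell_params()
  s <- cell_init_state()
  prot <- pacing_protocol(60)
  amp <- 60
  f <- function(t, y, parms) {
    istm <- if (t %% 1000 < 0.5) amp else 0
    list(cell_rhs(y, normoxic_metab(), istm, p)$deriv)
  }
  ode <- deSolve::lsoda(as.numeric(s), seq(0, 500, by = 1), f, NULL,
                        rtol = 1e-6, atol = 1e-6, hmax = 0.25)
  run <- .run_cell_raw(as.numeric(s), p, duration = 500, dt = 0.02,
                       stim_times = 0, stim_amp = amp, stim_width = 0.5,
                       trace_dt = 1, macro_dt = 500)
  vm_fixed <- run$trace[seq_len(run$n_trace), 2]
  vm_ref <- ode[, 2]
  # exclude the 5 ms around the upstroke where a 1 ms sampling grid
  # dominates the comparison
  sel <- ode[, 1] > 10
  rmse <- sqrt(mean((vm_fixed[sel] - vm_ref[sel])^2))
  expect_lt(rmse, 1.0)   # mV
})

test_that("halving the time step changes APD90 by less than 0.5 ms", {
  s <- cell_init_state()
  p <- cell_params()
  apd_at <- function(dt) {
    r <- .run_cell_raw(as.numeric(s), p, duration = 1000, dt = dt,
                       stim_times = 0, stim_amp = 60, stim_width = 0.5,
                       trace_dt = 0.5, macro_dt = 1000)
    tr <- as.data.frame(r$trace[seq_len(r$n_trace), ])
    names(tr) <- c("t", "Vm", "Ko", "Istm")
    beat_metrics(tr, stim_times = 0)$apd90
  }
  expect_lt(abs(apd_at(0.02) - apd_at(0.01)), 0.5)
})

test_that("run_single_cell is deterministic", {
  scn <- scenario("det", "0D", duration_min = 3 / 60, normoxia_min = Inf)
  r1 <- run_single_cell(scn)
  r2 <- run_single_cell(scn)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$final_state, r2$final_state)
})
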