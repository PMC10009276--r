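# Metabolite time courses, spatial profiles and the stimulation protocol.

test_that("metabolite time courses hit their anchors", {
  m <- metabolites_at(c(-1, 0, 15, 30))
  nx <- normoxic_metab()
  expect_equal(unlist(m[1, ]), nx, ignore_attr = TRUE)
  expect_equal(unlist(m[2, ]), nx, ignore_attr = TRUE)
  expect_equal(m$LPCi[3], 11)           # linear LPC midpoint
  expect_equal(m$LPCi[4], 20)
  # clamping beyond 30 min
  expect_equal(unlist(metabolites_at(45)), unlist(metabolites_at(30)),
               tolerance = 1e-12)
})

test_that("ATP and pH are non-increasing, LPC non-decreasing in time", {
  tt <- seq(0, 30, by = 0.25)
  m <- metabolites_at(tt)
  expect_true(all(diff(m$ATPi) <= 1e-12))
  expect_true(all(diff(m$pHi) <= 1e-12))
  expect_true(all(diff(m$pHo) <= 1e-12))
  expect_true(all(diff(m$LPCi) >= -1e-12))
})

test_that("spatial profiles: step at the border for ATP, linear pH ramp", {
  lay <- regional_layout(tz_cm = 0.5)
  m <- metabolites_at_x(c(1.0, 1.999, 2.0, 2.25, 2.5, 3.5), 10, lay)
  nx <- normoxic_metab()
  isch <- metabolites_at(10)
  # normoxic side
  expect_equal(unlist(m[1, ]), nx, ignore_attr = TRUE)
  expect_equal(unlist(m[2, ]), nx, ignore_attr = TRUE)
  # ATP steps to the full ischemic value right at the border
  expect_equal(m$ATPi[3], isch$ATPi)
  expect_equal(m$LPCi[3], isch$LPCi)
  # but pH is still normoxic at the proximal edge of the TZ
  expect_equal(m$pHi[3], nx[["pHi"]])
  # arithmetic midpoint of the ramp at x = 2.25
  expect_equal(m$pHi[4], (nx[["pHi"]] + isch$pHi) / 2)
  expect_equal(m$pHo[4], (nx[["pHo"]] + isch$pHo) / 2)
  # fully ischemic pH beyond the TZ
  expect_equal(m$pHi[5], isch$pHi)
  expect_equal(m$pHi[6], isch$pHi)
  expect_error(metabolites_at_x(5, 10, lay), "outside")
})

test_that("pH profile is continuous in x; ATP has a single discontinuity", {
  lay <- regional_layout(tz_cm = 0.5)
  x <- seq(0, 4, by = 0.01)
  m <- metabolites_at_x(x, 20, lay)
  expect_true(all(abs(diff(m$pHi)) < 0.05))            # no jumps
  jumps <- which(abs(diff(m$ATPi)) > 1e-9)
  expect_length(jumps, 1)
  expect_equal(x[jumps], 2.0, tolerance = 0.011)
})

test_that("stimulus train arithmetic", {
  prot <- pacing_protocol(bpm = 60)
  expect_equal(prot$bcl, 1000)
  expect_equal(stimulus_at(1000.2, prot, 60), 60)      # inside the pulse
  expect_equal(stimulus_at(1000.7, prot, 60), 0)       # outside
  # quiescent protocol: identically zero, no stimulus times
  q <- pacing_protocol(bpm = 0)
  expect_true(all(stimulus_at(seq(0, 5000, 0.1), q, 60) == 0))
  expect_length(stimulus_times(q, 60000), 0)
  # integral over one period = amplitude * width
  tt <- seq(0, 1000, by = 0.005)
  ii <- stimulus_at(tt, prot, 60)
  integ <- sum(diff(tt) * (head(ii, -1) + tail(ii, -1)) / 2)
  expect_equal(integ, 60 * 0.5, tolerance = 0.01)
})

test_that("diastolic threshold: protocol amplitude fires, 0.95x does not", {
  thr <- cached("threshold", find_diastolic_threshold())
  fires <- function(amp) {
    r <- .run_cell_raw(as.numeric(cell_init_state()), cell_params(),
                       duration = 60, dt = 0.02, stim_times = 5,
                       stim_amp = amp, stim_width = 0.5)
    max(r$trace[seq_len(r$n_trace), 2]) > 0
  }
  expect_true(fires(thr))
  expect_false(fires(0.95 * thr))
  # the default protocol amplitude is twice the threshold (to ~5%)
  expect_lt(abs(scenario()$stim_amp / thr - 2), 0.15)
})
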