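# Flux rates, APD, alternans, DmKL and border-zone metrics on synthetic
# fixtures with closed-form answers, plus model-run properties.

test_that("flux rate of a zero current is zero and of a constant current is alpha*I", {
  p <- cell_params()
  z <- make_fixture("constant-current", value = 0)
  expect_equal(k_flux_rate(z, 0, 1000, p), 0)
  cc <- make_fixture("constant-current", value = 1)
  expect_equal(k_flux_rate(cc, 0, 1000, p), p$alpha * 1e6, tolerance = 1e-12)
  # incomplete window errors
  expect_error(k_flux_rate(cc, 2000, 1000, p), "window")
})

test_that("flux decomposition is additive to round-off", {
  run <- ischemia_run()
  rep <- decompose_fluxes(run, c(60000, 270000))
  comp <- as.matrix(rep[, kloss:::.k_current_names])
  expect_equal(rowSums(comp), rep$net, tolerance = 1e-10)
  expect_equal(rep$efflux + rep$influx, rep$net, tolerance = 1e-10)
})

test_that("NaK pump flux is an influx at every sampled instant", {
  run <- ischemia_run()
  m <- run$macro
  # the cumulative integral of (-2 INaK) must be strictly decreasing
  expect_true(all(diff(m$int_INaK) < 0))
})

test_that("APD90 of a trapezoidal AP equals its width at the 90% level", {
  tr <- make_fixture("square-ap", apd = 200, n_beats = 3)
  st <- c(0, 1000, 2000)
  a <- apd90(tr, stim_times = st)
  expect_equal(a, rep(200, 3), tolerance = 2)
})

test_that("alternans detection on synthetic series", {
  # constant series: no episodes
  expect_equal(nrow(detect_alternans(rep(200, 20))), 0)
  # alternating +-10 ms: one 2:2 episode spanning the series
  alt <- make_fixture("alternating-apd", base = 200, delta = 10, n = 16)
  ep <- detect_alternans(alt)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$pattern, "2:2")
  expect_lte(ep$onset_beat, 2)
  expect_equal(ep$offset_beat, 16)
  # sub-threshold alternation is ignored
  small <- make_fixture("alternating-apd", base = 200, delta = 4, n = 16)
  expect_equal(nrow(detect_alternans(small)), 0)
  # complex pattern labelled as such
  cx <- 200 + c(10, -10, 10, 10, -10, 10, -10, 10, -10, 10) *
    c(1, 1, 1, -1, 1, 1, 1, 1, 1, 1)
  cpx <- detect_alternans(c(cx, cx), min_beats = 8)
  if (nrow(cpx)) expect_true(any(cpx$pattern == "complex"))
})

test_that("DmKL: constant in normoxia, strictly increasing early in ischemia", {
  nrun <- normoxic_run()
  d_nx <- dmkl(nrun)
  d_nx <- d_nx[!is.na(d_nx)]
  expect_lt(diff(range(tail(d_nx, 5))), 0.005)
  irun <- ischemia_run()
  b <- irun$beats
  onset <- irun$scenario$normoxia_min * 60000
  sel <- b$t_stim > onset + 60000 & b$t_stim < onset + 150000  # 1-2.5 min post
  expect_true(all(diff(b$dmkl[sel]) > 0))
})

test_that("border-zone metrics on constructed profiles", {
  lay <- regional_layout()
  x <- seq(0, 4, by = 0.025)
  flat <- data.frame(x = x, Ko = rep(5.4, length(x)))
  m0 <- bz_metrics(flat, lay)
  expect_true(m0$flat)
  expect_equal(m0$width_cm, 0)
  # ramp from 5.4 at x=2 to a peak of 12 at x=3.2, then plateau
  ko <- ifelse(x < 2, 5.4, ifelse(x < 3.2, 5.4 + (12 - 5.4) * (x - 2) / 1.2, 12))
  m1 <- bz_metrics(data.frame(x = x, Ko = ko), lay)
  expect_equal(m1$width_cm, 1.2, tolerance = 0.026)
  expect_equal(m1$peak_ko, 12)
  expect_equal(m1$ciz_ko, 12, tolerance = 1e-6)
  expect_equal(m1$invasion_cm, 0)
})

test_that("net flux and concentration change agree over a window (0D, no wash-out)", {
  run <- ischemia_run()
  m <- run$macro
  t0 <- 300000; win <- 4000
  net <- kloss:::.flux_from_macro(run, t0)[["total"]]   # (umol/L)/s
  ko <- stats::approx(m$t, m$Ko, xout = c(t0, t0 + win))$y
  expect_equal(net, (ko[2] - ko[1]) / win * 1e6, tolerance = 0.02 * max(1, abs(net)))
})
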