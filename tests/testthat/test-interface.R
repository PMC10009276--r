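# Scenario plumbing: presets, serialization round-trip, bundle output,
# fixtures.

test_that("preset catalog covers the experiment grid", {
  ps <- list_presets()
  expect_true(all(c("0D-control", "0D-quiescent", "0D-alternans-suppressed",
                    "1D-control", "1D-DVx0.4", "1D-DKx10") %in% ps))
  scn <- preset_scenario("0D-control")
  expect_s3_class(scn, "kloss_scenario")
  expect_equal(scn$protocol$bpm, 60)
  expect_equal(scn$normoxia_min, 5)
  expect_error(preset_scenario("nope"), "unknown preset")
})

test_that("scenario rejects unknown keys and round-trips through YAML", {
  expect_error(scenario(bogus_key = 1), "unused argument")
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "rt", dim = "0D", duration_min = 1,
                        normoxia_min = 0.5, bpm = 120), path)
  scn <- read_scenario(path)
  expect_equal(scn$name, "rt")
  expect_equal(scn$protocol$bcl, 500)
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "bad", nonsense = TRUE), bad)
  expect_error(read_scenario(bad), "unused argument")
})

test_that("write_bundle emits a re-readable scenario snapshot and tables", {
  run <- normoxic_run()
  dir <- tempfile()
  write_bundle(run, dir)
  expect_true(file.exists(file.path(dir, "scenario.json")))
  expect_true(file.exists(file.path(dir, "trace.csv")))
  tr <- utils::read.csv(file.path(dir, "trace.csv"))
  expect_equal(nrow(tr), nrow(run$trace))
  js <- jsonlite::fromJSON(file.path(dir, "scenario.json"))
  expect_equal(js$name, run$scenario$name)
})

test_that("fixtures have their stated analytic properties", {
  sq <- make_fixture("square-ap", apd = 150, n_beats = 2)
  expect_equal(apd90(sq, stim_times = c(0, 1000)), c(150, 150), tolerance = 2)
  cc <- make_fixture("constant-current", value = 2)
  p <- cell_params()
  expect_equal(k_flux_rate(cc, 0, 1000, p), 2 * p$alpha * 1e6)
  qv <- make_fixture("quadratic-vm", n = 21, a = 1.5, dx = 0.1)
  ii <- injury_current(qv, dx_cm = 0.1, DV = 0.001)
  expect_equal(ii[5], 2 * 1.5 * 0.001, tolerance = 1e-10)
  sc <- make_fixture("short-cable", n_nodes = 7)
  expect_equal(dim(sc), c(7, 39))
})

test_that("runs are bit-reproducible from their serialized scenario", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "repro", dim = "0D", duration_min = 3 / 60,
                        normoxia_min = 0.02), path)
  r1 <- run_single_cell(read_scenario(path))
  r2 <- run_single_cell(read_scenario(path))
  expect_identical(r1$trace$Vm, r2$trace$Vm)
  expect_identical(r1$trace$Ko, r2$trace$Ko)
})
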