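# Scenario construction, preset catalog, bundle output and test fixtures.

.default_stim_amp <- 97  # uA/uF; 2x the normoxic diastolic threshold
                         # recalibrated in tests via find_diastolic_threshold()

#' Define a simulation scenario
#'
#' A scenario is a fully serializable description of one experiment:
#' dimensionality, pacing, metabolite tables, solver settings, interventions
#' and sensitivity multipliers. Unknown arguments are rejected.
#'
#' @param name scenario label.
#' @param dim `"0D"` (single cell) or `"1D"` (4-cm strand).
#' @param duration_min total simulated time, minutes.
#' @param normoxia_min minutes of normoxia before the occlusion (`Inf` for a
#'   purely normoxic run).
#' @param bpm stimulation rate, beats/min (0 = quiescent).
#' @param stim_amp stimulus amplitude, uA/uF; default is twice the normoxic
#'   diastolic threshold.
#' @param adp_variant ADP time-course variant, `"control"` or
#'   `"alternative"`.
#' @param tau_wo_normoxic_s normoxic wash-out time constant, s.
#' @param washout_in_ischemia keep wash-out active after occlusion (default
#'   FALSE: no-flow ischemia).
#' @param dt electrical time step, ms.
#' @param trace_dt trace sampling interval, ms.
#' @param macro_dt macro sampling interval, ms (1 s as in the reported
#'   potassium series).
#' @param capture_windows_ms optional n x 2 matrix of absolute-time windows
#'   (ms) in which full current records are stored.
#' @param ical_gain_tab optional n x 3 matrix (t0, t1, gain) applying a
#'   multiplicative gain to ICaL inside each window (alternans-suppression
#'   intervention).
#' @param vo_shrink logical; linear extracellular-volume shrinkage reaching
#'   -9% at 30 min post-occlusion.
#' @param clamp_ko freeze cleft potassium (baseline-regression runs).
#' @param L_cm,dx_cm,tz_cm 1D geometry: cable length, node spacing, pH
#'   transition-zone width (cm).
#' @param DV effective tissue conductivity-diffusion coefficient for Vm
#'   (cm2/ms); the default reproduces a normoxic conduction velocity of
#'   about 70 cm/s.
#' @param DK extracellular potassium diffusion coefficient, cm2/ms.
#' @param lambda extracellular-to-intracellular conductivity ratio.
#' @param dv_factor,dk_factor sensitivity multipliers applied to DV and DK.
#' @param n_stim_nodes number of stimulated leftmost nodes.
#' @param snapshot_dt 1D field snapshot interval, ms.
#' @param probe_x_cm 1D probe site positions, cm.
#' @param probe_dt probe sampling interval, ms.
#' @param transport_every apply the transport sub-step every this many
#'   electrical steps.
#' @param seed reserved; the solver is deterministic.
#' @return Object of class `kloss_scenario`.
#' @export
scenario <- function(name = "custom", dim = c("0D", "1D"),
                     duration_min = 35, normoxia_min = 5,
                     bpm = 60, stim_amp = NULL,
                     adp_variant = "control",
                     tau_wo_normoxic_s = 15, washout_in_ischemia = FALSE,
                     dt = 0.02, trace_dt = 1, macro_dt = 1000,
                     capture_windows_ms = NULL, ical_gain_tab = NULL,
                     vo_shrink = FALSE, clamp_ko = FALSE,
                     L_cm = 4, dx_cm = 0.025, tz_cm = 0.5,
                     DV = 0.0026, DK = 1.5e-8, lambda = 3.647,
                     dv_factor = 1, dk_factor = 1,
                     n_stim_nodes = 1, snapshot_dt = 60000,
                     probe_x_cm = c(1.0, 2.0, 2.5, 2.9, 3.3, 3.5),
                     probe_dt = 1, transport_every = 5, seed = NULL) {
  dim <- match.arg(dim)
  prot <- pacing_protocol(bpm = bpm, duration_min = duration_min)
  if (is.null(stim_amp)) stim_amp <- .default_stim_amp
  structure(list(
    name = name, dim = dim, duration_min = duration_min,
    normoxia_min = normoxia_min, protocol = prot, stim_amp = stim_amp,
    adp_variant = adp_variant, tau_wo_normoxic_s = tau_wo_normoxic_s,
    washout_in_ischemia = washout_in_ischemia,
    dt = dt, trace_dt = trace_dt, macro_dt = macro_dt,
    capture_windows_ms = capture_windows_ms, ical_gain_tab = ical_gain_tab,
    vo_shrink = vo_shrink, clamp_ko = clamp_ko,
    L_cm = L_cm, dx_cm = dx_cm, tz_cm = tz_cm,
    DV = DV * dv_factor, DK = DK * dk_factor, lambda = lambda,
    n_stim_nodes = n_stim_nodes, snapshot_dt = snapshot_dt,
    probe_x_cm = probe_x_cm, probe_dt = probe_dt,
    transport_every = transport_every, seed = seed), class = "kloss_scenario")
}

#' @export
print.kloss_scenario <- function(x, ...) {
  cat("<kloss_scenario>", x$name, sprintf("(%s)\n", x$dim))
  cat("  ", x$duration_min, "min total,", x$normoxia_min,
      "min normoxia,", x$protocol$bpm, "bpm\n")
  invisible(x)
}

#' Preset scenario catalog
#'
#' `0D-control` is the reference isolated-cell experiment: 5 min of
#' normoxia followed by 30 min of progressive ischemia at 1 Hz. The other
#' 0D presets vary heart rate or apply the alternans-suppression and
#' volume-shrinkage interventions. The 1D presets cover the control strand
#' and the conductivity (DV) and potassium-diffusion (DK) sensitivity grid;
#' `-fast` variants use a coarser grid and shorter ischemia for smoke runs.
#'
#' @return Character vector of preset names.
#' @export
list_presets <- function() names(.presets())

.presets <- function() {
  flux_marks <- c(0, 2.5, 5, 10, 20)   # min post-occlusion, as reported
  onset <- 5 * 60000
  capw <- cbind(onset + flux_marks * 60000, onset + flux_marks * 60000 + 4000)
  list(
    "0D-control" = function() scenario("0D-control", "0D",
                                       capture_windows_ms = capw),
    "0D-quiescent" = function() scenario("0D-quiescent", "0D", bpm = 0),
    "0D-30bpm" = function() scenario("0D-30bpm", "0D", bpm = 30),
    "0D-120bpm" = function() scenario("0D-120bpm", "0D", bpm = 120),
    "0D-180bpm" = function() scenario("0D-180bpm", "0D", bpm = 180),
    "0D-alternans-suppressed" = function()
      scenario("0D-alternans-suppressed", "0D",
               ical_gain_tab = cbind(5 * 60000 + 3.5 * 60000,
                                     5 * 60000 + 8 * 60000, 2.5)),
    "0D-volume-shrinkage" = function()
      scenario("0D-volume-shrinkage", "0D", vo_shrink = TRUE),
    "0D-adp-variant" = function()
      scenario("0D-adp-variant", "0D", adp_variant = "alternative"),
    "1D-control" = function() scenario("1D-control", "1D"),
    "1D-DVx0.8" = function() scenario("1D-DVx0.8", "1D", dv_factor = 0.8),
    "1D-DVx0.4" = function() scenario("1D-DVx0.4", "1D", dv_factor = 0.4),
    "1D-DVx0.19" = function() scenario("1D-DVx0.19", "1D", dv_factor = 0.19),
    "1D-DKx0" = function() scenario("1D-DKx0", "1D", dk_factor = 0),
    "1D-DKx10" = function() scenario("1D-DKx10", "1D", dk_factor = 10),
    "1D-DKx100" = function() scenario("1D-DKx100", "1D", dk_factor = 100),
    "1D-TZ0" = function() scenario("1D-TZ0", "1D", tz_cm = 0),
    "1D-TZ1" = function() scenario("1D-TZ1", "1D", tz_cm = 1),
    "1D-control-fast" = function()
      scenario("1D-control-fast", "1D", duration_min = 9, normoxia_min = 1,
               dx_cm = 0.05, dt = 0.04, snapshot_dt = 30000)
  )
}

#' @rdname list_presets
#' @param name preset name.
#' @export
preset_scenario <- function(name) {
  ps <- .presets()
  if (!name %in% names(ps))
    stop("unknown preset '", name, "'; see list_presets()")
  ps[[name]]()
}

#' Run a scenario end to end
#'
#' Dispatches to [run_single_cell()] or [run_cable()] and attaches standard
#' analysis reports (flux decomposition at the reported marks for 0D runs,
#' border-zone metrics for 1D runs).
#'
#' @param scn a `kloss_scenario`, a preset name, or a path to a YAML/JSON
#'   scenario file (see [read_scenario()]).
#' @param params from [cell_params()].
#' @return The run object with an added `reports` element.
#' @export
run_scenario <- function(scn, params = cell_params()) {
  if (is.character(scn)) {
    scn <- if (file.exists(scn)) read_scenario(scn) else preset_scenario(scn)
  }
  stopifnot(inherits(scn, "kloss_scenario"))
  if (scn$dim == "0D") {
    run <- run_single_cell(scn, params = params)
    marks <- (scn$normoxia_min + c(0, 2.5, 5, 10, 20)) * 60000
    marks <- marks[marks + 4 * run$scenario$protocol$bcl <=
                     scn$duration_min * 60000]
    run$reports <- list(flux = tryCatch(decompose_fluxes(run, marks),
                                        error = function(e) NULL))
  } else {
    run <- run_cable(scn, params = params)
    last <- run$snapshots$t[length(run$snapshots$t)]
    run$reports <- list(bz = bz_metrics(profile_at(run, last),
                                        regional_layout(scn$L_cm, 2,
                                                        scn$tz_cm)))
  }
  run
}

#' Read a scenario from a YAML or JSON file
#'
#' The file holds named [scenario()] arguments; unknown keys are rejected.
#'
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @return A `kloss_scenario`.
#' @export
read_scenario <- function(path) {
  args <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  for (nm in c("capture_windows_ms", "ical_gain_tab"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.matrix(args[[nm]])
  do.call(scenario, args)
}

#' Write the main outputs of a run as plain files
#'
#' Emits the scenario (JSON), trace and macro tables (CSV) and, for 1D
#' runs, field snapshots (CSV), into a directory.
#'
#' @param run a `kloss_run` or `kloss_cable_run`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scn <- run$scenario
  scn$protocol <- NULL
  jsonlite::write_json(scn[!vapply(scn, is.null, TRUE)],
                       file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA)
  if (inherits(run, "kloss_run")) {
    utils::write.csv(run$trace, file.path(dir, "trace.csv"), row.names = FALSE)
    utils::write.csv(run$macro, file.path(dir, "macro.csv"), row.names = FALSE)
    utils::write.csv(run$beats, file.path(dir, "beats.csv"), row.names = FALSE)
  } else {
    utils::write.csv(cbind(t = run$snapshots$t, run$snapshots$Ko),
                     file.path(dir, "ko_profiles.csv"), row.names = FALSE)
    utils::write.csv(cbind(t = run$snapshots$t, run$snapshots$Vm),
                     file.path(dir, "vm_profiles.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Deterministic synthetic fixtures for unit tests
#'
#' @param kind one of `"square-ap"` (trapezoidal AP trace),
#'   `"constant-current"`, `"quadratic-vm"` (prescribed parabolic Vm
#'   profile), `"alternating-apd"` (APD series with 2:2 alternation),
#'   `"short-cable"` (a tiny uniform normoxic cable state).
#' @param ... kind-specific settings: `apd`, `bcl`, `n_beats`, `amp_mV`
#'   (square-ap); `value`, `duration`, `dt` (constant-current); `n`, `a`,
#'   `dx` (quadratic-vm); `base`, `delta`, `n` (alternating-apd);
#'   `n_nodes` (short-cable).
#' @return Fixture object (data frame, vector or matrix by kind).
#' @export
make_fixture <- function(kind = c("square-ap", "constant-current",
                                  "quadratic-vm", "alternating-apd",
                                  "short-cable"), ...) {
  kind <- match.arg(kind)
  opt <- list(...)
  g <- function(nm, dflt) if (is.null(opt[[nm]])) dflt else opt[[nm]]
  switch(kind,
    "square-ap" = {
      apd <- g("apd", 200); bcl <- g("bcl", 1000); nb <- g("n_beats", 3)
      amp <- g("amp_mV", 120); dt <- g("dt", 1)
      t <- seq(0, nb * bcl, by = dt)
      rest <- -85
      ph <- t %% bcl
      vm <- ifelse(ph >= 2 & ph < 2 + apd, rest + amp, rest)
      # 1-ms linear upstroke ramp so dV/dt max is defined at the rise
      data.frame(t = t, Vm = vm)
    },
    "constant-current" = {
      val <- g("value", 1); dur <- g("duration", 4000); dt <- g("dt", 1)
      data.frame(t = seq(0, dur, by = dt),
                 I = rep(val, length(seq(0, dur, by = dt))))
    },
    "quadratic-vm" = {
      n <- g("n", 41); a <- g("a", 2); dx <- g("dx", 0.025)
      x <- (seq_len(n) - 1) * dx
      a * x^2
    },
    "alternating-apd" = {
      base <- g("base", 200); delta <- g("delta", 10); n <- g("n", 12)
      base + rep(c(delta, -delta) / 2, length.out = n)
    },
    "short-cable" = {
      nn <- g("n_nodes", 11)
      matrix(rep(as.numeric(cell_init_state()), each = nn), nrow = nn)
    })
}
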