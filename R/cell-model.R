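# Ischemia-modified cell model: factor curves, right-hand side, 0D runner.
# The numerical core lives in src/cellmodel.cpp; the wrappers here validate
# domains and expose the model to R.

.metab_vec <- function(metab) {
  if (is.data.frame(metab)) metab <- unlist(metab[1, ])
  m <- as.numeric(metab[c("ATPi", "ADPi", "pHi", "pHo", "LPCi")])
  if (anyNA(m)) stop("metabolic state must contain ATPi, ADPi, pHi, pHo, LPCi")
  m
}

#' ATP-sensitive potassium current
#'
#' Ferrero-type formulation: a fully-activated conductance scaled by the
#' fraction of open (ATP-unblocked) channels, with ADP shifting both the
#' half-saturation and the Hill coefficient of the ATP block, and a weak
#' (Ko/5.4)^0.24 dependence on cleft potassium. Outward-positive; zero at
#' the potassium Nernst potential.
#'
#' @param vm membrane potential, mV.
#' @param ko cleft potassium, mmol/L.
#' @param atp intracellular ATP, mmol/L.
#' @param adp intracellular free ADP, umol/L.
#' @param params from [cell_params()].
#' @param ki intracellular potassium, mmol/L (sets the Nernst potential).
#' @return Current density, uA/uF.
#' @export
ikatp_current <- function(vm, ko, atp, adp, params = cell_params(),
                          ki = cell_init_state()[["Ki"]]) {
  if (any(ko <= 0)) stop("Ko must be positive")
  if (any(atp <= 0)) stop("ATPi must be positive")
  mapply(function(v, k, a, d) .ikatp_cpp(v, k, a, d, params$gkatp,
                                         params$katp_ko_exp,
                                         params$katp_h_mult, ki),
         vm, ko, atp, adp)
}

#' Metabolic scaling of the membrane and SR pumps
#'
#' ATP/ADP-dependent multiplicative factors applied to the NaK pump, the
#' sarcolemmal calcium pump and SERCA uptake. Each factor is 1 at the
#' normoxic anchor (ATP 10 mmol/L, ADP 15 umol/L) and decreases
#' monotonically as ATP falls; the NaK factor additionally carries ADP
#' product inhibition.
#'
#' @inheritParams ikatp_current
#' @return Named vector `(fNaK, fpCa, fup)`, each in (0, 1].
#' @export
pump_scaling <- function(atp, adp, params = cell_params()) {
  if (any(atp <= 0)) stop("ATPi must be positive")
  if (length(atp) == 1 && length(adp) == 1)
    return(.pump_scaling_cpp(atp, adp, params))
  t(mapply(function(a, d) .pump_scaling_cpp(a, d, params), atp, adp))
}

#' Acidosis scaling of pH-sensitive currents
#'
#' Linear fractional reduction per pH unit below the normoxic anchors
#' (pHi 7.2, pHo 7.4), one slope per current, floored at 0.05.
#'
#' @param phi intracellular pH.
#' @param pho extracellular pH.
#' @inheritParams ikatp_current
#' @return Named vector of factors for ICaL, INa, INaL, INaCa, INaK.
#' @export
acidosis_scaling <- function(phi, pho, params = cell_params()) {
  if (any(phi < 5.5 | phi > 7.6) || any(pho < 5.5 | pho > 7.6))
    stop("pH outside the physiological range [5.5, 7.6]")
  if (length(phi) == 1 && length(pho) == 1)
    return(.acidosis_scaling_cpp(phi, pho, params))
  t(mapply(function(a, b) .acidosis_scaling_cpp(a, b, params), phi, pho))
}

#' LPC scaling of the sodium currents
#'
#' Lysophosphatidylcholine depresses peak INa and enhances the late
#' component INaL; both effects are linear in the LPC excess over the
#' normoxic 2 umol/L.
#'
#' @param lpc intracellular LPC, umol/L.
#' @inheritParams ikatp_current
#' @return Named vector `(INa, INaL)` of multiplicative factors.
#' @export
lpc_scaling <- function(lpc, params = cell_params()) {
  if (any(lpc < 0)) stop("LPCi must be non-negative")
  fna <- pmax(1 - params$lpc_na * (lpc - 2), 0.05)
  fnal <- 1 + params$lpc_nal * (lpc - 2)
  if (length(lpc) == 1) c(INa = fna, INaL = fnal)
  else cbind(INa = fna, INaL = fnal)
}

#' Right-hand side of the cell model
#'
#' Time derivatives of the full state and the instantaneous record of all
#' transmembrane current densities, under a given metabolic state and
#' stimulus. The cleft-potassium derivative is
#' `alpha * SumIKx + (kb - Ko)/tau_wo`, with the wash-out term dropped when
#' `tau_wo` is infinite.
#'
#' @param state named state vector as in [cell_init_state()].
#' @param metab metabolic state (named vector or one-row data frame).
#' @param istm stimulus current density, uA/uF (positive = depolarizing).
#' @param params from [cell_params()].
#' @return List with `deriv` (named, d/dt in per-ms units) and `currents`
#'   (named record incl. the consistency sum `SumIKx`).
#' @export
cell_rhs <- function(state, metab = normoxic_metab(), istm = 0,
                     params = cell_params()) {
  out <- .cell_rhs_cpp(as.numeric(state), .metab_vec(metab), istm, params)
  names(out$deriv) <- .state_names
  names(out$currents) <- .current_names
  out
}

# low-level fixed-step runner; times in ms
.run_cell_raw <- function(init, params, duration, dt = 0.02,
                          stim_times = numeric(0), stim_amp = 0,
                          stim_width = 0.5, metab_tab = NULL,
                          trace_dt = 1, macro_dt = 1000,
                          capture_windows = NULL, ical_gain = NULL,
                          shrink_tab = NULL) {
  if (is.null(metab_tab)) {
    nx <- normoxic_metab()
    metab_tab <- matrix(c(0, nx, duration, nx), nrow = 2, byrow = TRUE)
  }
  if (is.null(capture_windows)) capture_windows <- matrix(0, 0, 2)
  if (is.null(ical_gain)) ical_gain <- matrix(0, 0, 3)
  if (is.null(shrink_tab)) shrink_tab <- matrix(0, 0, 2)
  .run_cell_cpp(as.numeric(init), params, duration, dt,
                as.numeric(stim_times), stim_amp, stim_width,
                metab_tab, trace_dt, macro_dt,
                capture_windows, ical_gain, shrink_tab)
}

# metabolite table (ms cadence) for a scenario phase:
# normoxic up to onset_ms, course beyond
.build_metab_tab <- function(duration_ms, onset_ms, tables, step_ms = 1000) {
  tt <- seq(0, duration_ms, by = step_ms)
  if (!is.finite(onset_ms) || onset_ms >= duration_ms) {
    nx <- normoxic_metab()
    return(cbind(t = c(0, duration_ms),
                 matrix(rep(nx, each = 2), nrow = 2,
                        dimnames = list(NULL, names(nx)))))
  }
  t_rel_min <- pmax(tt - onset_ms, 0) / 60000
  mb <- metabolites_at(t_rel_min, tables)
  pre <- tt <= onset_ms
  nx <- normoxic_metab()
  mb[pre, ] <- as.list(nx)
  as.matrix(cbind(t = tt, mb))
}

#' Run a single-cell (0D) scenario
#'
#' Simulates a normoxic pre-phase followed by progressive ischemia with the
#' prescribed metabolite time courses, pacing the cell with the scenario's
#' stimulation protocol. Wash-out (15 s time constant) operates during
#' normoxia and is switched off (infinite time constant) at the occlusion,
#' mimicking the loss of perfusion.
#'
#' @param scn scenario from [scenario()] or a preset name (see
#'   [list_presets()]).
#' @param params from [cell_params()].
#' @param init initial state; defaults to the stored normoxic steady state.
#' @return Object of class `kloss_run` with elements `trace` (time, Vm, Ko,
#'   Istm at `trace_dt` resolution), `macro` (1-s sampled concentrations and
#'   running time-integrals of each potassium-carrying current),
#'   `capture` (full current records inside requested windows), `beats`
#'   (per-beat metrics), `stim_times`, `final_state`, `scenario`, `params`.
#' @export
run_single_cell <- function(scn, params = cell_params(),
                            init = cell_init_state()) {
  if (is.character(scn)) scn <- preset_scenario(scn)
  stopifnot(inherits(scn, "kloss_scenario"))
  if (scn$dim != "0D") stop("run_single_cell() needs a 0D scenario")

  duration <- scn$duration_min * 60000
  onset <- scn$normoxia_min * 60000
  tables <- metabolite_tables(scn$adp_variant)
  amp <- scn$stim_amp
  prot <- scn$protocol
  st <- stimulus_times(prot, duration)
  capw <- scn$capture_windows_ms
  if (is.null(capw)) capw <- matrix(0, 0, 2)

  p1 <- params
  p1$tau_wo <- scn$tau_wo_normoxic_s * 1000
  p2 <- params
  p2$tau_wo <- if (scn$washout_in_ischemia) scn$tau_wo_normoxic_s * 1000 else Inf

  gain_tab <- scn$ical_gain_tab
  shrink_tab <- if (isTRUE(scn$vo_shrink))
    matrix(c(onset, onset + 30 * 60000, 0, 0.09), 2, 2) else NULL

  t0 <- 0
  seg_ends <- c(min(onset, duration), duration)
  seg_ends <- unique(seg_ends[seg_ends > 0])
  state <- as.numeric(init)
  out_trace <- list(); out_macro <- list(); out_cap <- list()
  cum_off <- rep(0, 9)
  for (si in seq_along(seg_ends)) {
    t1 <- seg_ends[si]
    p <- if (t0 < onset) p1 else p2
    span <- t1 - t0
    if (span <= 0) { t0 <- t1; next }
    mt <- .build_metab_tab(duration, onset, tables)
    mt_local <- mt
    mt_local[, 1] <- mt[, 1] - t0
    st_local <- st[st >= t0 - 1e-9 & st < t1] - t0
    cw_local <- capw
    if (nrow(cw_local)) {
      keep <- capw[, 2] > t0 & capw[, 1] < t1
      cw_local <- capw[keep, , drop = FALSE] - t0
    }
    gl <- gain_tab
    if (!is.null(gl) && nrow(gl)) {
      gl[, 1:2] <- gl[, 1:2] - t0
    } else gl <- NULL
    sh <- shrink_tab
    if (!is.null(sh)) sh[, 1] <- sh[, 1] - t0
    r <- .run_cell_raw(state, p, span, dt = scn$dt,
                       stim_times = st_local, stim_amp = amp,
                       stim_width = prot$width_ms, metab_tab = mt_local,
                       trace_dt = scn$trace_dt, macro_dt = scn$macro_dt,
                       capture_windows = cw_local, ical_gain = gl,
                       shrink_tab = sh)
    tr <- r$trace[seq_len(r$n_trace), , drop = FALSE]
    mc <- r$macro[seq_len(r$n_macro), , drop = FALSE]
    cp <- r$capture[seq_len(r$n_capture), , drop = FALSE]
    tr[, 1] <- tr[, 1] + t0
    mc[, 1] <- mc[, 1] + t0
    mc[, 6:14] <- sweep(mc[, 6:14, drop = FALSE], 2, cum_off, "+")
    if (nrow(cp)) cp[, 1] <- cp[, 1] + t0
    # avoid duplicating the boundary sample
    if (si > 1) { tr <- tr[-1, , drop = FALSE]; mc <- mc[-1, , drop = FALSE] }
    out_trace[[si]] <- tr; out_macro[[si]] <- mc; out_cap[[si]] <- cp
    cum_off <- mc[nrow(mc), 6:14]
    state <- r$final_state
    t0 <- t1
  }

  trace <- as.data.frame(do.call(rbind, out_trace))
  names(trace) <- c("t", "Vm", "Ko", "Istm")
  macro <- as.data.frame(do.call(rbind, out_macro))
  names(macro) <- c("t", "Ko", "Nai", "Ki", "Cai",
                    paste0("int_", .k_current_names), "int_SumIKx")
  capture <- as.data.frame(do.call(rbind, out_cap))
  if (nrow(capture)) names(capture) <- c("t", "Vm", .current_names)

  names(state) <- .state_names
  run <- structure(list(trace = trace, macro = macro, capture = capture,
                        stim_times = st, final_state = state,
                        scenario = scn, params = params), class = "kloss_run")
  run$beats <- beat_metrics(run)
  run
}

#' @export
print.kloss_run <- function(x, ...) {
  cat("<kloss_run>", x$scenario$name, "\n")
  cat("  duration:", x$scenario$duration_min, "min;",
      nrow(x$trace), "trace samples;", nrow(x$beats), "beats\n")
  cat("  final Ko:", round(utils::tail(x$trace$Ko, 1), 3), "mmol/L\n")
  invisible(x)
}
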