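# Time courses of the five ischemic drivers, their spatial layout along the
# strand, and the stimulation protocol.

#' Load the metabolite time-course tables
#'
#' The time evolution of the ischemic drivers over the first 30 min of
#' no-flow ischemia is prescribed, not mechanistically modelled: ATP, ADP and
#' pH follow digitized control points of published guinea-pig time courses
#' (shipped as plain CSV under `extdata/metabolites`), and intracellular LPC
#' is exactly linear from 2 to 20 umol/L over 30 min. An alternative,
#' slower ADP profile is available for sensitivity runs.
#'
#' @param adp_variant `"control"` (default) or `"alternative"`.
#' @return Named list of data frames with columns `t_min`, `value`.
#' @export
metabolite_tables <- function(adp_variant = c("control", "alternative")) {
  adp_variant <- match.arg(adp_variant)
  dir <- system.file("extdata", "metabolites", package = "kloss")
  rd <- function(f) utils::read.csv(file.path(dir, f))
  list(
    ATPi = rd("atp.csv"),
    ADPi = rd(if (adp_variant == "control") "adp.csv" else "adp_alt.csv"),
    pHi = rd("phi.csv"),
    pHo = rd("pho.csv"),
    LPCi = rd("lpc.csv")
  )
}

.interp_course <- function(tab, t_min) {
  t_min <- pmin(pmax(t_min, 0), max(tab$t_min))
  if (nrow(tab) == 2) { # exactly linear course (LPC)
    return(stats::approx(tab$t_min, tab$value, xout = t_min, rule = 2)$y)
  }
  f <- stats::splinefun(tab$t_min, tab$value, method = "monoH.FC")
  f(t_min)
}

#' Metabolic state at a time since the onset of ischemia
#'
#' Piecewise-monotone interpolation of the driver time courses. Times at or
#' before the occlusion return the normoxic anchors; times beyond 30 min are
#' clamped at the 30-min values.
#'
#' @param t_min minutes since occlusion (vectorized).
#' @param tables from [metabolite_tables()].
#' @return Data frame with columns `ATPi` (mmol/L), `ADPi` (umol/L),
#'   `pHi`, `pHo`, `LPCi` (umol/L), one row per element of `t_min`.
#' @export
metabolites_at <- function(t_min, tables = metabolite_tables()) {
  nx <- normoxic_metab()
  out <- data.frame(
    ATPi = .interp_course(tables$ATPi, t_min),
    ADPi = .interp_course(tables$ADPi, t_min),
    pHi = .interp_course(tables$pHi, t_min),
    pHo = .interp_course(tables$pHo, t_min),
    LPCi = .interp_course(tables$LPCi, t_min)
  )
  pre <- t_min <= 0
  if (any(pre)) out[pre, ] <- as.list(nx)
  out
}

#' Regional layout of the 4-cm strand
#'
#' The first 2 cm of the cable are normoxic, the remainder is the altered
#' (ischemic) segment. ATP, ADP and LPC change stepwise at the metabolic
#' border at x = 2 cm; pHi and pHo ramp linearly over a transition zone of
#' width `tz_cm` starting at the border.
#'
#' @param L_cm cable length (cm).
#' @param border_cm position of the metabolic border (cm).
#' @param tz_cm pH transition-zone width (cm); 0, 0.5 or 1 in the presets.
#' @return List with the layout fields.
#' @export
regional_layout <- function(L_cm = 4, border_cm = 2, tz_cm = 0.5) {
  stopifnot(L_cm > 0, border_cm > 0, border_cm < L_cm,
            tz_cm >= 0, border_cm + tz_cm <= L_cm)
  list(L_cm = L_cm, border_cm = border_cm, tz_cm = tz_cm)
}

#' Metabolic state at a position and time in the strand
#'
#' @param x_cm position along the cable (cm, vectorized).
#' @param t_min minutes since occlusion.
#' @param layout from [regional_layout()].
#' @param tables from [metabolite_tables()].
#' @return Data frame as in [metabolites_at()], one row per `x_cm`.
#' @export
metabolites_at_x <- function(x_cm, t_min, layout = regional_layout(),
                             tables = metabolite_tables()) {
  if (any(x_cm < 0 | x_cm > layout$L_cm))
    stop("x outside the cable [0, ", layout$L_cm, "] cm")
  stopifnot(length(t_min) == 1)
  nx <- normoxic_metab()
  isch <- metabolites_at(t_min, tables)
  w <- ph_ramp_weight(x_cm, layout)
  ischemic <- x_cm >= layout$border_cm
  out <- data.frame(
    ATPi = ifelse(ischemic, isch$ATPi, nx[["ATPi"]]),
    ADPi = ifelse(ischemic, isch$ADPi, nx[["ADPi"]]),
    pHi = nx[["pHi"]] + w * (isch$pHi - nx[["pHi"]]),
    pHo = nx[["pHo"]] + w * (isch$pHo - nx[["pHo"]]),
    LPCi = ifelse(ischemic, isch$LPCi, nx[["LPCi"]])
  )
  out
}

#' pH transition-zone ramp weight
#'
#' 0 in the normoxic segment and at the proximal edge of the transition
#' zone, 1 beyond it; linear within. A zero-width transition zone gives a
#' step at the border.
#'
#' @inheritParams metabolites_at_x
#' @return Numeric vector in `[0, 1]`.
#' @export
ph_ramp_weight <- function(x_cm, layout = regional_layout()) {
  if (layout$tz_cm == 0) return(as.numeric(x_cm >= layout$border_cm))
  w <- (x_cm - layout$border_cm) / layout$tz_cm
  pmin(pmax(w, 0), 1)
}

#' Pacing protocol
#'
#' Rectangular stimulus pulses 0.5 ms wide and (by default) twice the
#' normoxic diastolic threshold in amplitude. `bpm = 0` means a quiescent
#' (unstimulated) preparation.
#'
#' @param bpm stimulation rate, beats per minute.
#' @param width_ms pulse width, ms.
#' @param amp_factor amplitude as a multiple of the diastolic threshold.
#' @param duration_min protocol duration, minutes.
#' @return List describing the protocol, including `bcl` in ms
#'   (`Inf` for a quiescent protocol).
#' @export
pacing_protocol <- function(bpm = 60, width_ms = 0.5, amp_factor = 2,
                            duration_min = 35) {
  stopifnot(bpm >= 0, width_ms > 0, amp_factor > 0, duration_min > 0)
  list(bpm = bpm, bcl = if (bpm > 0) 60000 / bpm else Inf,
       width_ms = width_ms, amp_factor = amp_factor,
       duration_min = duration_min)
}

#' Stimulus train onset times
#'
#' @param protocol from [pacing_protocol()].
#' @param duration_ms span to cover, ms.
#' @return Numeric vector of pulse onset times (ms); empty if quiescent.
#' @export
stimulus_times <- function(protocol, duration_ms) {
  if (protocol$bpm == 0) return(numeric(0))
  seq(0, duration_ms - 1e-9, by = protocol$bcl)
}

#' Stimulus current at a time
#'
#' @param t_ms time (ms, vectorized).
#' @param protocol from [pacing_protocol()].
#' @param amplitude pulse amplitude, uA/uF (positive = depolarizing).
#' @return Istm at each `t_ms`, uA/uF.
#' @export
stimulus_at <- function(t_ms, protocol, amplitude) {
  if (protocol$bpm == 0) return(rep(0, length(t_ms)))
  phase <- t_ms %% protocol$bcl
  ifelse(t_ms >= 0 & phase < protocol$width_ms, amplitude, 0)
}

#' Normoxic diastolic stimulation threshold
#'
#' Bisection on the amplitude of a single 0.5-ms diastolic pulse applied to
#' the steady-paced normoxic cell, to 1% relative precision. An action
#' potential is deemed elicited when the peak Vm within 50 ms of the pulse
#' exceeds `ap_peak_mV`.
#'
#' @param params from [cell_params()].
#' @param init diastolic state; defaults to the stored steady state.
#' @param width_ms pulse width, ms.
#' @param ap_peak_mV peak-voltage criterion for a fired AP, mV.
#' @param lo,hi initial amplitude bracket, uA/uF.
#' @return Threshold amplitude (uA/uF).
#' @export
find_diastolic_threshold <- function(params = cell_params(),
                                     init = cell_init_state(),
                                     width_ms = 0.5, ap_peak_mV = 0,
                                     lo = 5, hi = 200) {
  fires <- function(amp) {
    run <- .run_cell_raw(init, params, duration = 60, dt = 0.02,
                         stim_times = 5, stim_amp = amp,
                         stim_width = width_ms)
    max(run$trace[, 2]) > ap_peak_mV
  }
  if (fires(lo)) stop("lower bracket already fires; reduce `lo`")
  if (!fires(hi)) stop("no finite bracketing interval: upper bracket does not fire")
  while ((hi - lo) / hi > 0.01) {
    mid <- 0.5 * (lo + hi)
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}
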