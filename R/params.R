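#' Cell and ischemia-factor parameters
#'
#' Returns the full parameter set of the ischemia-modified cell model.
#' Membrane capacitance is 1 uF/cm2 and all current densities are in uA/uF.
#'
#' The raw geometric anchors of the extracellular cleft (capacitive surface
#' `Ac` = 0.0152 mm2, cleft volume `vo` = 13.3 um3) are dimensionally
#' inconsistent with the observed normoxic potassium turnover, so the
#' bookkeeping prefactor Ac/(F*vo) entering the cleft-potassium balance is a
#' single calibrated constant (`alpha`, in (mmol/L)/ms per uA/uF), fixed by
#' requiring the unidirectional potassium efflux rate of the normoxic cell
#' paced at 1 Hz to equal 34.5 (umol/L)/s. The raw anchors are kept in the
#' returned list for reference.
#'
#' The ischemia-factor curves (K(ATP) gating, pump scaling, acidosis and LPC
#' scaling) are parametric forms constrained by their normoxic anchors and
#' monotonicity; their parameters are model fits, not literature constants.
#'
#' @param ... named overrides of any returned element.
#' @return A list of model parameters.
#' @export
cell_params <- function(...) {
  p <- list(
    # physical constants and geometry
    Cm = 1.0,                # uF/cm2
    F = 96485, R = 8314, T = 310,
    Ac_raw = 0.0152,         # mm2 (reference only)
    vo_raw = 13.3,           # um3 (reference only)
    # calibrated cleft-potassium bookkeeping prefactor, (mmol/L)/ms per uA/uF
    alpha = 1.120912e-4,
    kb = 5.4,                # bulk [K+], mmol/L
    tau_wo = 15000,          # wash-out time constant, ms (Inf = no wash-out)
    # K(ATP) current (Ferrero-type gating, human-adapted conductance)
    gkatp = 165,             # mS/uF, fully-activated
    katp_ko_exp = 1.3,
    katp_h_mult = 1.8,       # ATP-block steepening (silent in normoxia)
    # IK1 conductance factor, calibrated to the ischemic diastolic efflux
    gk1_mult = 2.0,
    # NaK pump metabolic scaling (ATP activation x ADP product inhibition)
    nak_katp = 3.6, nak_hatp = 2.0,
    nak_kadp = 42, nak_hadp = 1.5,
    # sarcolemmal Ca pump and SERCA ATP dependence
    pca_katp = 0.5, pca_hatp = 2.0,
    up_katp = 2.0, up_hatp = 2.0,
    # acidosis scaling slopes, fractional reduction per pH unit
    aci_cal = 0.417, aci_na = 0.21, aci_nal = 0.21,
    aci_naca = 0.25, aci_nak = 0.17,
    # LPC scaling slopes per umol/L above the normoxic 2 umol/L
    lpc_na = 0.010, lpc_nal = 0.050,
    # late-Na conductance factor of the INa/INaL modification, calibrated
    # against the normoxic APD90 of the paced endocardial cell
    gna_mod = 1.0,       # peak-Na conductance factor
    na_tm_mult = 2.1,    # INa activation time-constant factor (CV calibration)
    na_h_shift = -5,     # shift of INa steady-state inactivation, mV
    gnal_mod = 1.5,
    hl_shift = 20,       # depolarizing shift of INaL inactivation, mV
    # per-current conductance multipliers (fixture and intervention hooks)
    current_scale = stats::setNames(rep(1, 17), .current_names[1:17]),
    clamp_ko = FALSE
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  p
}

#' Normoxic metabolic state
#'
#' The normoxic anchors of the five ischemic drivers:
#' intracellular ATP 10 mmol/L, intracellular free ADP 15 umol/L,
#' pHi 7.2, pHo 7.4, intracellular LPC 2 umol/L.
#'
#' @return Named numeric vector `(ATPi, ADPi, pHi, pHo, LPCi)`.
#' @export
normoxic_metab <- function() {
  c(ATPi = 10, ADPi = 15, pHi = 7.2, pHo = 7.4, LPCi = 2)
}

#' Initial state vector of the cell model
#'
#' State of the normoxic endocardial cell paced to steady state at 1 Hz
#' (with dynamic cleft potassium and 15 s wash-out), taken at diastole.
#' Derived by long pre-pacing with [make_steady_state()]; stored so that
#' simulations start close to limit-cycle conditions.
#'
#' @return Named numeric vector of length 39.
#' @export
cell_init_state <- function() {
  s <- .init_state_values
  names(s) <- .state_names
  s
}

.state_names <- c("V", "Nai", "Nass", "Ki", "Kss", "Cai", "Cass",
                  "Cansr", "Cajsr", "m", "h", "j", "mL", "hL", "hLp",
                  "a", "iF", "iS", "ap", "iFp", "iSp",
                  "d", "ff", "fs", "fcaf", "fcas", "jca", "nca",
                  "ffp", "fcafp", "xrf", "xrs", "xs1", "xs2", "xk1",
                  "Jrelnp", "Jrelp", "CaMKt", "Ko")

# normoxic 1 Hz limit-cycle state (long pre-pacing at dt = 0.02 ms)
.init_state_values <- c(
  -87.100061, 7.3584047, 7.3584929, 142.13921, 142.13918, 8.5711593e-05, 8.4685169e-05, 1.6284191, 1.5733119, 0.0011514524, 0.64850676, 0.64800018, 0.00022343532, 0.90964371, 0.72687054, 0.0010638491, 0.99947787, 0.56870847, 0.00054207655, 0.99947789, 0.61659932, 2.8970965e-09, 0.99999999, 0.89149658, 0.99999999, 0.99971473, 0.99996226, 0.0027195322, 0.99999999, 0.99999999, 9.3310687e-06, 0.47675768, 0.30764331, 0.00021340728, 0.99686266, 3.0494728e-07, 3.809654e-07, 0.013901471, 5.4774925)

#' Re-derive the stored steady-state initial condition
#'
#' Paces the normoxic cell at the given cycle length until the state reaches
#' its limit cycle and returns the diastolic state just before a stimulus.
#'
#' @param n_beats number of pre-pacing beats.
#' @param bcl basic cycle length, ms.
#' @param params parameter list from [cell_params()].
#' @return Named state vector of length 39.
#' @export
make_steady_state <- function(n_beats = 500, bcl = 1000, params = cell_params()) {
  sc <- scenario(name = "prepace", duration_min = n_beats * bcl / 60000,
                 bpm = 60000 / bcl, normoxia_min = Inf)
  run <- run_single_cell(sc, params = params, init = cell_init_state())
  s <- run$final_state
  names(s) <- .state_names
  s
}
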