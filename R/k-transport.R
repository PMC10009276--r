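# Extracellular potassium transport: diffusion + electromigration
# (Nernst-Planck), transmembrane source and wash-out, zero-flux ends.

#' One explicit step of the extracellular potassium transport equation
#'
#' Conservative flux-form discretization of
#' d[K]o/dt = DK d/dx(d[K]o/dx + F/RT [K]o dVo/dx)
#'            + alpha SumIKx + ([K]b - [K]o)/tau_wo
#' with zero total flux through both ends. Face fluxes use arithmetic-mean
#' [K]o for the electromigration (drift) term. Exposed for unit testing;
#' inside [run_cable()] the same kernel runs sub-cycled against the
#' electrical step.
#'
#' @param ko potassium profile, mmol/L.
#' @param vo extracellular potential profile, mV.
#' @param sumikx total transmembrane potassium current per node, uA/uF
#'   (zero vector for pure-transport tests).
#' @param dt time step, ms.
#' @param dx node spacing, cm.
#' @param DK potassium diffusion coefficient, cm2/ms.
#' @param tau_wo wash-out time constant per node, ms (`Inf` = none);
#'   recycled to the profile length.
#' @param params from [cell_params()]; supplies `alpha` and `kb`.
#' @return Updated Ko profile.
#' @export
step_k_transport <- function(ko, vo, sumikx = rep(0, length(ko)), dt, dx,
                             DK = 1.5e-8, tau_wo = Inf,
                             params = cell_params()) {
  stopifnot(length(vo) == length(ko), length(sumikx) == length(ko))
  if (DK > 0 && dt * DK / dx^2 > 0.5)
    stop("explicit stability bound violated for DK")
  tau <- rep_len(tau_wo, length(ko))
  .k_transport_step_cpp(ko, vo, sumikx, tau, dt, dx, DK,
                        params$alpha, params$kb)
}

#' Net transport (diffusion + drift) flux rate at a site
#'
#' The local contribution of the transport operator to d[K]o/dt, i.e. the
#' divergence of the diffusive plus electromigration flux, evaluated at a
#' position and averaged over a window of snapshots. Units: (umol/L)/s,
#' positive = local potassium gain by transport. In the coupled model this
#' term is orders of magnitude smaller than the transmembrane flux rates.
#'
#' @param run a `kloss_cable_run`.
#' @param x_cm site, cm.
#' @param t_ms window start (snapshot times), ms.
#' @param window_ms averaging window, ms.
#' @return Time-averaged transport flux rate, (umol/L)/s.
#' @export
diffusion_flux_rate <- function(run, x_cm, t_ms, window_ms = 4000) {
  g <- run$grid
  DK <- run$scenario$DK
  sel <- which(run$snapshots$t >= t_ms - 1e-9 &
                 run$snapshots$t <= t_ms + window_ms + 1e-9)
  if (!length(sel)) stop("no snapshots in the requested window")
  j <- which.min(abs(g$x - x_cm))
  FRT <- 96485 / (8314 * 310)
  vals <- vapply(sel, function(i) {
    ko <- run$snapshots$Ko[i, ]
    vm <- run$snapshots$Vm[i, ]
    vo <- extracellular_potential(vm, g$lambda)
    n <- length(ko)
    face_flux <- function(a, b) # between nodes a,b
      -DK * ((ko[b] - ko[a]) / g$dx_cm +
               FRT * 0.5 * (ko[a] + ko[b]) * (vo[b] - vo[a]) / g$dx_cm)
    fl <- if (j == 1) 0 else face_flux(j - 1, j)
    fr <- if (j == n) 0 else face_flux(j, j + 1)
    -(fr - fl) / g$dx_cm          # mmol/L per ms
  }, 0.0)
  mean(vals) * 1e6                # (umol/L)/s
}
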