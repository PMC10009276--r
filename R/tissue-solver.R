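# 1D cable electrophysiology: reaction-diffusion for Vm with operator
# splitting, extracellular-potential recovery, injury current, electrograms.

#' Construct the cable grid
#'
#' Validates the discretization against the explicit-stability bound
#' dt * DV / dx^2 <= 1/2 at construction time.
#'
#' @param L_cm cable length, cm.
#' @param dx_cm node spacing, cm (0.025 cm = 0.25 mm default).
#' @param dt_ms time step, ms.
#' @param DV effective conductivity-diffusion coefficient, cm2/ms.
#' @param lambda extracellular/intracellular conductivity ratio.
#' @return List with `x` (node positions, cm), `n`, and the settings.
#' @export
cable_grid <- function(L_cm = 4, dx_cm = 0.025, dt_ms = 0.02, DV = 0.0026,
                       lambda = 3.647) {
  n <- round(L_cm / dx_cm) + 1
  if (abs((n - 1) * dx_cm - L_cm) > 1e-9)
    stop("L must be an integral multiple of dx")
  if (dt_ms * DV / dx_cm^2 > 0.5)
    stop("explicit stability bound violated: dt*DV/dx^2 = ",
         signif(dt_ms * DV / dx_cm^2, 3), " > 0.5")
  list(x = (seq_len(n) - 1) * dx_cm, n = n, L_cm = L_cm, dx_cm = dx_cm,
       dt_ms = dt_ms, DV = DV, lambda = lambda)
}

#' Run a 1D strand scenario
#'
#' Operator-splitting integration of the cable equation (per-node reaction
#' update of the ischemia-modified cell model, explicit diffusion of Vm with
#' zero-flux ends) coupled to the extracellular potassium transport
#' equation. The first 2 cm of the strand stay normoxic (with potassium
#' wash-out); the remainder follows the prescribed ischemic metabolite time
#' courses with no wash-out. The leftmost node(s) are paced.
#'
#' @param scn a 1D [scenario()].
#' @param params from [cell_params()].
#' @param init optional n x 39 state matrix (defaults to the normoxic
#'   steady state at every node).
#' @return Object of class `kloss_cable_run`: `snapshots` (list of `t`,
#'   `Vm`, `Ko`, `SumIKx` matrices, time x node), `probes` (per-site Vm/Ko
#'   traces at `probe_dt`), `grid`, `final_state`, `scenario`, `params`.
#' @export
run_cable <- function(scn, params = cell_params(), init = NULL) {
  if (is.character(scn)) scn <- preset_scenario(scn)
  stopifnot(inherits(scn, "kloss_scenario"))
  if (scn$dim != "1D") stop("run_cable() needs a 1D scenario")
  grid <- cable_grid(scn$L_cm, scn$dx_cm, scn$dt, scn$DV, scn$lambda)
  layout <- regional_layout(scn$L_cm, 2, scn$tz_cm)
  if (is.null(init))
    init <- matrix(rep(as.numeric(cell_init_state()), each = grid$n),
                   nrow = grid$n)
  duration <- scn$duration_min * 60000
  onset <- scn$normoxia_min * 60000
  tables <- metabolite_tables(scn$adp_variant)
  ischemic <- grid$x >= layout$border_cm
  phw <- ph_ramp_weight(grid$x, layout)
  prot <- scn$protocol
  st <- stimulus_times(prot, duration)

  probe_idx <- vapply(scn$probe_x_cm,
                      function(xx) which.min(abs(grid$x - xx)) - 1L, 1L)

  run_phase <- function(state, t0, t1, tau_wo_alt) {
    tau_x <- ifelse(ischemic, tau_wo_alt, scn$tau_wo_normoxic_s * 1000)
    mt <- .build_metab_tab(duration, onset, tables)
    mt[, 1] <- mt[, 1] - t0
    stl <- st[st >= t0 - 1e-9 & st < t1] - t0
    .run_cable_cpp(state, params, t1 - t0, scn$dt, scn$dx_cm, scn$DV,
                   scn$DK, scn$lambda, tau_x, phw, ischemic,
                   stl, scn$stim_amp, prot$width_ms, scn$n_stim_nodes,
                   mt, scn$snapshot_dt, as.numeric(probe_idx),
                   scn$probe_dt, as.integer(scn$transport_every))
  }

  segs <- unique(c(min(onset, duration), duration))
  segs <- segs[segs > 0]
  t0 <- 0; state <- init
  snaps_t <- list(); snaps_V <- list(); snaps_K <- list(); snaps_S <- list()
  probes_t <- list(); probes_V <- list(); probes_K <- list()
  for (si in seq_along(segs)) {
    t1 <- segs[si]
    if (t1 <= t0) next
    tau_alt <- if (t0 < onset) scn$tau_wo_normoxic_s * 1000 else Inf
    r <- run_phase(state, t0, t1, tau_alt)
    ns <- r$n_snap; np <- r$n_probe
    drop1 <- if (si > 1) -1 else TRUE
    sel_s <- seq_len(ns); sel_p <- seq_len(np)
    if (si > 1) { sel_s <- sel_s[-1]; sel_p <- sel_p[-1] }
    snaps_t[[si]] <- r$snap_t[sel_s] + t0
    snaps_V[[si]] <- r$snap_V[sel_s, , drop = FALSE]
    snaps_K[[si]] <- r$snap_K[sel_s, , drop = FALSE]
    snaps_S[[si]] <- r$snap_sumikx[sel_s, , drop = FALSE]
    probes_t[[si]] <- r$probe_t[sel_p] + t0
    probes_V[[si]] <- r$probe_V[sel_p, , drop = FALSE]
    probes_K[[si]] <- r$probe_K[sel_p, , drop = FALSE]
    state <- r$final_state
    t0 <- t1
  }
  probes <- list(t = do.call(c, probes_t),
                 Vm = do.call(rbind, probes_V),
                 Ko = do.call(rbind, probes_K),
                 x_cm = grid$x[probe_idx + 1])
  structure(list(snapshots = list(t = do.call(c, snaps_t),
                                  Vm = do.call(rbind, snaps_V),
                                  Ko = do.call(rbind, snaps_K),
                                  SumIKx = do.call(rbind, snaps_S)),
                 probes = probes, grid = grid, layout = layout,
                 stim_times = st, final_state = state,
                 scenario = scn, params = params),
            class = "kloss_cable_run")
}

#' @export
print.kloss_cable_run <- function(x, ...) {
  cat("<kloss_cable_run>", x$scenario$name, "\n")
  cat("  ", x$grid$n, "nodes,", x$scenario$duration_min, "min,",
      length(x$snapshots$t), "snapshots\n")
  invisible(x)
}

#' Extract a spatial profile from a cable run
#'
#' @param run a `kloss_cable_run`.
#' @param t_ms snapshot time (nearest stored snapshot is used).
#' @param field `"Ko"` or `"Vm"`.
#' @return Data frame with `x` (cm) and the field.
#' @export
profile_at <- function(run, t_ms, field = c("Ko", "Vm")) {
  field <- match.arg(field)
  i <- which.min(abs(run$snapshots$t - t_ms))
  out <- data.frame(x = run$grid$x, v = run$snapshots[[field]][i, ])
  names(out)[2] <- field
  out
}

#' Recover the extracellular potential from a Vm profile
#'
#' Solves d2Vo/dx2 = -1/(1+lambda) d2Vm/dx2 with zero-flux ends. The double
#' Neumann problem fixes Vo only up to an additive constant; the gauge is
#' either zero spatial mean (default) or zero at the left end. With
#' zero-flux Vm the closed form Vo = -Vm/(1+lambda) + c holds, and the
#' discrete solve (second-difference stencil, tridiagonal solve) matches it
#' to round-off; the discrete route is kept as an independent check and for
#' non-ideal profiles.
#'
#' @param vm Vm profile (mV) on a uniform grid.
#' @param lambda conductivity ratio.
#' @param gauge `"zero-mean"` or `"zero-left"`.
#' @param method `"closed-form"` (default) or `"poisson"` (discrete solve).
#' @return Vo profile, mV.
#' @export
extracellular_potential <- function(vm, lambda = 3.647,
                                    gauge = c("zero-mean", "zero-left"),
                                    method = c("closed-form", "poisson")) {
  gauge <- match.arg(gauge)
  method <- match.arg(method)
  n <- length(vm)
  vo <- if (method == "closed-form") {
    -vm / (1 + lambda)
  } else {
    # discrete Poisson with Neumann BCs: A vo = b, b = -1/(1+lambda) D2 vm,
    # D2 with reflected ghost nodes; singular system pinned at node 1 and
    # re-gauged afterwards.
    d2 <- function(u) {
      ul <- c(u[2], u[-n]); ur <- c(u[-1], u[n - 1])
      ul - 2 * u + ur
    }
    b <- -d2(vm) / (1 + lambda)
    A <- matrix(0, n, n)
    for (i in seq_len(n)) {
      if (i == 1) { A[1, 1] <- -2; A[1, 2] <- 2 }
      else if (i == n) { A[n, n] <- -2; A[n, n - 1] <- 2 }
      else { A[i, i - 1] <- 1; A[i, i] <- -2; A[i, i + 1] <- 1 }
    }
    A[1, ] <- 0; A[1, 1] <- 1; b[1] <- -vm[1] / (1 + lambda)
    solve(A, b)
  }
  if (gauge == "zero-mean") vo - mean(vo) else vo - vo[1]
}

#' Intracellular injury current profile
#'
#' I_inj = DV * d2Vm/dx2 by the second-difference stencil, with reflected
#' (zero-flux consistent) end stencils; a postprocessing quantity. The
#' optional `svi` converts from uA/uF-based units to uA/mm3 via the
#' intracellular surface-to-volume ratio (363.6 mm^-1) and 0.01 uF/mm2
#' membrane capacitance: I[uA/mm3] = I[uA/uF] * Cm[uF/mm2] * Svi[1/mm].
#'
#' @param vm Vm profile, mV.
#' @param dx_cm node spacing, cm.
#' @param DV conductivity-diffusion coefficient, cm2/ms.
#' @param per_volume logical; report uA/mm3 instead of uA/uF.
#' @param svi intracellular surface-to-volume ratio, mm^-1.
#' @return Injury current profile.
#' @export
injury_current <- function(vm, dx_cm = 0.025, DV = 0.0026,
                           per_volume = FALSE, svi = 363.6) {
  n <- length(vm)
  vl <- c(vm[2], vm[-n]); vr <- c(vm[-1], vm[n - 1])
  iinj <- DV * (vl - 2 * vm + vr) / dx_cm^2   # uA/uF (Cm = 1), mV/ms scale
  if (per_volume) iinj <- iinj * 0.01 * svi   # Cm = 1 uF/cm2 = 0.01 uF/mm2
  iinj
}

#' Electrogram at a site
#'
#' The extracellular potential at a fixed position over time, recovered
#' from the stored Vm probe traces, with per-beat baseline alignment: the
#' mean over the diastolic window (last `baseline_ms` before each
#' stimulus) is subtracted beat by beat, so ST-segment shifts are measured
#' against the local diastolic reference.
#'
#' @param run a `kloss_cable_run`.
#' @param x_cm site position (nearest probe is used; a warning is issued
#'   if no probe is within `dx`).
#' @param baseline_ms diastolic reference window before each stimulus.
#' @return Data frame `t`, `Vo` (baseline-aligned, mV).
#' @export
electrogram_at <- function(run, x_cm, baseline_ms = 50) {
  d <- abs(run$probes$x_cm - x_cm)
  j <- which.min(d)
  if (d[j] > run$grid$dx_cm + 1e-9)
    warning("no probe at x = ", x_cm, " cm; using nearest at ",
            run$probes$x_cm[j], " cm")
  tt <- run$probes$t
  # Vo at a point needs the gauge-fixed profile; with zero-mean gauge,
  # Vo(x, t) = -(Vm(x, t) - mean_x Vm(., t))/(1 + lambda). The spatial mean
  # is only available at snapshot times, so interpolate it over t.
  mn <- rowMeans(run$snapshots$Vm)
  mnt <- stats::approx(run$snapshots$t, mn, xout = tt, rule = 2)$y
  vo <- -(run$probes$Vm[, j] - mnt) / (1 + run$grid$lambda)
  st <- run$stim_times
  if (length(st)) {
    base <- vo
    for (b in seq_along(st)) {
      sel <- tt >= st[b] & tt < c(st[-1], max(tt) + 1)[b]
      ref <- tt >= st[b] - baseline_ms & tt < st[b]
      if (any(ref)) base[sel] <- vo[sel] - mean(vo[ref])
    }
    vo <- base
  }
  data.frame(t = tt, Vo = vo)
}

#' Conduction velocity from activation times
#'
#' Activation (maximum dVm/dt) times at two sites on the final paced beat;
#' CV = distance / time difference.
#'
#' @param run a `kloss_cable_run`.
#' @param x1_cm,x2_cm measurement sites, cm.
#' @param beat which stimulus to use (default: the last).
#' @return Conduction velocity, cm/s.
#' @export
measure_cv <- function(run, x1_cm = 1.0, x2_cm = 1.5, beat = NULL) {
  st <- run$stim_times
  if (!length(st)) stop("unpaced run")
  if (is.null(beat)) beat <- length(st)
  t0 <- st[beat]
  t1 <- if (beat < length(st)) st[beat + 1] else max(run$probes$t)
  act_time <- function(xx) {
    d <- abs(run$probes$x_cm - xx)
    j <- which.min(d)
    if (d[j] > 1e-6) stop("no probe stored at x = ", xx, " cm")
    sel <- run$probes$t >= t0 & run$probes$t < t1
    tt <- run$probes$t[sel]; vv <- run$probes$Vm[sel, j]
    dv <- diff(vv) / diff(tt)
    tt[which.max(dv)]
  }
  ta <- act_time(x1_cm); tb <- act_time(x2_cm)
  if (tb <= ta) stop("no propagation between the sites on this beat")
  abs(x2_cm - x1_cm) / (tb - ta) * 1000
}
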