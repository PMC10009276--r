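# Derived quantities: potassium flux rates, per-beat AP metrics, alternans
# episodes, diastolic potassium minima, border-zone metrics.

#' Potassium flux rate of one current over a 4-beat window
#'
#' The flux rate K_FRx generated by a potassium-carrying current is the
#' rate of change of cleft potassium directly provoked by that current,
#' averaged over four beats:
#' K_FRx(t) = 1/(4 BCL) * alpha * integral_t^{t+4 BCL} I_Kx dt,
#' with alpha the calibrated Ac/(F vo) prefactor. Positive = efflux.
#'
#' @param trace data frame with columns `t` (ms) and `I` (uA/uF), covering
#'   the full window.
#' @param t window start, ms.
#' @param bcl basic cycle length, ms.
#' @param params from [cell_params()]; supplies `alpha`.
#' @param n_beats averaging-window length in beats.
#' @return Flux rate in (umol/L)/s.
#' @export
k_flux_rate <- function(trace, t, bcl = 1000, params = cell_params(),
                        n_beats = 4) {
  t1 <- t + n_beats * bcl
  if (min(trace$t) > t + 1e-6 || max(trace$t) < t1 - 1e-6)
    stop("trace does not cover the window [", t, ", ", t1, "] ms")
  sel <- trace$t >= t - 1e-9 & trace$t <= t1 + 1e-9
  tt <- trace$t[sel]; ii <- trace$I[sel]
  integ <- sum(diff(tt) * (utils::head(ii, -1) + utils::tail(ii, -1)) / 2)
  # alpha is (mmol/L)/ms per uA/uF; report (umol/L)/s = alpha * 1e6 * mean I
  params$alpha * 1e6 * integ / (n_beats * bcl)
}

# flux rates for all K currents from the run's cumulative integrals
.flux_from_macro <- function(run, t, n_beats = 4, bcl = NULL) {
  if (is.null(bcl)) bcl <- run$scenario$protocol$bcl
  mac <- run$macro
  cols <- c(paste0("int_", .k_current_names), "int_SumIKx")
  at <- function(tq) vapply(cols, function(cn)
    stats::approx(mac$t, mac[[cn]], xout = tq, rule = 2)$y, 0.0)
  win <- n_beats * bcl
  dint <- at(t + win) - at(t)
  rate <- run$params$alpha * 1e6 * dint / win
  names(rate) <- c(.k_current_names, "total")
  rate
}

#' Decompose potassium flux rates by current
#'
#' Evaluates the per-current potassium flux rates over 4-beat windows
#' starting at the requested times, from the run's accumulated current
#' integrals. In the record, the NaK entry is the full pump term (-2 INaK,
#' an influx). The additivity identity total = sum of components holds to
#' round-off and is checked.
#'
#' @param run a `kloss_run` from [run_single_cell()].
#' @param times window start times, ms (absolute simulation time).
#' @param n_beats window length in beats.
#' @return Data frame with one row per time: per-current rates, `efflux`
#'   (sum of positive rates), `influx` (sum of negative rates), `net`.
#'   All in (umol/L)/s.
#' @export
decompose_fluxes <- function(run, times, n_beats = 4) {
  bcl <- run$scenario$protocol$bcl
  if (!is.finite(bcl)) stop("flux decomposition needs a paced run")
  rows <- lapply(times, function(t) {
    r <- .flux_from_macro(run, t, n_beats, bcl)
    comp <- r[.k_current_names]
    if (abs(sum(comp) - r[["total"]]) > 1e-8 * max(1, abs(r[["total"]])))
      stop("flux additivity violated; current trace incomplete")
    data.frame(t = t, t_post_occl_min =
                 (t - run$scenario$normoxia_min * 60000) / 60000,
               as.list(comp),
               efflux = sum(comp[comp > 0]), influx = sum(comp[comp < 0]),
               net = r[["total"]])
  })
  out <- do.call(rbind, rows)
  names(out)[3:10] <- .k_current_names
  out
}

#' Per-beat action-potential and potassium metrics
#'
#' For every stimulus in a paced run: activation time (maximum dVm/dt
#' within the cycle), peak Vm, maximum upstroke velocity, capture flag
#' (peak Vm above `capture_mV` within 50 ms of the stimulus), APD90
#' (time from activation until Vm first repolarizes below 90% of the
#' beat amplitude, relative to the pre-stimulus diastolic potential) and
#' the diastolic minimum cleft potassium (DmKL) in the last 100 ms before
#' the next stimulus. APD90 is `NA` for non-captured beats.
#'
#' @param run a `kloss_run`, or a data frame with columns `t`, `Vm`
#'   (and optionally `Ko`).
#' @param stim_times stimulus onsets, ms (taken from the run if omitted).
#' @param capture_mV capture criterion for peak Vm, mV.
#' @return Data frame with one row per beat.
#' @export
beat_metrics <- function(run, stim_times = NULL, capture_mV = -20) {
  tr <- if (inherits(run, "kloss_run")) run$trace else run
  if (is.null(stim_times))
    stim_times <- if (inherits(run, "kloss_run")) run$stim_times else
      stop("stim_times required")
  if (!length(stim_times)) return(data.frame())
  tmax <- max(tr$t)
  n <- length(stim_times)
  ends <- c(stim_times[-1], tmax)
  out <- vector("list", n)
  for (b in seq_len(n)) {
    s <- stim_times[b]; e <- ends[b]
    if (e - s < 10) next
    sel <- which(tr$t >= s & tr$t < e)
    if (length(sel) < 5) next
    tt <- tr$t[sel]; vv <- tr$Vm[sel]
    dvdt <- diff(vv) / diff(tt)
    iact <- which.max(dvdt)
    vdias <- vv[1]
    ipk <- which.max(vv)
    vpk <- vv[ipk]
    captured <- any(vv[tt - s <= 50] > capture_mV)
    apd <- NA_real_
    if (captured) {
      v90 <- vpk - 0.9 * (vpk - vdias)
      below <- which(tt > tt[ipk] & vv < v90)
      if (length(below)) {
        i2 <- below[1]
        # linear interpolation of the crossing
        t90 <- tt[i2 - 1] + (v90 - vv[i2 - 1]) * (tt[i2] - tt[i2 - 1]) /
          (vv[i2] - vv[i2 - 1])
        apd <- t90 - tt[iact]
      }
    }
    dmkl <- NA_real_
    if (!is.null(tr$Ko)) {
      dsel <- tt >= e - 100
      if (any(dsel)) dmkl <- min(tr$Ko[sel][dsel])
    }
    out[[b]] <- data.frame(beat = b, t_stim = s, v_diastolic = vdias,
                           peak_vm = vpk, dvdt_max = max(dvdt),
                           t_act = tt[iact], apd90 = apd,
                           captured = captured, dmkl = dmkl)
  }
  do.call(rbind, out)
}

#' APD at 90% repolarization for a voltage trace
#'
#' Convenience wrapper around [beat_metrics()] returning the APD90 series.
#'
#' @inheritParams beat_metrics
#' @return Numeric vector, one APD90 (ms) per beat (`NA` = not captured).
#' @export
apd90 <- function(run, stim_times = NULL) {
  bm <- beat_metrics(run, stim_times)
  if (!nrow(bm)) return(numeric(0))
  bm$apd90
}

#' Detect APD alternans episodes
#'
#' Flags beat-to-beat APD90 alternation: consecutive captured beats whose
#' APD90 differs by more than `threshold_ms`. Runs of flagged beats are
#' merged into episodes and labelled `"2:2"` when the successive APD
#' differences alternate strictly in sign, `"complex"` otherwise.
#' Non-captured beats break episodes.
#'
#' @param apd numeric APD90 series (ms), `NA` for non-captured beats.
#' @param t_stim optional stimulus times for onset/offset reporting.
#' @param threshold_ms alternation threshold (default 5 ms, far above
#'   solver noise and far below ischemic alternans magnitude).
#' @param min_beats minimum episode length in beats.
#' @return Data frame with one row per episode: `onset_beat`,
#'   `offset_beat`, `onset_t`, `offset_t`, `pattern`, `max_delta`.
#' @export
detect_alternans <- function(apd, t_stim = NULL, threshold_ms = 5,
                             min_beats = 8) {
  n <- length(apd)
  if (n < min_beats) return(data.frame())
  d <- c(NA, diff(apd))
  alt <- !is.na(d) & abs(d) > threshold_ms
  alt[is.na(apd)] <- FALSE
  r <- rle(alt)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  eps <- which(r$values & r$lengths >= (min_beats - 1))
  if (!length(eps)) return(data.frame())
  out <- lapply(eps, function(k) {
    i0 <- max(starts[k] - 1, 1); i1 <- ends[k]
    dd <- d[(i0 + 1):i1]
    pure <- all(diff(sign(dd)) != 0)
    data.frame(onset_beat = i0, offset_beat = i1,
               onset_t = if (!is.null(t_stim)) t_stim[i0] else NA_real_,
               offset_t = if (!is.null(t_stim)) t_stim[i1] else NA_real_,
               pattern = if (pure) "2:2" else "complex",
               max_delta = max(abs(dd)))
  })
  do.call(rbind, out)
}

#' Diastolic minimum potassium levels
#'
#' @inheritParams beat_metrics
#' @return Numeric vector of per-beat DmKL (mmol/L).
#' @export
dmkl <- function(run, stim_times = NULL) {
  bm <- beat_metrics(run, stim_times)
  if (!nrow(bm)) return(numeric(0))
  bm$dmkl
}

#' Border-zone metrics from a potassium spatial profile
#'
#' The border zone (BZ) is the spatial gradient of cleft potassium between
#' the normoxic tissue and the central ischemic zone (CIZ). The BZ width is
#' the distance from the metabolic border to the position of the profile
#' peak; the invasion depth is how far potassium elevation (above the
#' normoxic level plus `elev_thresh`) reaches into the normoxic segment.
#' An alternative width measure, the 10%-90% span of the normoxic-to-peak
#' rise, is reported alongside.
#'
#' @param profile data frame with columns `x` (cm) and `Ko` (mmol/L).
#' @param layout from [regional_layout()].
#' @param kb normoxic bulk potassium, mmol/L.
#' @param elev_thresh elevation threshold above `kb`, mmol/L.
#' @return List: `peak_x`, `peak_ko`, `width_cm` (border to peak),
#'   `width_10_90_cm`, `ciz_ko` (mean over the distal 0.5 cm),
#'   `invasion_cm`, `flat` (TRUE when no elevation is present).
#' @export
bz_metrics <- function(profile, layout = regional_layout(), kb = 5.4,
                       elev_thresh = 0.2) {
  x <- profile$x; ko <- profile$Ko
  elevated <- ko > kb + elev_thresh
  if (!any(elevated))
    return(list(peak_x = NA_real_, peak_ko = max(ko), width_cm = 0,
                width_10_90_cm = 0, ciz_ko = mean(ko[x >= max(x) - 0.5]),
                invasion_cm = 0, flat = TRUE))
  alt <- x >= layout$border_cm
  ipk <- which(alt)[which.max(ko[alt])]
  peak_x <- x[ipk]; peak_ko <- ko[ipk]
  width <- peak_x - layout$border_cm
  # 10-90% rise span on the proximal flank
  lo <- kb + 0.1 * (peak_ko - kb); hi <- kb + 0.9 * (peak_ko - kb)
  prox <- seq_len(ipk)
  x10 <- x[prox][which(ko[prox] >= lo)[1]]
  x90 <- x[prox][which(ko[prox] >= hi)[1]]
  w1090 <- if (is.na(x10) || is.na(x90)) NA_real_ else x90 - x10
  inv <- 0
  norm <- x < layout$border_cm
  if (any(elevated & norm))
    inv <- layout$border_cm - min(x[elevated & norm])
  list(peak_x = peak_x, peak_ko = peak_ko, width_cm = width,
       width_10_90_cm = w1090,
       ciz_ko = mean(ko[x >= max(x) - 0.5]),
       invasion_cm = inv, flat = FALSE)
}

#' Detect the potassium plateau interval of a 0D ischemia run
#'
#' The plateau is the contiguous interval in which the magnitude of the
#' net potassium flux rate (sliding 4-beat window) stays below `frac` of
#' its peak value. Returns the interval and the mean 1-s-sampled cleft
#' potassium within it.
#'
#' @param run a `kloss_run` of an ischemia scenario.
#' @param frac threshold fraction of the peak net flux rate.
#' @return List `t0_min`, `t1_min` (minutes post-occlusion), `ko_mean`.
#' @export
ko_plateau <- function(run, frac = 0.1) {
  onset <- run$scenario$normoxia_min * 60000
  bcl <- run$scenario$protocol$bcl
  mac <- run$macro
  win <- 4 * bcl
  tq <- mac$t[mac$t >= onset & mac$t + win <= max(mac$t)]
  cum <- stats::approx(mac$t, mac$int_SumIKx, xout = c(tq, tq + win),
                       rule = 2)$y
  nq <- length(tq)
  net <- run$params$alpha * 1e6 * (cum[(nq + 1):(2 * nq)] - cum[1:nq]) / win
  pk <- max(net)
  low <- abs(net) < frac * pk
  # longest low run
  r <- rle(low)
  if (!any(r$values)) return(list(t0_min = NA, t1_min = NA, ko_mean = NA))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  k <- which(r$values)[which.max(r$lengths[r$values])]
  i0 <- starts[k]; i1 <- ends[k]
  sel <- mac$t >= tq[i0] & mac$t <= tq[i1] + win
  list(t0_min = (tq[i0] - onset) / 60000,
       t1_min = (tq[i1] + win - onset) / 60000,
       ko_mean = mean(mac$Ko[sel]))
}
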