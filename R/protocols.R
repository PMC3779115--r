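#' Action-potential duration from a paced trace
#'
#' APD at `level`\% repolarisation, measured on one beat of a `cell_trace`
#' (or any list with `t`, `V`, `stim_times`): from the AP peak of the beat
#' back toward the pre-stimulus diastolic potential, with linear
#' interpolation between samples. Returns `NaN` when the beat has no action
#' potential (peak below 0 mV).
#'
#' @param trace a `cell_trace` (or compatible list).
#' @param beat_index which beat to measure (default: last).
#' @param level repolarisation level in percent, in (0, 100).
#' @return APD in ms (or `NaN` if no AP was elicited).
#' @export
measure_apd <- function(trace, beat_index = NULL, level = 90) {
  if (level <= 0 || level >= 100) stop("level must be in (0, 100)")
  st <- sort(trace$stim_times)
  if (!length(st)) stop("trace contains no stimuli")
  if (is.null(beat_index)) beat_index <- length(st)
  if (beat_index < 1 || beat_index > length(st))
    stop("trace does not contain beat ", beat_index)
  t0 <- st[beat_index]
  t1 <- if (beat_index < length(st)) st[beat_index + 1] else max(trace$t)
  sel <- trace$t >= t0 & trace$t <= t1
  tt <- trace$t[sel]; vv <- trace$V[sel]
  if (length(tt) < 3) stop("trace does not cover beat ", beat_index)
  v_dia <- vv[1]                       # pre-stimulus diastolic potential
  ipk <- which.max(vv)
  v_pk <- vv[ipk]
  if (v_pk < 0) return(NaN)
  v_lvl <- v_pk - (level / 100) * (v_pk - v_dia)
  after <- seq(ipk, length(vv))
  below <- after[vv[after] <= v_lvl]
  if (!length(below)) return(NaN)
  ic <- below[1]
  if (ic == ipk) return(tt[ipk] - t0)
  tc <- tt[ic - 1] + (v_lvl - vv[ic - 1]) / (vv[ic] - vv[ic - 1]) *
    (tt[ic] - tt[ic - 1])
  tc - t0
}

#' Paced steady-state APD90 of a parameter set
#'
#' Convenience wrapper: pace `n_beats` at `bcl` (2 nA / 2 ms stimuli) from
#' the default state and measure the final-beat APD.
#'
#' @inheritParams pace_cell
#' @param level repolarisation level (percent).
#' @param dt integration step (ms).
#' @return APD in ms.
#' @export
apd90 <- function(params, bcl = 1000, n_beats = 10, level = 90, dt = 0.005) {
  tr <- pace_cell(params, bcl = bcl, n_beats = n_beats, dt = dt)
  measure_apd(tr, level = level)
}

#' APD restitution curve
#'
#' Steady-state (dynamic) pacing restitution: at each BCL the cell is paced
#' a fixed number of beats and the final-beat APD90 recorded. The maximum
#' slope is the largest finite-difference slope of APD90 against diastolic
#' interval (DI = BCL - APD90). Points that lose 1:1 capture are marked
#' `NA`, not raised as errors. An S1-S2 variant (`type = "s1s2"`) paces at
#' `s1_bcl` and varies only the final coupling interval.
#'
#' @param params a [channel_params()] object.
#' @param bcl_list BCLs in ms, sorted descending.
#' @param n_beats beats per BCL (default 10).
#' @param type `"dynamic"` (default) or `"s1s2"`.
#' @param s1_bcl S1 cycle length for the S1-S2 variant.
#' @param dt integration step (ms).
#' @return Object of class `restitution_curve`: list with `bcl`, `apd90`,
#'   `di` and `max_slope`.
#' @export
restitution <- function(params, bcl_list = c(1000, 800, 600, 500, 400, 350, 300),
                        n_beats = 10, type = c("dynamic", "s1s2"),
                        s1_bcl = 1000, dt = 0.005) {
  type <- match.arg(type)
  if (is.unsorted(rev(bcl_list)))
    stop("bcl_list must be sorted descending")
  apd <- vapply(bcl_list, function(b) {
    tr <- if (type == "dynamic") {
      pace_cell(params, bcl = b, n_beats = n_beats, dt = dt)
    } else {
      st <- c((seq_len(n_beats - 1) - 1) * s1_bcl,
              (n_beats - 2) * s1_bcl + b)
      run_cell(params, t_end = max(st) + b, stim_times = st, dt = dt)
    }
    a <- measure_apd(tr)
    # 1:1 capture check: every beat must have elicited an AP
    if (is.nan(a)) NA_real_ else a
  }, numeric(1))
  di <- bcl_list - apd
  ok <- !is.na(apd)
  slope <- if (sum(ok) >= 2) {
    max(abs(diff(apd[ok]) / diff(di[ok])))
  } else NA_real_
  structure(list(bcl = bcl_list, apd90 = apd, di = di, max_slope = slope),
            class = "restitution_curve")
}

#' @export
print.restitution_curve <- function(x, ...) {
  cat("<restitution_curve>\n")
  print(data.frame(bcl = x$bcl, di = round(x$di, 1), apd90 = round(x$apd90, 1)))
  cat("max slope:", signif(x$max_slope, 3), "\n")
  invisible(x)
}

#' @export
plot.restitution_curve <- function(x, ...) {
  plot(x$di, x$apd90, type = "b", xlab = "diastolic interval (ms)",
       ylab = "APD90 (ms)", ...)
  invisible(x)
}

# did an S2 beat elicit a regenerative AP? (peak above 0 mV and maximum
# upstroke rate above 10 V/s = 10 mV/ms)
.s2_captured <- function(params, state, ci, s2_amplitude = 2,
                         s2_duration = 2, dt = 0.005) {
  tr <- run_cell(params, state, t_end = ci + 400, stim_times = ci,
                 stim_amplitude = s2_amplitude, stim_duration = s2_duration,
                 dt = dt, record_every = 0.5)
  sel <- tr$t >= ci
  peak <- max(tr$V[sel])
  dv <- max(diff(tr$V[sel]) / diff(tr$t[sel]))
  peak > 0 && dv > 10
}

#' Cellular effective refractory period
#'
#' S1-S2 protocol at the cell level: `n_s1` conditioning beats at
#' `s1_bcl`, then a premature S2; the ERP is the shortest S2 coupling
#' interval (from the last S1) that still elicits a regenerative AP (peak
#' above 0 mV, max dV/dt above 10 V/s), located by bisection to `resolution`
#' ms. Bisection is exact here because capture is monotone in the coupling
#' interval; [measure_erp_cell()] with `method = "sweep"` verifies this by
#' exhaustive search.
#'
#' @param params a [channel_params()] object.
#' @param s1_bcl S1 cycle length (ms, default 350).
#' @param n_s1 number of conditioning beats (default 10).
#' @param ci_range search range of coupling intervals (ms).
#' @param resolution ERP resolution (ms, default 1).
#' @param method `"bisect"` (default) or `"sweep"` (exhaustive, for
#'   verification).
#' @param dt integration step (ms).
#' @return ERP in ms.
#' @export
measure_erp_cell <- function(params, s1_bcl = 350, n_s1 = 10,
                             ci_range = c(50, 400), resolution = 1,
                             method = c("bisect", "sweep"), dt = 0.005) {
  method <- match.arg(method)
  s1 <- (seq_len(n_s1) - 1) * s1_bcl
  cond <- run_cell(params, t_end = n_s1 * s1_bcl, stim_times = s1,
                   dt = dt, record_every = 0)
  # state at the end of the S1 train; S2 measured from the last S1 onset,
  # so re-run to one BCL after the last S1 and offset coupling intervals
  last_s1_state <- run_cell(params, t_end = (n_s1 - 1) * s1_bcl,
                            stim_times = s1[-n_s1], dt = dt,
                            record_every = 0)$final_state
  test <- function(ci) .s2_captured(params, last_s1_state, ci, dt = dt)
  lo <- ci_range[1]; hi <- ci_range[2]
  if (!test(hi)) stop("no capture at any tested S2 coupling interval")
  if (test(lo)) return(lo)
  if (method == "sweep") {
    for (ci in seq(lo, hi, by = resolution)) if (test(ci)) return(ci)
    stop("no capture at any tested S2 coupling interval")
  }
  while (hi - lo > resolution) {
    mid <- lo + ceiling((hi - lo) / (2 * resolution)) * resolution
    if (mid >= hi) mid <- hi - resolution
    if (test(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Rapid-pacing conditioning state
#'
#' Conditions a cell model by a long rapid train at the scenario-specific
#' BCL (see [rapid_pacing_bcl()]) and returns the state one time step
#' before the final stimulus, the convention used to initialise tissue
#' simulations of AF. Loss of 1:1 capture is reported as an attribute, not
#' an error.
#'
#' @param params a [channel_params()] object (already remodelled).
#' @param scenario_id scenario id, sets the conditioning BCL.
#' @param n_beats length of the conditioning train (default 50).
#' @param dt integration step (ms).
#' @return A `membrane_state` with attribute `captured` (logical: 1:1
#'   capture maintained over the last beats).
#' @export
rapid_pace_condition <- function(params, scenario_id = "CONTROL",
                                 n_beats = 50, dt = 0.005) {
  bcl <- rapid_pacing_bcl(scenario_id)
  stim <- (seq_len(n_beats) - 1) * bcl
  t_end <- (n_beats - 1) * bcl - dt    # one step before the final stimulus
  tr <- run_cell(params, t_end = t_end, stim_times = stim[-n_beats],
                 dt = dt, record_every = 1)
  # capture check on the last three conditioned beats
  ok <- vapply(seq(n_beats - 3, n_beats - 1), function(k) {
    sel <- tr$t >= stim[k] & tr$t < stim[k] + bcl
    any(tr$V[sel] > 0)
  }, logical(1))
  st <- tr$final_state
  attr(st, "captured") <- all(ok)
  st
}

#' Ca2+ transient metrics of the final beat
#'
#' Diastolic and peak interior Ca2+, amplitude, and decay time (time from
#' peak to 50\% recovery toward diastolic level) measured on the `Ca_cen`
#' series of the last beat of a trace.
#'
#' @param trace a `cell_trace`.
#' @return Named list: `diastolic`, `peak`, `amplitude` (mM), `decay_time`
#'   (ms; `NA` when the transient does not decay to half within the trace).
#' @export
cat_metrics <- function(trace) {
  st <- sort(trace$stim_times)
  t0 <- if (length(st)) st[length(st)] else min(trace$t)
  sel <- trace$t >= t0
  tt <- trace$t[sel]; ca <- trace$Ca_cen[sel]
  dia <- ca[1]
  ipk <- which.max(ca)
  peak <- ca[ipk]
  amp <- peak - dia
  half <- peak - 0.5 * amp
  after <- seq(ipk, length(ca))
  below <- after[ca[after] <= half]
  decay <- if (length(below) && amp > 0) tt[below[1]] - tt[ipk] else NA_real_
  list(diastolic = dia, peak = peak, amplitude = amp, decay_time = decay)
}
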