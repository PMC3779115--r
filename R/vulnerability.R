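#' Excitation wavelength
#'
#' WL = CV x ERP, the spatial extent of refractory tissue behind a
#' wavefront (the classical lower bound on re-entrant path length).
#'
#' @param cv conduction velocity (m/s).
#' @param erp effective refractory period (ms).
#' @return Wavelength in mm (1 m/s x 1 ms = 1 mm).
#' @export
wavelength <- function(cv, erp) {
  stopifnot(cv >= 0, erp >= 0)
  cv * erp
}

#' Empirical vulnerability factor of a tissue junction
#'
#' Combines the refractory-period gap across a two-region junction with
#' the excitation wavelength of the shorter-ERP region:
#' `F_VWR = (ERP_1 - ERP_2) / WL_2` with `ERP_1 >= ERP_2`. A large ERP gap
#' widens the window for unidirectional block, while a short wavelength
#' shrinks the minimum re-entrant circuit, so larger values index higher
#' vulnerability to re-entry. When a reference value is supplied the
#' result is normalised by it (the convention used to compare junctions
#' across remodelling scenarios).
#'
#' @param erp_1,erp_2 the two regions' ERPs (ms), `erp_1 >= erp_2`.
#' @param wl_2 wavelength in the shorter-ERP region (mm), > 0.
#' @param reference optional reference `F_VWR` for normalisation.
#' @return Dimensionless vulnerability factor.
#' @export
f_vwr <- function(erp_1, erp_2, wl_2, reference = NULL) {
  if (wl_2 <= 0) stop("wl_2 must be > 0")
  if (erp_1 < erp_2) stop("erp_1 must be >= erp_2")
  v <- (erp_1 - erp_2) / wl_2
  if (!is.null(reference)) v <- v / reference
  v
}

#' Detect sustained re-entry in a field history
#'
#' Re-entry is classified as sustained when self-regenerating activation
#' (activations at a probe node after the last applied stimulus) continues
#' for at least `min_duration` ms. The cycle length is the median
#' inter-activation interval at the probe.
#'
#' @param history a `field_history`.
#' @param min_duration sustained-re-entry threshold (ms; 4000 at full
#'   scale, shorter values may be passed for scaled-down runs and are
#'   reported as such).
#' @param probe_node probe node index (default: domain centre).
#' @return List with `sustained`, `cycle_length` (ms, `NA` without
#'   re-entry), `n_reentrant` activations and `min_duration`.
#' @export
detect_reentry <- function(history, min_duration = 4000, probe_node = NULL) {
  stopifnot(inherits(history, "field_history"))
  if (is.null(probe_node))
    probe_node <- max(1L, floor(n_nodes(history$geom) / 2))
  last_stim <- 0
  for (s in history$stimuli) {
    dur <- if (is.null(s$duration)) 2 else s$duration
    last_stim <- max(last_stim, max(s$times) + dur)
  }
  at <- history$activation_times[probe_node, ]
  at <- at[!is.na(at)]
  # ignore the directly paced activations (within 250 ms of final stimulus,
  # the upper bound of one paced transit across desk-scale domains)
  re <- at[at > last_stim + 250]
  if (length(re) < 2)
    return(list(sustained = FALSE, cycle_length = NA_real_,
                n_reentrant = length(re), min_duration = min_duration))
  span <- max(re) - last_stim
  list(sustained = span >= min_duration,
       cycle_length = median(diff(re)),
       n_reentrant = length(re),
       min_duration = min_duration)
}

# classify conduction after an S2 at a junction: does the wave reach a
# probe >= probe_dist_mm into each region (beyond the stimulus edge)?
.classify_s2 <- function(geom, scenario, ci, cond_states, stim_nodes,
                         probe_a, probe_b, base, table, dt,
                         follow = 300, keep_history = FALSE) {
  stim <- list(list(nodes = stim_nodes, times = ci))
  h <- run_simulation(geom, scenario, stim, duration = ci + follow,
                      record_every = 0, init_states = cond_states,
                      base = base, table = table, dt = dt)
  act_after <- function(node) {
    at <- h$activation_times[node, ]
    any(!is.na(at) & at > ci)
  }
  a <- act_after(probe_a); b <- act_after(probe_b)
  cls <- if (a && b) "bilateral" else if (!a && !b) "block"
         else "unidirectional"
  list(class = cls, into_a = a, into_b = b, history = if (keep_history) h)
}

#' S1-S2 vulnerability-window scan at a tissue junction
#'
#' Applies the junction vulnerability protocol: conditioning at the S1
#' cycle length (10 beats of 2 nA / 2 ms stimuli to a 3.3 mm disc on the
#' interface), then a single premature S2 to the same site at each tested
#' coupling interval. Each interval is classified as bilateral conduction,
#' bilateral block, or unidirectional block (conduction into one region,
#' failure into the other); the vulnerable window for conduction block
#' (VW_CB) is the maximal interval of unidirectional outcomes. With
#' `test_reentry = TRUE` each unidirectional interval is followed long
#' enough to test for sustained re-entry, building VW_R (necessarily a
#' subset of VW_CB). The scan also measures each region's ERP next to the
#' stimulus site, and reports wavelength and the vulnerability factor
#' [f_vwr()].
#'
#' For efficiency the S1 conditioning is computed per cell type (each
#' region conditioned at the S1 rate in isolation) and imposed as the
#' tissue state before the final S1 beat, which is then delivered in
#' tissue so that electrotonic interaction shapes the repolarisation
#' gradient the S2 probes.
#'
#' @param geom a two-region junction geometry ([make_junction_sheet()] or
#'   a two-region cable).
#' @param scenario an [af_scenario()] or id string.
#' @param s1_bcl S1 cycle length (ms, default 350).
#' @param n_s1 conditioning beats (default 10).
#' @param ci_range coupling intervals to scan (ms, relative to the last S1).
#' @param ci_step scan resolution (ms, default 1; coarser values give a
#'   faster, coarser window).
#' @param test_reentry follow unidirectional outcomes to test re-entry.
#' @param reentry_min_duration sustained threshold passed to
#'   [detect_reentry()].
#' @param probe_dist_mm probe distance beyond the stimulus edge (default 5).
#' @param base,table,dt as in [run_simulation()].
#' @return Object of class `vw_result` with fields `erp_1`, `erp_2` (ms,
#'   `erp_1 >= erp_2`, regions identified), `wl_2` (mm), `vw_cb`, `vw_r`
#'   (ms intervals or NULL), `f_vwr`, `outcomes` (per-CI table) and
#'   `n_s2_stimuli`.
#' @export
scan_s1s2 <- function(geom, scenario = "CONTROL", s1_bcl = 350, n_s1 = 10,
                      ci_range = c(120, 350), ci_step = 1,
                      test_reentry = FALSE, reentry_min_duration = 1000,
                      probe_dist_mm = 5,
                      base = channel_params(),
                      table = default_regional_table(), dt = 0.005) {
  if (is.character(scenario)) scenario <- af_scenario(scenario)
  regs <- unique(geom$region[geom$inside])
  if (length(regs) > 2) stop("scan_s1s2 requires a one- or two-region geometry")
  radius <- 3.3
  stim_nodes <- stim_disc(geom, radius_mm = radius)
  if (!length(stim_nodes)) stop("empty stimulus disc")

  xyz <- node_coords(geom)
  ctr <- colMeans(xyz[stim_nodes, , drop = FALSE])
  regvec <- geom$region[geom$inside]
  if (length(regs) == 2) {
    probe_for <- function(rg) {
      cand <- which(regvec == rg)
      d <- sqrt(rowSums((xyz[cand, , drop = FALSE] -
                         matrix(ctr, length(cand), 3, byrow = TRUE))^2))
      ok <- cand[d >= radius + probe_dist_mm]
      if (!length(ok)) stop("domain too small for probe distance in ", rg)
      dd <- d[d >= radius + probe_dist_mm]
      ok[which.min(dd)]
    }
    probe_a <- probe_for(regs[1]); probe_b <- probe_for(regs[2])
  } else {
    # homogeneous tissue: probes on either side of the stimulus along x
    regs <- c(regs, regs)
    dxv <- xyz[, 1] - ctr[1]
    dd <- sqrt(rowSums((xyz - matrix(ctr, nrow(xyz), 3, byrow = TRUE))^2))
    left <- which(dxv < 0 & dd >= radius + probe_dist_mm)
    right <- which(dxv > 0 & dd >= radius + probe_dist_mm)
    if (!length(left) || !length(right))
      stop("domain too small for probe distance")
    probe_a <- left[which.min(dd[left])]
    probe_b <- right[which.min(dd[right])]
  }

  # per-region S1 conditioning imposed before a final in-tissue S1 beat
  tp <- build_tissue_params(geom, scenario, base, table)
  cond <- matrix(0, n_nodes(geom), length(state_names()))
  for (k in seq_len(nrow(tp$param_matrix))) {
    p <- structure(tp$param_matrix[k, ], names = names(.base_params),
                   class = "channel_params")
    st <- run_cell(p, t_end = (n_s1 - 1) * s1_bcl,
                   stim_times = (seq_len(n_s1 - 1) - 1) * s1_bcl,
                   dt = dt, record_every = 0)$final_state
    rows <- tp$node_param == k
    cond[rows, ] <- matrix(as.numeric(st), sum(rows), ncol(cond), byrow = TRUE)
  }
  # S1 capture check: deliver the final S1 beat in tissue
  s1 <- run_simulation(geom, scenario,
                       list(list(nodes = stim_nodes, times = 0)),
                       duration = 60, record_every = 0,
                       init_states = cond, base = base, table = table, dt = dt)
  if (all(is.na(s1$activation_times[probe_a, ])) ||
      all(is.na(s1$activation_times[probe_b, ])))
    stop("S1 capture failure at the junction")

  # each trial: final S1 at t = 0 and S2 at t = CI in one run, from the
  # per-region conditioned state
  cis <- seq(ci_range[1], ci_range[2], by = ci_step)
  out <- data.frame(ci = cis, class = NA_character_,
                    into_a = NA, into_b = NA,
                    reentry = NA, stringsAsFactors = FALSE)
  vw_r_hits <- numeric(0)
  follow <- 300
  for (i in seq_along(cis)) {
    ci <- cis[i]
    run_to <- ci + if (test_reentry) reentry_min_duration + 400 else follow
    h <- run_simulation(geom, scenario,
                        list(list(nodes = stim_nodes, times = c(0, ci))),
                        duration = run_to, record_every = 0,
                        init_states = cond, base = base, table = table,
                        dt = dt)
    act_after <- function(node) {
      at <- h$activation_times[node, ]
      any(!is.na(at) & at > ci)
    }
    a <- act_after(probe_a); b <- act_after(probe_b)
    out$into_a[i] <- a
    out$into_b[i] <- b
    out$class[i] <- if (a && b) "bilateral" else if (!a && !b) "block"
                    else "unidirectional"
    if (out$class[i] == "unidirectional" && test_reentry) {
      h$stimuli <- list(list(nodes = stim_nodes, times = ci))
      det <- detect_reentry(h, reentry_min_duration, probe_a)
      out$reentry[i] <- det$sustained
      if (isTRUE(det$sustained)) vw_r_hits <- c(vw_r_hits, ci)
    }
  }
  uni <- out$ci[out$class == "unidirectional"]
  vw_cb <- if (length(uni)) range(uni) else NULL
  vw_r <- if (length(vw_r_hits)) range(vw_r_hits) else NULL

  # region ERPs adjacent to the stimulus: minimum CI that conducts into
  # the region's probe
  erp_a <- if (any(out$into_a %in% TRUE)) min(out$ci[out$into_a %in% TRUE])
           else NA_real_
  erp_b <- if (any(out$into_b %in% TRUE)) min(out$ci[out$into_b %in% TRUE])
           else NA_real_
  ord <- order(c(erp_a, erp_b), decreasing = TRUE)
  erps <- c(erp_a, erp_b)[ord]
  reg_sorted <- regs[ord]

  # wavelength in the shorter-ERP region (cable CV of that region)
  cv2 <- tryCatch({
    cg <- make_cable(200, dx = geom$dx,
                     region_layout = stats::setNames(list(1:200),
                                                     reg_sorted[2]),
                     d_iso = geom$d_iso, d_long = geom$d_long,
                     d_trans = geom$d_trans)
    measure_cv(cg, scenario, base = base, table = table, dt = dt)$cv
  }, error = function(e) NA_real_)
  wl2 <- if (is.na(cv2) || is.na(erps[2])) NA_real_ else wavelength(cv2, erps[2])
  fv <- if (!is.na(wl2) && wl2 > 0 && !any(is.na(erps)))
    f_vwr(erps[1], erps[2], wl2) else NA_real_

  structure(list(regions = reg_sorted, erp_1 = erps[1], erp_2 = erps[2],
                 wl_2 = wl2, vw_cb = vw_cb, vw_r = vw_r, f_vwr = fv,
                 outcomes = out, n_s2_stimuli = 1L,
                 scenario = scenario$id),
            class = "vw_result")
}

#' @export
print.vw_result <- function(x, ...) {
  cat("<vw_result> scenario ", x$scenario, "\n", sep = "")
  cat(sprintf("  ERP %s = %.0f ms, ERP %s = %.0f ms, WL_2 = %.1f mm\n",
              x$regions[1], x$erp_1, x$regions[2], x$erp_2, x$wl_2))
  cat("  VW_CB: ", if (is.null(x$vw_cb)) "empty" else
    paste0("[", x$vw_cb[1], ", ", x$vw_cb[2], "] ms"), "\n", sep = "")
  cat("  VW_R:  ", if (is.null(x$vw_r)) "empty" else
    paste0("[", x$vw_r[1], ", ", x$vw_r[2], "] ms"), "\n", sep = "")
  cat("  F_VWR: ", signif(x$f_vwr, 3), "\n", sep = "")
  invisible(x)
}

#' Tissue effective refractory period at a probe site
#'
#' ERP measured in tissue: minimum S2 coupling interval for which the AP
#' conducts at least `probe_dist_mm` beyond the stimulus edge within the
#' probed region, found by bisection to `resolution` ms (`method =
#' "sweep"` verifies by exhaustive search).
#'
#' @param geom geometry; @param scenario scenario; @param region region to
#'   probe; @param ci_range search range (ms); @param resolution ms;
#'   @param method bisect or sweep; @param s1_bcl,n_s1 S1 protocol;
#'   @param probe_dist_mm probe distance; @param base,table,dt as usual.
#' @return ERP in ms.
#' @export
erp_at <- function(geom, scenario = "CONTROL", region = NULL,
                   ci_range = c(100, 350), resolution = 1,
                   method = c("bisect", "sweep"),
                   s1_bcl = 350, n_s1 = 10, probe_dist_mm = 5,
                   base = channel_params(),
                   table = default_regional_table(), dt = 0.005) {
  method <- match.arg(method)
  if (is.character(scenario)) scenario <- af_scenario(scenario)
  regs <- unique(geom$region[geom$inside])
  if (is.null(region)) region <- regs[1]
  radius <- 3.3
  stim_nodes <- stim_disc(geom, radius_mm = radius)
  xyz <- node_coords(geom)
  ctr <- colMeans(xyz[stim_nodes, , drop = FALSE])
  regvec <- geom$region[geom$inside]
  cand <- which(regvec == region)
  d <- sqrt(rowSums((xyz[cand, , drop = FALSE] -
                     matrix(ctr, length(cand), 3, byrow = TRUE))^2))
  sel <- cand[d >= radius + probe_dist_mm]
  if (!length(sel)) stop("domain too small for probe distance in ", region)
  probe <- sel[which.min(d[d >= radius + probe_dist_mm])]

  tp <- build_tissue_params(geom, scenario, base, table)
  cond <- matrix(0, n_nodes(geom), length(state_names()))
  for (k in seq_len(nrow(tp$param_matrix))) {
    p <- structure(tp$param_matrix[k, ], names = names(.base_params),
                   class = "channel_params")
    st <- run_cell(p, t_end = (n_s1 - 1) * s1_bcl,
                   stim_times = (seq_len(n_s1 - 1) - 1) * s1_bcl,
                   dt = dt, record_every = 0)$final_state
    cond[tp$node_param == k, ] <- matrix(as.numeric(st),
                                         sum(tp$node_param == k),
                                         ncol(cond), byrow = TRUE)
  }
  test <- function(ci) {
    h <- run_simulation(geom, scenario,
                        list(list(nodes = stim_nodes, times = c(0, ci))),
                        duration = ci + 300, record_every = 0,
                        init_states = cond, base = base,
                        table = table, dt = dt)
    at <- h$activation_times[probe, ]
    any(!is.na(at) & at > ci)
  }
  lo <- ci_range[1]; hi <- ci_range[2]
  if (!test(hi)) stop("no conduction at any tested S2 coupling interval")
  if (test(lo)) return(lo)
  if (method == "sweep") {
    for (ci in seq(lo, hi, by = resolution)) if (test(ci)) return(ci)
  }
  while (hi - lo > resolution) {
    mid <- lo + ceiling((hi - lo) / (2 * resolution)) * resolution
    if (mid >= hi) mid <- hi - resolution
    if (test(mid)) hi <- mid else lo <- mid
  }
  hi
}
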