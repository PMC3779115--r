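#' Channel parameters of the atrial cell model
#'
#' Construct the maximal-conductance / flux-scale parameter set of the
#' updated atrial myocyte model. The defaults reproduce the control right
#' atrial (RA) base cell; regional variants and AF remodelling scenarios are
#' expressed as transforms of this object (see [apply_region()] and
#' [apply_af()]).
#'
#' Conductances are in nS/pF, the exchanger scale `k_NaCa` in pA/pF,
#' `i_NaK_max` and `i_pCa_max` in pA/pF, `shift_to_inact` in mV
#' (depolarising shift of the I_to steady-state inactivation curve),
#' `tau_CaL_mult` a dimensionless multiplier on the I_CaL activation and
#' inactivation time constants, `C_m` in pF. `serca_vmax`, `ryr_scale` and
#' `sr_leak_scale` are dimensionless multipliers on the SR uptake, release
#' and leak fluxes.
#'
#' @param ... named overrides of individual parameters.
#' @return A named numeric vector of class `channel_params`.
#' @examples
#' p <- channel_params()
#' p_af <- channel_params(g_K1 = 2 * p[["g_K1"]])
#' @export
channel_params <- function(...) {
  p <- .base_params
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("channel_params() overrides must be named")
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown channel parameter(s): ", paste(unknown, collapse = ", "))
    p[names(ov)] <- as.numeric(unlist(ov))
  }
  validate_params(p)
  structure(p, class = "channel_params")
}

# Control base-cell parameter values. Conductance balance calibrated so the
# paced base cell reproduces the published control AP (APD90 242 ms at
# BCL 1000 ms, resting potential near -81 mV, spike-and-dome morphology)
# and the documented remodelling responses; see the methods vignette.
.base_params <- c(
  g_Na = 12,
  g_CaL = 0.08,
  g_to = 0.20,
  g_Kur = 0.077,
  g_Kr = 0.028,
  g_Ks = 2.3,
  g_K1 = 0.042,
  k_NaCa = 3200,
  i_NaK_max = 0.59933874,
  i_pCa_max = 0.275,
  g_bNa = 0.0004,
  g_bCa = 0.001131,
  serca_vmax = 1,
  ryr_scale = 1,
  sr_leak_scale = 1,
  shift_to_inact = 0,
  tau_CaL_mult = 1,
  C_m = 100
)

validate_params <- function(p) {
  if (!is.numeric(p) || length(p) != length(.base_params) ||
      !identical(names(p), names(.base_params)))
    stop("malformed channel_params object")
  if (any(!is.finite(p))) stop("non-finite channel parameter")
  nonneg <- setdiff(names(.base_params), c("shift_to_inact"))
  if (any(p[nonneg] < 0)) stop("conductances and scales must be >= 0")
  if (p[["tau_CaL_mult"]] <= 0 || p[["C_m"]] <= 0)
    stop("multipliers and C_m must be > 0")
  invisible(p)
}

#' @export
print.channel_params <- function(x, ...) {
  cat("<channel_params>\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Names and layout of the membrane state vector
#'
#' The cell state holds, in fixed order: membrane potential `V` (mV); the
#' Hodgkin-Huxley gates of I_Na (`m`, `h`, `j`), I_CaL (`d`, `f_1`, `f_2`,
#' `f_Ca`), I_to (`to_act`, `to_inact`), I_Kur (`kur_act`, `kur_inact`),
#' I_Kr (`x_r`) and I_Ks (`x_s`); the SR release-channel states (`ryr_u`,
#' `ryr_v`, `ryr_w`); intracellular Na+ and K+ (`Na_i`, `K_i`, mM);
#' peripheral and interior cytosolic Ca2+ (`Ca_sub`, `Ca_cen`, mM); and the
#' SR uptake- and release-compartment Ca2+ (`Ca_up`, `Ca_rel`, mM).
#'
#' @return Character vector of state-variable names (length 23).
#' @export
state_names <- function() .state_names_cpp()

#' Default (unconverged) membrane state
#'
#' A physiologically sensible starting state used to seed quiescent
#' relaxation; use [resting_state()] for a converged resting state.
#'
#' @return Named numeric vector of class `membrane_state`.
#' @export
default_state <- function() {
  s <- c(V = -81.2, m = 0.0029, h = 0.965, j = 0.978,
         d = 1.37e-4, f_1 = 0.999, f_2 = 0.999, f_Ca = 0.775,
         to_act = 7e-4, to_inact = 0.97, kur_act = 1.6e-4, kur_inact = 0.999,
         x_r = 3.3e-5, x_s = 0.0187, ryr_u = 0, ryr_v = 1, ryr_w = 0.999,
         Na_i = 11.17, K_i = 139, Ca_sub = 1e-4, Ca_cen = 1e-4,
         Ca_up = 1.2, Ca_rel = 1.2)
  stopifnot(identical(names(s), as.character(state_names())))
  structure(s, class = "membrane_state")
}

validate_state <- function(s) {
  nm <- as.character(state_names())
  if (!is.numeric(s) || length(s) != length(nm))
    stop("membrane state must be a numeric vector of length ", length(nm))
  if (is.null(names(s))) names(s) <- nm
  if (any(!is.finite(s))) {
    bad <- nm[which(!is.finite(s))[1]]
    stop("invalid state: non-finite entry in ", bad)
  }
  gates <- nm[2:17]
  if (any(s[gates] < 0 | s[gates] > 1))
    stop("invalid state: gating variable outside [0, 1]")
  conc <- nm[18:23]
  if (any(s[conc] <= 0))
    stop("invalid state: non-positive concentration")
  invisible(s)
}
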