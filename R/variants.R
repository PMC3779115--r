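#' Atrial region identifiers
#'
#' The electrophysiologically distinct atrial regions supported by the
#' regional cell-model family: right atrium (RA, the base model), crista
#' terminalis (CT), pectinate muscles (PM), right atrial appendage (RAA),
#' atrio-ventricular ring (AVR), atrial septum (AS), Bachmann's bundle
#' (BB), left atrium (LA), left atrial appendage (LAA) and pulmonary veins
#' (PV).
#'
#' @return Character vector of region ids.
#' @export
region_ids <- function() {
  c("RA", "CT", "PM", "RAA", "AVR", "AS", "BB", "LA", "LAA", "PV")
}

# channels a regional transform may touch, per region. PM/RAA/AVR/AS vary
# the depolarising-phase currents (I_CaL/I_to/I_Kur, plus I_K1 where the
# data require it); CT and BB additionally scale the slow delayed-rectifier
# reserve (their prolonged APs are unreachable through I_CaL/I_to alone in
# this base model); LA/LAA vary the delayed rectifiers and I_to; PV is a
# short-AP variant with deep I_CaL/I_Kur reduction and increased I_Kr.
.region_channels <- list(
  RA  = character(0),
  CT  = c("g_CaL", "g_to", "g_Ks"),
  PM  = c("g_CaL", "g_to", "g_Kur"),
  AVR = c("g_CaL", "g_to", "g_Kur", "g_K1"),
  RAA = c("g_CaL", "g_to", "g_Kur", "g_K1"),
  AS  = c("g_CaL", "g_to", "g_Kur", "g_K1"),
  BB  = c("g_CaL", "g_K1", "g_Ks"),
  LA  = c("g_Kr", "g_Ks", "g_to"),
  LAA = c("g_Kr", "g_Ks", "g_to", "g_Kur"),
  PV  = c("g_CaL", "g_Kr", "g_Kur", "g_to", "g_K1")
)

#' Regional scaling table
#'
#' A `regional_table` maps each region id to multiplicative factors on a
#' subset of maximal conductances. The RA row is the identity. The table
#' shipped with the package ([default_regional_table()]) was produced by
#' [calibrate_regional_table()] against the published regional APD90
#' targets; this constructor is mainly useful for building custom tables.
#'
#' @param factors named list: per region, a named numeric vector of
#'   multiplicative factors (allowed names per region are restricted to the
#'   channels that region's variant may touch).
#' @return An object of class `regional_table`.
#' @export
regional_table <- function(factors) {
  stopifnot(is.list(factors))
  unknown <- setdiff(names(factors), region_ids())
  if (length(unknown))
    stop("unknown region(s): ", paste(unknown, collapse = ", "))
  for (rg in names(factors)) {
    f <- factors[[rg]]
    if (length(f)) {
      bad <- setdiff(names(f), .region_channels[[rg]])
      if (length(bad))
        stop("region ", rg, " may not scale: ", paste(bad, collapse = ", "))
      if (any(f <= 0)) stop("regional factors must be > 0")
    }
  }
  if (is.null(factors$RA)) factors$RA <- numeric(0)
  if (length(factors$RA)) stop("the RA row must be the identity")
  structure(factors, class = "regional_table")
}

#' @export
print.regional_table <- function(x, ...) {
  cat("<regional_table>\n")
  for (rg in names(x)) {
    f <- x[[rg]]
    cat(sprintf("  %-4s %s\n", rg,
                if (!length(f)) "(identity)" else
                paste(sprintf("%s=%.4g", names(f), f), collapse = " ")))
  }
  invisible(x)
}

#' Apply a regional variant to a parameter set
#'
#' Returns a new [channel_params()] object with the region's multiplicative
#' factors applied; the input is not modified and only listed parameters
#' change.
#'
#' @param base a [channel_params()] object (the RA base model).
#' @param region a region id (see [region_ids()]).
#' @param table a `regional_table`; defaults to the calibrated table
#'   shipped with the package.
#' @return A `channel_params` object for the regional cell model.
#' @examples
#' p_ct <- apply_region(channel_params(), "CT")
#' @export
apply_region <- function(base, region, table = default_regional_table()) {
  validate_params(base)
  if (!region %in% region_ids()) stop("unknown region: ", region)
  if (!region %in% names(table))
    stop("table does not contain region ", region)
  p <- unclass(base)
  f <- table[[region]]
  if (length(f)) p[names(f)] <- p[names(f)] * f
  structure(p, class = "channel_params")
}

#' AF remodelling scenarios
#'
#' The electrical-remodelling scenarios expressed as parameter transforms:
#' `CONTROL` (identity, no coupling change), `AF0` (no channel remodelling,
#' 60\% diffusion reduction), and `AF1`-`AF4` (channel remodelling per the
#' experimental data sets they encode, each with a 40\% diffusion
#' reduction). Factors multiply maximal conductances/flux scales; `AF1`
#' additionally slows the I_CaL time constants by 60\% and shifts the I_to
#' steady-state inactivation curve by +16 mV.
#'
#' @param id one of `"CONTROL"`, `"AF0"`, `"AF1"`, `"AF2"`, `"AF3"`,
#'   `"AF4"`.
#' @return An object of class `af_scenario` with elements `id`, `factors`
#'   (multiplicative), `shifts` (additive, mV / multipliers) and
#'   `d_reduction` (fractional reduction of the tissue diffusion
#'   coefficient).
#' @export
af_scenario <- function(id = c("CONTROL", "AF0", "AF1", "AF2", "AF3", "AF4")) {
  id <- match.arg(id)
  sc <- switch(id,
    CONTROL = list(factors = c(), shifts = c(), d_reduction = 0),
    AF0 = list(factors = c(), shifts = c(), d_reduction = 0.60),
    AF1 = list(factors = c(g_CaL = 0.30, g_to = 0.30, g_K1 = 2.00),
               shifts = c(shift_to_inact = 16, tau_CaL_mult = 1.6),
               d_reduction = 0.40),
    AF2 = list(factors = c(g_CaL = 0.35, g_to = 0.35, g_K1 = 1.75),
               shifts = c(), d_reduction = 0.40),
    AF3 = list(factors = c(g_CaL = 0.37, g_to = 0.34, g_K1 = 2.06,
                           g_Kur = 0.51),
               shifts = c(), d_reduction = 0.40),
    AF4 = list(factors = c(g_CaL = 0.30, g_to = 0.35, g_K1 = 2.00,
                           g_Kur = 0.50, g_Ks = 2.00, k_NaCa = 1.55,
                           serca_vmax = 1.50, ryr_scale = 4.00,
                           sr_leak_scale = 1.25),
               shifts = c(), d_reduction = 0.40))
  structure(c(list(id = id), sc), class = "af_scenario")
}

#' @export
print.af_scenario <- function(x, ...) {
  cat("<af_scenario> ", x$id, "  (diffusion reduction ",
      100 * x$d_reduction, "%)\n", sep = "")
  if (length(x$factors))
    cat("  factors: ", paste(sprintf("%s x%.2f", names(x$factors), x$factors),
                             collapse = ", "), "\n", sep = "")
  if (length(x$shifts))
    cat("  kinetics: ", paste(sprintf("%s %+g", names(x$shifts), x$shifts),
                              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Apply an AF remodelling scenario to a parameter set
#'
#' Multiplicative factors are applied as stated percentages (a "-70\%"
#' entry is a factor 0.30); the I_to inactivation shift is added to
#' `shift_to_inact` and the I_CaL time-constant change multiplies
#' `tau_CaL_mult`. The input is never modified. Composition with
#' [apply_region()] commutes for purely multiplicative entries.
#'
#' @param base a [channel_params()] object.
#' @param scenario an [af_scenario()] object or scenario id string.
#' @return A remodelled `channel_params` object.
#' @examples
#' p_af4 <- apply_af(channel_params(), "AF4")
#' @export
apply_af <- function(base, scenario) {
  validate_params(base)
  if (is.character(scenario)) scenario <- af_scenario(scenario)
  stopifnot(inherits(scenario, "af_scenario"))
  p <- unclass(base)
  f <- scenario$factors
  if (length(f)) p[names(f)] <- p[names(f)] * f
  sh <- scenario$shifts
  if ("shift_to_inact" %in% names(sh))
    p[["shift_to_inact"]] <- p[["shift_to_inact"]] + sh[["shift_to_inact"]]
  if ("tau_CaL_mult" %in% names(sh))
    p[["tau_CaL_mult"]] <- p[["tau_CaL_mult"]] * sh[["tau_CaL_mult"]]
  structure(p, class = "channel_params")
}

#' Scenario-specific rapid-pacing cycle lengths
#'
#' The conditioning rates used before AF initiation: 140 ms for AF1/AF2,
#' 165 ms for AF3/AF4, 275 ms for control (and AF0, which has unremodelled
#' cells).
#'
#' @param id scenario id.
#' @return BCL in ms.
#' @export
rapid_pacing_bcl <- function(id) {
  switch(id,
         AF1 = , AF2 = 140,
         AF3 = , AF4 = 165,
         CONTROL = , AF0 = 275,
         stop("unknown scenario id: ", id))
}
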