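# shared fixtures: memoised paced APDs and traces so expensive simulations
# run once per session

.memo <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.memo[[key]])) .memo[[key]] <- force(expr)
  .memo[[key]]
}

params_for <- function(region = "RA", scenario = "CONTROL") {
  apply_af(apply_region(channel_params(), region), scenario)
}

paced_trace <- function(region = "RA", scenario = "CONTROL", bcl = 1000,
                        n_beats = 10) {
  key <- paste("trace", region, scenario, bcl, n_beats, sep = "|")
  memo(key, pace_cell(params_for(region, scenario), bcl = bcl,
                      n_beats = n_beats))
}

paced_apd <- function(region = "RA", scenario = "CONTROL", bcl = 1000,
                      n_beats = 10) {
  measure_apd(paced_trace(region, scenario, bcl, n_beats))
}

# parameter set with every current switched off: the reaction term is
# exactly zero, turning the monodomain solver into a pure diffusion solver
zero_conductance_params <- function() {
  channel_params(g_Na = 0, g_CaL = 0, g_to = 0, g_Kur = 0, g_Kr = 0,
                 g_Ks = 0, g_K1 = 0, k_NaCa = 0, i_NaK_max = 0,
                 i_pCa_max = 0, g_bNa = 0, g_bCa = 0)
}

# synthetic trace helper
synthetic_trace <- function(t, V, stim_times = 0) {
  structure(list(t = t, V = V, Ca_sub = rep(1e-4, length(t)),
                 Ca_cen = rep(1e-4, length(t)), stim_times = stim_times,
                 final_state = NULL, max_dvdt = NA_real_),
            class = "cell_trace")
}

standard_junction_cable <- function() {
  make_cable(200, region_layout = list(PM = 1:100, CT = 101:200))
}
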