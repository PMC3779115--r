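test_that("currents vanish at their reversal / closed-gate conditions", {
  p <- channel_params()
  s <- default_state()
  # V at the K+ Nernst potential: IK1 (and all pure K+ currents) zero
  RTF <- 8.3143 * 310 / 96.4867
  s["V"] <- RTF * log(5.4 / s[["K_i"]])
  cur <- ionic_currents(s, p)
  expect_equal(cur[["I_K1"]], 0, tolerance = 1e-12)
  expect_equal(cur[["I_to"]], 0, tolerance = 1e-12)
  # closed activation gate: ICaL = 0 regardless of V
  s2 <- default_state()
  s2["d"] <- 0
  for (v in c(-80, -20, 30)) {
    s2["V"] <- v
    expect_identical(ionic_currents(s2, p)[["I_CaL"]], 0)
  }
  # component sum equals total to machine precision
  cur <- ionic_currents(default_state(), p)
  expect_equal(sum(cur[-length(cur)]), cur[["total"]], tolerance = 1e-12)
})

test_that("non-finite state entries are rejected with the variable named", {
  s <- default_state()
  s["Na_i"] <- NaN
  expect_error(ionic_currents(s), "Na_i")
  s <- default_state()
  s["m"] <- 1.5
  expect_error(ionic_currents(s), "gating")
})

test_that("the converged resting state is a quiescent fixed point", {
  p <- channel_params()
  rs <- memo("rest_RA", resting_state(p))
  # fully quiescent rest sits ~1 mV above the classical polarised band
  # (slow Na efflux in quiescence); the paced diastolic potential is inside
  expect_gte(rs[["V"]], -85)
  expect_lte(rs[["V"]], -72)
  tr10 <- paced_trace()
  v_dia <- tr10$V[which(tr10$t >= 8995)[1]]   # end of 9th diastole
  expect_gte(v_dia, -85)
  expect_lte(v_dia, -75)
  # total ionic current nearly zero at rest
  expect_lt(abs(ionic_currents(rs, p)[["total"]]), 0.01)
  # 1000 ms of unstimulated integration moves V by < 0.5 mV
  tr <- run_cell(p, rs, t_end = 1000)
  expect_lt(abs(tr$final_state[["V"]] - rs[["V"]]), 0.5)
  # idempotence at the operational stationarity tolerance
  rs2 <- resting_state(p, state = rs)
  expect_lt(abs(rs2[["V"]] - rs[["V"]]), 0.05)
  expect_lt(max(abs(as.numeric(rs2) - as.numeric(rs))), 0.05)
})

test_that("raised IK1 hyperpolarises the resting potential", {
  p <- channel_params()
  rs <- memo("rest_RA", resting_state(p))
  rs_k1 <- resting_state(channel_params(g_K1 = 2 * p[["g_K1"]]))
  expect_lt(rs_k1[["V"]], rs[["V"]])
})

test_that("time-step refinement leaves the paced AP unchanged", {
  p <- channel_params()
  tr1 <- run_cell(p, t_end = 600, stim_times = 0, dt = 0.005,
                  record_every = 1)
  tr2 <- run_cell(p, t_end = 600, stim_times = 0, dt = 0.0025,
                  record_every = 1)
  expect_lt(max(abs(tr1$V - tr2$V)), 0.5)
  # Rush-Larsen gate updates converge to the same solution
  tr3 <- run_cell(p, t_end = 600, stim_times = 0, dt = 0.005,
                  record_every = 1, rush_larsen = TRUE)
  expect_lt(max(abs(tr1$V - tr3$V)), 1)
})

test_that("overly large time steps trigger the stability warning", {
  expect_warning(run_cell(channel_params(), t_end = 1, stim_times = numeric(0),
                          dt = 0.05), "stability")
})

test_that("the control AP keeps the atrial spike-and-dome morphology", {
  tr <- paced_trace()
  sel <- tr$t >= 9000 & tr$t <= 9400
  v <- tr$V[sel]
  peaks <- which(diff(sign(diff(v))) == -2) + 1
  # a spike followed by a secondary (dome) local maximum
  expect_gte(length(peaks), 2)
  expect_gt(v[peaks[1]], 0)
  expect_gt(tr$max_dvdt, 100)   # fast sodium upstroke (> 100 V/s)
})

test_that("the Ca transient has a two-phase upstroke (peripheral leads)", {
  tr <- paced_trace()
  sel <- tr$t >= 9000
  t_pk_sub <- tr$t[sel][which.max(tr$Ca_sub[sel])]
  t_pk_cen <- tr$t[sel][which.max(tr$Ca_cen[sel])]
  expect_lt(t_pk_sub, t_pk_cen)
})

test_that("gates stay in [0,1] and concentrations positive after a step", {
  set.seed(421)
  n <- 1e6
  nm <- as.character(state_names())
  states <- matrix(0, n, length(nm))
  colnames(states) <- nm
  states[, "V"] <- runif(n, -95, 50)
  for (g in nm[2:17]) states[, g] <- runif(n)
  states[, "Na_i"] <- runif(n, 5, 20)
  states[, "K_i"] <- runif(n, 120, 150)
  states[, "Ca_sub"] <- runif(n, 1e-5, 5e-3)
  states[, "Ca_cen"] <- runif(n, 1e-5, 2e-3)
  states[, "Ca_up"] <- runif(n, 0.05, 14)
  states[, "Ca_rel"] <- runif(n, 0.05, 14)
  out <- atriasim:::.batch_step_cpp(states, as.numeric(channel_params()),
                                    0.005)
  expect_true(all(out[, 2:17] >= 0 & out[, 2:17] <= 1))
  expect_true(all(out[, 18:23] > 0))
  expect_true(all(is.finite(out)))
})

test_that("ionic concentrations are stable over long pacing", {
  # stimulus charge is carried by K+, so Na/K must not drift
  tr <- memo("longrun", pace_cell(channel_params(), bcl = 1000,
                                  n_beats = 100, record_every = 0))
  fs <- tr$final_state
  s0 <- default_state()
  expect_lt(abs(fs[["Na_i"]] - s0[["Na_i"]]) / s0[["Na_i"]], 0.05)
  expect_lt(abs(fs[["K_i"]] - s0[["K_i"]]) / s0[["K_i"]], 0.05)
})
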