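test_that("diffusion tensor has the fibre-aligned eigenstructure", {
  D <- diffusion_tensor(c(1, 0, 0), 0.9, 0.1)
  expect_equal(D, diag(c(0.9, 0.1, 0.1)))
  # isotropy when d_long = d_trans
  f <- c(1, 2, -1) / sqrt(6)
  expect_equal(diffusion_tensor(f, 0.3, 0.3), 0.3 * diag(3))
  # eigenvalues {d_long, d_trans, d_trans} for random unit fibres
  set.seed(7)
  for (i in 1:5) {
    f <- rnorm(3); f <- f / sqrt(sum(f^2))
    ev <- sort(eigen(diffusion_tensor(f, 0.72, 0.08))$values)
    expect_equal(ev, c(0.08, 0.08, 0.72), tolerance = 1e-10)
  }
  expect_error(diffusion_tensor(c(1, 1, 0), 1, 0.1), "unit")
})

test_that("the diffusion operator conserves mean V and spreads a Gaussian", {
  zc <- zero_conductance_params()
  # conservation on a no-flux sheet
  g <- make_junction_sheet(21, 21, region_a = "RA", region_b = "RA")
  n <- n_nodes(g)
  set.seed(11)
  init <- matrix(rep(as.numeric(default_state()), each = n), n)
  init[, 1] <- -80 + 30 * runif(n)
  h <- run_simulation(g, "CONTROL", list(), duration = 50,
                      record_every = 0, init_states = init, base = zc)
  expect_equal(mean(h$final_states[, 1]), mean(init[, 1]),
               tolerance = 1e-10)
  # uniform field unchanged to machine precision
  init2 <- matrix(rep(as.numeric(default_state()), each = n), n)
  init2[, 1] <- -63.5
  h2 <- run_simulation(g, "CONTROL", list(), duration = 10,
                       record_every = 0, init_states = init2, base = zc)
  expect_equal(h2$final_states[, 1], rep(-63.5, n), tolerance = 1e-12)
})

test_that("1D diffusion matches the analytic heat kernel", {
  zc <- zero_conductance_params()
  g <- make_cable(400, dx = 0.33)
  n <- n_nodes(g)
  x <- (seq_len(n) - 1) * g$dx
  x0 <- x[n / 2]
  s0 <- 2                        # initial Gaussian width (mm)
  init <- matrix(rep(as.numeric(default_state()), each = n), n)
  init[, 1] <- -80 + 40 * exp(-(x - x0)^2 / (2 * s0^2))
  tt <- 50
  h <- run_simulation(g, "CONTROL", list(), duration = tt,
                      record_every = 0, init_states = init, base = zc)
  s2 <- s0^2 + 2 * g$d_iso * tt
  analytic <- -80 + 40 * (s0 / sqrt(s2)) * exp(-(x - x0)^2 / (2 * s2))
  num <- h$final_states[, 1]
  rms <- sqrt(mean((num - analytic)^2)) / 40
  expect_lt(rms, 0.01)
})

test_that("stability bound is enforced before integration starts", {
  g <- make_cable(200)
  expect_error(run_simulation(g, "CONTROL", list(), duration = 1, dt = 0.5),
               "stability")
})

test_that("control cable conducts at the calibrated velocity", {
  cv <- memo("cv_ctrl", measure_cv(make_cable(200)))
  expect_false(cv$blocked)
  expect_equal(cv$cv, 0.70, tolerance = 0.02)
  # CT bundle, longitudinal
  ct <- make_cable(200, region_layout = list(CT = 1:200),
                   d_iso = atriasim:::.calibrated$d_long)
  cvl <- memo("cv_ct", measure_cv(ct))
  expect_equal(cvl$cv, 1.30, tolerance = 0.03)
})

test_that("conduction velocity follows the square-root diffusion law", {
  # measured on a fine cable where grid dispersion is subdominant
  g <- make_cable(800, dx = 0.0825)
  cv0 <- memo("cv_fine", measure_cv(g)$cv)
  cv6 <- memo("cv_fine_06",
              measure_cv(make_cable(800, dx = 0.0825,
                                    d_iso = 0.6 * g$d_iso))$cv)
  cv4 <- memo("cv_fine_04", measure_cv(g, "AF0")$cv)  # 60% reduction
  expect_lt(abs(cv6 / cv0 - sqrt(0.6)) / sqrt(0.6), 0.03)
  expect_lt(abs(cv4 / cv0 - sqrt(0.4)) / sqrt(0.4), 0.03)
})

test_that("grid refinement converges the conduction velocity from below", {
  cv_coarse <- memo("cv_ctrl", measure_cv(make_cable(200)))$cv
  cv_fine <- memo("cv_half", measure_cv(make_cable(400, dx = 0.165))$cv)
  cv_finer <- memo("cv_fine", measure_cv(make_cable(800, dx = 0.0825))$cv)
  # forward-Euler/centred-difference dispersion slows coarse grids
  expect_gt(cv_fine, cv_coarse)
  expect_gt(cv_finer, cv_fine)
  # successive refinement steps shrink the change (convergence)
  expect_lt(abs(cv_finer - cv_fine), abs(cv_fine - cv_coarse))
})

test_that("a centred stimulus produces circular (and 9:1 elliptic) wavefronts", {
  axis_reach <- function(g, h, t_iso) {
    at <- h$activation_times[, 1]
    ij <- arrayInd(which(g$inside), g$dims)
    xy <- cbind((ij[, 1] - 1) * g$dx, (ij[, 2] - 1) * g$dx)
    c0 <- (g$dims - 1) * g$dx / 2
    reach <- function(axis) {
      onax <- abs(xy[, 3 - axis] - c0[3 - axis]) < 1e-6 &
        xy[, axis] >= c0[axis]
      d <- xy[onax, axis] - c0[axis]
      tt <- at[onax]
      ok <- !is.na(tt)
      o <- order(d[ok])
      approx(tt[ok][o], d[ok][o], xout = t_iso)$y
    }
    c(x = reach(1), y = reach(2))
  }
  g <- make_junction_sheet(61, 61, region_a = "RA", region_b = "RA")
  h <- run_simulation(g, "CONTROL",
                      list(list(nodes = stim_disc(g, radius_mm = 2),
                                times = 0, amplitude = 4)),
                      duration = 14, record_every = 0)
  r <- axis_reach(g, h, 10)
  expect_lt(max(r) / min(r), 1.05)
  # fibres along x, anisotropy 9:1 -> axis ratio sqrt(9) = 3
  g2 <- make_junction_sheet(121, 61, region_a = "CT", region_b = "CT",
                            bundle_strip = list(region = "CT", rows = 1:61))
  h2 <- run_simulation(g2, "CONTROL",
                       list(list(nodes = stim_disc(g2, radius_mm = 2),
                                 times = 0, amplitude = 4)),
                       duration = 14, record_every = 0)
  r2 <- axis_reach(g2, h2, 12)
  expect_equal(unname(r2[1] / r2[2]), 3.0, tolerance = 0.15 / 3)
})

test_that("a paced homogeneous cable has a uniform APD90 map", {
  g <- make_cable(150)
  stim <- list(list(nodes = 1:7, times = 0))
  h <- run_simulation(g, "CONTROL", stim, duration = 700, record_every = 1)
  # APD90 per node, away from the stimulated end and the far boundary
  apds <- vapply(seq(20, 130, by = 10), function(nd) {
    on <- h$activation_times[nd, 1]
    measure_apd(list(t = h$t, V = h$V[nd, ], stim_times = on - 2))
  }, numeric(1))
  # the near-bifurcation dome dynamics leave a stable +-7 ms spatial
  # pattern; the map must be bounded and free of a systematic gradient
  expect_lt(max(apds) - min(apds), 20)
  trend <- abs(coef(lm(apds ~ seq_along(apds)))[2]) * length(apds)
  expect_lt(trend, 0.5 * (max(apds) - min(apds) + 1))
})
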