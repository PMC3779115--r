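test_that("cable generator covers regions and lengths exactly", {
  g <- make_cable(120, dx = 0.33)
  expect_equal(n_nodes(g), 120)
  expect_true(all(g$region == "RA"))
  expect_equal(120 * g$dx, 39.6)
  g2 <- make_cable(100, region_layout = list(PM = 1:40, CT = 41:100))
  expect_equal(g2$region[40], "PM")
  expect_equal(g2$region[41], "CT")
  expect_error(make_cable(10, region_layout = list(RA = 1:5)), "cover")
  # pure function: identical reruns
  expect_identical(make_cable(50), make_cable(50))
})

test_that("junction sheets split regions and confine fibres to the strip", {
  g <- make_junction_sheet(40, 30, region_a = "PM", region_b = "CT",
                           interface = 21)
  rg <- matrix(g$region, 40, 30)
  expect_true(all(rg[1:20, ] == "PM"))
  expect_true(all(rg[21:40, ] == "CT"))
  expect_equal(mean(g$region == "PM"), 0.5)
  gs <- make_junction_sheet(40, 30, bundle_strip =
                              list(region = "CT", rows = 14:17))
  m <- matrix(FALSE, 40, 30); m[, 14:17] <- TRUE
  has_fibre <- rowSums(gs$fibre^2) > 0
  expect_identical(has_fibre, as.vector(m))
  expect_error(make_junction_sheet(40, 30, bundle_strip =
                                     list(region = "CT", rows = 29:33)),
               "strip outside")
})

test_that("the stimulus disc has the standard electrode radius", {
  g <- make_junction_sheet(61, 61)
  nodes <- stim_disc(g)
  xy <- cbind((arrayInd(which(g$inside), g$dims)[, 1] - 1) * g$dx,
              (arrayInd(which(g$inside), g$dims)[, 2] - 1) * g$dx)
  ctr <- (g$dims - 1) * g$dx / 2
  d <- sqrt(rowSums((xy - matrix(ctr, nrow(xy), 2, byrow = TRUE))^2))
  expect_true(all(d[nodes] <= 3.3))
  expect_true(all(d[-nodes] > 3.3))
})

test_that("rings are periodic: a wave circulates across the seam", {
  ring <- make_ring(60, region = "RA")
  L <- build_laplacian(ring)
  # periodic operator: every node has two neighbours, zero row sums
  expect_true(all(abs(Matrix::rowSums(L)) < 1e-12))
  expect_equal(unname(Matrix::diag(L)), rep(-2 * ring$d_iso / ring$dx^2, 60))
})

test_that("graded junctions blend parameters linearly across the interface", {
  g <- make_cable(100, region_layout = list(PM = 1:50, CT = 51:100))
  expect_identical(graded_junction(g, 0), g)
  gg <- graded_junction(g, width_mm = 6.6)   # 20 nodes
  expect_false(is.null(gg$blend))
  tp <- atriasim:::build_tissue_params(gg, "CONTROL")
  pa <- as.numeric(apply_region(channel_params(), "PM"))
  pb <- as.numeric(apply_region(channel_params(), "CT"))
  # far ends are pure PM / CT
  expect_equal(tp$param_matrix[tp$node_param[1], ], pa, tolerance = 1e-12)
  expect_equal(tp$param_matrix[tp$node_param[100], ], pb, tolerance = 1e-12)
  # the mid-interface node carries mean parameters
  wmid <- gg$blend[which.min(abs(gg$blend - 0.5))]
  expect_lt(abs(wmid - 0.5), 0.05)
  pm <- tp$param_matrix[tp$node_param[which.min(abs(gg$blend - 0.5))], ]
  expect_equal(pm, (pa + pb) / 2, tolerance = 0.05 * max(abs(pa - pb)))
})

test_that("electrotonus smooths the APD step at a junction", {
  g <- standard_junction_cable()
  stim <- list(list(nodes = 95:106, times = 0))
  h <- memo("junction_pace",
            run_simulation(g, "CONTROL", stim, duration = 700,
                           record_every = 1))
  # per-node APD measured from each node's own activation (upstroke time),
  # so conduction delay does not contaminate the map
  apds <- vapply(seq(30, 170, by = 2), function(nd) {
    on <- h$activation_times[nd, 1]
    measure_apd(list(t = h$t, V = h$V[nd, ], stim_times = on - 2))
  }, numeric(1))
  nodes <- seq(30, 170, by = 2)
  pm_apd <- mean(apds[nodes < 70])
  ct_apd <- mean(apds[nodes > 130])
  expect_gt(ct_apd, pm_apd + 10)   # a real step exists
  # electrotonus smears the step over a finite, domain-contained width
  # (this model's shallow tail conductance gives a long length constant)
  lo <- pm_apd + 0.1 * (ct_apd - pm_apd)
  hi <- pm_apd + 0.9 * (ct_apd - pm_apd)
  inband <- nodes[apds > lo & apds < hi]
  width_mm <- (max(inband) - min(inband)) * g$dx
  expect_gt(width_mm, 0)
  expect_lt(width_mm, diff(range(nodes)) * g$dx)
  # coupling reduces the cell-intrinsic APD difference at the junction
  intrinsic <- paced_apd("CT") - paced_apd("PM")
  expect_lt(ct_apd - pm_apd, intrinsic + 5)
})

test_that("graded and stepwise junctions give practically the same window", {
  g <- standard_junction_cable()
  vw_step <- memo("vw_step",
                  scan_s1s2(g, "CONTROL", ci_range = c(220, 260), ci_step = 5))
  gg <- graded_junction(g, width_mm = 3.3)
  vw_grad <- memo("vw_grad",
                  scan_s1s2(gg, "CONTROL", ci_range = c(220, 260), ci_step = 5))
  expect_false(is.null(vw_step$vw_cb))
  # bounds differ by < 5 ms
  if (is.null(vw_grad$vw_cb)) {
    fail("graded junction lost its vulnerable window entirely")
  } else {
    expect_lt(max(abs(vw_step$vw_cb - vw_grad$vw_cb)), 5 + 1e-9)
  }
})
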