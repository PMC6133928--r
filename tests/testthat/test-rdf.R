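test_that("rdf validates groups and range", {
  gas <- gen_ideal_gas(shell_fluid_spec(60, c(3, 3, 3), 2, seed = 1))
  expect_error(compute_rdf(gas, 1:30, 25:60, 0.05), "disjoint")
  expect_error(compute_rdf(gas, 1:30, 31:60, 0.05, r_max = 2), "half")
  expect_error(compute_rdf(gas, 1:30, "XX", 0.05), "matches no atoms")
})

test_that("ideal-gas coordination follows the uniform-density closed form", {
  gas <- gen_ideal_gas(shell_fluid_spec(800, c(3, 3, 3), 40, seed = 6))
  rdf <- compute_rdf(gas, 1:400, 401:800, bin_width = 0.02, r_max = 1.4)
  rho <- 400 / 27
  for (rc in c(0.5, 1.0, 1.4)) {
    expect_lt(abs(coordination_number(rdf, rc) - rho * 4 / 3 * pi * rc^3) /
                (rho * 4 / 3 * pi * rc^3), 0.02)
  }
  # below the first occupied distances: essentially no partners
  expect_lt(coordination_number(rdf, 0.005), 1e-4)
})

test_that("pair-count bookkeeping is conserved through the normalization", {
  gas <- gen_ideal_gas(shell_fluid_spec(200, c(3, 3, 3), 5, seed = 9))
  rdf <- compute_rdf(gas, 1:100, 101:200, bin_width = 0.03, r_max = 1.2)
  # n(r_max) * n_a * n_frames must equal the raw pair count below r_max
  lhs <- coordination_number(rdf, 1.2) * rdf$n_a * rdf$n_frames
  expect_equal(lhs, sum(rdf$counts), tolerance = 1e-9)
})

test_that("rdf is symmetric under group exchange for equal-size groups", {
  gas <- gen_ideal_gas(shell_fluid_spec(300, c(3, 3, 3), 4, seed = 10))
  g_ab <- compute_rdf(gas, 1:150, 151:300, bin_width = 0.05, r_max = 1.4)
  g_ba <- compute_rdf(gas, 151:300, 1:150, bin_width = 0.05, r_max = 1.4)
  expect_lt(max(abs(g_ab$g - g_ba$g)), 1e-9)
})

test_that("coordination numbers are stable under bin-width doubling", {
  gas <- gen_ideal_gas(shell_fluid_spec(800, c(3, 3, 3), 30, seed = 12))
  r1 <- compute_rdf(gas, 1:400, 401:800, bin_width = 0.01, r_max = 1.4)
  r2 <- compute_rdf(gas, 1:400, 401:800, bin_width = 0.02, r_max = 1.4)
  n1 <- coordination_number(r1, 1.0); n2 <- coordination_number(r2, 1.0)
  expect_lt(abs(n1 - n2) / n1, 0.02)
})

test_that("first-shell extrema are found on constructed curves", {
  g_fun <- function(r)
    1 + 2.5 * exp(-(r - 0.30)^2 / (2 * 0.02^2)) -
      0.8 * exp(-(r - 0.40)^2 / (2 * 0.02^2))
  rdf <- analytic_rdf(g_fun)
  expect_lt(abs(first_peak(rdf) - 0.30), 0.006)     # within one bin
  expect_lt(abs(first_minimum(rdf) - 0.40), 0.006)

  # pure repulsion: monotone rise to 1, no structured shell
  mono <- analytic_rdf(function(r) pmin(r / 0.5, 1))
  expect_error(first_minimum(mono), "no structured first shell")
})

test_that("a synthetic shell produces a first minimum between shell and bulk", {
  spec <- shell_fluid_spec(400, c(4, 4, 4), 15, shell_center_count = 2,
                           shell_radius = 0.30, shell_occupants = 6, seed = 33)
  traj <- gen_shell_config(spec)
  rdf <- compute_rdf(traj, "CEN", 3:400, bin_width = 0.005, r_max = 1.9)
  rmin <- first_minimum(rdf)
  expect_gt(rmin, 0.30)
  expect_lt(rmin, 0.45)
})

test_that("frame-counting occupancy recovers the stationary bond probability", {
  spec <- two_state_kinetics_spec(1, 0.25, 1.0, 0.05, 1.2e6, seed = 61)
  ind <- gen_two_state_bonds(spec)
  traj <- embed_bonds_as_trajectory(ind, cutoff = 0.3, box = c(3, 3, 3))
  occ <- shell_occupancy(traj, pair_criterion("CEN", "PRT", 0.3))
  expect_lt(abs(occ$fraction - 0.2) / 0.2, 0.02)

  ones <- indicator_series(matrix(1L, 1, 100), dt = 0.1)
  traj1 <- embed_bonds_as_trajectory(ones, 0.3, c(3, 3, 3))
  expect_equal(shell_occupancy(traj1, pair_criterion("CEN", "PRT", 0.3))$fraction, 1)
  zeros <- indicator_series(matrix(0L, 1, 100), dt = 0.1)
  traj0 <- embed_bonds_as_trajectory(zeros, 0.3, c(3, 3, 3))
  expect_equal(shell_occupancy(traj0, pair_criterion("CEN", "PRT", 0.3))$fraction, 0)
})

test_that("region density ratio is 1 for a uniform species and extreme for pinned ones", {
  # two fixed sites plus a uniform species
  n_sp <- 1500; nf <- 150
  set.seed(3)
  coords <- array(runif((n_sp + 2) * 3 * nf, 0, 4), dim = c(n_sp + 2, 3, nf))
  coords[1, , ] <- c(1.0, 2.0, 2.0)
  coords[2, , ] <- c(2.0, 2.0, 2.0)
  traj <- trajectory(coords, c(4, 4, 4),
                     labels = c("SA", "SB", rep("ION", n_sp)))
  rep_u <- region_density_ratio(traj, "SA", "SB", "ION", region_radius = 0.5)
  expect_lt(abs(rep_u$ratio - 1), 0.05)

  # species pinned at the midpoint every frame
  coords[3, , ] <- c(1.5, 2.0, 2.0)
  traj_p <- trajectory(coords, c(4, 4, 4),
                       labels = c("SA", "SB", rep("ION", n_sp)))
  rep_p <- region_density_ratio(traj_p, "SA", "SB", c(3), region_radius = 0.2)
  v_box <- 64; v_reg <- 4 / 3 * pi * 0.2^3
  expect_equal(rep_p$ratio, v_box / v_reg, tolerance = 1e-9)

  # species excluded from the region
  far <- traj
  far$coords[3:(n_sp + 2), 1, ] <- 3.5   # all ions far from midpoint x=1.5
  rep_0 <- region_density_ratio(far, "SA", "SB", "ION", region_radius = 0.3)
  expect_equal(rep_0$ratio, 0)

  expect_error(region_density_ratio(traj, "SA", "SB", "ION", region_radius = 2.5),
               "half")
  expect_error(region_density_ratio(traj, "ION", "SB", c(3), region_radius = 0.3),
               "single atoms")
})

test_that("shell_report bundles geometry, coordination and occupancy coherently", {
  spec <- shell_fluid_spec(60, c(4, 4, 4), 12, shell_center_count = 2,
                           shell_radius = 0.30, shell_occupants = 6, seed = 44)
  traj <- gen_shell_config(spec)
  rep <- shell_report(traj, "CEN", "OCC", bin_width = 0.01)
  expect_lt(rep$r_first_peak, rep$r_first_min)
  expect_equal(rep$coordination_number, 6, tolerance = 0.01)
  expect_equal(rep$occupancy_fraction, 1)
})
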