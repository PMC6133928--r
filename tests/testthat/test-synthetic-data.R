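test_that("generators are pure functions of their spec, seed included", {
  rs <- rotor_ensemble_spec(20, 0.05, 0.1, 100, seed = 9)
  expect_identical(gen_rotor_ensemble(rs)$vectors, gen_rotor_ensemble(rs)$vectors)

  ks <- two_state_kinetics_spec(10, 0.01, 0.04, 0.1, 2000, seed = 9)
  expect_identical(gen_two_state_bonds(ks)$indicator, gen_two_state_bonds(ks)$indicator)

  fs <- shell_fluid_spec(50, c(3, 3, 3), 5, seed = 9)
  expect_identical(gen_ideal_gas(fs)$coords, gen_ideal_gas(fs)$coords)

  ss <- shell_fluid_spec(40, c(4, 4, 4), 3, shell_center_count = 2,
                         shell_radius = 0.3, shell_occupants = 4, seed = 9)
  expect_identical(gen_shell_config(ss)$coords, gen_shell_config(ss)$coords)

  ps <- umbrella_pull_spec(pmf_zero(), 100, 1e-3, 0.5, 10, 296, 0.01, 500, seed = 9)
  expect_identical(gen_umbrella_pull(ps)$values, gen_umbrella_pull(ps)$values)
})

test_that("rotor vectors stay unit-norm and freeze when diffusion vanishes", {
  vs <- gen_rotor_ensemble(rotor_ensemble_spec(30, 0.05, 0.1, 300, seed = 2))
  nrm <- sqrt(vs$vectors[, 1, ]^2 + vs$vectors[, 2, ]^2 + vs$vectors[, 3, ]^2)
  expect_lt(max(abs(nrm - 1)), 1e-9)

  frozen <- gen_rotor_ensemble(rotor_ensemble_spec(5, 0, 0.1, 50, seed = 2))
  expect_equal(frozen$vectors[50, , ], frozen$vectors[1, , ], tolerance = 1e-12)
  acf <- vector_acf(frozen)
  expect_equal(acf$values, rep(1, length(acf$values)), tolerance = 1e-12)

  expect_error(gen_rotor_ensemble(rotor_ensemble_spec(5, 1, 0.1, 50)),
               "too coarse")
})

test_that("rotor ensembles decay with the closed-form C1(t) = exp(-2 D t)", {
  vs <- gen_rotor_ensemble(rotor_ensemble_spec(400, 0.05, 0.1, 4000, seed = 31))
  acf <- vector_acf(vs, max_lag = 30)
  theory <- exp(-2 * 0.05 * acf$lags)
  # pooled sampling error: n_rotors x effectively-independent origins
  n_eff <- 400 * (4000 * 0.1 / 10)
  expect_lt(max(abs(acf$values - theory)), 3 / sqrt(n_eff) + 0.02)

  # mixture: 30% of rotors 5x slower
  vm <- gen_rotor_ensemble(rotor_ensemble_spec(400, 0.05, 0.1, 4000,
                                               slow_fraction = 0.3,
                                               d_rot_slow = 0.01, seed = 32))
  am <- vector_acf(vm, max_lag = 30)
  mix <- 0.7 * exp(-2 * 0.05 * am$lags) + 0.3 * exp(-2 * 0.01 * am$lags)
  expect_lt(mean(abs(am$values - mix)), 0.02)
})

test_that("two-state chains hit stationary occupancy and per-step rates", {
  spec <- two_state_kinetics_spec(200, 0.01, 0.04, 0.1, 2e4, seed = 7)
  ind <- gen_two_state_bonds(spec)$indicator
  p_eq <- 0.01 / 0.05
  # 3 sigma at this sampling (200 pairs, 2e4 steps, 20 ps decorrelation)
  expect_lt(abs(mean(ind) - p_eq) / p_eq, 0.05)

  # empirical transition probabilities vs 1 - exp(-k dt), within 3 SE
  from1 <- ind[, -ncol(ind)] == 1L
  to0 <- ind[, -1] == 0L
  n1 <- sum(from1)
  p_off_hat <- sum(from1 & to0) / n1
  p_off <- 1 - exp(-0.04 * 0.1)
  expect_lt(abs(p_off_hat - p_off), 3 * sqrt(p_off * (1 - p_off) / n1))
  n0 <- sum(!from1)
  p_on_hat <- sum(!from1 & ind[, -1] == 1L) / n0
  p_on <- 1 - exp(-0.01 * 0.1)
  expect_lt(abs(p_on_hat - p_on), 3 * sqrt(p_on * (1 - p_on) / n0))
})

test_that("vanishing breakage rate drives the indicator to all-bonded", {
  spec <- two_state_kinetics_spec(5, 0.5, 1e-9, 0.1, 5000, seed = 3)
  ind <- gen_two_state_bonds(spec)$indicator
  expect_true(all(ind[, 5000] == 1L))
  expect_gt(mean(ind), 0.99)
})

test_that("geometric embedding is exactly invertible by the distance criterion", {
  spec <- two_state_kinetics_spec(6, 0.02, 0.05, 0.1, 400, seed = 13)
  ind <- gen_two_state_bonds(spec)
  traj <- embed_bonds_as_trajectory(ind, cutoff = 0.3, box = c(6, 6, 6))
  rec <- pair_indicator(traj, pair_criterion("CEN", "PRT", 0.3))
  # matched pair (i, i) sits at row (i-1)*n_b + i of the bipartite product
  nb <- 6L
  matched <- (seq_len(nb) - 1L) * nb + seq_len(nb)
  expect_identical(rec$indicator[matched, ], ind$indicator)
  expect_true(all(rec$indicator[-matched, ] == 0L))

  ind0 <- indicator_series(matrix(0L, 3, 10), dt = 0.1)
  rec0 <- pair_indicator(embed_bonds_as_trajectory(ind0, 0.3, c(6, 6, 6)),
                         pair_criterion("CEN", "PRT", 0.3))
  expect_true(all(rec0$indicator == 0L))

  ind1 <- indicator_series(matrix(1L, 3, 10), dt = 0.1)
  rec1 <- pair_indicator(embed_bonds_as_trajectory(ind1, 0.3, c(6, 6, 6)),
                         pair_criterion("CEN", "PRT", 0.3))
  matched1 <- (1:3 - 1L) * 3L + 1:3
  expect_true(all(rec1$indicator[matched1, ] == 1L))

  expect_error(embed_bonds_as_trajectory(ind, 0.3, c(1, 1, 1)), "capacity")
})

test_that("ideal gas is structureless: g(r) = 1 within counting noise", {
  gas <- gen_ideal_gas(shell_fluid_spec(600, c(3, 3, 3), 30, seed = 5))
  rdf <- compute_rdf(gas, 1:300, 301:600, bin_width = 0.05, r_max = 1.4)
  sel <- rdf$r >= 0.2
  expect_lt(sqrt(mean((rdf$g[sel] - 1)^2)), 0.02)
})

test_that("shell construction yields its designed coordination and occupancy", {
  spec <- shell_fluid_spec(100, c(4, 4, 4), 10, shell_center_count = 2,
                           shell_radius = 0.30, shell_occupants = 6, seed = 21)
  traj <- gen_shell_config(spec)
  rdf <- compute_rdf(traj, "CEN", "OCC", bin_width = 0.01, r_max = 1.9)
  expect_equal(coordination_number(rdf, 0.35), 6, tolerance = 1e-9)
  occ <- shell_occupancy(traj, pair_criterion("CEN", "OCC", 0.35))
  expect_equal(occ$fraction, 1.0)
  expect_equal(occ$mean_partners, 12)  # 6 per centre, 2 centres

  expect_error(gen_shell_config(shell_fluid_spec(5, c(4, 4, 4), 2,
                                                 shell_center_count = 2,
                                                 shell_occupants = 6)),
               "budget")
})

test_that("free, unpulled restraint equilibrates to the equipartition variance", {
  spec <- umbrella_pull_spec(pmf_zero(), k_spring = 1000, pull_speed = 0,
                             x_start = 0.5, friction = 50, temperature = 296,
                             dt = 2e-3, n_steps = 5e4, seed = 17)
  ts <- gen_umbrella_pull(spec)
  x <- ts$values[, "x"]
  kT <- 0.008314462618 * 296
  expect_lt(abs(mean(ts$values[, "f_restraint"])), 3 * sqrt(kT * 1000 / 5e2))
  expect_lt(abs(var(x) - kT / 1000) / (kT / 1000), 0.10)
})

test_that("zero-temperature pull tracks the moving minimum with constant lag", {
  spec <- umbrella_pull_spec(pmf_zero(), k_spring = 500, pull_speed = 1e-3,
                             x_start = 0.4, friction = 50, temperature = 0,
                             dt = 1e-3, n_steps = 2e4, seed = 1)
  ts <- gen_umbrella_pull(spec)
  f <- ts$values[, "f_restraint"]
  # stationary lag force = friction * speed
  expect_equal(mean(f[10000:20000]), 50 * 1e-3, tolerance = 1e-6)
  expect_lt(sd(f[10000:20000]), 1e-9)
})

test_that("quasi-static pull over a harmonic well reads back its gradient", {
  pmf <- pmf_harmonic(200, 0.5)
  spec <- umbrella_pull_spec(pmf, k_spring = 5000, pull_speed = 5e-4,
                             x_start = 0.35, friction = 5, temperature = 296,
                             dt = 1e-4, n_steps = 6e6, seed = 23)
  prof <- bin_mean_force(as_pull_record(gen_umbrella_pull(spec)),
                         bin_width = 0.01, x_range = c(0.40, 0.60))
  expected <- pmf_gradient(pmf, prof$bin_centers)
  # positive-repulsive convention: mean force = -V'(x)
  expect_lt(sqrt(mean((prof$mean_force + expected)^2)),
            0.1 * max(abs(expected)))

  expect_error(gen_umbrella_pull(
    umbrella_pull_spec(pmf, k_spring = 5000, pull_speed = 0, x_start = 0.5,
                       friction = 1, temperature = 296, dt = 0.1, n_steps = 10)),
    "too large")
})
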