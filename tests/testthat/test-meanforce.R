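test_that("pull records enforce the sign convention at construction", {
  ts <- time_series(0:9, cbind(x = seq(0.4, 0.58, by = 0.02),
                               f_restraint = rep(2, 10)))
  rec <- as_pull_record(ts)
  expect_equal(rec$force, rep(-2, 10))      # restraint force negated
  rec2 <- as_pull_record(ts, restraint = FALSE)
  expect_equal(rec2$force, rep(2, 10))
  expect_error(as_pull_record(ts, force_col = "nope"), "columns")
  expect_error(pull_record(0:2, c(-0.1, 0.2, 0.3), 1:3), "> 0")
  expect_error(pull_record(c(0, 0, 1), c(0.1, 0.2, 0.3), 1:3), "increasing")
})

test_that("binning reports exact means for constant force and flags misuse", {
  rec <- pull_record(1:100, seq(0.3, 0.6, length.out = 100), rep(7, 100))
  prof <- bin_mean_force(rec, bin_width = 0.05)
  expect_true(all(abs(prof$mean_force - 7) < 1e-12))
  expect_true(all(prof$stderr == 0))
  expect_equal(sum(prof$n_samples), 100)

  expect_warning(bin_mean_force(rec, bin_width = 5), "one bin")
  expect_error(bin_mean_force(pull_record(numeric(0), numeric(0), numeric(0))),
               "equal length|empty")
})

test_that("profiles are invariant under time reversal of the record", {
  set.seed(8)
  x <- runif(500, 0.3, 0.7); f <- rnorm(500)
  fwd <- bin_mean_force(pull_record(1:500, x, f), 0.02)
  rev <- bin_mean_force(pull_record(1:500, rev(x), rev(f)), 0.02)
  expect_equal(fwd$mean_force, rev$mean_force, tolerance = 1e-12)
  expect_equal(fwd$n_samples, rev$n_samples)
})

test_that("screened-Coulomb reference matches CODATA-level constants", {
  expect_equal(screened_coulomb_force(1, 1, 1, -1), -138.935458,
               tolerance = 138.935 * 1e-4)
  expect_equal(screened_coulomb_force(2, 1, 1, -1) /
                 screened_coulomb_force(1, 1, 1, -1), 0.25, tolerance = 1e-12)
  expect_equal(screened_coulomb_force(0.43, 80, 1, -1), -9.39,
               tolerance = 9.39e-3)
  expect_gt(screened_coulomb_force(0.5, 80, 1, 1), 0)   # like charges repel
  expect_error(screened_coulomb_force(0, 80), "> 0")
})

test_that("regime detection finds crossings and alternating windows", {
  # harmonic mean force -a(x - c): single crossing at c
  prof <- analytic_profile(function(x) -200 * (x - 0.5), 0.3, 0.7)
  reg <- find_regimes(prof, noise_floor = 1)
  expect_equal(length(reg$zero_crossings), 1L)
  expect_lt(abs(reg$zero_crossings - 0.5), 0.01)
  expect_identical(reg$windows$sign, c("repulsive", "attractive"))

  # all-positive: no crossing, one repulsive window
  pos <- analytic_profile(function(x) 5 + 0 * x, 0.3, 0.7)
  reg_pos <- find_regimes(pos, noise_floor = 1)
  expect_length(reg_pos$zero_crossings, 0)
  expect_identical(reg_pos$windows$sign, "repulsive")

  # three-regime shape: repulsive / attractive / repulsive / attractive tail
  shape <- function(x) -4 * 8 * ((x - 0.5) / 0.1) * (((x - 0.5) / 0.1)^2 - 1) / 0.1
  prof3 <- analytic_profile(shape, 0.36, 0.64)
  reg3 <- find_regimes(prof3, noise_floor = 2)
  expect_equal(length(reg3$zero_crossings), 3L)
  expect_lt(max(abs(reg3$zero_crossings - c(0.4, 0.5, 0.6))), 0.01)
  expect_identical(reg3$windows$sign,
                   c("repulsive", "attractive", "repulsive", "attractive"))

  expect_error(find_regimes(analytic_profile(function(x) x, 0.3, 0.31)),
               "3 occupied bins")
})

test_that("a pull across the screened-Coulomb pmf leaves near-zero residuals", {
  pmf <- pmf_screened_coulomb(80)
  spec <- umbrella_pull_spec(pmf, k_spring = 3e4, pull_speed = 1e-4,
                             x_start = 0.4, friction = 50, temperature = 296,
                             dt = 1.5e-4, n_steps = 1.5e7, seed = 71)
  prof <- bin_mean_force(as_pull_record(gen_umbrella_pull(spec)),
                         bin_width = 0.02, x_range = c(0.46, 0.56))
  cmp <- compare_to_reference(prof, eps_r = 80)
  # systematic agreement: the window-mean residual sits well below the
  # reference force scale (per-bin scatter is sampling noise)
  expect_lt(abs(mean(cmp$residual)), 0.1 * mean(abs(cmp$reference)))
  expect_lt(sqrt(mean(cmp$residual^2)), 0.25 * mean(abs(cmp$reference)))

  zero <- analytic_profile(function(x) 0 * x, 0.4, 0.8)
  cmp0 <- compare_to_reference(zero, eps_r = 80)
  expect_equal(cmp0$residual, -cmp0$reference)

  cmp_inf <- compare_to_reference(zero, eps_r = 1e12)
  expect_lt(max(abs(cmp_inf$reference)), 1e-9)
})

test_that("slower pulling never degrades the force-balance recovery", {
  pmf <- pmf_harmonic(300, 0.5)
  rmse_at <- function(speed, n_steps, seed) {
    spec <- umbrella_pull_spec(pmf, k_spring = 4000, pull_speed = speed,
                               x_start = 0.38, friction = 20, temperature = 296,
                               dt = 2e-4, n_steps = n_steps, seed = seed)
    prof <- bin_mean_force(as_pull_record(gen_umbrella_pull(spec)),
                           bin_width = 0.01, x_range = c(0.43, 0.57))
    sqrt(mean((prof$mean_force + pmf_gradient(pmf, prof$bin_centers))^2))
  }
  # each sweep covers 0.38 -> 0.62 nm (speed * n_steps * dt = 0.24 nm)
  r_fast <- rmse_at(4e-3, 3e5, 81)
  r_mid <- rmse_at(1e-3, 1.2e6, 82)
  r_slow <- rmse_at(5e-4, 2.4e6, 83)
  # monotone convergence up to sampling noise
  expect_lt(r_mid, r_fast + 1)
  expect_lt(r_slow, r_mid + 1)
})

test_that("integrating the mean force between crossings recovers pmf differences", {
  pmf <- pmf_double_well(8, 0.5, 0.1)
  spec <- umbrella_pull_spec(pmf, k_spring = 5e4, pull_speed = 1.2e-3,
                             x_start = 0.30, friction = 50, temperature = 296,
                             dt = 5e-5, n_steps = 7e6, seed = 91)
  prof <- bin_mean_force(as_pull_record(gen_umbrella_pull(spec)),
                         bin_width = 0.01, x_range = c(0.36, 0.64))
  sel <- prof$bin_centers >= 0.4 & prof$bin_centers <= 0.5
  # -integral(mean force) from the well (0.4) to the barrier top (0.5)
  dV <- -sum(prof$mean_force[sel]) * 0.01
  expect_lt(abs(dV - 8) / 8, 0.15)
})
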