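#' Synthetic-data specifications
#'
#' Constructors for the seeded generator specs. Each generator is a pure
#' function of its spec (seed included): repeated calls give bitwise
#' identical output. The generators emulate the statistical structure of
#' salt-solution MD trajectories — rotor ensembles under isotropic
#' rotational diffusion (water reorientation), two-state Markov bond
#' kinetics (ion-pair formation/breakage), homogeneous and shell-structured
#' fluids in periodic boxes (coordination structure), and an overdamped
#' particle pulled by a moving harmonic restraint (forced dissociation).
#'
#' @param n_rotors number of unit vectors.
#' @param d_rot rotational diffusion constant, ps^-1.
#' @param dt time step, ps.
#' @param n_steps number of stored steps.
#' @param slow_fraction fraction of rotors diffusing with `d_rot_slow`.
#' @param d_rot_slow diffusion constant of the slow subset, ps^-1.
#' @param seed RNG seed.
#' @return a spec object for the matching generator.
#' @name synthetic_specs
NULL

#' @rdname synthetic_specs
#' @export
rotor_ensemble_spec <- function(n_rotors, d_rot, dt, n_steps,
                                slow_fraction = 0, d_rot_slow = d_rot,
                                seed = 1L) {
  stopifnot_scalar_pos(n_rotors, "n_rotors"); stopifnot_scalar_pos(d_rot + (d_rot == 0), "d_rot")
  stopifnot_scalar_pos(dt, "dt"); stopifnot_scalar_pos(n_steps, "n_steps")
  if (d_rot < 0 || d_rot_slow < 0) stop("diffusion constants must be >= 0", call. = FALSE)
  if (slow_fraction < 0 || slow_fraction > 1)
    stop("'slow_fraction' must lie in [0, 1]", call. = FALSE)
  structure(list(n_rotors = as.integer(n_rotors), d_rot = d_rot, dt = dt,
                 n_steps = as.integer(n_steps), slow_fraction = slow_fraction,
                 d_rot_slow = d_rot_slow, seed = as.integer(seed)),
            class = "rotor_ensemble_spec")
}

#' @rdname synthetic_specs
#' @param k_on,k_off formation / breakage rates, ps^-1. The discretisation
#'   requires `k_off * dt < 0.1` (and likewise for `k_on`).
#' @param n_pairs number of independent bond processes.
#' @export
two_state_kinetics_spec <- function(n_pairs, k_on, k_off, dt, n_steps, seed = 1L) {
  stopifnot_scalar_pos(n_pairs, "n_pairs"); stopifnot_scalar_pos(k_on, "k_on")
  stopifnot_scalar_pos(k_off, "k_off"); stopifnot_scalar_pos(dt, "dt")
  stopifnot_scalar_pos(n_steps, "n_steps")
  if (k_off * dt >= 0.1 || k_on * dt >= 0.1)
    stop("rate * dt must be < 0.1 for the discrete chain to be valid", call. = FALSE)
  structure(list(n_pairs = as.integer(n_pairs), k_on = k_on, k_off = k_off,
                 dt = dt, n_steps = as.integer(n_steps), seed = as.integer(seed)),
            class = "two_state_kinetics_spec")
}

#' @rdname synthetic_specs
#' @param n_particles total particle count (centres + shell occupants + bulk).
#' @param box orthorhombic edge lengths, nm (length 3).
#' @param n_frames number of frames.
#' @param shell_center_count number of designated shell centres.
#' @param shell_radius first-shell radius, nm (must be < min(box)/2).
#' @param shell_occupants occupants placed on each centre's shell.
#' @export
shell_fluid_spec <- function(n_particles, box, n_frames,
                             shell_center_count = 0L, shell_radius = 0.3,
                             shell_occupants = 0L, seed = 1L) {
  stopifnot_scalar_pos(n_particles, "n_particles"); stopifnot_scalar_pos(n_frames, "n_frames")
  if (length(box) != 3L || any(box <= 0)) stop("'box' must be 3 positive edges", call. = FALSE)
  if (shell_radius >= min(box) / 2)
    stop("'shell_radius' must be < min(box)/2", call. = FALSE)
  if (shell_occupants < 0) stop("'shell_occupants' must be >= 0", call. = FALSE)
  structure(list(n_particles = as.integer(n_particles), box = as.numeric(box),
                 n_frames = as.integer(n_frames),
                 shell_center_count = as.integer(shell_center_count),
                 shell_radius = shell_radius,
                 shell_occupants = as.integer(shell_occupants),
                 seed = as.integer(seed)),
            class = "shell_fluid_spec")
}

#' @rdname synthetic_specs
#' @param pmf an analytic potential from [pmf_zero()], [pmf_harmonic()],
#'   [pmf_double_well()] or [pmf_screened_coulomb()] (kJ/mol vs nm).
#' @param k_spring restraint spring constant, kJ mol^-1 nm^-2.
#' @param pull_speed restraint-minimum speed, nm ps^-1 (>= 0).
#' @param x_start initial coordinate and restraint minimum, nm.
#' @param friction friction coefficient zeta of the overdamped equation
#'   `dx = (F/zeta) dt + sqrt(2 kB T dt / zeta) dW`, kJ mol^-1 nm^-2 ps.
#' @param temperature K.
#' @export
umbrella_pull_spec <- function(pmf, k_spring, pull_speed, x_start,
                               friction, temperature, dt, n_steps, seed = 1L) {
  if (!inherits(pmf, "pmf_spec")) stop("'pmf' must be a pmf_spec", call. = FALSE)
  stopifnot_scalar_pos(k_spring, "k_spring"); stopifnot_scalar_pos(friction, "friction")
  stopifnot_scalar_pos(dt, "dt"); stopifnot_scalar_pos(n_steps, "n_steps")
  if (pull_speed < 0) stop("'pull_speed' must be >= 0", call. = FALSE)
  if (temperature < 0) stop("'temperature' must be >= 0", call. = FALSE)
  structure(list(pmf = pmf, k_spring = k_spring, pull_speed = pull_speed,
                 x_start = x_start, friction = friction,
                 temperature = temperature, dt = dt,
                 n_steps = as.integer(n_steps), seed = as.integer(seed)),
            class = "umbrella_pull_spec")
}

#' Analytic potentials for the pulling simulator
#'
#' Small library of named one-dimensional potentials of mean force (kJ/mol
#' as a function of the coordinate x in nm) with analytic gradients, used
#' both to drive [gen_umbrella_pull()] and as ground truth when validating
#' the binned mean-force estimator.
#'
#' * `pmf_zero()`: V = 0.
#' * `pmf_harmonic(a, center)`: V = a/2 (x - center)^2.
#' * `pmf_double_well(height, center, half_width)`:
#'   V = height * (((x - center)/half_width)^2 - 1)^2, minima at
#'   center +/- half_width, barrier `height` at `center`.
#' * `pmf_screened_coulomb(eps_r, z_a, z_b)`: V = f_C z_a z_b / (eps_r x).
#'
#' @param a curvature, kJ mol^-1 nm^-2.
#' @param center,half_width nm.
#' @param height kJ/mol.
#' @param eps_r relative dielectric constant (>= 1).
#' @param z_a,z_b charges in elementary units.
#' @return a `pmf_spec` object.
#' @name pmf_specs
NULL

#' @rdname pmf_specs
#' @export
pmf_zero <- function() structure(list(type = "zero", params = numeric()),
                                 class = "pmf_spec")

#' @rdname pmf_specs
#' @export
pmf_harmonic <- function(a, center)
  structure(list(type = "harmonic", params = c(a = a, center = center)),
            class = "pmf_spec")

#' @rdname pmf_specs
#' @export
pmf_double_well <- function(height, center, half_width)
  structure(list(type = "double_well",
                 params = c(height = height, center = center,
                            half_width = half_width)),
            class = "pmf_spec")

#' @rdname pmf_specs
#' @export
pmf_screened_coulomb <- function(eps_r, z_a = 1, z_b = -1) {
  if (eps_r < 1) stop("'eps_r' must be >= 1", call. = FALSE)
  structure(list(type = "coulomb",
                 params = c(q = .const$coulomb * z_a * z_b / eps_r)),
            class = "pmf_spec")
}

#' @rdname pmf_specs
#' @param pmf a `pmf_spec`.
#' @param x coordinate(s), nm.
#' @export
pmf_value <- function(pmf, x) {
  p <- pmf$params
  switch(pmf$type,
         zero = rep(0, length(x)),
         harmonic = 0.5 * p[["a"]] * (x - p[["center"]])^2,
         double_well = {
           u <- (x - p[["center"]]) / p[["half_width"]]
           p[["height"]] * (u^2 - 1)^2
         },
         coulomb = p[["q"]] / x,
         stop("unknown pmf type"))
}

#' @rdname pmf_specs
#' @export
pmf_gradient <- function(pmf, x) {
  p <- pmf$params
  switch(pmf$type,
         zero = rep(0, length(x)),
         harmonic = p[["a"]] * (x - p[["center"]]),
         double_well = {
           u <- (x - p[["center"]]) / p[["half_width"]]
           4 * p[["height"]] * u * (u^2 - 1) / p[["half_width"]]
         },
         coulomb = -p[["q"]] / x^2,
         stop("unknown pmf type"))
}

.pmf_type_code <- c(zero = 0L, harmonic = 1L, double_well = 2L, coulomb = 3L)

#' Generate a rotor ensemble under isotropic rotational diffusion
#'
#' Each unit vector performs rotational Brownian motion: per step it is
#' rotated about two axes orthogonal to its current direction by Gaussian
#' angles of variance `2 * d_rot * dt` each, which reproduces the
#' closed-form rank-1 autocorrelation `C1(t) = exp(-2 d_rot t)` in the
#' small-step limit (the step-size precondition `d_rot * dt <= 0.05`
#' enforces that regime). The first `round(slow_fraction * n_rotors)`
#' rotors use `d_rot_slow` instead, emulating the ion-slowed subset of
#' water molecules.
#'
#' @param spec a [rotor_ensemble_spec()].
#' @return a [vector_series()].
#' @export
gen_rotor_ensemble <- function(spec) {
  stopifnot(inherits(spec, "rotor_ensemble_spec"))
  if (max(spec$d_rot, spec$d_rot_slow) * spec$dt > 0.05)
    stop("d_rot * dt > 0.05: time step too coarse for the diffusion limit",
         call. = FALSE)
  n <- spec$n_rotors; ns <- spec$n_steps
  n_slow <- round(spec$slow_fraction * n)
  sd_ang <- sqrt(2 * spec$dt * c(rep(spec$d_rot_slow, n_slow),
                                 rep(spec$d_rot, n - n_slow)))
  with_seed(spec$seed, {
    # isotropic initial directions
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    arr <- array(NA_real_, dim = c(ns, 3L, n))
    arr[1L, , ] <- t(u)
    if (ns > 1L) for (s in 2:ns) {
      # orthonormal frame (e1, e2) perpendicular to u
      pick_z <- abs(u[, 3]) < 0.9
      a <- cbind(ifelse(pick_z, 0, 1), 0, ifelse(pick_z, 1, 0))
      e1 <- cbind(u[, 2] * a[, 3] - u[, 3] * a[, 2],
                  u[, 3] * a[, 1] - u[, 1] * a[, 3],
                  u[, 1] * a[, 2] - u[, 2] * a[, 1])
      e1 <- e1 / sqrt(rowSums(e1^2))
      e2 <- cbind(u[, 2] * e1[, 3] - u[, 3] * e1[, 2],
                  u[, 3] * e1[, 1] - u[, 1] * e1[, 3],
                  u[, 1] * e1[, 2] - u[, 2] * e1[, 1])
      u <- rotate_about(u, e1, stats::rnorm(n, sd = sd_ang))
      u <- rotate_about(u, e2, stats::rnorm(n, sd = sd_ang))
      # renormalize: keeps floating-point drift from feeding back through
      # the axis construction over long runs
      u <- u / sqrt(rowSums(u^2))
      arr[s, , ] <- t(u)
    }
    vs <- vector_series(arr, spec$dt, check = FALSE)
    vs$slow_index <- seq_len(n_slow)
    vs
  })
}

# Rodrigues rotation of row vectors v about unit axes k by angles theta.
rotate_about <- function(v, k, theta) {
  ct <- cos(theta); st <- sin(theta)
  kxv <- cbind(k[, 2] * v[, 3] - k[, 3] * v[, 2],
               k[, 3] * v[, 1] - k[, 1] * v[, 3],
               k[, 1] * v[, 2] - k[, 2] * v[, 1])
  kdv <- rowSums(k * v)
  v * ct + kxv * st + k * (kdv * (1 - ct))
}

#' Generate two-state Markov bond indicator series
#'
#' Simulates `n_pairs` independent bonded/unbonded processes with per-step
#' transition probabilities `1 - exp(-k dt)`, started from the stationary
#' distribution `p_eq = k_on / (k_on + k_off)` (so no burn-in is needed and
#' intermittent ACFs are stationary from lag zero). Sojourn lengths in each
#' state are geometric, which is exactly the law of the per-step chain, so
#' the series is generated run-length-wise.
#'
#' @param spec a [two_state_kinetics_spec()].
#' @return an [indicator_series()].
#' @export
gen_two_state_bonds <- function(spec) {
  stopifnot(inherits(spec, "two_state_kinetics_spec"))
  np <- spec$n_pairs; ns <- spec$n_steps
  p_on <- 1 - exp(-spec$k_on * spec$dt)   # unbonded -> bonded
  p_off <- 1 - exp(-spec$k_off * spec$dt) # bonded -> unbonded
  p_eq <- spec$k_on / (spec$k_on + spec$k_off)
  exp_runs <- max(16L, ceiling(2 * ns / (1 / p_on + 1 / p_off)) + 8L)
  one_pair <- function(state0) {
    lens <- integer(0); states <- integer(0); covered <- 0; k <- 0L
    while (covered < ns) {
      m <- 2L * exp_runs
      st <- (state0 + k + seq_len(m) - 1L) %% 2L
      ln <- stats::rgeom(m, ifelse(st == 1L, p_off, p_on)) + 1
      ln <- pmin(ln, ns)   # sojourns beyond the horizon need not be resolved
      lens <- c(lens, ln); states <- c(states, st)
      covered <- covered + sum(ln); k <- k + m
    }
    rep.int(states, lens)[seq_len(ns)]
  }
  ind <- with_seed(spec$seed, {
    s0 <- stats::rbinom(np, 1L, p_eq)
    # build (steps x pairs), one contiguous column per pair, transpose once
    t(vapply(seq_len(np), function(p) one_pair(s0[p]), integer(ns)))
  })
  indicator_series(ind, spec$dt,
                   pair_ids = cbind(a = seq_len(np), b = seq_len(np)))
}

#' Embed a bond indicator series as a geometric trajectory
#'
#' Places each pair as a centre atom (label `CEN`) on a sparse grid and a
#' partner atom (label `PRT`) at distance `0.8 * cutoff` when bonded and
#' `1.5 * cutoff` when unbonded, so [pair_indicator()] with the same cutoff
#' recovers the input indicator exactly on the matched (i, i) pairs while
#' all cross pairs stay beyond the cutoff. This lets the full geometric
#' pipeline be exercised against known kinetics.
#'
#' @param indicator an [indicator_series()].
#' @param cutoff distance criterion, nm (`< min(box)/2`).
#' @param box orthorhombic edge lengths, nm.
#' @return a [trajectory()].
#' @export
embed_bonds_as_trajectory <- function(indicator, cutoff, box) {
  stopifnot(inherits(indicator, "indicator_series"))
  if (cutoff >= min(box) / 2) stop("'cutoff' must be < min(box)/2", call. = FALSE)
  np <- nrow(indicator$indicator); nf <- ncol(indicator$indicator)
  m <- pmax(1L, floor(box / (3 * cutoff)))
  if (np > prod(m))
    stop(sprintf("cannot place %d pairs at spacing 3*cutoff in this box (capacity %d)",
                 np, prod(m)), call. = FALSE)
  cell <- box / m
  p <- seq_len(np) - 1L
  centres <- cbind((p %% m[1] + 0.25) * cell[1],
                   ((p %/% m[1]) %% m[2] + 0.25) * cell[2],
                   (p %/% (m[1] * m[2]) + 0.25) * cell[3])
  coords <- array(NA_real_, dim = c(2L * np, 3L, nf))
  odd <- seq(1L, 2L * np, by = 2L)
  dist <- ifelse(indicator$indicator == 1L, 0.8 * cutoff, 1.5 * cutoff)
  for (f in seq_len(nf)) {
    coords[odd, , f] <- centres
    coords[odd + 1L, , f] <- centres + cbind(dist[, f], 0, 0)
  }
  trajectory(coords, box, times = (seq_len(nf) - 1) * indicator$dt,
             labels = rep(c("CEN", "PRT"), np))
}

#' Generate an ideal-gas trajectory
#'
#' Independent uniform positions in the box each frame: the null model for
#' RDF normalization, for which g(r) is identically 1.
#'
#' @param spec a [shell_fluid_spec()] (shell fields ignored).
#' @return a [trajectory()] with labels `GAS`.
#' @export
gen_ideal_gas <- function(spec) {
  stopifnot(inherits(spec, "shell_fluid_spec"))
  n <- spec$n_particles; nf <- spec$n_frames
  with_seed(spec$seed, {
    coords <- array(stats::runif(n * 3L * nf), dim = c(n, 3L, nf))
    for (c in 1:3) coords[, c, ] <- coords[, c, ] * spec$box[c]
    trajectory(coords, spec$box, times = seq_len(nf) - 1,
               labels = rep("GAS", n))
  })
}

#' Generate a shell-structured fluid
#'
#' `shell_center_count` centres (label `CEN`) sit on a sparse grid; each
#' gets exactly `shell_occupants` partners (label `OCC`) redrawn each frame
#' isotropically at `shell_radius` plus a uniform +/- 0.005 nm radial
#' jitter; all remaining particles (label `BULK`) are uniform. A synthetic
#' stand-in for a tightly coordinated first solvation shell.
#'
#' @param spec a [shell_fluid_spec()].
#' @return a [trajectory()].
#' @export
gen_shell_config <- function(spec) {
  stopifnot(inherits(spec, "shell_fluid_spec"))
  cc <- spec$shell_center_count; so <- spec$shell_occupants
  n_shell <- cc * so
  n_bulk <- spec$n_particles - cc - n_shell
  if (n_bulk < 0)
    stop("shell placement exceeds the particle budget", call. = FALSE)
  m <- pmax(1L, floor(spec$box / (4 * spec$shell_radius)))
  if (cc > prod(m))
    stop("too many shell centres for non-overlapping shells in this box", call. = FALSE)
  cell <- spec$box / m
  p <- seq_len(cc) - 1L
  centres <- cbind((p %% m[1] + 0.5) * cell[1],
                   ((p %/% m[1]) %% m[2] + 0.5) * cell[2],
                   (p %/% (m[1] * m[2]) + 0.5) * cell[3])
  nf <- spec$n_frames
  coords <- array(NA_real_, dim = c(spec$n_particles, 3L, nf))
  with_seed(spec$seed, {
    for (f in seq_len(nf)) {
      coords[seq_len(cc), , f] <- centres
      if (n_shell > 0) {
        dir <- matrix(stats::rnorm(3 * n_shell), n_shell, 3)
        dir <- dir / sqrt(rowSums(dir^2))
        r <- spec$shell_radius + stats::runif(n_shell, -0.005, 0.005)
        coords[cc + seq_len(n_shell), , f] <-
          centres[rep(seq_len(cc), each = so), , drop = FALSE] + dir * r
      }
      if (n_bulk > 0)
        coords[cc + n_shell + seq_len(n_bulk), , f] <-
          matrix(stats::runif(3 * n_bulk), n_bulk, 3) %*% diag(spec$box)
    }
  })
  trajectory(coords, spec$box, times = seq_len(nf) - 1,
             labels = c(rep("CEN", cc), rep("OCC", n_shell), rep("BULK", n_bulk)))
}

#' Simulate an umbrella-pulling record
#'
#' Overdamped (Euler--Maruyama) Langevin dynamics of a single coordinate x
#' in `pmf(x) + k_spring/2 (x - x0(t))^2` with the restraint minimum moving
#' as `x0(t) = x_start + pull_speed * t`. Emits a [time_series()] with
#' columns `x` (nm) and `f_restraint = k_spring * (x0(t) - x)`
#' (kJ mol^-1 nm^-1; positive when the restraint pulls the coordinate
#' forward). The Gaussian increments come from the R RNG, so the spec seed
#' fixes the full record.
#'
#' @param spec an [umbrella_pull_spec()].
#' @return a [time_series()]; the spec is attached as attribute `"spec"`.
#' @export
gen_umbrella_pull <- function(spec) {
  stopifnot(inherits(spec, "umbrella_pull_spec"))
  if (spec$k_spring * spec$dt / spec$friction > 0.1)
    stop("k_spring * dt / friction > 0.1: step too large for this spring",
         call. = FALSE)
  kT <- .const$kB * spec$temperature
  res <- with_seed(spec$seed, {
    noise <- stats::rnorm(spec$n_steps)
    cpp_langevin_pull(.pmf_type_code[[spec$pmf$type]],
                      as.numeric(spec$pmf$params), spec$k_spring,
                      spec$pull_speed, spec$x_start, spec$friction,
                      kT, spec$dt, spec$n_steps, noise)
  })
  ts <- time_series(res$times, cbind(x = res$x, f_restraint = res$force))
  attr(ts, "spec") <- spec
  ts
}
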