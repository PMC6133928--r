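#' Per-molecule unit-vector series
#'
#' Substrate of the reorientation analysis: one unit 3-vector per molecule
#' per frame (water dipole vectors, OH bond vectors, ...), stored as an
#' `(n_steps, 3, n_molecules)` array with uniform frame spacing `dt` (ps).
#'
#' @param vectors `(n_steps, 3, n_molecules)` array.
#' @param dt frame spacing, ps.
#' @param check verify unit norms (within 1e-6); disable for large arrays
#'   whose construction guarantees normalization.
#' @return object of class `vector_series`.
#' @export
vector_series <- function(vectors, dt, check = TRUE) {
  if (!is.array(vectors) || length(dim(vectors)) != 3L || dim(vectors)[2] != 3L)
    stop("'vectors' must be an (n_steps, 3, n_molecules) array", call. = FALSE)
  stopifnot_scalar_pos(dt, "dt")
  if (check) {
    nrm2 <- vectors[, 1, , drop = FALSE]^2 + vectors[, 2, , drop = FALSE]^2 +
      vectors[, 3, , drop = FALSE]^2
    if (any(abs(nrm2 - 1) > 2.1e-6))
      stop("vectors must have unit norm (within 1e-6)", call. = FALSE)
  }
  structure(list(vectors = vectors, dt = dt), class = "vector_series")
}

#' Extract molecular vectors from a trajectory
#'
#' Builds the unit-vector series pointing from the `from` site of each
#' molecule to its `to` site. `to` may be a list of several site groups, in
#' which case the endpoint is their unweighted midpoint (e.g. a 'dipole'
#' axis from the water oxygen to the midpoint of the two hydrogens; the
#' endpoint sites are caller-defined precisely because different water
#' models place their charge sites differently). Displacements are taken
#' under the minimum-image convention before normalization, so molecules
#' straddling the periodic boundary are handled correctly.
#'
#' @param traj a [trajectory()].
#' @param endpoints `list(from = , to = )` of site specs ([select_sites()]
#'   patterns, index vectors or `site_group`s); `to` may be a list of
#'   specs. All groups must resolve to the same molecule count.
#' @return a [vector_series()].
#' @export
extract_vectors <- function(traj, endpoints) {
  idx_a <- resolve_group(traj, endpoints$from, "from")
  to <- endpoints$to
  if (!is.list(to) || inherits(to, "site_group")) to <- list(to)
  idx_b <- lapply(seq_along(to), function(k)
    resolve_group(traj, to[[k]], paste0("to", k)))
  nm <- length(idx_a)
  if (any(vapply(idx_b, length, 1L) != nm))
    stop("endpoint groups resolve to different molecule counts", call. = FALSE)
  nf <- n_frames(traj)
  arr <- array(NA_real_, dim = c(nf, 3L, nm))
  for (f in seq_len(nf)) {
    box <- traj$box[f, ]
    pa <- traj$coords[idx_a, , f, drop = FALSE]
    dim(pa) <- c(nm, 3L)
    d <- matrix(0, nm, 3L)
    for (g in idx_b) {
      pb <- traj$coords[g, , f, drop = FALSE]
      dim(pb) <- c(nm, 3L)
      dg <- pb - pa
      dg <- dg - rep(box, each = nm) * round(dg / rep(box, each = nm))
      d <- d + dg
    }
    d <- d / length(idx_b)
    d <- d / sqrt(rowSums(d^2))
    arr[f, , ] <- t(d)
  }
  vector_series(arr, if (is.na(traj$dt)) 1 else traj$dt, check = FALSE)
}

#' Vector autocorrelation function
#'
#' Rank-1 reorientation correlation `C(t) = <u(t0) . u(t0 + t)>`, averaged
#' over all molecules and all valid time origins (every frame is an
#' origin), normalized so `C(0) = 1`. The default implementation goes
#' through zero-padded FFTs; `method = "direct"` runs the literal double
#' loop over lags and origins, kept as an independent cross-check (the two
#' agree to ~1e-12).
#'
#' @param series a [vector_series()].
#' @param max_lag largest lag, ps; defaults to half the series length.
#' @param method `"fft"` or `"direct"`.
#' @return an [acf_result()].
#' @export
vector_acf <- function(series, max_lag = NULL, method = c("fft", "direct")) {
  stopifnot(inherits(series, "vector_series"))
  method <- match.arg(method)
  d <- dim(series$vectors)
  n <- d[1]; nm <- d[3]
  if (n < 2L || nm < 1L) stop("empty vector series", call. = FALSE)
  dt <- series$dt
  if (is.null(max_lag)) max_lag <- floor((n - 1L) / 2) * dt
  ml <- round(max_lag / dt)
  if (ml > n - 1L) stop("max_lag exceeds series length", call. = FALSE)
  flat <- series$vectors
  dim(flat) <- c(n, 3L * nm)   # columns are (component, molecule) series
  get_cols <- function(j) flat[, j, drop = FALSE]
  s <- if (method == "fft")
    acf_sums_fft(get_cols, n, 3L * nm, ml, chunk = max(1L, 4096L %/% max(1L, n %/% 512L)))
  else acf_sums_direct(get_cols, n, 3L * nm, ml)
  n_origins <- (n - (0:ml)) * nm
  vals <- s / n_origins
  vals <- vals / vals[1]
  acf_result((0:ml) * dt, vals, n_origins)
}

#' Exponential-fit result
#'
#' Least-squares fit of `sum_i a_i exp(-t / tau_i)` to an ACF window.
#' Components are reported with time constants ascending. Printed time
#' constants are in ps.
#'
#' @name exp_fit_result
#' @export
print.exp_fit_result <- function(x, ...) {
  cat(sprintf("exp fit (%d component%s) over [%g, %g] ps:\n",
              length(x$time_constants), if (length(x$time_constants) > 1) "s" else "",
              x$fit_window[1], x$fit_window[2]))
  for (i in seq_along(x$time_constants))
    cat(sprintf("  a = %.4f, tau = %.4g ps\n", x$amplitudes[i], x$time_constants[i]))
  cat(sprintf("  rss = %.4g\n", x$rss))
  invisible(x)
}

#' Fit exponential decays to an autocorrelation function
#'
#' Unweighted least squares of `sum_i a_i exp(-t / tau_i)` on C(t) (not on
#' log C, to avoid over-weighting the noisy tail) over `fit_window`.
#' Initialization is deterministic: a log-linear fit of the window tail
#' seeds the slow component and, for bi-exponential fits, a log-linear fit
#' of the early-time residual seeds the fast one. Refinement uses
#' Levenberg--Marquardt ([minpack.lm::nlsLM]).
#'
#' @param acf an [acf_result()].
#' @param n_components 1 or 2.
#' @param fit_window `c(t_min, t_max)` ps; defaults to the full lag range.
#'   Must contain at least 10 points.
#' @return object of class `exp_fit_result` with `amplitudes`,
#'   `time_constants` (ps, ascending), `fit_window`, `rss`.
#' @export
fit_exponentials <- function(acf, n_components = 1, fit_window = NULL) {
  stopifnot(inherits(acf, "acf_result"))
  if (!n_components %in% c(1, 2)) stop("'n_components' must be 1 or 2", call. = FALSE)
  if (is.null(fit_window)) fit_window <- range(acf$lags)
  sel <- acf$lags >= fit_window[1] & acf$lags <= fit_window[2]
  if (sum(sel) < 10L) stop("fit window contains fewer than 10 points", call. = FALSE)
  t <- acf$lags[sel]; y <- acf$values[sel]

  loglin <- function(t, y) {
    ok <- y > 0
    if (sum(ok) < 3L) return(NULL)
    co <- stats::coef(stats::lm(log(y[ok]) ~ t[ok]))
    if (!is.finite(co[2]) || co[2] >= 0) return(NULL)
    c(a = unname(exp(co[1])), tau = unname(-1 / co[2]))
  }

  if (n_components == 1) {
    init <- loglin(t, y) %||% c(a = max(y[1], 0.5), tau = max(diff(fit_window) / 3, t[2]))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-t / tau), start = as.list(init),
                        lower = c(a = 0, tau = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e)
        stop(sprintf("mono-exponential fit failed (init a = %.3g, tau = %.3g): %s",
                     init[["a"]], init[["tau"]], conditionMessage(e)), call. = FALSE))
    cf <- stats::coef(fit)
    amps <- cf[["a"]]; taus <- cf[["tau"]]
  } else {
    tail_sel <- t >= fit_window[1] + 0.6 * diff(fit_window)
    slow <- loglin(t[tail_sel], y[tail_sel]) %||% c(a = 0.5, tau = diff(fit_window))
    early_sel <- t <= fit_window[1] + 0.2 * diff(fit_window)
    resid <- y[early_sel] - slow[["a"]] * exp(-t[early_sel] / slow[["tau"]])
    fast <- loglin(t[early_sel], resid) %||%
      c(a = max(1 - slow[["a"]], 0.1), tau = max(slow[["tau"]] / 10, t[2]))
    init <- list(a1 = fast[["a"]], tau1 = fast[["tau"]],
                 a2 = slow[["a"]], tau2 = slow[["tau"]])
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a1 * exp(-t / tau1) + a2 * exp(-t / tau2),
                        start = init,
                        lower = c(a1 = 0, tau1 = 1e-12, a2 = 0, tau2 = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e)
        stop(sprintf("bi-exponential fit failed (init tau1 = %.3g, tau2 = %.3g): %s",
                     init$tau1, init$tau2, conditionMessage(e)), call. = FALSE))
    cf <- stats::coef(fit)
    ord <- order(c(cf[["tau1"]], cf[["tau2"]]))
    amps <- c(cf[["a1"]], cf[["a2"]])[ord]
    taus <- c(cf[["tau1"]], cf[["tau2"]])[ord]
  }
  structure(list(amplitudes = amps, time_constants = taus,
                 fit_window = fit_window,
                 rss = sum(stats::resid(fit)^2)),
            class = "exp_fit_result")
}

#' Slow-to-reference time-constant ratio
#'
#' Ratio of the designated slow time constant of a (possibly
#' bi-exponential) fit to the single time constant of a mono-exponential
#' reference fit — the slowdown factor of water reorientation in salt
#' solution relative to pure water.
#'
#' @param fit_salt an [fit_exponentials()] result (slowest component used).
#' @param fit_pure a mono-exponential reference fit.
#' @return dimensionless ratio.
#' @export
time_constant_ratio <- function(fit_salt, fit_pure) {
  stopifnot(inherits(fit_salt, "exp_fit_result"), inherits(fit_pure, "exp_fit_result"))
  if (length(fit_pure$time_constants) != 1L)
    stop("reference fit must be mono-exponential", call. = FALSE)
  max(fit_salt$time_constants) / fit_pure$time_constants
}
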