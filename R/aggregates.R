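#' Bond indicator series
#'
#' Boolean bond matrix b_pair(t): one row per site pair, one column per
#' frame, 1 while the pair satisfies the distance criterion. The substrate
#' of the intermittent-lifetime analysis.
#'
#' @param indicator integer/logical matrix (pairs x frames).
#' @param dt frame spacing, ps.
#' @param pair_ids two-column matrix of (a, b) atom indices per row;
#'   rows must be unique.
#' @return object of class `indicator_series`.
#' @export
indicator_series <- function(indicator, dt, pair_ids = NULL) {
  if (!is.matrix(indicator)) indicator <- as.matrix(indicator)
  if (!is.integer(indicator)) storage.mode(indicator) <- "integer"
  rng <- range(indicator)
  if (rng[1] < 0L || rng[2] > 1L)
    stop("indicator entries must be 0/1", call. = FALSE)
  stopifnot_scalar_pos(dt, "dt")
  if (is.null(pair_ids))
    pair_ids <- cbind(a = seq_len(nrow(indicator)), b = seq_len(nrow(indicator)))
  if (nrow(pair_ids) != nrow(indicator))
    stop("'pair_ids' must have one row per pair", call. = FALSE)
  if (anyDuplicated(pair_ids)) stop("'pair_ids' rows must be unique", call. = FALSE)
  structure(list(indicator = indicator, dt = dt, pair_ids = pair_ids),
            class = "indicator_series")
}

#' Distance criterion defining an aggregate
#'
#' A pair of site roles plus a cutoff: two sites are aggregated (bonded)
#' while their minimum-image distance is `<= cutoff`. Cutoffs follow the
#' first minimum of the corresponding RDF; they are stored in nm (a 300 pm
#' criterion is 0.30 nm).
#'
#' @param group_a,group_b site specs (role pattern, index vector or
#'   `site_group`).
#' @param cutoff nm, > 0.
#' @param name optional label for reports.
#' @return object of class `pair_criterion`.
#' @export
pair_criterion <- function(group_a, group_b, cutoff, name = NULL) {
  stopifnot_scalar_pos(cutoff, "cutoff")
  structure(list(group_a = group_a, group_b = group_b, cutoff = cutoff,
                 name = name %||% "pair"),
            class = "pair_criterion")
}

#' Evaluate a distance criterion over a trajectory
#'
#' Enumerates the full bipartite product of the two site groups (every
#' possible bonding aggregate, no nearest-partner exclusivity) and marks
#' pair p bonded at frame t iff its minimum-image distance is `<= cutoff`
#' (boundary counts as bonded). Pairs are ordered group-a-major.
#'
#' @param traj a [trajectory()].
#' @param criterion a [pair_criterion()].
#' @return an [indicator_series()].
#' @export
pair_indicator <- function(traj, criterion) {
  stopifnot(inherits(criterion, "pair_criterion"))
  ia <- resolve_group(traj, criterion$group_a, "group_a")
  ib <- resolve_group(traj, criterion$group_b, "group_b")
  if (length(ia) == 0L || length(ib) == 0L) stop("empty site group", call. = FALSE)
  if (length(intersect(ia, ib)))
    stop("site groups share atoms; criterion groups must be disjoint", call. = FALSE)
  if (criterion$cutoff >= min(traj$box) / 2)
    stop("cutoff must be < half the smallest box edge", call. = FALSE)
  ind <- cpp_pair_indicator(traj$coords, ia, ib, traj$box, criterion$cutoff)
  pair_ids <- cbind(a = rep(ia, each = length(ib)), b = rep(ib, length(ia)))
  indicator_series(ind, if (is.na(traj$dt)) 1 else traj$dt, pair_ids)
}

#' Intermittent aggregate autocorrelation function
#'
#' Rapaport-style intermittent ACF of the bond indicator,
#' `C_raw(t) = <b(t0) b(t0+t)> / <b>`, pooled over all pairs and all time
#' origins; bonds may break and re-form between the correlated times.
#' `C_raw(0) = 1` by construction. In a finite system C_raw decays to the
#' ensemble average (the probability of re-observing the bond at random),
#' not to zero — see [ensemble_average_correction()].
#'
#' The per-lag `stderr` is the naive binomial standard error of the pooled
#' product mean divided by `<b>`; it ignores origin-origin correlation but
#' scales correctly with the rarity of the bond.
#'
#' @param indicator an [indicator_series()].
#' @param max_lag ps; defaults to half the series length.
#' @return an [acf_result()].
#' @export
intermittent_acf <- function(indicator, max_lag = NULL) {
  stopifnot(inherits(indicator, "indicator_series"))
  b <- indicator$indicator
  np <- nrow(b); n <- ncol(b); dt <- indicator$dt
  mean_b <- mean(b)
  if (mean_b == 0) stop("no aggregates observed (indicator is all zero)", call. = FALSE)
  if (is.null(max_lag)) max_lag <- floor((n - 1L) / 2) * dt
  ml <- round(max_lag / dt)
  if (ml > n - 1L) stop("max_lag exceeds series length", call. = FALSE)
  get_cols <- function(j) t(b[j, , drop = FALSE])  # pairs become columns
  s <- acf_sums_fft(get_cols, n, np, ml)
  n_origins <- (n - (0:ml)) * np
  m <- s / n_origins                  # <b(t0) b(t0+t)>
  vals <- m / mean_b
  se <- sqrt(pmax(m * (1 - m), 0) / n_origins) / mean_b
  acf_result((0:ml) * dt, vals, n_origins, stderr = se)
}

#' Pooled ensemble average of a bond indicator
#'
#' The average probability of observing the bond in one specific pair,
#' estimated as the pooled occupancy over all pairs and frames (pairs are
#' exchangeable; pooling is stabler for rare bonds than averaging per-pair
#' means).
#'
#' @param indicator an [indicator_series()].
#' @return dimensionless occupancy in `[0, 1]`.
#' @export
estimate_ensemble_average <- function(indicator) {
  stopifnot(inherits(indicator, "indicator_series"))
  if (length(indicator$indicator) == 0L) stop("empty indicator", call. = FALSE)
  mean(indicator$indicator)
}

#' Ensemble-average correction of an intermittent ACF
#'
#' Removes the finite-size plateau: `C_corr(t) = (C_raw(t) - p) / (1 - p)`
#' with p the ensemble average, an affine map fixing `C_corr(0) = 1` and
#' the long-lag limit at 0. The renormalisation by `(1 - p)` (rather than
#' bare subtraction) is what makes the integral of C_corr equal the
#' exponential time constant for a mono-exponential decay.
#'
#' @param acf_raw an [acf_result()] from [intermittent_acf()].
#' @param ensemble_average p in `[0, 1)`.
#' @return an [acf_result()].
#' @export
ensemble_average_correction <- function(acf_raw, ensemble_average) {
  stopifnot(inherits(acf_raw, "acf_result"))
  p <- ensemble_average
  if (p < 0 || p >= 1)
    stop("ensemble average must lie in [0, 1); p = 1 is a degenerate always-bonded system",
         call. = FALSE)
  acf_result(acf_raw$lags, (acf_raw$values - p) / (1 - p), acf_raw$n_origins,
             stderr = if (!is.null(acf_raw$stderr)) acf_raw$stderr / (1 - p))
}

#' Integrate a corrected ACF to an aggregate lifetime
#'
#' Trapezoidal integral of the corrected intermittent ACF over its lag
#' window, extended beyond the window by the analytic tail of a
#' mono-exponential fitted (log-linearly) to the final quarter of the
#' window. Both contributions are reported separately: lifetimes far above
#' the feasible lag window are dominated by the extrapolated tail, and the
#' split makes that visible.
#'
#' @param acf_corrected an [acf_result()] with `C(0) = 1`.
#' @param tail_extension fit and add the exponential tail (default TRUE).
#' @return object of class `lifetime_estimate`: list with `lifetime` (ps),
#'   `windowed`, `tail`, and the tail fit parameters (`a`, `tau`) or NULL.
#' @export
lifetime_integral <- function(acf_corrected, tail_extension = TRUE) {
  stopifnot(inherits(acf_corrected, "acf_result"))
  t <- acf_corrected$lags; y <- acf_corrected$values
  if (abs(y[1] - 1) > 1e-6)
    stop("corrected ACF must start at C(0) = 1", call. = FALSE)
  windowed <- sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
  tail_part <- 0; tail_fit <- NULL
  if (tail_extension && length(t) >= 8L) {
    sel <- t >= t[1] + 0.75 * (t[length(t)] - t[1])
    tt <- t[sel]; yy <- y[sel]
    ok <- yy > 0
    if (sum(ok) >= 5L) {
      co <- stats::coef(stats::lm(log(yy[ok]) ~ tt[ok]))
      if (is.finite(co[2]) && co[2] < 0) {
        tau <- unname(-1 / co[2]); a <- unname(exp(co[1]))
        tail_part <- a * tau * exp(-t[length(t)] / tau)
        tail_fit <- c(a = a, tau = tau)
      }
    }
  }
  lifetime <- windowed + tail_part
  if (lifetime < 0)
    warning("negative lifetime integral (anti-correlated input); value reported as-is")
  structure(list(lifetime = lifetime, windowed = windowed, tail = tail_part,
                 tail_fit = tail_fit),
            class = "lifetime_estimate")
}

#' @export
print.lifetime_estimate <- function(x, ...) {
  cat(sprintf("lifetime = %.4g ps (windowed %.4g + tail %.4g)\n",
              x$lifetime, x$windowed, x$tail))
  invisible(x)
}

#' Full intermittent-lifetime pipeline for one criterion
#'
#' Convenience wrapper chaining [intermittent_acf()],
#' [estimate_ensemble_average()], [ensemble_average_correction()] and
#' [lifetime_integral()].
#'
#' @param indicator an [indicator_series()].
#' @param max_lag ps; passed to [intermittent_acf()].
#' @return object of class `lifetime_result`: list with `acf_raw`,
#'   `ensemble_average`, `acf_corrected`, `lifetime` (ps) and `estimate`
#'   (the [lifetime_integral()] split).
#' @export
aggregate_lifetime <- function(indicator, max_lag = NULL) {
  acf_raw <- intermittent_acf(indicator, max_lag)
  p <- estimate_ensemble_average(indicator)
  acf_corr <- ensemble_average_correction(acf_raw, p)
  est <- lifetime_integral(acf_corr)
  structure(list(acf_raw = acf_raw, ensemble_average = p,
                 acf_corrected = acf_corr, lifetime = est$lifetime,
                 estimate = est),
            class = "lifetime_result")
}

#' @export
print.lifetime_result <- function(x, ...) {
  cat(sprintf("aggregate lifetime: %.4g ps (ensemble average %.4g)\n",
              x$lifetime, x$ensemble_average))
  invisible(x)
}
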