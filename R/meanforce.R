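#' Pull record along a dissociation coordinate
#'
#' Samples of the reaction coordinate (nm) and of the mean-force-convention
#' projected force (kJ mol^-1 nm^-1) during a forced dissociation. The sign
#' convention throughout the mean-force analysis is positive = repulsive
#' (the pair is pushed apart along increasing x).
#'
#' A pulling simulator or MD pull module records the restraint (spring)
#' force, which is positive while the restraint drags the coordinate
#' forward; quasi-statically its mean equals +dV/dx, i.e. minus the mean
#' force. [as_pull_record()] therefore negates a restraint-force column by
#' default when building a record from a raw pull time series.
#'
#' @param times ps, strictly increasing.
#' @param x coordinate, nm, > 0.
#' @param force projected force samples, kJ mol^-1 nm^-1, positive =
#'   repulsive.
#' @return object of class `pull_record`.
#' @export
pull_record <- function(times, x, force) {
  if (length(times) != length(x) || length(x) != length(force))
    stop("times, x and force must have equal length", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(x <= 0)) stop("coordinate values must be > 0", call. = FALSE)
  structure(list(times = as.numeric(times), x = as.numeric(x),
                 force = as.numeric(force)),
            class = "pull_record")
}

#' @rdname pull_record
#' @param ts a [time_series()] (e.g. from [gen_umbrella_pull()] or
#'   [read_xvg_series()]).
#' @param x_col,force_col column names in `ts`.
#' @param restraint if TRUE (default) the force column holds the restraint
#'   force and is negated into the positive-repulsive convention.
#' @export
as_pull_record <- function(ts, x_col = "x", force_col = "f_restraint",
                           restraint = TRUE) {
  stopifnot(inherits(ts, "time_series"))
  if (!all(c(x_col, force_col) %in% colnames(ts$values)))
    stop("requested columns not present in the time series", call. = FALSE)
  f <- ts$values[, force_col]
  pull_record(ts$times, ts$values[, x_col], if (restraint) -f else f)
}

#' Bin a pull record into a mean-force profile
#'
#' Assigns samples to half-open coordinate bins of width `bin_width` and
#' reports the per-bin mean force, its naive standard error (treating
#' samples as independent; successive samples are correlated over the
#' relaxation time of the restraint, so the true uncertainty is larger by
#' the square root of that correlation length in samples) and the sample
#' count. Empty bins are dropped, never interpolated. Binning has no time
#' dependence, so the profile is invariant under time reversal of the
#' record.
#'
#' @param record a [pull_record()].
#' @param bin_width nm (default 0.005; dissociation profiles typically
#'   structure at the 0.05-nm scale).
#' @param x_range optional `c(lo, hi)` evaluation window, nm. Samples
#'   outside it are dropped: near the start and end of a finite sweep the
#'   coordinate is only visited by transient fluctuations, where the
#'   restraint-force mean does not estimate the mean force, so profiles
#'   are usually evaluated with a margin inside the swept range.
#' @return object of class `force_profile`: `bin_centers` (nm),
#'   `mean_force`, `stderr` (kJ mol^-1 nm^-1), `n_samples`.
#' @export
bin_mean_force <- function(record, bin_width = 0.005, x_range = NULL) {
  stopifnot(inherits(record, "pull_record"))
  stopifnot_scalar_pos(bin_width, "bin_width")
  if (!is.null(x_range)) {
    keep <- record$x >= x_range[1] & record$x < x_range[2]
    record <- pull_record(record$times[keep], record$x[keep], record$force[keep])
  }
  if (!length(record$x)) stop("empty pull record", call. = FALSE)
  bin <- floor(record$x / bin_width)
  tab <- sort(unique(bin))
  if (length(tab) == 1L)
    warning("all samples fall into one bin; pull too short or bins too wide")
  idx <- match(bin, tab)
  n <- tabulate(idx, nbins = length(tab))
  s <- vapply(split(record$force, idx), sum, numeric(1))
  m <- s / n
  ss <- vapply(split(record$force, idx), function(v) sum((v - mean(v))^2), numeric(1))
  se <- ifelse(n > 1, sqrt(ss / (n - 1)) / sqrt(n), 0)
  structure(list(bin_centers = (tab + 0.5) * bin_width, mean_force = unname(m),
                 stderr = unname(se), n_samples = n, bin_width = bin_width),
            class = "force_profile")
}

#' @export
print.force_profile <- function(x, ...) {
  cat(sprintf("force_profile: %d bins over [%.3g, %.3g] nm (positive = repulsive)\n",
              length(x$bin_centers), min(x$bin_centers), max(x$bin_centers)))
  invisible(x)
}

#' @export
plot.force_profile <- function(x, ...) {
  graphics::plot(x$bin_centers, x$mean_force, type = "l",
                 xlab = "x (nm)", ylab = "mean force (kJ/mol/nm)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Screened-Coulomb reference force
#'
#' Force between two point charges in a dielectric continuum,
#' `f_C z_a z_b / (eps_r r^2)` with the Coulomb constant
#' `f_C = 138.935458 kJ mol^-1 nm e^-2`. Positive (repulsive) for like
#' charges, negative (attractive) for unlike charges — the same
#' convention as [bin_mean_force()] profiles.
#'
#' @param r separation(s), nm, > 0.
#' @param eps_r relative dielectric constant, >= 1 (80 for bulk water).
#' @param z_a,z_b charges, elementary units.
#' @return force, kJ mol^-1 nm^-1.
#' @export
screened_coulomb_force <- function(r, eps_r = 80, z_a = 1, z_b = -1) {
  if (any(r <= 0)) stop("'r' must be > 0", call. = FALSE)
  if (eps_r < 1) stop("'eps_r' must be >= 1", call. = FALSE)
  .const$coulomb * z_a * z_b / (eps_r * r^2)
}

#' Zero crossings and attractive/repulsive windows of a force profile
#'
#' Collapses the profile into consecutive same-sign groups of bins whose
#' `|mean force|` exceeds `noise_floor`; each adjacent pair of
#' opposite-sign groups yields a zero crossing by linear interpolation
#' between the flanking bin centres. Windows alternate sign by
#' construction. A profile with no crossing above the noise floor returns
#' an empty crossing list (not an error).
#'
#' @param profile a [bin_mean_force()] profile.
#' @param noise_floor kJ mol^-1 nm^-1; defaults to the median per-bin
#'   standard error.
#' @return object of class `regime_report`: `zero_crossings` (nm, sorted)
#'   and `windows` (data.frame of `from`, `to`, `sign`).
#' @export
find_regimes <- function(profile, noise_floor = NULL) {
  stopifnot(inherits(profile, "force_profile"))
  if (length(profile$bin_centers) < 3L)
    stop("profile needs at least 3 occupied bins", call. = FALSE)
  if (is.null(noise_floor)) noise_floor <- stats::median(profile$stderr)
  keep <- abs(profile$mean_force) > noise_floor
  x <- profile$bin_centers[keep]; f <- profile$mean_force[keep]
  if (!length(x))
    return(structure(list(zero_crossings = numeric(0),
                          windows = data.frame(from = numeric(0), to = numeric(0),
                                               sign = character(0))),
                     class = "regime_report"))
  sgn <- sign(f)
  grp <- cumsum(c(1L, diff(sgn) != 0))
  g_from <- tapply(x, grp, min); g_to <- tapply(x, grp, max)
  g_sgn <- tapply(sgn, grp, `[`, 1L)
  crossings <- numeric(0)
  if (length(g_sgn) > 1L) for (i in seq_len(length(g_sgn) - 1L)) {
    # interpolate between the last bin of group i and first of group i+1
    i_last <- max(which(grp == i)); i_first <- min(which(grp == i + 1L))
    x1 <- x[i_last]; y1 <- f[i_last]; x2 <- x[i_first]; y2 <- f[i_first]
    crossings <- c(crossings, x1 + (0 - y1) * (x2 - x1) / (y2 - y1))
  }
  windows <- data.frame(from = as.numeric(g_from), to = as.numeric(g_to),
                        sign = ifelse(g_sgn > 0, "repulsive", "attractive"))
  structure(list(zero_crossings = crossings, windows = windows),
            class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  if (!length(x$zero_crossings)) cat("no zero crossings above the noise floor\n")
  else cat(sprintf("zero crossings at %s nm\n",
                   paste(sprintf("%.3f", x$zero_crossings), collapse = ", ")))
  if (nrow(x$windows))
    for (i in seq_len(nrow(x$windows)))
      cat(sprintf("  [%.3f, %.3f] nm: %s\n",
                  x$windows$from[i], x$windows$to[i], x$windows$sign[i]))
  invisible(x)
}

#' Residuals against the screened-Coulomb reference
#'
#' Per-bin difference between the measured mean force and the
#' screened-Coulomb force for charges `z_a`, `z_b` at the bin centres.
#' Beyond the contact/solvent-structured region a dissociating unlike
#' charge pair should track the reference, leaving residuals within their
#' standard errors.
#'
#' @param profile a [bin_mean_force()] profile.
#' @param eps_r relative dielectric constant.
#' @param z_a,z_b charges, elementary units.
#' @return data.frame with `x`, `mean_force`, `reference`, `residual`,
#'   `stderr`.
#' @export
compare_to_reference <- function(profile, eps_r = 80, z_a = 1, z_b = -1) {
  stopifnot(inherits(profile, "force_profile"))
  ref <- screened_coulomb_force(profile$bin_centers, eps_r, z_a, z_b)
  data.frame(x = profile$bin_centers, mean_force = profile$mean_force,
             reference = ref, residual = profile$mean_force - ref,
             stderr = profile$stderr)
}
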