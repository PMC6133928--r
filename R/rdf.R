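#' Radial distribution function
#'
#' g(r) between two disjoint site groups under the minimum-image
#' convention, normalized to uniform partner density: pair counts per
#' half-open bin `[edge_i, edge_{i+1})` divided by
#' `n_a * rho_b * V_shell * n_frames`, with `rho_b = n_b / V_box` and
#' V_shell the exact spherical-shell volume between the bin edges. A value
#' of 1 means the partner is found at that distance with the same
#' probability as at a random point of the cell.
#'
#' @param traj a [trajectory()].
#' @param group_a,group_b disjoint site specs.
#' @param bin_width nm; the 0.002 nm default resolves first minima at the
#'   10-pm scale of typical aggregation cutoffs.
#' @param r_max nm; defaults to (and must not exceed) half the smallest
#'   box edge.
#' @return object of class `rdf_result`: `bin_edges`, `r` (centres), `g`,
#'   `counts`, `rho_b` (nm^-3), `n_a`, `n_frames`.
#' @export
compute_rdf <- function(traj, group_a, group_b, bin_width = 0.002, r_max = NULL) {
  stopifnot_scalar_pos(bin_width, "bin_width")
  ia <- resolve_group(traj, group_a, "group_a")
  ib <- resolve_group(traj, group_b, "group_b")
  if (length(ia) == 0L || length(ib) == 0L) stop("empty site group", call. = FALSE)
  if (length(intersect(ia, ib))) stop("site groups must be disjoint", call. = FALSE)
  half_box <- min(traj$box) / 2
  if (is.null(r_max)) r_max <- half_box
  if (r_max > half_box + 1e-12)
    stop("r_max exceeds half the smallest box edge; the minimum-image convention is only valid below it",
         call. = FALSE)
  n_bins <- floor(r_max / bin_width + 1e-9)
  if (n_bins < 1L) stop("r_max smaller than one bin", call. = FALSE)
  counts <- cpp_rdf_counts(traj$coords, ia, ib, traj$box, bin_width, n_bins)
  edges <- (0:n_bins) * bin_width
  vol <- 4 / 3 * pi * diff(edges^3)
  v_box <- mean(apply(traj$box, 1L, prod))
  rho_b <- length(ib) / v_box
  nf <- n_frames(traj)
  g <- counts / (length(ia) * rho_b * vol * nf)
  structure(list(bin_edges = edges, r = (edges[-1] + edges[-length(edges)]) / 2,
                 g = g, counts = counts, rho_b = rho_b, n_a = length(ia),
                 n_frames = nf),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("rdf_result: %d bins to %.3g nm, rho_b = %.4g nm^-3, max g = %.4g\n",
              length(x$g), x$bin_edges[length(x$bin_edges)], x$rho_b, max(x$g)))
  invisible(x)
}

#' @export
plot.rdf_result <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "r (nm)", ylab = "g(r)", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

# Centered moving average used only inside extremum detection; the raw g
# is never modified.
smooth_ma <- function(y, window) {
  if (window <= 1L) return(y)
  k <- rep(1 / window, window)
  as.numeric(stats::filter(y, k, sides = 2))
}

# First local maximum of the smoothed curve above `min_height`.
first_peak_bin <- function(gs, min_height) {
  n <- length(gs)
  for (i in 2:(n - 1)) {
    if (is.na(gs[i])) next
    if (!is.na(gs[i - 1]) && !is.na(gs[i + 1]) &&
        gs[i] >= gs[i - 1] && gs[i] > gs[i + 1] && gs[i] > min_height)
      return(i)
  }
  NA_integer_
}

#' Position of the first RDF minimum
#'
#' Locates the first local minimum after the first peak on a
#' moving-average-smoothed copy of g(r) (the raw curve is untouched). This
#' is the standard way to derive aggregation cutoffs from coordination
#' structure. The peak must exceed 1 by at least `3 * noise`, where noise
#' is estimated as the RMS difference between raw and smoothed g; a curve
#' with no such peak (pure repulsion) is an error.
#'
#' @param rdf an [compute_rdf()] result.
#' @param smoothing_window bins of the centered moving average (default 5).
#' @return first-minimum position, nm (bin centre).
#' @export
first_minimum <- function(rdf, smoothing_window = 5L) {
  gs <- smooth_ma(rdf$g, smoothing_window)
  noise <- stats::sd(rdf$g - gs, na.rm = TRUE)
  peak <- first_peak_bin(gs, 1 + 3 * noise)
  if (is.na(peak))
    stop("no structured first shell: no peak rises above 1 by 3x bin noise", call. = FALSE)
  n <- length(gs)
  # a genuine shell boundary must dip below halfway between the peak and
  # the bulk level; this rejects plateau wiggles inside a broad peak
  dip_level <- 1 + 0.5 * (gs[peak] - 1)
  for (i in (peak + 1L):(n - 1L)) {
    if (any(is.na(gs[(i - 1):(i + 1)]))) next
    if (gs[i] <= gs[i - 1] && gs[i] < gs[i + 1] && gs[i] < dip_level)
      return(rdf$r[i])
  }
  stop("no local minimum found after the first peak within r_max", call. = FALSE)
}

#' Position of the first RDF peak
#'
#' @inheritParams first_minimum
#' @return first-peak position, nm (bin centre).
#' @export
first_peak <- function(rdf, smoothing_window = 5L) {
  gs <- smooth_ma(rdf$g, smoothing_window)
  noise <- stats::sd(rdf$g - gs, na.rm = TRUE)
  peak <- first_peak_bin(gs, 1 + 3 * noise)
  if (is.na(peak)) stop("no structured first shell", call. = FALSE)
  rdf$r[peak]
}

#' Running coordination number
#'
#' `n(r_cut) = 4 pi rho_b int_0^r_cut g(r) r^2 dr`, evaluated with exact
#' per-bin shell volumes (so it is just the normalized cumulative pair
#' count): the mean number of partners within `r_cut`.
#'
#' @param rdf an [compute_rdf()] result.
#' @param r_cut nm, `<= r_max`.
#' @return dimensionless mean partner count.
#' @export
coordination_number <- function(rdf, r_cut) {
  if (r_cut > rdf$bin_edges[length(rdf$bin_edges)] + 1e-12)
    stop("r_cut exceeds the RDF range", call. = FALSE)
  lo <- rdf$bin_edges[-length(rdf$bin_edges)]
  hi <- rdf$bin_edges[-1]
  # exact shell volumes, with the bin containing r_cut entered partially
  vol <- 4 / 3 * pi * (pmin(hi, r_cut)^3 - pmin(lo, r_cut)^3)
  sum(rdf$g * rdf$rho_b * vol)
}

#' First-shell occupancy by frame counting
#'
#' Fraction of frames in which at least one `group_b` member lies within
#' the cutoff of any `group_a` member, plus the mean partner count per
#' frame. Occupancy and the RDF first-peak integral (coordination number)
#' agree only when shells are rarely multiply occupied, so both are
#' reported by the shell analysis rather than conflated.
#'
#' @param traj a [trajectory()].
#' @param criterion a [pair_criterion()].
#' @return list with `fraction` and `mean_partners`.
#' @export
shell_occupancy <- function(traj, criterion) {
  ind <- pair_indicator(traj, criterion)
  per_frame <- colSums(ind$indicator)
  list(fraction = mean(per_frame > 0), mean_partners = mean(per_frame))
}

#' Shell report for a site pairing
#'
#' Bundles the first-shell geometry and statistics of one RDF: first-peak
#' and first-minimum positions, the coordination number integrated to the
#' first minimum, and the frame-counting occupancy at the same cutoff.
#'
#' @param traj a [trajectory()].
#' @param group_a,group_b disjoint site specs.
#' @param bin_width,r_max passed to [compute_rdf()].
#' @param smoothing_window passed to [first_minimum()].
#' @return list of class `shell_report`.
#' @export
shell_report <- function(traj, group_a, group_b, bin_width = 0.002,
                         r_max = NULL, smoothing_window = 5L) {
  rdf <- compute_rdf(traj, group_a, group_b, bin_width, r_max)
  r_pk <- first_peak(rdf, smoothing_window)
  r_min <- first_minimum(rdf, smoothing_window)
  cn <- coordination_number(rdf, r_min)
  occ <- shell_occupancy(traj, pair_criterion(group_a, group_b, r_min))
  structure(list(r_first_peak = r_pk, r_first_min = r_min,
                 coordination_number = cn,
                 occupancy_fraction = occ$fraction,
                 mean_partners = occ$mean_partners, rdf = rdf),
            class = "shell_report")
}

#' @export
print.shell_report <- function(x, ...) {
  cat(sprintf(paste0("first peak %.3f nm, first minimum %.3f nm, ",
                     "n(first min) = %.3g, occupancy %.3g\n"),
              x$r_first_peak, x$r_first_min, x$coordination_number,
              x$occupancy_fraction))
  invisible(x)
}

#' Species density ratio in the inter-site region
#'
#' Time-averaged number density of a species inside a sphere centred at
#' the midpoint of the minimum-image segment between two single sites
#' (re-evaluated every frame), divided by the species' overall density in
#' the box. Values above 1 mean the species is attracted to the inter-site
#' region, below 1 repelled. The region radius is a mandatory explicit
#' parameter: the 'between the charge groups' region has no canonical
#' geometric definition, so it is never defaulted silently.
#'
#' @param traj a [trajectory()].
#' @param site_a,site_b single-atom site specs.
#' @param species_group species site spec.
#' @param region_radius nm, must not exceed half the smallest box edge.
#' @return list of class `density_ratio_report` with `region_density`,
#'   `bulk_density` (nm^-3) and `ratio`.
#' @export
region_density_ratio <- function(traj, site_a, site_b, species_group,
                                 region_radius) {
  stopifnot_scalar_pos(region_radius, "region_radius")
  ia <- resolve_group(traj, site_a, "site_a")
  ib <- resolve_group(traj, site_b, "site_b")
  if (length(ia) != 1L || length(ib) != 1L)
    stop("'site_a' and 'site_b' must resolve to single atoms", call. = FALSE)
  if (region_radius > min(traj$box) / 2)
    stop("region extends beyond half the box", call. = FALSE)
  isp <- resolve_group(traj, species_group, "species")
  counts <- cpp_region_counts(traj$coords, ia, ib, isp, traj$box, region_radius)
  v_region <- 4 / 3 * pi * region_radius^3
  v_box <- mean(apply(traj$box, 1L, prod))
  region_density <- mean(counts) / v_region
  bulk_density <- length(isp) / v_box
  structure(list(region_density = region_density, bulk_density = bulk_density,
                 ratio = region_density / bulk_density),
            class = "density_ratio_report")
}

#' @export
print.density_ratio_report <- function(x, ...) {
  cat(sprintf("region density %.4g nm^-3 / bulk %.4g nm^-3 = ratio %.3g\n",
              x$region_density, x$bulk_density, x$ratio))
  invisible(x)
}
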