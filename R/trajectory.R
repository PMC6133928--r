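#' Construct a trajectory object
#'
#' A trajectory holds atomic positions for a sequence of frames in an
#' orthorhombic periodic box. Internal units are nm for lengths and ps for
#' times, matching common MD-engine conventions; distance cutoffs quoted in
#' pm elsewhere are converted at the configuration boundary (300 pm =
#' 0.30 nm). Positions are stored as read: frames are never wrapped into the
#' box on construction, so intra-molecular vectors stay continuous. Wrapping
#' is applied lazily inside every distance computation via the
#' minimum-image convention.
#'
#' @param coords numeric array of dimension `(n_atoms, 3, n_frames)`, nm.
#' @param box numeric: either a length-3 vector (constant box) or an
#'   `n_frames x 3` matrix of orthorhombic edge lengths, nm. Triclinic
#'   boxes are not supported.
#' @param times frame times in ps; defaults to `0:(n_frames-1)` ps.
#'   Spacing must be uniform (relative tolerance 1e-9).
#' @param labels character per-atom element/role labels.
#' @return an object of class `trajectory` with elements `coords`, `box`
#'   (matrix), `times`, `dt`, `labels`.
#' @export
trajectory <- function(coords, box, times = NULL, labels = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[2] != 3L)
    stop("'coords' must be an (n_atoms, 3, n_frames) array", call. = FALSE)
  na <- dim(coords)[1]; nf <- dim(coords)[3]
  if (!all(is.finite(coords))) stop("positions must be finite", call. = FALSE)
  if (is.matrix(box)) {
    if (nrow(box) != nf || ncol(box) != 3L)
      stop("'box' matrix must be n_frames x 3", call. = FALSE)
  } else {
    if (length(box) == 9L)
      stop("triclinic boxes are not supported; supply 3 orthorhombic edge lengths",
           call. = FALSE)
    if (length(box) != 3L)
      stop("'box' must have 3 orthorhombic edge lengths", call. = FALSE)
    box <- matrix(box, nrow = nf, ncol = 3L, byrow = TRUE)
  }
  if (any(box <= 0)) stop("box edges must be > 0", call. = FALSE)
  if (is.null(times)) times <- seq_len(nf) - 1
  if (length(times) != nf) stop("'times' length must equal n_frames", call. = FALSE)
  dt <- NA_real_
  if (nf >= 2L) {
    steps <- diff(times)
    dt <- steps[1]
    if (dt <= 0 || any(abs(steps - dt) > 1e-9 * max(abs(dt), 1)))
      stop("frame times must be uniformly spaced and increasing", call. = FALSE)
  }
  if (is.null(labels)) labels <- rep("X", na)
  if (length(labels) != na) stop("'labels' length must equal atom count", call. = FALSE)
  structure(list(coords = coords, box = box, times = as.numeric(times),
                 dt = dt, labels = as.character(labels)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frames, dt = %s ps, box = [%s] nm\n",
              n_atoms(x), n_frames(x),
              format(x$dt), paste(format(x$box[1, ]), collapse = ", ")))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj a [trajectory()].
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame
#'
#' @param traj a [trajectory()].
#' @param i frame index (1-based).
#' @return object of class `frame`: list of `positions` (n x 3 matrix, nm),
#'   `box` (length-3, nm) and `time` (ps).
#' @export
get_frame <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range", call. = FALSE)
  structure(list(positions = traj$coords[, , i, drop = TRUE],
                 box = traj$box[i, ], time = traj$times[i]),
            class = "frame")
}

#' Minimum-image distance between two atoms of a frame
#'
#' Euclidean distance between atoms `i` and `j` using the nearest periodic
#' image in an orthorhombic box. The result lies in `[0, half box
#' diagonal]`.
#'
#' @param frame a `frame` as returned by [get_frame()].
#' @param i,j distinct atom indices (1-based).
#' @return distance in nm.
#' @export
minimum_image_distance <- function(frame, i, j) {
  if (i == j) stop("atom indices must differ", call. = FALSE)
  d <- frame$positions[j, ] - frame$positions[i, ]
  d <- d - frame$box * round(d / frame$box)
  sqrt(sum(d * d))
}

# Minimum-image displacement vector from atom i to atom j (nm).
min_image_disp <- function(frame, i, j) {
  d <- frame$positions[j, ] - frame$positions[i, ]
  d - frame$box * round(d / frame$box)
}

#' Resolve a named site group
#'
#' Maps a role specification to atom indices. A specification is either an
#' explicit integer index vector or a character pattern matched against the
#' trajectory's atom labels (exact match first; if nothing matches exactly
#' the pattern is used as a regular expression).
#'
#' @param traj a [trajectory()].
#' @param spec integer indices (1-based) or a single character pattern.
#' @param name role name used in error messages and carried on the result.
#' @return object of class `site_group`: list of `name` and sorted unique
#'   `indices`.
#' @export
select_sites <- function(traj, spec, name = deparse(substitute(spec))) {
  na <- n_atoms(traj)
  if (is.numeric(spec)) {
    idx <- as.integer(spec)
    if (anyDuplicated(idx)) stop(sprintf("duplicate atom index in site group '%s'", name),
                                 call. = FALSE)
    if (any(idx < 1L | idx > na))
      stop(sprintf("site group '%s' has indices outside 1..%d", name, na), call. = FALSE)
  } else if (is.character(spec) && length(spec) == 1L) {
    idx <- which(traj$labels == spec)
    if (length(idx) == 0L) idx <- grep(spec, traj$labels)
    if (length(idx) == 0L)
      stop(sprintf("role '%s': pattern '%s' matches no atoms", name, spec), call. = FALSE)
  } else stop("'spec' must be an index vector or a single character pattern",
              call. = FALSE)
  structure(list(name = name, indices = sort(unique(idx))), class = "site_group")
}

# Accept either a site_group or a raw spec and return indices.
resolve_group <- function(traj, group, name = "group") {
  if (inherits(group, "site_group")) return(group$indices)
  select_sites(traj, group, name = name)$indices
}

#' Construct a time series
#'
#' Carrier for pull records and other sampled scalar columns: strictly
#' increasing times (ps) plus one or more named value columns (nm for a
#' pull coordinate, kJ mol^-1 nm^-1 for a force).
#'
#' @param times numeric, ps, strictly increasing.
#' @param values numeric matrix or data.frame of columns.
#' @return object of class `time_series`.
#' @export
time_series <- function(times, values) {
  values <- as.matrix(values)
  if (length(times) != nrow(values))
    stop("'times' and 'values' lengths differ", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("v", seq_len(ncol(values)))
  structure(list(times = as.numeric(times), values = values), class = "time_series")
}
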