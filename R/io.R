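#' Read an extended-XYZ trajectory
#'
#' Reads a (possibly gzip-compressed) XYZ file whose per-frame comment line
#' carries the orthorhombic box edges as three numbers, e.g.
#' `box= 4.0 4.0 4.0 time= 2.0`, or simply `4.0 4.0 4.0`. Positions are
#' interpreted in nm (this package's internal unit), not the Angstrom of
#' conventional XYZ. A `time=` token, when present, sets the frame time in
#' ps; otherwise frames are numbered 0, 1, 2, ... ps.
#'
#' @param path file path.
#' @return a [trajectory()].
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  pos <- 1L; frames <- list(); boxes <- list(); times <- c(); labels <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(na) || na <= 0L)
      stop(sprintf("line %d: malformed atom count '%s'", pos, lines[pos]), call. = FALSE)
    if (pos + 1L + na > length(lines))
      stop(sprintf("line %d: truncated frame (expected %d atoms)", pos, na), call. = FALSE)
    comment <- lines[pos + 1L]
    toks <- strsplit(gsub("=", " ", comment), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    nums <- suppressWarnings(as.numeric(toks))
    bkey <- match("box", tolower(toks))
    if (!is.na(bkey) && bkey + 3L <= length(toks) && all(is.finite(nums[bkey + 1:3]))) {
      box <- nums[bkey + 1:3]
    } else if (sum(is.finite(nums)) >= 3L) {
      box <- nums[is.finite(nums)][1:3]
    } else {
      stop(sprintf(paste("line %d: no box found in comment line; extended-XYZ",
                         "frames need the three orthorhombic edges, e.g. 'box= 4 4 4'"),
                   pos + 1L), call. = FALSE)
    }
    tkey <- match("time", tolower(toks))
    tm <- if (!is.na(tkey) && tkey < length(toks) && is.finite(nums[tkey + 1L]))
      nums[tkey + 1L] else length(frames)
    atoms <- lines[pos + 1L + seq_len(na)]
    fields <- strsplit(trimws(atoms), "[[:space:]]+")
    bad <- which(vapply(fields, length, 1L) < 4L)
    if (length(bad))
      stop(sprintf("line %d: malformed atom record", pos + 1L + bad[1]), call. = FALSE)
    lab <- vapply(fields, `[[`, "", 1L)
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop(sprintf("non-numeric coordinates in frame starting at line %d", pos),
           call. = FALSE)
    if (is.null(labels)) labels <- lab
    else if (length(lab) != length(labels))
      stop(sprintf("line %d: frame has %d atoms but first frame had %d",
                   pos, na, length(labels)), call. = FALSE)
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- box
    times <- c(times, tm)
    pos <- pos + 2L + na
  }
  if (!length(frames)) stop("no frames found", call. = FALSE)
  coords <- array(unlist(frames), dim = c(length(labels), 3L, length(frames)))
  trajectory(coords, do.call(rbind, boxes), times = times, labels = labels)
}

#' Write an extended-XYZ trajectory
#'
#' @param traj a [trajectory()].
#' @param path output path (".gz" suffix writes gzip).
#' @param digits coordinate digits (default 6, i.e. 1e-6 nm resolution).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, digits = 6) {
  nf <- n_frames(traj); na <- n_atoms(traj)
  fmt <- sprintf("%%s %%.%df %%.%df %%.%df", digits, digits, digits)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(as.character(na), con)
    writeLines(sprintf("box= %.6f %.6f %.6f time= %.6f",
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3],
                       traj$times[f]), con)
    writeLines(sprintf(fmt, traj$labels,
                       traj$coords[, 1, f], traj$coords[, 2, f], traj$coords[, 3, f]),
               con)
  }
  invisible(path)
}

#' Read a GRO trajectory
#'
#' Fixed-column GROMACS coordinate records (positions in nm to 1e-3 nm),
#' single- or multi-frame, gzip accepted. The final line of each frame must
#' be the box line; a 9-component (triclinic) box line is rejected unless
#' its off-diagonal components are all zero. Atom names become the
#' trajectory labels.
#'
#' @param path file path.
#' @return a [trajectory()].
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  pos <- 1L; frames <- list(); boxes <- list(); times <- c(); labels <- NULL
  fidx <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos])) && pos == length(lines)) break
    fidx <- fidx + 1L
    title <- lines[pos]
    if (pos + 1L > length(lines))
      stop(sprintf("frame %d: truncated file (missing atom count)", fidx), call. = FALSE)
    na <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(na) || na <= 0L)
      stop(sprintf("frame %d: malformed atom count at line %d", fidx, pos + 1L),
           call. = FALSE)
    if (pos + 2L + na > length(lines))
      stop(sprintf("frame %d: truncated file (expected %d atom records and a box line)",
                   fidx, na), call. = FALSE)
    recs <- lines[pos + 1L + seq_len(na)]
    lab <- trimws(substring(recs, 11L, 15L))
    x <- as.numeric(substring(recs, 21L, 28L))
    y <- as.numeric(substring(recs, 29L, 36L))
    z <- as.numeric(substring(recs, 37L, 44L))
    if (any(!is.finite(c(x, y, z))))
      stop(sprintf("frame %d: malformed coordinate record", fidx), call. = FALSE)
    btoks <- strsplit(trimws(lines[pos + 2L + na]), "[[:space:]]+")[[1]]
    bnum <- suppressWarnings(as.numeric(btoks))
    if (length(bnum) < 3L || any(!is.finite(bnum)))
      stop(sprintf("frame %d: missing box line", fidx), call. = FALSE)
    if (length(bnum) > 3L && any(bnum[4:length(bnum)] != 0))
      stop(sprintf("frame %d: triclinic box not supported", fidx), call. = FALSE)
    tm <- fidx - 1
    m <- regmatches(title, regexec("t=\\s*([0-9.eE+-]+)", title))[[1]]
    if (length(m) == 2L) tm <- as.numeric(m[2])
    if (is.null(labels)) labels <- lab
    else if (length(lab) != length(labels))
      stop(sprintf("frame %d: atom count changed", fidx), call. = FALSE)
    frames[[fidx]] <- cbind(x, y, z)
    boxes[[fidx]] <- bnum[1:3]
    times <- c(times, tm)
    pos <- pos + 3L + na
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (!length(frames)) stop("no frames found", call. = FALSE)
  coords <- array(unlist(frames), dim = c(length(labels), 3L, length(frames)))
  trajectory(coords, do.call(rbind, boxes), times = times, labels = labels)
}

#' Write a GRO trajectory
#'
#' Positions are written at the format's native 1e-3 nm precision; residue
#' numbering is a running atom index (the format keeps 1-based numbering).
#'
#' @param traj a [trajectory()].
#' @param path output path (".gz" suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path) {
  nf <- n_frames(traj); na <- n_atoms(traj)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  idx <- seq_len(na) %% 100000L
  for (f in seq_len(nf)) {
    writeLines(sprintf("frame t= %.4f", traj$times[f]), con)
    writeLines(sprintf("%5d", na), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       idx, "MOL", substr(traj$labels, 1L, 5L), idx,
                       traj$coords[, 1, f], traj$coords[, 2, f], traj$coords[, 3, f]),
               con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]), con)
  }
  invisible(path)
}

#' Read an xvg-style time series
#'
#' Whitespace-separated numeric columns; lines starting with `#` or `@`
#' (xmgrace headers) are skipped. The first column becomes `times`, the
#' remaining columns the named values.
#'
#' @param path file path (gzip accepted).
#' @param col_names optional names for the value columns.
#' @return a [time_series()].
#' @export
read_xvg_series <- function(path, col_names = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^[[:space:]]*[#@]", lines) & nzchar(trimws(lines))
  data_lines <- lines[keep]
  if (!length(data_lines)) stop("no data rows found", call. = FALSE)
  line_no <- which(keep)
  fields <- strsplit(trimws(data_lines), "[[:space:]]+")
  ncols <- length(fields[[1]])
  vals <- suppressWarnings(vapply(fields, function(f) as.numeric(f[seq_len(ncols)]),
                                  numeric(ncols)))
  bad <- which(apply(is.na(vals), 2L, any))
  if (length(bad))
    stop(sprintf("non-numeric data at line %d", line_no[bad[1]]), call. = FALSE)
  vals <- t(vals)
  values <- vals[, -1L, drop = FALSE]
  if (!is.null(col_names)) colnames(values) <- col_names
  time_series(vals[, 1L], values)
}

#' Write an xvg-style time series
#'
#' @param ts a [time_series()].
#' @param path output path (".gz" suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_xvg_series <- function(ts, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# columns: time %s", paste(colnames(ts$values), collapse = " ")),
             con)
  mat <- cbind(ts$times, ts$values)
  writeLines(apply(formatC(mat, digits = 10, format = "g"), 1L, paste, collapse = " "),
             con)
  invisible(path)
}
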