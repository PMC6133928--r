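# Shared fixture builders and independent oracles. Everything is generated
# in code; no data files.

# Tiny 3-atom, 2-frame trajectory with distinct coordinates.
make_tiny_traj <- function(box = c(4, 4, 4)) {
  coords <- array(0, dim = c(3, 3, 2))
  coords[, , 1] <- rbind(c(0.1, 0.2, 0.3), c(1.0, 1.1, 1.2), c(3.9, 0.0, 0.1))
  coords[, , 2] <- rbind(c(0.2, 0.2, 0.3), c(1.0, 1.2, 1.2), c(3.8, 0.1, 0.1))
  trajectory(coords, box, times = c(0, 0.5), labels = c("OW", "HW", "LI"))
}

# Independent minimum-image oracle: enumerate all 27 periodic images.
brute_min_image <- function(p1, p2, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- p2 + c(i, j, k) * box - p1
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# Embed per-molecule unit vectors as a 2-atom-per-molecule trajectory
# (base on a grid, tip at base + scale * u) in a large box.
embed_vectors_as_traj <- function(vs, scale = 0.1, box = c(50, 50, 50)) {
  d <- dim(vs$vectors)
  ns <- d[1]; nm <- d[3]
  coords <- array(NA_real_, dim = c(2L * nm, 3L, ns))
  base <- cbind((seq_len(nm) - 1) %% 10 + 1, (seq_len(nm) - 1) %/% 10 + 1, 1)
  for (f in seq_len(ns)) {
    u <- t(vs$vectors[f, , ])        # nm x 3
    coords[seq(1, 2 * nm, 2), , f] <- base
    coords[seq(2, 2 * nm, 2), , f] <- base + scale * u
  }
  trajectory(coords, box, times = (seq_len(ns) - 1) * vs$dt,
             labels = rep(c("BASE", "TIP"), nm))
}

# Build an rdf_result by hand from an analytic g(r) curve (for extremum
# detection tests); counts are back-filled consistently.
analytic_rdf <- function(g_fun, bin_width = 0.005, r_max = 1.0, rho_b = 10,
                         n_a = 1, n_frames = 1) {
  edges <- seq(0, r_max, by = bin_width)
  r <- (edges[-1] + edges[-length(edges)]) / 2
  g <- g_fun(r)
  vol <- 4 / 3 * pi * diff(edges^3)
  structure(list(bin_edges = edges, r = r, g = g,
                 counts = g * n_a * rho_b * vol * n_frames,
                 rho_b = rho_b, n_a = n_a, n_frames = n_frames),
            class = "rdf_result")
}

# Force profile built directly from an analytic mean-force curve.
analytic_profile <- function(f_fun, from, to, bin_width = 0.01, stderr = 0.1) {
  x <- seq(from + bin_width / 2, to, by = bin_width)
  structure(list(bin_centers = x, mean_force = f_fun(x),
                 stderr = rep(stderr, length(x)),
                 n_samples = rep(1000L, length(x)), bin_width = bin_width),
            class = "force_profile")
}
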