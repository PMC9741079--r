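# Independent oracles and fixture builders used across the suite.

# Numeric surface-of-revolution integration of the lateral surface of one
# section whose radius varies linearly from r1 to r2 over height h:
# S = 2*pi * integral r(z) * sqrt(1 + r'(z)^2) dz
oracle_section_surface <- function(r1, r2, h) {
  if (h == 0) return(0)
  slope <- (r2 - r1) / h
  f <- function(z) 2 * pi * (r1 + slope * z) * sqrt(1 + slope^2)
  stats::integrate(f, 0, h, rel.tol = 1e-10)$value
}

# Numeric solid-of-revolution integration of the section volume:
# V = pi * integral r(z)^2 dz
oracle_section_volume <- function(r1, r2, h) {
  if (h == 0) return(0)
  slope <- (r2 - r1) / h
  f <- function(z) pi * (r1 + slope * z)^2
  stats::integrate(f, 0, h, rel.tol = 1e-10)$value
}

# Integrates the full piecewise-linear radius profile of a channel.
oracle_measure_channel <- function(profile) {
  nodes <- profile$nodes
  n <- nrow(nodes)
  h <- sqrt(rowSums(diff(as.matrix(nodes[, c("x", "y", "z")]))^2))
  r1 <- nodes$r[-n]
  r2 <- nodes$r[-1]
  c(length = sum(h),
    surface = sum(mapply(oracle_section_surface, r1, r2, h)),
    volume = sum(mapply(oracle_section_volume, r1, r2, h)))
}

# Seeded random channel profile: a jittered 3D walk with positive step
# lengths and radii in [0.5, 3] Angstrom.
random_profile <- function(n_nodes = 8, seed = 1, id = "rnd") {
  set.seed(seed)
  steps <- matrix(rnorm(3 * (n_nodes - 1), sd = 1.5), ncol = 3)
  lens <- sqrt(rowSums(steps^2))
  steps <- steps * (runif(n_nodes - 1, 0.5, 3) / lens)  # step length 0.5-3
  centers <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
  channel_profile(id, data.frame(x = centers[, 1], y = centers[, 2],
                                 z = centers[, 3],
                                 r = runif(n_nodes, 0.5, 3)))
}

# Splits every section of a profile at a random interior parameter, linearly
# interpolating position and radius; frustum totals must be unchanged.
subdivide_profile <- function(profile, seed = 1) {
  set.seed(seed)
  nodes <- profile$nodes
  out <- nodes[1, , drop = FALSE]
  for (i in seq_len(nrow(nodes) - 1)) {
    t <- runif(1, 0.1, 0.9)
    mid <- (1 - t) * nodes[i, c("x", "y", "z", "r")] +
      t * nodes[i + 1, c("x", "y", "z", "r")]
    out <- rbind(out, mid, nodes[i + 1, , drop = FALSE])
  }
  channel_profile(profile$channel_id, out)
}

# --- exhaustive widest-bottleneck oracle (binary search over thresholds +
# 26-connected flood fill), for small grids ---------------------------------

dilate26 <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[xs, ys, zs] <- out[xs, ys, zs] |
      mask[xs - dx, ys - dy, zs - dz]
  }
  out
}

touches_boundary <- function(mask) {
  d <- dim(mask)
  any(mask[1, , ]) || any(mask[d[1], , ]) || any(mask[, 1, ]) ||
    any(mask[, d[2], ]) || any(mask[, , 1]) || any(mask[, , d[3]])
}

# TRUE when the start voxel connects (26-connectivity) to any boundary voxel
# through voxels with clearance >= thr
connects_at_threshold <- function(clearance, start, thr) {
  open <- clearance >= thr
  if (!open[start]) return(FALSE)
  visited <- array(FALSE, dim(clearance))
  visited[start] <- TRUE
  repeat {
    grown <- dilate26(visited) & open
    if (identical(grown, visited)) break
    visited <- grown
  }
  touches_boundary(visited)
}

# Exhaustive maximin bottleneck: the largest clearance threshold at which the
# start still connects to the boundary.
oracle_bottleneck <- function(clearance, start, min_radius) {
  cand <- sort(unique(as.vector(clearance[clearance >= min_radius])))
  if (!length(cand) || !connects_at_threshold(clearance, start, cand[1]))
    return(NA_real_)
  lo <- 1L
  hi <- length(cand)
  while (lo < hi) {  # invariant: cand[lo] connects
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (connects_at_threshold(clearance, start, cand[mid])) lo <- mid
    else hi <- mid - 1L
  }
  cand[lo]
}

# Random tube spec used by the tracer recovery checks: constant or tapered
# radius in [1.5, 3] Angstrom, buried (capped) wide end so the traced path
# must traverse the whole tube.
random_tube_spec <- function(seed) {
  set.seed(seed)
  r_ends <- sort(runif(2, 1.5, 3), decreasing = TRUE)
  if (runif(1) < 0.5) r_ends[2] <- r_ends[1]  # half the tubes are straight
  tube_spec(length = 20,
            radius = data.frame(z = c(0, 20), r = r_ends),
            atom_spacing = 1.2, capped = c(TRUE, FALSE), seed = seed)
}
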