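# Built-in channel tracer: a clearance field on a regular grid plus a
# widest-bottleneck path search. Intended for toy-scale structures so the
# measurement pipeline can run without external tunnel-detection software;
# it makes no claim of reproducing Voronoi-based tunnel finders numerically.

#' Build a clearance grid around an atom set
#'
#' The clearance at a point is the distance to the nearest atom surface,
#' `min_i(||p - atom_i|| - vdw_i)`; negative inside an atom. The grid covers
#' the atom bounding box padded by `pad` Angstrom on all sides, and every
#' grid value is the exact brute-force minimum over all atoms.
#'
#' @param atoms an [atom_set()].
#' @param spacing grid spacing in Angstrom, within `[0.25, 2]`.
#' @param pad padding around the atom bounding box in Angstrom, `>= 3`.
#' @param max_cells cap on the number of grid cells; exceeding it is an
#'   error advising a larger spacing.
#' @return an object of class `clearance_grid`: list with `origin` (Angstrom),
#'   `spacing`, `dim` (3 integers) and `clearance` (3D array).
#' @export
build_clearance_grid <- function(atoms, spacing = 0.5, pad = 5, max_cells = 2e7) {
  stopifnot(inherits(atoms, "atom_set"))
  if (!is.finite(spacing) || spacing < 0.25 || spacing > 2)
    stop("spacing must lie in [0.25, 2] Angstrom", call. = FALSE)
  if (!is.finite(pad) || pad < 3)
    stop("pad must be >= 3 Angstrom", call. = FALSE)
  lo <- c(min(atoms$x), min(atoms$y), min(atoms$z)) - pad
  hi <- c(max(atoms$x), max(atoms$y), max(atoms$z)) + pad
  dims <- as.integer(floor((hi - lo) / spacing)) + 1L
  if (prod(as.numeric(dims)) > max_cells)
    stop("grid of ", paste(dims, collapse = "x"), " cells exceeds max_cells (",
         format(max_cells, scientific = FALSE),
         "); increase spacing or max_cells", call. = FALSE)
  cl <- cpp_clearance_grid(as.matrix(atoms[, c("x", "y", "z")]), atoms$vdw,
                           lo, spacing, dims)
  dim(cl) <- dims
  structure(list(origin = lo, spacing = spacing, dim = dims, clearance = cl),
            class = "clearance_grid")
}

#' @export
print.clearance_grid <- function(x, ...) {
  cat("clearance_grid", paste(x$dim, collapse = " x "), "at spacing",
      x$spacing, "Angstrom\n")
  invisible(x)
}

#' Exact clearance of arbitrary points
#'
#' Brute-force distance to the nearest atom surface for each query point.
#'
#' @param atoms an [atom_set()].
#' @param points numeric matrix (n x 3) or length-3 vector, Angstrom.
#' @return numeric vector of clearances in Angstrom.
#' @export
clearance_at <- function(atoms, points) {
  stopifnot(inherits(atoms, "atom_set"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  apply(points, 1, function(p) {
    d <- sqrt((atoms$x - p[1])^2 + (atoms$y - p[2])^2 + (atoms$z - p[3])^2)
    min(d - atoms$vdw)
  })
}

grid_voxel_center <- function(grid, idx) {
  # idx: 1-based linear index/indices into the clearance array
  ijk <- arrayInd(idx, grid$dim) - 1L
  sweep(ijk * grid$spacing, 2, grid$origin, `+`)
}

grid_nearest_voxel <- function(grid, point) {
  ijk <- round((point - grid$origin) / grid$spacing)
  ijk <- pmin(pmax(ijk, 0), grid$dim - 1L)
  as.integer(1 + ijk[1] + grid$dim[1] * (ijk[2] + grid$dim[2] * ijk[3]))
}

#' Trace a channel through a structure
#'
#' Builds a clearance grid around the atoms and finds the widest-bottleneck
#' path — the path that maximizes the minimum clearance along it, with ties
#' broken by fewer steps then by voxel order — from the start point's voxel
#' to any voxel on the padded-box boundary, moving over 26-connected voxels
#' whose clearance is at least `min_radius`. The result is deterministic for
#' fixed inputs.
#'
#' @param atoms an [atom_set()].
#' @param start length-3 numeric, the start point in Angstrom; its voxel must
#'   have clearance `>= min_radius`.
#' @param spacing,pad,max_cells passed to [build_clearance_grid()].
#' @param min_radius minimum channel radius in Angstrom (default 0.9).
#' @param channel_id id given to the traced profile.
#' @return a [channel_profile()] whose nodes are the path voxel centers with
#'   `r` equal to the local clearance.
#' @export
trace_channel <- function(atoms, start, spacing = 0.5, min_radius = 0.9,
                          pad = 5, max_cells = 2e7, channel_id = "traced") {
  if (!is.numeric(start) || length(start) != 3 || any(!is.finite(start)))
    stop("start must be a finite length-3 numeric vector", call. = FALSE)
  if (!is.finite(min_radius) || min_radius <= 0)
    stop("min_radius must be > 0", call. = FALSE)
  grid <- build_clearance_grid(atoms, spacing = spacing, pad = pad,
                               max_cells = max_cells)
  hi <- grid$origin + (grid$dim - 1L) * grid$spacing
  if (any(start < grid$origin) || any(start > hi))
    stop("start point (", paste(start, collapse = ", "),
         ") lies outside the padded grid box", call. = FALSE)
  v0 <- grid_nearest_voxel(grid, start)
  if (grid$clearance[v0] < min_radius)
    stop("start occluded: clearance ", signif(grid$clearance[v0], 4),
         " Angstrom at the start voxel is below min_radius ", min_radius,
         call. = FALSE)
  res <- cpp_widest_path(as.vector(grid$clearance), grid$dim, v0 - 1L, min_radius)
  if (!isTRUE(res$found))
    stop(res$reason, call. = FALSE)
  if (length(res$path) < 2)
    stop("traced path is degenerate: the start voxel already lies on the ",
         "grid boundary", call. = FALSE)
  centers <- grid_voxel_center(grid, res$path)
  channel_profile(channel_id,
                  data.frame(x = centers[, 1], y = centers[, 2],
                             z = centers[, 3],
                             r = as.vector(grid$clearance)[res$path]))
}
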