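# Seeded synthetic generators: (a) dimension-versus-temperature tables with
# the variance-contraction structure seen in thermoadaptation data — roughly
# temperature-independent means with a within-class spread that shrinks as
# the optimum growth temperature rises — and (b) toy channel-bearing tube
# structures with known ground-truth centerline profiles for the tracer.

#' Specification for the synthetic dimension-table generator
#'
#' Defaults emulate the study conditions the package targets: optimum growth
#' temperatures spread over 18-110 degrees C, temperature-independent mean
#' dimensions, and a within-class spread that contracts log-linearly with
#' temperature so that the coolest class (< 50 C) is several-fold more
#' variable than the hottest (> 80 C).
#'
#' @param n_per_class species per temperature class per (enzyme, subunit)
#'   panel (default 30).
#' @param t_range temperature range in degrees C (default `c(18, 110)`).
#' @param mu named mean dimensions (length Angstrom, surface Angstrom^2,
#'   volume Angstrom^3), temperature-independent by default.
#' @param sigma0 sd of each dimension at the cool end (default `mu / 8`;
#'   must satisfy `mu > 6 * sigma0` so truncation at 0 is negligible).
#' @param kappa sd contraction factor, sd(hot end) / sd(cool end), in
#'   (0, 1]; default 0.25.
#' @param beta named slopes of the mean per degree C (default 0).
#' @param subunits named list mapping each enzyme to its subunits.
#' @param seed integer RNG seed.
#' @return an object of class `dimension_gen_spec`.
#' @export
dimension_gen_spec <- function(n_per_class = 30,
                               t_range = c(18, 110),
                               mu = c(length = 100, surface = 2000, volume = 3000),
                               sigma0 = mu / 8,
                               kappa = 0.25,
                               beta = c(length = 0, surface = 0, volume = 0),
                               subunits = list(Mmr = c("alpha", "beta", "gamma"),
                                               Hdr = c("A", "B", "C")),
                               seed = 1) {
  dims <- c("length", "surface", "volume")
  if (!all(dims %in% names(mu)) || !all(dims %in% names(sigma0)) ||
      !all(dims %in% names(beta)))
    stop("mu, sigma0 and beta must be named with length, surface, volume",
         call. = FALSE)
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  if (length(t_range) != 2 || t_range[1] >= t_range[2] ||
      t_range[1] <= 0 || t_range[2] >= 130)
    stop("t_range must be increasing and inside (0, 130) degrees C", call. = FALSE)
  if (t_range[1] >= 50 || t_range[2] <= 80)
    stop("t_range must cover all three temperature classes", call. = FALSE)
  if (any(sigma0[dims] <= 0)) stop("sigma0 must be > 0", call. = FALSE)
  if (!is.finite(kappa) || kappa <= 0 || kappa > 1)
    stop("kappa must lie in (0, 1]", call. = FALSE)
  if (any(mu[dims] <= 6 * sigma0[dims]))
    stop("means must satisfy mu > 6 * sigma0 so truncation at 0 is negligible",
         call. = FALSE)
  if (!all(names(subunits) %in% ENZYMES))
    stop("subunits must be named by enzyme (Mmr, Hdr)", call. = FALSE)
  structure(list(n_per_class = as.integer(n_per_class), t_range = t_range,
                 mu = mu[dims], sigma0 = sigma0[dims], kappa = kappa,
                 beta = beta[dims], subunits = subunits,
                 seed = as.integer(seed)),
            class = "dimension_gen_spec")
}

# sd contracts log-linearly in t_opt from sigma0 at t_range[1] to
# kappa * sigma0 at t_range[2]
sd_at_temperature <- function(spec, t_opt, dim) {
  frac <- (t_opt - spec$t_range[1]) / (spec$t_range[2] - spec$t_range[1])
  spec$sigma0[[dim]] * spec$kappa^frac
}

#' Generate a synthetic dimension-versus-temperature dataset
#'
#' Per (enzyme, subunit) panel and per temperature class, `n_per_class`
#' optimum growth temperatures are drawn uniformly within the class band
#' (clipped to `t_range`), and each dimension is drawn from a normal with
#' mean `mu + beta * t_opt` and a standard deviation that interpolates
#' log-linearly from `sigma0` at the cool end of `t_range` to
#' `kappa * sigma0` at the hot end; draws at or below 0 are rejected and
#' redrawn. Fully reproducible from the spec's seed.
#'
#' @param spec a [dimension_gen_spec()].
#' @return a [measurement_dataset()].
#' @export
generate_dimension_dataset <- function(spec) {
  stopifnot(inherits(spec, "dimension_gen_spec"))
  set.seed(spec$seed)
  bands <- list("<50" = c(spec$t_range[1], 50),
                "50-80" = c(50, 80),
                ">80" = c(80, spec$t_range[2]))
  rows <- list()
  counter <- 0L
  for (enz in names(spec$subunits)) {
    for (sub in spec$subunits[[enz]]) {
      for (cl in names(bands)) {
        b <- bands[[cl]]
        # nudge away from the open boundaries so class membership is exact
        t_opt <- runif(spec$n_per_class, b[1], b[2])
        if (cl == "<50") t_opt <- pmin(t_opt, 50 - 1e-6)
        if (cl == ">80") t_opt <- pmax(t_opt, 80 + 1e-6)
        vals <- sapply(c("length", "surface", "volume"), function(dim) {
          m <- spec$mu[[dim]] + spec$beta[[dim]] * t_opt
          s <- sd_at_temperature(spec, t_opt, dim)
          v <- rnorm(spec$n_per_class, m, s)
          while (any(v <= 0)) {  # truncate at 0 by redrawing
            bad <- v <= 0
            v[bad] <- rnorm(sum(bad), m[bad], s[bad])
          }
          v
        })
        vals <- matrix(vals, ncol = 3,
                       dimnames = list(NULL, c("length", "surface", "volume")))
        rows[[length(rows) + 1L]] <- data.frame(
          species = sprintf("synsp_%04d", counter + seq_len(spec$n_per_class)),
          enzyme = enz, subunit = sub, t_opt = t_opt,
          length = vals[, "length"], surface = vals[, "surface"],
          volume = vals[, "volume"])
        counter <- counter + spec$n_per_class
      }
    }
  }
  measurement_dataset(do.call(rbind, rows))
}

#' Generate synthetic channel profiles matching a dimension dataset
#'
#' For end-to-end pipeline runs: one protein per dataset row, holding a
#' single straight-axis channel whose frustum measurements reproduce the
#' row's `length` exactly and its `surface` exactly (constant radius
#' `surface / (2 * pi * length)`); the volume follows as `pi r^2 L`.
#'
#' @param spec a [dimension_gen_spec()].
#' @param nodes_per_channel number of centerline nodes (default 11).
#' @return a list with `sets` (list of [protein_channel_set()]) and
#'   `species` (data.frame of `species`, `t_opt`).
#' @export
generate_profile_sets <- function(spec, nodes_per_channel = 11) {
  dataset <- generate_dimension_dataset(spec)
  sets <- lapply(seq_len(nrow(dataset)), function(i) {
    row <- dataset[i, ]
    L <- row$length
    r <- row$surface / (2 * pi * L)
    z <- seq(0, L, length.out = nodes_per_channel)
    prof <- channel_profile("T1", data.frame(x = 0, y = 0, z = z, r = r))
    protein_channel_set(sprintf("prot_%04d", i), row$species, row$enzyme,
                        row$subunit, "predicted", list(prof))
  })
  list(sets = sets,
       species = unique(data.frame(species = dataset$species,
                                   t_opt = dataset$t_opt)))
}

#' Specification for the synthetic tube-structure generator
#'
#' A wall of carbon atoms around the z-axis whose inner radius follows a
#' piecewise-linear profile `R(z)`; the open ends reach the structure
#' boundary so a channel runs along the axis.
#'
#' @param length tube axis length in Angstrom.
#' @param radius inner radius: a single number for a straight tube or a
#'   `data.frame(z, r)` piecewise-linear profile over `[0, length]`; the
#'   minimum must exceed 1 Angstrom.
#' @param atom_spacing spacing of wall atoms in Angstrom; must be <= 2 or
#'   the wall leaks at the tracer's scale.
#' @param capped length-2 logical: cap the z = 0 and z = length ends.
#' @param seed integer seed (used for the angular offsets of wall rings).
#' @return an object of class `tube_spec`.
#' @export
tube_spec <- function(length = 20, radius = 2, atom_spacing = 1.2,
                      capped = c(FALSE, FALSE), seed = 1) {
  if (is.data.frame(radius)) {
    if (!all(c("z", "r") %in% names(radius)) || nrow(radius) < 2)
      stop("radius profile needs columns z, r and >= 2 rows", call. = FALSE)
    radius <- radius[order(radius$z), ]
  } else {
    radius <- data.frame(z = c(0, length), r = radius)
  }
  if (min(radius$r) <= 1)
    stop("minimum tube radius must exceed 1 Angstrom", call. = FALSE)
  if (atom_spacing > 2)
    stop("atom_spacing above 2 Angstrom leaks: the wall would not be tight ",
         "at the tracer's default min_radius", call. = FALSE)
  if (length <= 0) stop("tube length must be > 0", call. = FALSE)
  structure(list(length = length, radius = radius,
                 atom_spacing = atom_spacing,
                 capped = rep_len(as.logical(capped), 2),
                 seed = as.integer(seed)),
            class = "tube_spec")
}

tube_radius_at <- function(spec, z) {
  stats::approx(spec$radius$z, spec$radius$r, xout = z, rule = 2)$y
}

#' Generate a synthetic tube structure with known ground truth
#'
#' Places carbon wall atoms (van der Waals radius 1.70 Angstrom) on rings of
#' radius `R(z) + vdw` around the z-axis at the spec's atom spacing, so the
#' clearance along the axis equals the design radius `R(z)`. Capped ends get
#' an atom disc closing the opening. The ground-truth centerline profile is
#' the axis sampled at the ring positions with `r = R(z)`.
#'
#' @param spec a [tube_spec()].
#' @return a list with `atoms` (an [atom_set()]), `profile` (the ground-truth
#'   [channel_profile()]) and `spec`.
#' @export
generate_tube_structure <- function(spec) {
  stopifnot(inherits(spec, "tube_spec"))
  set.seed(spec$seed)
  vdw <- unname(VDW_RADII["C"])
  zs <- seq(0, spec$length, by = spec$atom_spacing)
  if (zs[length(zs)] < spec$length) zs <- c(zs, spec$length)
  pts <- list()
  for (z in zs) {
    ring_r <- tube_radius_at(spec, z) + vdw
    n_ang <- max(6L, ceiling(2 * pi * ring_r / spec$atom_spacing))
    ang <- 2 * pi * (seq_len(n_ang) - 1) / n_ang + runif(1, 0, 2 * pi / n_ang)
    pts[[length(pts) + 1L]] <- cbind(ring_r * cos(ang), ring_r * sin(ang), z)
  }
  cap_disc <- function(z) {
    ring_r <- tube_radius_at(spec, z) + vdw
    radii <- seq(0, ring_r, by = spec$atom_spacing)
    do.call(rbind, lapply(radii, function(rr) {
      if (rr == 0) return(cbind(0, 0, z))
      n_ang <- max(6L, ceiling(2 * pi * rr / spec$atom_spacing))
      ang <- 2 * pi * (seq_len(n_ang) - 1) / n_ang
      cbind(rr * cos(ang), rr * sin(ang), z)
    }))
  }
  if (spec$capped[1]) pts[[length(pts) + 1L]] <- cap_disc(0)
  if (spec$capped[2]) pts[[length(pts) + 1L]] <- cap_disc(spec$length)
  xyz <- do.call(rbind, pts)
  atoms <- atom_set(xyz[, 1], xyz[, 2], xyz[, 3], vdw = vdw,
                    name = "C", element = "C")
  profile <- channel_profile("truth",
                             data.frame(x = 0, y = 0, z = zs,
                                        r = tube_radius_at(spec, zs)))
  list(atoms = atoms, profile = profile, spec = spec)
}
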