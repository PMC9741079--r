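# Section-wise and total channel measurements with the cylinder /
# truncated-cone (frustum) model. Each pair of consecutive centerline
# spheres bounds one section: the section height h is the straight-line
# distance between the two centers and the two sphere radii are the section's
# end radii. Totals for a channel (and for a protein) are sums over sections
# (and over channels).

#' Volume of one channel section (frustum)
#'
#' `V = (1/3) * pi * h * (r1^2 + r1*r2 + r2^2)`, the volume of a truncated
#' cone with end radii `r1`, `r2` and height `h`; for `r1 == r2` this reduces
#' to the cylinder volume `pi * r^2 * h`. Vectorized over all arguments.
#'
#' @param r1,r2 end radii in Angstrom, strictly positive.
#' @param h section height in Angstrom, non-negative.
#' @return section volume(s) in Angstrom^3.
#' @export
section_volume <- function(r1, r2, h) {
  check_section_args(r1, r2, h)
  pi * h * (r1^2 + r1 * r2 + r2^2) / 3
}

#' Lateral surface of one channel section (frustum)
#'
#' `S = pi * (r1 + r2) * sqrt((r1 - r2)^2 + h^2)`, the lateral (side) surface
#' of a truncated cone — end caps are never counted; for `r1 == r2` this
#' reduces to the cylinder lateral area `2 * pi * r * h`, and at `h = 0` it
#' degenerates to the annulus between the two radii. Vectorized.
#'
#' @inheritParams section_volume
#' @return lateral surface(s) in Angstrom^2.
#' @export
section_surface <- function(r1, r2, h) {
  check_section_args(r1, r2, h)
  pi * (r1 + r2) * sqrt((r1 - r2)^2 + h^2)
}

check_section_args <- function(r1, r2, h) {
  if (any(!is.finite(r1) | r1 <= 0) || any(!is.finite(r2) | r2 <= 0))
    stop("section radii must be finite and > 0", call. = FALSE)
  if (any(!is.finite(h) | h < 0))
    stop("section height must be finite and >= 0", call. = FALSE)
  invisible(NULL)
}

#' Measure one channel
#'
#' Sums section length, lateral surface and volume over the consecutive-node
#' sections of a profile: `h` is the Euclidean distance between consecutive
#' sphere centers and the pair's radii are the section's end radii.
#'
#' @param profile a [channel_profile()].
#' @return a named numeric vector `c(length =, surface =, volume =)` in
#'   Angstrom, Angstrom^2 and Angstrom^3.
#' @export
measure_channel <- function(profile) {
  if (!inherits(profile, "channel_profile"))
    stop("profile must be a channel_profile", call. = FALSE)
  nodes <- profile$nodes
  if (nrow(nodes) < 2)
    stop("a channel profile needs at least 2 nodes", call. = FALSE)
  h <- section_heights(nodes)
  if (any(h == 0))
    stop("coincident consecutive centers in channel '", profile$channel_id, "'",
         call. = FALSE)
  n <- nrow(nodes)
  r1 <- nodes$r[-n]
  r2 <- nodes$r[-1]
  c(length = sum(h),
    surface = sum(section_surface(r1, r2, h)),
    volume = sum(section_volume(r1, r2, h)))
}

#' Measure all channels of a protein
#'
#' Per-protein totals are the component-wise sums of [measure_channel()] over
#' all channels in the set. `longest_only = TRUE` restricts the totals to the
#' single channel with the greatest length.
#'
#' @param set a [protein_channel_set()] with at least one channel.
#' @param longest_only if `TRUE`, measure only the longest channel.
#' @return a named numeric vector `c(length =, surface =, volume =)`.
#' @export
measure_protein <- function(set, longest_only = FALSE) {
  if (!inherits(set, "protein_channel_set"))
    stop("set must be a protein_channel_set", call. = FALSE)
  if (length(set$channels) == 0)
    stop("protein '", set$protein_id, "' has no channels to measure", call. = FALSE)
  per_channel <- lapply(set$channels, measure_channel)
  if (longest_only) {
    lengths <- vapply(per_channel, `[[`, numeric(1), "length")
    per_channel <- per_channel[which.max(lengths)]
  }
  Reduce(`+`, per_channel)
}

#' Measure a collection of proteins into a dataset table
#'
#' Applies [measure_protein()] to each set and joins optional species
#' metadata (optimum growth temperatures) by species name.
#'
#' @param sets list of [protein_channel_set()] objects.
#' @param species_table optional `data.frame` with columns `species`, `t_opt`.
#' @param longest_only passed to [measure_protein()].
#' @return a [measurement_dataset()] when `species_table` is given (rows
#'   without a matching species are dropped with a warning); otherwise a plain
#'   `data.frame` without `t_opt`/`t_class`.
#' @export
measure_proteins <- function(sets, species_table = NULL, longest_only = FALSE) {
  rows <- lapply(sets, function(s) {
    m <- measure_protein(s, longest_only = longest_only)
    data.frame(protein_id = s$protein_id, species = s$species,
               enzyme = s$enzyme, subunit = s$subunit, source = s$source,
               length = m[["length"]], surface = m[["surface"]],
               volume = m[["volume"]])
  })
  df <- do.call(rbind, rows)
  if (is.null(species_table)) return(df)
  if (!all(c("species", "t_opt") %in% names(species_table)))
    stop("species_table needs columns species, t_opt", call. = FALSE)
  idx <- match(df$species, species_table$species)
  if (any(is.na(idx))) {
    warning("dropping ", sum(is.na(idx)), " protein(s) with no t_opt entry: ",
            paste(unique(df$species[is.na(idx)]), collapse = ", "), call. = FALSE)
    df <- df[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  df$t_opt <- species_table$t_opt[idx]
  measurement_dataset(df[, c("species", "enzyme", "subunit", "t_opt",
                             "length", "surface", "volume")])
}
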