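# Domain types and file I/O: channel-profile interchange formats, PDB
# structure reading, and measurement/metadata tables.

#' Construct a table of centerline sphere nodes
#'
#' A node is one sample of a channel centerline: a 3D center (Angstrom) plus
#' the local channel radius (Angstrom). Consecutive node radii are the two
#' radii of the truncated-cone section between them.
#'
#' @param x,y,z numeric coordinates in Angstrom.
#' @param r numeric local channel radii in Angstrom; must be strictly positive.
#' @return a `data.frame` with columns `x`, `y`, `z`, `r`.
#' @export
sphere_nodes <- function(x, y, z, r) {
  n <- length(x)
  if (length(y) != n || length(z) != n || length(r) != n)
    stop("x, y, z, r must have equal length", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("node coordinates must be finite", call. = FALSE)
  if (!all(is.finite(r)) || any(r <= 0))
    stop("node radii must be finite and > 0", call. = FALSE)
  data.frame(x = as.numeric(x), y = as.numeric(y),
             z = as.numeric(z), r = as.numeric(r))
}

#' Construct a channel profile
#'
#' An ordered sequence of centerline sphere nodes describing one tunnel.
#' Profiles need at least two nodes and consecutive nodes must be distinct
#' points, so that every section has a positive height.
#'
#' @param channel_id character identifier, unique within a protein.
#' @param nodes a node table as returned by [sphere_nodes()].
#' @return an object of class `channel_profile`.
#' @export
channel_profile <- function(channel_id, nodes) {
  if (!is.character(channel_id) || length(channel_id) != 1 || !nzchar(channel_id))
    stop("channel_id must be a non-empty string", call. = FALSE)
  nodes <- sphere_nodes(nodes$x, nodes$y, nodes$z, nodes$r)
  if (nrow(nodes) < 2)
    stop("a channel profile needs at least 2 nodes", call. = FALSE)
  h <- section_heights(nodes)
  if (any(h == 0))
    stop("consecutive nodes must be distinct points (zero-height section at index ",
         which(h == 0)[1], ")", call. = FALSE)
  structure(list(channel_id = channel_id, nodes = nodes),
            class = "channel_profile")
}

section_heights <- function(nodes) {
  d <- diff(as.matrix(nodes[, c("x", "y", "z")]))
  sqrt(rowSums(d^2))
}

#' @export
print.channel_profile <- function(x, ...) {
  cat("channel_profile", x$channel_id, "with", nrow(x$nodes), "nodes\n")
  invisible(x)
}

#' Construct a protein channel set
#'
#' All channel profiles found in one protein structure, together with the
#' identity of the protein: species, enzyme (`Mmr` methyl-coenzyme M
#' reductase or `Hdr` heterodisulfide reductase), subunit, and whether the
#' structure was predicted from sequence or is a resolved model.
#'
#' @param protein_id character identifier.
#' @param species character species name.
#' @param enzyme `"Mmr"` or `"Hdr"`.
#' @param subunit character subunit label (e.g. alpha/beta/gamma or A/B/C).
#' @param source `"predicted"` or `"resolved"`.
#' @param channels list of [channel_profile()] objects with unique ids.
#' @return an object of class `protein_channel_set`.
#' @export
protein_channel_set <- function(protein_id, species, enzyme, subunit,
                                source = "predicted", channels) {
  enzyme <- match.arg(enzyme, ENZYMES)
  source <- match.arg(source, SOURCES)
  if (!is.list(channels) || !all(vapply(channels, inherits, logical(1), "channel_profile")))
    stop("channels must be a list of channel_profile objects", call. = FALSE)
  ids <- vapply(channels, function(ch) ch$channel_id, character(1))
  if (anyDuplicated(ids))
    stop("channel ids must be unique within a protein: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(list(protein_id = as.character(protein_id),
                 species = as.character(species),
                 enzyme = enzyme, subunit = as.character(subunit),
                 source = source, channels = channels),
            class = "protein_channel_set")
}

#' @export
print.protein_channel_set <- function(x, ...) {
  cat("protein_channel_set", x$protein_id, sprintf("(%s %s %s, %s):", x$species,
      x$enzyme, x$subunit, x$source), length(x$channels), "channel(s)\n")
  invisible(x)
}

# ---- profile JSON dialect (canonical interchange) --------------------------

#' Write protein channel sets to the profile JSON dialect
#'
#' The dialect is a top-level array of objects
#' `{protein_id, species, enzyme, subunit, source, channels: [{channel_id,
#' nodes: [{x, y, z, r}]}]}` with all coordinates and radii in Angstrom.
#' Full double precision is preserved so that a write/read round trip is the
#' identity.
#'
#' @param sets a single `protein_channel_set` or a list of them.
#' @param path output file path.
#' @export
write_profile_json <- function(sets, path) {
  if (inherits(sets, "protein_channel_set")) sets <- list(sets)
  payload <- lapply(sets, function(s) {
    list(protein_id = jsonlite::unbox(s$protein_id),
         species = jsonlite::unbox(s$species),
         enzyme = jsonlite::unbox(s$enzyme),
         subunit = jsonlite::unbox(s$subunit),
         source = jsonlite::unbox(s$source),
         channels = lapply(s$channels, function(ch) {
           list(channel_id = jsonlite::unbox(ch$channel_id),
                nodes = ch$nodes)
         }))
  })
  writeLines(jsonlite::toJSON(payload, digits = NA, dataframe = "rows"), path)
  invisible(path)
}

#' Read protein channel sets from the profile JSON dialect
#'
#' @param path input file path (see [write_profile_json()] for the dialect).
#' @return a list of `protein_channel_set` objects, node order preserved.
#' @export
read_profile_json <- function(path) {
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed profile JSON in '", path,
                                           "': ", conditionMessage(e), call. = FALSE))
  if (!is.list(raw))
    stop("profile JSON must be a top-level array of protein objects", call. = FALSE)
  lapply(seq_along(raw), function(i) {
    p <- raw[[i]]
    need <- c("protein_id", "species", "enzyme", "subunit", "source", "channels")
    miss <- setdiff(need, names(p))
    if (length(miss))
      stop("protein record ", i, " is missing field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    channels <- lapply(seq_along(p$channels), function(j) {
      ch <- p$channels[[j]]
      if (is.null(ch$channel_id) || is.null(ch$nodes))
        stop("protein record ", i, ", channel ", j,
             ": need channel_id and nodes", call. = FALSE)
      get_col <- function(field) vapply(ch$nodes, function(nd) {
        v <- nd[[field]]
        if (is.null(v) || !is.numeric(v))
          stop("protein record ", i, ", channel '", ch$channel_id,
               "': node missing numeric field '", field, "'", call. = FALSE)
        as.numeric(v)
      }, numeric(1))
      nodes <- data.frame(x = get_col("x"), y = get_col("y"),
                          z = get_col("z"), r = get_col("r"))
      if (any(nodes$r <= 0))
        stop("protein record ", i, ", channel '", ch$channel_id,
             "': node radius must be > 0", call. = FALSE)
      channel_profile(as.character(ch$channel_id), nodes)
    })
    protein_channel_set(p$protein_id, p$species, p$enzyme, p$subunit,
                        p$source, channels)
  })
}

# ---- profile CSV (tunnel-tool export compatibility) ------------------------

#' Write channel profiles to CSV
#'
#' Header `channel_id,x,y,z,r`, comma-delimited, `.` decimal separator; the
#' rows of each channel are contiguous and in path order.
#'
#' @param profiles a single `channel_profile` or a list of them.
#' @param path output file path.
#' @export
write_profile_csv <- function(profiles, path) {
  if (inherits(profiles, "channel_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(ch)
    cbind(channel_id = ch$channel_id, ch$nodes)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read channel profiles from CSV
#'
#' Expects columns `channel_id, x, y, z, r`; the rows of each channel must be
#' contiguous and in path order (interleaved channel ids are rejected).
#'
#' @param path input file path.
#' @return a list of `channel_profile` objects, one per distinct channel id.
#' @export
read_profile_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel_id", "x", "y", "z", "r")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("profile CSV is missing required column(s): ",
         paste(miss, collapse = ", "), " (header must contain ",
         paste(need, collapse = ","), ")", call. = FALSE)
  runs <- rle(as.character(df$channel_id))
  if (anyDuplicated(runs$values))
    stop("rows of channel '", runs$values[duplicated(runs$values)][1],
         "' are not contiguous; the CSV dialect requires each channel's rows ",
         "to be consecutive and in path order", call. = FALSE)
  lapply(split(df, factor(df$channel_id, levels = runs$values)), function(g)
    channel_profile(g$channel_id[1], g[, c("x", "y", "z", "r")]))
}

# ---- PDB structures --------------------------------------------------------

#' Read a PDB structure into an atom set
#'
#' Keeps all ATOM and HETATM records from all chains and models. Van der
#' Waals radii are assigned per element from a built-in table (C 1.70,
#' N 1.55, O 1.52, S 1.80, H 1.20 Angstrom); unknown elements get the default
#' 1.70 Angstrom with a warning.
#'
#' @param path PDB file path.
#' @return an object of class `atom_set`: a `data.frame` with columns
#'   `x`, `y`, `z`, `vdw`, `name`, `element`.
#' @export
read_structure_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("cannot read PDB file '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0)
    stop("no ATOM/HETATM records in '", path, "'", call. = FALSE)
  elem <- toupper(trimws(at$elesy))
  blank <- is.na(elem) | elem == ""
  # fall back to the first alphabetic character of the atom name
  elem[blank] <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                     gsub("^[0-9]+", "", trimws(at$elety[blank]))), 1, 1))
  vdw <- unname(VDW_RADII[elem])
  unknown <- is.na(vdw)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(elem[unknown]), collapse = ", "),
            ": using default van der Waals radius ", VDW_DEFAULT, " Angstrom",
            call. = FALSE)
    vdw[unknown] <- VDW_DEFAULT
  }
  atom_set(at$x, at$y, at$z, vdw, name = trimws(at$elety), element = elem)
}

#' Construct an atom set
#'
#' @param x,y,z atom center coordinates in Angstrom.
#' @param vdw van der Waals radii in Angstrom, strictly positive.
#' @param name atom names; `element` element symbols.
#' @param element element symbols.
#' @return an object of class `atom_set` (a `data.frame`).
#' @export
atom_set <- function(x, y, z, vdw, name = "C", element = "C") {
  if (length(x) == 0) stop("an atom set must be non-empty", call. = FALSE)
  if (!all(is.finite(c(x, y, z))))
    stop("atom coordinates must be finite", call. = FALSE)
  if (any(!is.finite(vdw) | vdw <= 0))
    stop("van der Waals radii must be finite and > 0", call. = FALSE)
  structure(data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                       vdw = as.numeric(vdw),
                       name = as.character(name), element = as.character(element)),
            class = c("atom_set", "data.frame"))
}

#' Write an atom set to a PDB file
#'
#' Atoms are written as HETATM records of a single chain via bio3d.
#'
#' @param atoms an `atom_set`.
#' @param path output file path.
#' @export
write_structure_pdb <- function(atoms, path) {
  stopifnot(inherits(atoms, "atom_set"))
  xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("HETATM", nrow(atoms)),
                   resno = seq_len(nrow(atoms)),
                   resid = rep("TUB", nrow(atoms)),
                   elety = atoms$name,
                   elesy = atoms$element)
  invisible(path)
}

# ---- measurement/metadata tables -------------------------------------------

#' Construct a measurement dataset
#'
#' One row per measured protein: species metadata (with the optimum growth
#' temperature and its temperature class) plus the three total channel
#' dimensions. The temperature class is always (re)derived from `t_opt` via
#' [assign_class()].
#'
#' @param df a `data.frame` with columns `species`, `enzyme`, `subunit`,
#'   `t_opt` (degrees C), `length` (Angstrom), `surface` (Angstrom^2),
#'   `volume` (Angstrom^3).
#' @return an object of class `measurement_dataset` (a `data.frame` with an
#'   added `t_class` column).
#' @export
measurement_dataset <- function(df) {
  need <- c("species", "enzyme", "subunit", "t_opt", "length", "surface", "volume")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("measurement dataset is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) > 0) {
    if (!is.numeric(df$t_opt) || any(!is.finite(df$t_opt)))
      stop("t_opt must be numeric and finite", call. = FALSE)
    if (any(df$t_opt <= 0 | df$t_opt >= 130))
      stop("t_opt out of the supported range (0, 130) degrees C", call. = FALSE)
    for (dim in c("length", "surface", "volume")) {
      v <- df[[dim]]
      if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
        stop("measurement column '", dim, "' must be numeric, finite and >= 0",
             call. = FALSE)
    }
    key <- df[, c("species", "enzyme", "subunit")]
    if (anyDuplicated(key))
      stop("duplicate (species, enzyme, subunit) rows in dataset", call. = FALSE)
    df$t_class <- assign_class(df$t_opt)
  } else {
    df$t_class <- character(0)
  }
  out <- df[, c("species", "enzyme", "subunit", "t_opt", "t_class",
                "length", "surface", "volume")]
  rownames(out) <- NULL
  structure(out, class = c("measurement_dataset", "data.frame"))
}

#' Read a measurement dataset from a TSV table
#'
#' Expects a tab-separated table with columns `species`, `enzyme`, `subunit`,
#' `t_opt`, `length`, `surface`, `volume`. The temperature class is assigned
#' from `t_opt`. An empty table (header only) yields an empty dataset.
#' Externally produced tables with different headers can be ingested through
#' `col_map`, a named character vector mapping the canonical column names to
#' the file's headers, e.g. `c(species = "Species name", t_opt = "Topt")`.
#'
#' @param path input TSV path.
#' @param col_map optional named character vector renaming file columns to
#'   the canonical ones.
#' @return a `measurement_dataset`.
#' @export
read_dataset_table <- function(path, col_map = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(df))
    if (length(missing_src))
      stop("col_map refers to column(s) not in the file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    names(df)[match(col_map, names(df))] <- names(col_map)
  }
  need <- c("species", "enzyme", "subunit", "t_opt", "length", "surface", "volume")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("dataset table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) > 0) {
    t_num <- suppressWarnings(as.numeric(df$t_opt))
    if (any(is.na(t_num)))
      stop("non-numeric t_opt at row ", which(is.na(t_num))[1], call. = FALSE)
    df$t_opt <- t_num
  }
  measurement_dataset(df)
}

#' Write a measurement dataset to a TSV table
#'
#' @param dataset a `measurement_dataset`.
#' @param path output TSV path.
#' @export
write_dataset_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "measurement_dataset"))
  write.table(as.data.frame(dataset)[, c("species", "enzyme", "subunit", "t_opt",
                                         "length", "surface", "volume")],
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
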