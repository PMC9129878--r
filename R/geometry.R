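# Pore-axis frame construction, ion pore coordinates, permeation-event
# counting, and the binned-profile container shared by all analysis stages.

#' Construct the pore-axis frame from two atom selections
#'
#' The pore axis is defined by two centres, each the unweighted centroid of a
#' group of atoms (e.g. the C-alpha rings flanking a constriction). The axis
#' unit vector points from centre B to centre A; the origin is their
#' midpoint, which places z = 0 at the constriction when the two centres
#' flank it.
#'
#' @param coords_a numeric matrix (n x 3) of atom positions defining centre A,
#'   in Angstrom.
#' @param coords_b numeric matrix (m x 3) for centre B.
#' @param flip if `TRUE`, reverse the axis direction (sign convention:
#'   positive z is the luminal side by default).
#' @return An object of class `pore_axis`: list with `center_a`, `center_b`,
#'   `origin` and unit vector `axis`.
#' @export
#' @examples
#' ax <- pore_axis(rbind(c(0, 0, -0.5)), rbind(c(0, 0, 0.5)))
#' ax$origin  # c(0, 0, 0)
pore_axis <- function(coords_a, coords_b, flip = FALSE) {
  coords_a <- rbind(coords_a)
  coords_b <- rbind(coords_b)
  if (nrow(coords_a) == 0L || nrow(coords_b) == 0L)
    stop("empty atom selection")
  if (ncol(coords_a) != 3L || ncol(coords_b) != 3L)
    stop("coordinates must have three columns")
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  d <- ca - cb
  len <- sqrt(sum(d^2))
  if (len < 1e-6)
    stop("degenerate axis: centres A and B coincide")
  u <- d / len
  if (flip) u <- -u
  structure(
    list(center_a = ca, center_b = cb, origin = (ca + cb) / 2, axis = u),
    class = "pore_axis"
  )
}

#' Project ion positions into pore coordinates (z, R)
#'
#' z is the signed projection of the ion position onto the pore axis
#' (origin at the midpoint of the two axis centres); R is the perpendicular
#' distance to the axis. With a periodic `box`, displacements from the origin
#' follow the minimum-image convention.
#'
#' @param positions numeric matrix (n x 3) of ion positions, Angstrom.
#' @param axis a [pore_axis()] object.
#' @param box optional orthorhombic box lengths (length-3), Angstrom.
#' @return data.frame with columns `z` and `r` (Angstrom).
#' @export
#' @examples
#' ax <- pore_axis(rbind(c(0, 0, 1)), rbind(c(0, 0, -1)))
#' pore_coordinates(rbind(c(3, 4, 5)), ax)  # z = 5, r = 5
pore_coordinates <- function(positions, axis, box = NULL) {
  stopifnot(inherits(axis, "pore_axis"))
  positions <- rbind(positions)
  d <- sweep(positions, 2L, axis$origin)
  if (!is.null(box)) {
    stopifnot(length(box) == 3L, all(box > 0))
    d <- sweep(d, 2L, box, function(x, b) x - b * round(x / b))
  }
  z <- as.numeric(d %*% axis$axis)
  perp <- d - outer(z, axis$axis)
  data.frame(z = z, r = sqrt(rowSums(perp^2)))
}

#' Count completed permeation events in a pore-coordinate time series
#'
#' An event is a completed transit of one ion from beyond one axial bound to
#' beyond the other, during which the ion stayed within `r0` of the pore axis
#' while inside the pore region. Excursions that re-exit on the entry side,
#' or transits during which R exceeded `r0` inside the pore, are not counted.
#' Inward means from above `z_hi` (luminal side) to below `z_lo`.
#'
#' @param z per-frame axial coordinate of one ion, Angstrom.
#' @param r per-frame distance to the axis, Angstrom.
#' @param z_lo,z_hi pore-region bounds (default -15 and +15 Angstrom).
#' @param r0 maximum axial distance for a valid transit (default 10).
#' @return list with integer counts `inward` and `outward`.
#' @export
#' @examples
#' z <- seq(15.5, -15.5, length.out = 100)
#' count_permeations(z, rep(0, 100))$inward  # 1
count_permeations <- function(z, r, z_lo = -15, z_hi = 15, r0 = 10) {
  if (length(z) == 0L) stop("empty series")
  if (length(z) != length(r)) stop("z and r series differ in length")
  if (z_lo >= z_hi) stop("z_lo must be below z_hi")
  inward <- 0L
  outward <- 0L
  entered_from <- NA_character_
  valid <- FALSE
  region <- function(zi) {
    if (zi > z_hi) "high" else if (zi < z_lo) "low" else "inside"
  }
  prev <- region(z[1])
  if (prev == "inside") valid <- FALSE
  for (i in seq_along(z)) {
    cur <- region(z[i])
    if (cur == "inside") {
      if (prev != "inside") {
        entered_from <- prev
        valid <- TRUE
      }
      if (r[i] > r0) valid <- FALSE
    } else if (prev == "inside") {
      if (!is.na(entered_from) && valid && cur != entered_from) {
        if (entered_from == "high") inward <- inward + 1L
        else outward <- outward + 1L
      }
      entered_from <- NA_character_
      valid <- FALSE
    }
    prev <- cur
  }
  list(inward = inward, outward = outward)
}

#' Binned profile along the pore axis
#'
#' Container for any per-bin quantity along z: occupancy, free energy,
#' coordination number, electrostatic energy. Bin centres must be uniformly
#' spaced and strictly increasing; `count` carries the per-bin summed
#' statistical weight (or raw tallies) backing each value.
#'
#' @param bin_centers uniformly spaced bin centres, Angstrom.
#' @param values per-bin values (`NA` marks masked, undefined bins).
#' @param counts per-bin effective counts (non-negative).
#' @param quantity,units metadata strings.
#' @param r0 axial cut-off used when assigning ions to bins, if any.
#' @return data.frame of class `pore_profile` with columns `z`, `value`,
#'   `count` and attributes `quantity`, `units`, `r0`.
#' @export
pore_profile <- function(bin_centers, values, counts = rep(0, length(values)),
                         quantity = "value", units = "", r0 = NA_real_) {
  n <- length(bin_centers)
  stopifnot(length(values) == n, length(counts) == n, n >= 1)
  if (n > 1) {
    dz <- diff(bin_centers)
    if (any(dz <= 0)) stop("bin centres must be strictly increasing")
    if (max(abs(dz - dz[1])) > 1e-9) stop("bin spacing must be uniform")
  }
  if (any(counts < 0)) stop("effective counts must be non-negative")
  structure(
    data.frame(z = bin_centers, value = values, count = counts),
    quantity = quantity, units = units, r0 = r0,
    class = c("pore_profile", "data.frame")
  )
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf("pore_profile: %s [%s], %d bins, z in [%g, %g] A\n",
              attr(x, "quantity"), attr(x, "units"), nrow(x),
              min(x$z), max(x$z)))
  invisible(x)
}

#' Write a profile to TSV
#'
#' Header comment lines carry the quantity and units; columns are
#' `z_center`, `value`, `effective_count`. Values are printed with 10
#' significant digits so that a read/write round trip is bit-stable at that
#' precision.
#'
#' @param profile a [pore_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "pore_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# quantity\t", attr(profile, "quantity")),
    paste0("# units\t", attr(profile, "units")),
    paste0("# r0\t", sprintf("%.10g", attr(profile, "r0"))),
    "z_center\tvalue\teffective_count"
  ), con)
  writeLines(sprintf("%.10g\t%.10g\t%.10g",
                     profile$z, profile$value, profile$count), con)
  invisible(path)
}

#' Read a profile written by [write_profile_tsv()]
#'
#' @param path file path.
#' @return a [pore_profile()].
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, "\t"), meta, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, "\t"), "", hit[1]) else ""
  }
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t")
  pore_profile(tab$z_center, tab$value, tab$effective_count,
               quantity = get_meta("quantity"), units = get_meta("units"),
               r0 = suppressWarnings(as.numeric(get_meta("r0"))))
}

#' Write a tabular trajectory (frame, time, species, x, y, z)
#'
#' The internal plain-text trajectory format produced by the toy simulator
#' and accepted by the analysis stages.
#'
#' @param traj data.frame with columns `frame`, `time`, `species`, `x`, `y`,
#'   `z` (time in ps, coordinates in Angstrom).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  need <- c("frame", "time", "species", "x", "y", "z")
  if (!all(need %in% names(traj))) stop("missing trajectory columns")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(need, collapse = "\t"), con)
  writeLines(sprintf("%d\t%.10g\t%s\t%.10g\t%.10g\t%.10g",
                     as.integer(traj$frame), traj$time,
                     as.character(traj$species), traj$x, traj$y, traj$z), con)
  invisible(path)
}

#' Read a tabular trajectory written by [write_trajectory_tsv()]
#' @param path file path.
#' @return data.frame with the trajectory columns.
#' @export
read_trajectory_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t",
             colClasses = c("integer", "numeric", "character",
                            "numeric", "numeric", "numeric"))
}

#' Read an MD trajectory via standard readers (PDB topology + DCD coords)
#'
#' Thin wrapper over the bio3d readers for externally produced trajectories.
#' Returns per-frame coordinate matrices plus the atom table, ready for
#' [pore_axis()] / [pore_coordinates()] selections. Requires the suggested
#' package bio3d.
#'
#' @param pdb_path PDB topology path.
#' @param dcd_path DCD coordinate path.
#' @return list with `atoms` (bio3d atom data.frame) and `frames` (list of
#'   n_atoms x 3 coordinate matrices, Angstrom).
#' @export
read_md_trajectory <- function(pdb_path, dcd_path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB/DCD requires the bio3d package")
  pdb <- bio3d::read.pdb(pdb_path)
  dcd <- bio3d::read.dcd(dcd_path, verbose = FALSE)
  frames <- lapply(seq_len(nrow(dcd)), function(i) {
    matrix(dcd[i, ], ncol = 3, byrow = TRUE)
  })
  list(atoms = pdb$atom, frames = frames)
}
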