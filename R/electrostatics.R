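# Continuum electrostatics: heterogeneous dielectric lattice construction,
# finite-difference linearized Poisson solve, and ion-protein interaction
# energies and their axial profiles.

#' Dielectric region specification
#'
#' Default permittivities: protein 2, implicit membrane 2, bulk water 80,
#' pore water 40, ion cavity 2 (protein and ion values of 1 are also in
#' common use and configurable). Geometry: membrane slab thickness 28.8
#' Angstrom centred at z = 0; low-dielectric pore-water cylinder of radius
#' 18 and height 28.8 Angstrom on the pore axis; probe radius 1 Angstrom for
#' the molecular surface.
#'
#' @param eps_protein,eps_membrane,eps_bulk,eps_pore_water,eps_ion_cavity
#'   relative permittivities (all >= 1).
#' @param membrane_thickness,pore_cylinder_radius,pore_cylinder_height,probe_radius
#'   geometry, Angstrom.
#' @return list of class `region_spec`.
#' @export
region_spec <- function(eps_protein = 2, eps_membrane = 2, eps_bulk = 80,
                        eps_pore_water = 40, eps_ion_cavity = 2,
                        membrane_thickness = 28.8, pore_cylinder_radius = 18,
                        pore_cylinder_height = 28.8, probe_radius = 1) {
  eps <- c(eps_protein, eps_membrane, eps_bulk, eps_pore_water,
           eps_ion_cavity)
  stopifnot(all(eps >= 1), membrane_thickness > 0, pore_cylinder_radius > 0,
            pore_cylinder_height > 0, probe_radius > 0)
  structure(list(eps_protein = eps_protein, eps_membrane = eps_membrane,
                 eps_bulk = eps_bulk, eps_pore_water = eps_pore_water,
                 eps_ion_cavity = eps_ion_cavity,
                 membrane_thickness = membrane_thickness,
                 pore_cylinder_radius = pore_cylinder_radius,
                 pore_cylinder_height = pore_cylinder_height,
                 probe_radius = probe_radius),
            class = "region_spec")
}

#' Cubic lattice specification
#'
#' @param n points per dimension (default 150).
#' @param spacing lattice spacing, Angstrom (default 1).
#' @param center lattice centre (length-3), Angstrom.
#' @return list of class `lattice_spec` with node coordinate vectors `x`,
#'   `y`, `z`.
#' @export
lattice_spec <- function(n = 150, spacing = 1, center = c(0, 0, 0)) {
  stopifnot(n >= 8, spacing > 0, length(center) == 3)
  half <- (n - 1) / 2 * spacing
  structure(list(n = n, spacing = spacing, center = center,
                 x = center[1] + seq(-half, half, length.out = n),
                 y = center[2] + seq(-half, half, length.out = n),
                 z = center[3] + seq(-half, half, length.out = n)),
            class = "lattice_spec")
}

# region codes
.REGION <- c(bulk = 0L, membrane = 1L, pore_water = 2L, ion_cavity = 3L,
             protein = 4L)

#' Build the heterogeneous dielectric lattice
#'
#' Region precedence (highest wins): protein interior > ion cavity >
#' pore-water cylinder > membrane slab > bulk. The protein interior is the
#' union of atom spheres inflated by the probe radius, followed by one
#' morphological closing pass (6-neighbour dilation then erosion) as an
#' approximation to probe-reentrant surface smoothing.
#'
#' @param atoms `NULL` or data.frame with columns `x`, `y`, `z`, `radius`
#'   (Angstrom). Atoms must lie inside the lattice.
#' @param region a [region_spec()].
#' @param grid a [lattice_spec()].
#' @param ion_positions optional matrix (n x 3) of ion centres carving
#'   `eps_ion_cavity` spheres of `ion_radius`.
#' @param ion_radius cavity radius, Angstrom (default 2).
#' @return list of class `dielectric_lattice`: `eps` and integer `region`
#'   arrays (n^3), plus `grid` and `region_spec`.
#' @export
dielectric_map <- function(atoms = NULL, region = region_spec(),
                           grid = lattice_spec(), ion_positions = NULL,
                           ion_radius = 2) {
  stopifnot(inherits(region, "region_spec"), inherits(grid, "lattice_spec"))
  n <- grid$n
  reg <- array(.REGION[["bulk"]], dim = c(n, n, n))
  # membrane slab
  zmask <- abs(grid$z) <= region$membrane_thickness / 2
  reg[, , zmask] <- .REGION[["membrane"]]
  # pore-water cylinder (centred on the z axis at the membrane mid-plane)
  r2 <- outer(grid$x^2, grid$y^2, "+")
  cyl_xy <- r2 <= region$pore_cylinder_radius^2
  zcyl <- abs(grid$z) <= region$pore_cylinder_height / 2
  for (k in which(zcyl)) {
    slab <- reg[, , k]
    slab[cyl_xy] <- .REGION[["pore_water"]]
    reg[, , k] <- slab
  }
  mark_spheres <- function(reg, centers, radii, code) {
    centers <- rbind(centers)
    for (a in seq_len(nrow(centers))) {
      ctr <- as.numeric(centers[a, 1:3])
      rad <- radii[a]
      ix <- which(abs(grid$x - ctr[1]) <= rad)
      iy <- which(abs(grid$y - ctr[2]) <= rad)
      iz <- which(abs(grid$z - ctr[3]) <= rad)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx2 <- (grid$x[ix] - ctr[1])^2
      dy2 <- (grid$y[iy] - ctr[2])^2
      dz2 <- (grid$z[iz] - ctr[3])^2
      d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      sub <- reg[ix, iy, iz, drop = FALSE]
      sub[d2 <= rad^2] <- code
      reg[ix, iy, iz] <- sub
    }
    reg
  }
  if (!is.null(ion_positions)) {
    reg <- mark_spheres(reg, ion_positions,
                        rep(ion_radius, nrow(rbind(ion_positions))),
                        .REGION[["ion_cavity"]])
  }
  if (!is.null(atoms) && nrow(atoms) > 0) {
    lim <- range(grid$x)
    if (any(atoms$x < lim[1] | atoms$x > lim[2] |
            atoms$y < lim[1] - grid$center[1] + grid$center[2] |
            atoms$y > lim[2] - grid$center[1] + grid$center[2] |
            atoms$z < min(grid$z) | atoms$z > max(grid$z)))
      stop("protein extends beyond the lattice")
    inflated <- atoms$radius + region$probe_radius
    reg <- mark_spheres(reg, as.matrix(atoms[, c("x", "y", "z")]),
                        inflated, .REGION[["protein"]])
    # one closing pass: dilation then erosion, 6-neighbourhood
    prot <- reg == .REGION[["protein"]]
    dil <- prot
    dil[-1, , ] <- dil[-1, , ] | prot[-n, , ]
    dil[-n, , ] <- dil[-n, , ] | prot[-1, , ]
    dil[, -1, ] <- dil[, -1, ] | prot[, -n, ]
    dil[, -n, ] <- dil[, -n, ] | prot[, -1, ]
    dil[, , -1] <- dil[, , -1] | prot[, , -n]
    dil[, , -n] <- dil[, , -n] | prot[, , -1]
    ero <- dil
    ero[-1, , ] <- ero[-1, , ] & dil[-n, , ]
    ero[-n, , ] <- ero[-n, , ] & dil[-1, , ]
    ero[, -1, ] <- ero[, -1, ] & dil[, -n, ]
    ero[, -n, ] <- ero[, -n, ] & dil[, -1, ]
    ero[, , -1] <- ero[, , -1] & dil[, , -n]
    ero[, , -n] <- ero[, , -n] & dil[, , -1]
    add <- ero & !prot
    # closing may only add points; protein still wins over lower regions
    reg[add] <- .REGION[["protein"]]
  }
  eps_of <- c(region$eps_bulk, region$eps_membrane, region$eps_pore_water,
              region$eps_ion_cavity, region$eps_protein)
  eps <- array(eps_of[reg + 1L], dim = dim(reg))
  structure(list(eps = eps, region = reg, grid = grid,
                 region_spec = region),
            class = "dielectric_lattice")
}

# Trilinear spread of point charges (e) onto the lattice nodes.
#' @noRd
spread_charges <- function(charges, grid) {
  n <- grid$n
  rho <- array(0, dim = c(n, n, n))
  if (is.null(charges) || nrow(charges) == 0) return(rho)
  for (a in seq_len(nrow(charges))) {
    fx <- (charges$x[a] - grid$x[1]) / grid$spacing
    fy <- (charges$y[a] - grid$y[1]) / grid$spacing
    fz <- (charges$z[a] - grid$z[1]) / grid$spacing
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 >= n - 1 || j0 >= n - 1 ||
        k0 >= n - 1)
      stop("charge outside the lattice")
    tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) tx else 1 - tx) * (if (dj) ty else 1 - ty) *
        (if (dk) tz else 1 - tz)
      rho[i0 + di + 1, j0 + dj + 1, k0 + dk + 1] <-
        rho[i0 + di + 1, j0 + dj + 1, k0 + dk + 1] + w * charges$q[a]
    }
  }
  rho
}

# Coulomb potential of all charges screened by a uniform permittivity,
# evaluated at every lattice node (used as Dirichlet boundary + initial
# guess). Singularity capped at half a lattice spacing.
#' @noRd
coulomb_guess <- function(charges, grid, eps) {
  n <- grid$n
  phi <- array(0, dim = c(n, n, n))
  if (is.null(charges) || nrow(charges) == 0) return(phi)
  k <- permeon_constants$coulomb / eps
  for (a in seq_len(nrow(charges))) {
    dx2 <- (grid$x - charges$x[a])^2
    dy2 <- (grid$y - charges$y[a])^2
    dz2 <- (grid$z - charges$z[a])^2
    r <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    r <- pmax(r, grid$spacing / 2)
    phi <- phi + k * charges$q[a] / r
  }
  phi
}

#' Solve the linearized Poisson equation on the lattice
#'
#' Finite-difference solve of \eqn{\nabla\cdot(\epsilon\nabla\Phi) = -4\pi
#' k \rho} (zero ionic strength) by successive over-relaxation, with
#' Dirichlet boundary values from the analytic Coulomb potential of the
#' charges screened by the bulk permittivity. Potentials are in
#' kcal/(mol e) for charges in e and distances in Angstrom.
#'
#' @param charges data.frame with columns `x`, `y`, `z` (Angstrom) and `q`
#'   (e); spread onto the lattice trilinearly.
#' @param dielectric a [dielectric_map()].
#' @param tol convergence threshold on the largest potential update per
#'   sweep, kcal/(mol e).
#' @param max_iter iteration cap (error on non-convergence).
#' @param omega over-relaxation factor; default `2 / (1 + pi/n)`.
#' @param boundary_phi optional n^3 array of Dirichlet values overriding the
#'   bulk-Coulomb default (its interior also serves as the initial guess);
#'   useful when an analytic far-field solution is known.
#' @return list of class `potential_lattice`: `phi` (n^3 array), `grid`,
#'   `iterations`, `max_update`.
#' @export
solve_poisson <- function(charges, dielectric, tol = 1e-5, max_iter = 20000,
                          omega = NULL, boundary_phi = NULL) {
  stopifnot(inherits(dielectric, "dielectric_lattice"))
  grid <- dielectric$grid
  n <- grid$n
  if (is.null(omega)) omega <- 2 / (1 + pi / n)
  rho <- spread_charges(charges, grid)
  phi0 <- if (is.null(boundary_phi)) {
    coulomb_guess(charges, grid, dielectric$region_spec$eps_bulk)
  } else {
    stopifnot(identical(dim(boundary_phi), rep(n, 3L) + 0L) ||
                identical(dim(boundary_phi), as.integer(rep(n, 3L))))
    boundary_phi
  }
  res <- cpp_solve_poisson(as.numeric(dielectric$eps), as.numeric(rho),
                           as.numeric(phi0), n, n, n, grid$spacing,
                           tol, as.integer(max_iter), omega)
  structure(list(phi = res$phi, grid = grid, iterations = res$iterations,
                 max_update = res$max_update),
            class = "potential_lattice")
}

#' Trilinear interpolation of a lattice potential
#'
#' @param potential a [solve_poisson()] result.
#' @param positions matrix (n x 3) of evaluation points, Angstrom (inside
#'   the lattice).
#' @return potential values, kcal/(mol e).
#' @export
interpolate_potential <- function(potential, positions) {
  stopifnot(inherits(potential, "potential_lattice"))
  grid <- potential$grid
  positions <- rbind(positions)
  n <- grid$n
  vapply(seq_len(nrow(positions)), function(a) {
    fx <- (positions[a, 1] - grid$x[1]) / grid$spacing
    fy <- (positions[a, 2] - grid$y[1]) / grid$spacing
    fz <- (positions[a, 3] - grid$z[1]) / grid$spacing
    i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
    if (i0 < 0 || j0 < 0 || k0 < 0 || i0 >= n - 1 || j0 >= n - 1 ||
        k0 >= n - 1)
      stop("position outside the lattice")
    tx <- fx - i0; ty <- fy - j0; tz <- fz - k0
    acc <- 0
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      w <- (if (di) tx else 1 - tx) * (if (dj) ty else 1 - ty) *
        (if (dk) tz else 1 - tz)
      acc <- acc + w * potential$phi[i0 + di + 1, j0 + dj + 1, k0 + dk + 1]
    }
    acc
  }, numeric(1))
}

#' Ion-protein electrostatic interaction energy
#'
#' \eqn{E_k = q_k \Phi_k} where \eqn{\Phi_k} is the potential generated by
#' the protein charges alone (the ion's cavity belongs in the dielectric
#' map, its charge does not), interpolated at the ion position.
#'
#' @param q_ion ion charge, e.
#' @param potential a [solve_poisson()] result computed from protein charges
#'   only.
#' @param position length-3 ion position, Angstrom.
#' @return interaction energy, kcal/mol.
#' @export
ion_protein_energy <- function(q_ion, potential, position) {
  q_ion * interpolate_potential(potential, rbind(position))
}

#' Reweighted ion-protein electrostatic energy profile
#'
#' For each snapshot: builds the dielectric map (protein interior plus the
#' ion cavities), solves the linearized Poisson equation with the protein
#' charges only, evaluates \eqn{E_k = q_k \Phi(r_k)} per ion, and averages
#' along the pore axis with the snapshot weights. This is a lattice solve
#' per frame: keep grids modest.
#'
#' @param frames list of per-snapshot lists: `protein` (data.frame `x`, `y`,
#'   `z`, `q`, `radius`), `ions` (data.frame `x`, `y`, `z`, `q`).
#' @param axis a [pore_axis()].
#' @param weights a [snapshot_weights()], one weight per frame.
#' @param breaks axial bin boundaries, Angstrom.
#' @param region a [region_spec()].
#' @param grid a [lattice_spec()].
#' @param r0_pore axial-distance cut-off for binning (default 10).
#' @param ion_radius ion cavity radius, Angstrom.
#' @param ... passed to [solve_poisson()].
#' @return a [pore_profile()] of mean interaction energies, kcal/mol.
#' @export
electrostatic_profile <- function(frames, axis, weights, breaks,
                                  region = region_spec(),
                                  grid = lattice_spec(n = 48),
                                  r0_pore = 10, ion_radius = 2, ...) {
  rows <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    dm <- dielectric_map(f$protein, region, grid,
                         ion_positions = as.matrix(f$ions[, c("x", "y", "z")]),
                         ion_radius = ion_radius)
    pot <- solve_poisson(
      data.frame(x = f$protein$x, y = f$protein$y, z = f$protein$z,
                 q = f$protein$q), dm, ...)
    e <- f$ions$q * interpolate_potential(pot,
                                          as.matrix(f$ions[, c("x", "y", "z")]))
    pc <- pore_coordinates(as.matrix(f$ions[, c("x", "y", "z")]), axis)
    data.frame(snapshot = i, z = pc$z, r = pc$r, obs = e)
  })
  ions <- do.call(rbind, rows)
  observable_profile(ions, weights, breaks, r0 = r0_pore,
                     quantity = "ion_protein_electrostatic_energy",
                     units = "kcal/mol")
}

#' Read protein atoms with charges and radii from a PQR-style table
#'
#' Accepts whitespace-separated PQR lines (`ATOM`/`HETATM` records with
#' trailing charge and radius columns) and returns the atom table used by
#' [dielectric_map()] and [solve_poisson()].
#'
#' @param path PQR file path.
#' @return data.frame with `x`, `y`, `z`, `q`, `radius`.
#' @export
read_pqr_atoms <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (length(lines) == 0L) stop("no atom records found")
  parts <- strsplit(trimws(lines), "\\s+")
  as.data.frame(do.call(rbind, lapply(parts, function(p) {
    nf <- length(p)
    as.numeric(p[(nf - 4):nf])
  })) |> (\(m) {colnames(m) <- c("x", "y", "z", "q", "radius"); m})())
}
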