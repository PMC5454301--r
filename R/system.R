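#' Orthorhombic periodic simulation box
#'
#' Houses the cell geometry: the cross-sectional area perpendicular to the
#' heat-flux axis (Lx*Ly for flux along z) enters the flux bookkeeping.
#'
#' @param lx,ly,lz box edge lengths in Angstrom (all > 0)
#' @param periodic logical length-3, periodicity per axis
#' @param flux_axis axis along which heat flows; must be periodic
#' @return an object of class `sim_box`
#' @export
sim_box <- function(lx, ly, lz, periodic = c(TRUE, TRUE, TRUE), flux_axis = "z") {
  stopifnot(lx > 0, ly > 0, lz > 0, length(periodic) == 3)
  ax <- match.arg(flux_axis, c("x", "y", "z"))
  if (!periodic[match(ax, c("x", "y", "z"))])
    stop("flux axis must be periodic")
  structure(list(lengths = c(x = lx, y = ly, z = lz),
                 periodic = periodic, flux_axis = ax),
            class = "sim_box")
}

#' @export
print.sim_box <- function(x, ...) {
  cat(sprintf("<sim_box> %.3f x %.3f x %.3f A, flux axis %s\n",
              x$lengths[1], x$lengths[2], x$lengths[3], x$flux_axis))
  invisible(x)
}

#' Cross-sectional area perpendicular to the flux axis
#' @param box a [sim_box()]
#' @return area in A^2
#' @export
box_area <- function(box) {
  l <- box$lengths
  switch(box$flux_axis, x = l[2] * l[3], y = l[1] * l[3], z = l[1] * l[2])[[1]]
}

#' Box volume in A^3
#' @param box a [sim_box()]
#' @export
box_volume <- function(box) prod(box$lengths)

#' A collection of coarse-grained particles
#'
#' Positions in Angstrom, velocities in A/fs, masses in amu, charges in e.
#' Each particle carries a bead type (index into the forcefield tables), a
#' molecule id, a group label (`WATER`, `HEAD` or `TAIL`) and, for lipid
#' beads, a leaflet id (0 or 1; `NA` for solvent).
#'
#' @param positions,velocities n x 3 numeric matrices
#' @param mass,charge numeric length n
#' @param type integer bead-type index (1-based)
#' @param mol_id integer molecule id
#' @param group character, one of WATER/HEAD/TAIL per particle
#' @param leaflet integer 0/1 for lipid beads, NA for solvent
#' @return an object of class `particle_system`
#' @export
particle_system <- function(positions, velocities = NULL, mass, charge = NULL,
                            type = NULL, mol_id = NULL, group = NULL,
                            leaflet = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  if (is.null(charge)) charge <- rep(0, n)
  if (is.null(type)) type <- rep(1L, n)
  if (is.null(mol_id)) mol_id <- seq_len(n)
  if (is.null(group)) group <- rep("WATER", n)
  if (is.null(leaflet)) leaflet <- rep(NA_integer_, n)
  if (!all(is.finite(positions)) || !all(is.finite(velocities)))
    stop("non-finite coordinates or velocities")
  if (any(mass <= 0)) stop("all masses must be positive")
  if (!all(group %in% c("WATER", "HEAD", "TAIL")))
    stop("group labels must be WATER, HEAD or TAIL")
  lip <- group %in% c("HEAD", "TAIL")
  if (any(lip & is.na(leaflet)) || any(!lip & !is.na(leaflet)))
    stop("leaflet id must be set exactly for HEAD/TAIL beads")
  structure(list(positions = positions, velocities = velocities,
                 mass = as.numeric(mass), charge = as.numeric(charge),
                 type = as.integer(type), mol_id = as.integer(mol_id),
                 group = group, leaflet = as.integer(leaflet)),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("<particle_system> %d particles (%d WATER, %d HEAD, %d TAIL)\n",
              length(x$mass), sum(x$group == "WATER"),
              sum(x$group == "HEAD"), sum(x$group == "TAIL")))
  invisible(x)
}

#' Number of particles
#' @param system a [particle_system()]
#' @export
n_particles <- function(system) length(system$mass)

#' Select particle indices by group label, leaflet and/or molecule id
#'
#' @param system a [particle_system()]
#' @param group optional character vector of group labels
#' @param leaflet optional leaflet id(s)
#' @param mol_id optional molecule id(s)
#' @return integer vector of particle indices
#' @export
select_particles <- function(system, group = NULL, leaflet = NULL, mol_id = NULL) {
  keep <- rep(TRUE, n_particles(system))
  if (!is.null(group)) keep <- keep & system$group %in% group
  if (!is.null(leaflet)) keep <- keep & !is.na(system$leaflet) & system$leaflet %in% leaflet
  if (!is.null(mol_id)) keep <- keep & system$mol_id %in% mol_id
  which(keep)
}

#' Extract a subset of a particle system (bonded terms are dropped by the
#' caller's forcefield subset; see [subset_forcefield()])
#' @param system a [particle_system()]
#' @param idx integer particle indices to keep
#' @export
subset_system <- function(system, idx) {
  particle_system(system$positions[idx, , drop = FALSE],
                  system$velocities[idx, , drop = FALSE],
                  system$mass[idx], system$charge[idx], system$type[idx],
                  system$mol_id[idx], system$group[idx], system$leaflet[idx])
}

#' Pairwise forcefield parameters
#'
#' Lennard-Jones epsilon/sigma tables per bead-type pair, a shared pair
#' cutoff, cutoff Coulomb electrostatics and harmonic bond/angle terms.
#' Bonds and angles use the half-k convention E = k/2 (r - r0)^2 and
#' E = k/2 (theta - theta0)^2.
#'
#' `coulomb_shift = "none"` is the plain truncated 1/r interaction (exact
#' closed forms inside the cutoff); `"force"` shifts both energy and force to
#' zero at the cutoff, which is what the dynamics presets use so that pairs
#' crossing the cutoff do not inject energy.
#'
#' @param eps,sigma per-type-pair matrices (or per-type vectors, combined by
#'   Lorentz-Berthelot mixing)
#' @param cutoff pair cutoff in Angstrom; must exceed max sigma
#' @param coulomb_k Coulomb constant in kcal mol^-1 A e^-2 (0 disables)
#' @param coulomb_shift "none" or "force"
#' @param lj_shift logical; shift the LJ energy to zero at the cutoff
#' @param bonds data.frame(i, j, k, r0) harmonic bonds (1-based indices)
#' @param angles data.frame(i, j, k, k_theta, theta0) with j the central bead
#'   and theta0 in radians
#' @param skin Verlet neighbour-list skin in Angstrom
#' @return an object of class `forcefield`
#' @export
forcefield_params <- function(eps, sigma, cutoff = 12, coulomb_k = 332.0637,
                              coulomb_shift = c("none", "force"),
                              lj_shift = FALSE, bonds = NULL, angles = NULL,
                              skin = 2) {
  coulomb_shift <- match.arg(coulomb_shift)
  if (is.null(dim(eps))) {
    ev <- as.numeric(eps); sv <- as.numeric(sigma)
    eps <- sqrt(outer(ev, ev))            # Lorentz-Berthelot
    sigma <- outer(sv, sv, function(a, b) (a + b) / 2)
  }
  eps <- as.matrix(eps); sigma <- as.matrix(sigma)
  stopifnot(nrow(eps) == ncol(eps), all(dim(eps) == dim(sigma)))
  if (any(eps < 0)) stop("epsilon must be >= 0")
  if (any(sigma <= 0)) stop("sigma must be > 0")
  if (cutoff <= max(sigma)) stop("cutoff must exceed the largest sigma")
  if (!is.null(bonds)) {
    bonds <- as.data.frame(bonds)
    stopifnot(all(c("i", "j", "k", "r0") %in% names(bonds)))
  }
  if (!is.null(angles)) {
    angles <- as.data.frame(angles)
    stopifnot(all(c("i", "j", "k", "k_theta", "theta0") %in% names(angles)))
  }
  structure(list(eps = eps, sigma = sigma, cutoff = cutoff,
                 coulomb_k = coulomb_k, coulomb_shift = coulomb_shift,
                 lj_shift = lj_shift, bonds = bonds, angles = angles,
                 skin = skin),
            class = "forcefield")
}

# internal: forcefield as the list the C++ engine expects
.ff_cpp <- function(ff) {
  list(eps = ff$eps, sigma = ff$sigma, cutoff = ff$cutoff,
       lj_shift = isTRUE(ff$lj_shift),
       coulomb_k = ff$coulomb_k,
       coul_mode = if (ff$coulomb_shift == "force") 1L else 0L,
       skin = ff$skin,
       bonds = if (is.null(ff$bonds)) NULL else
         unname(as.matrix(ff$bonds[, c("i", "j", "k", "r0")])),
       angles = if (is.null(ff$angles)) NULL else
         unname(as.matrix(ff$angles[, c("i", "j", "k", "k_theta", "theta0")])))
}

#' Restrict a forcefield's bonded terms to a particle subset
#'
#' Keeps bonds/angles whose members all lie in `idx` and renumbers them.
#' Used when evaluating the energy of an isolated group with the same
#' coordinates and box as the full system.
#'
#' @param ff a [forcefield_params()] object
#' @param idx integer particle indices of the subset
#' @export
subset_forcefield <- function(ff, idx) {
  map <- integer(0)
  map[idx] <- seq_along(idx)
  out <- ff
  if (!is.null(ff$bonds)) {
    keep <- ff$bonds$i %in% idx & ff$bonds$j %in% idx
    b <- ff$bonds[keep, , drop = FALSE]
    b$i <- map[b$i]; b$j <- map[b$j]
    out$bonds <- if (nrow(b)) b else NULL
  }
  if (!is.null(ff$angles)) {
    keep <- ff$angles$i %in% idx & ff$angles$j %in% idx & ff$angles$k %in% idx
    a <- ff$angles[keep, , drop = FALSE]
    a$i <- map[a$i]; a$j <- map[a$j]; a$k <- map[a$k]
    out$angles <- if (nrow(a)) a else NULL
  }
  out
}

#' Energy bookkeeping for a configuration
#'
#' @param kinetic,vdw,coulomb,bond,angle components in kcal/mol
#' @return object of class `energy_report`; `total` is the exact sum
#' @export
energy_report <- function(kinetic, vdw, coulomb, bond, angle) {
  structure(list(kinetic = kinetic, vdw = vdw, coulomb = coulomb,
                 bond = bond, angle = angle,
                 potential = vdw + coulomb + bond + angle,
                 total = kinetic + vdw + coulomb + bond + angle),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf(paste0("<energy_report> total %.6g kcal/mol ",
                     "(kin %.6g, vdw %.6g, coul %.6g, bond %.6g, angle %.6g)\n"),
              x$total, x$kinetic, x$vdw, x$coulomb, x$bond, x$angle))
  invisible(x)
}
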