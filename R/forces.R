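#' Forces and energies of a configuration
#'
#' Evaluates the full potential (pair LJ + Coulomb, bonds, angles) under the
#' minimum-image convention and returns per-particle forces together with an
#' [energy_report()]. Forces are the exact analytic negative gradients of the
#' reported potential and obey Newton's third law pairwise.
#'
#' @param system a [particle_system()]
#' @param ff a [forcefield_params()]
#' @param box a [sim_box()]
#' @return list with `forces` (n x 3, kcal mol^-1 A^-1), `energy`
#'   (an [energy_report()]) and `virial` (diagonal, kcal/mol)
#' @export
compute_forces <- function(system, ff, box) {
  r <- cpp_forces(system$positions, system$velocities, system$mass,
                  system$charge, system$type, .ff_cpp(ff),
                  unname(box$lengths))
  list(forces = r$forces,
       energy = energy_report(r$kinetic, r$evdw, r$ecoul, r$ebond, r$eangle),
       virial = r$virial)
}

#' Kinetic temperature from velocities
#'
#' T = 2 KE / (dof * kB) with KE = sum m v^2 / 2 in kcal/mol.
#'
#' @param velocities n x 3 matrix in A/fs
#' @param mass numeric, amu
#' @param dof number of degrees of freedom (> 0); 3N - 3 for a whole system
#'   with centre-of-mass momentum removed
#' @return temperature in K
#' @export
kinetic_temperature <- function(velocities, mass, dof) {
  if (dof <= 0) stop("undefined temperature: dof must be > 0")
  2 * kinetic_energy(velocities, mass) / (dof * kB_kcalmol)
}

#' Kinetic energy in kcal/mol
#' @inheritParams kinetic_temperature
#' @export
kinetic_energy <- function(velocities, mass) {
  0.5 * sum(mass * rowSums(as.matrix(velocities)^2)) * .mvsq2e
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Uses R's RNG (seed with [set.seed()]). Optionally removes the
#' centre-of-mass momentum and rescales to the exact target temperature.
#'
#' @param mass numeric, amu
#' @param temperature target temperature in K
#' @param zero_momentum remove COM momentum (default TRUE)
#' @param exact rescale so the kinetic temperature is exactly `temperature`
#' @return n x 3 velocity matrix in A/fs
#' @export
maxwell_velocities <- function(mass, temperature, zero_momentum = TRUE,
                               exact = TRUE) {
  n <- length(mass)
  sd_v <- sqrt(kB_kcalmol * temperature / (mass * .mvsq2e))
  v <- matrix(rnorm(3 * n), n, 3) * sd_v
  if (zero_momentum) {
    p <- colSums(v * mass) / sum(mass)
    v <- sweep(v, 2, p)
  }
  if (exact && temperature > 0) {
    dof <- if (zero_momentum) 3 * n - 3 else 3 * n
    Tc <- kinetic_temperature(v, mass, dof)
    if (Tc > 0) v <- v * sqrt(temperature / Tc)
  }
  v
}
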