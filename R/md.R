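#' Run molecular dynamics
#'
#' Velocity-Verlet integration with optional Nose-Hoover (single chain)
#' thermostat and Berendsen barostat. `ensemble = "nve"` is plain Verlet;
#' `"nvt"` adds the thermostat; `"npt"` adds both. The barostat couples
#' either isotropically or to the z axis only (`p_couple = "z"`, the slab
#' default, which keeps the flux cross-section fixed).
#'
#' A linear temperature ramp is requested by giving `ramp_T = c(T_start,
#' T_end)`; otherwise `target_T` is held.
#'
#' @param system a [particle_system()]
#' @param ff a [forcefield_params()]
#' @param box a [sim_box()]
#' @param n_steps number of integration steps
#' @param dt timestep in fs (default 2)
#' @param ensemble "nve", "nvt" or "npt"
#' @param target_T thermostat target in K
#' @param tau_T thermostat coupling time in fs
#' @param target_P barostat target in atm
#' @param tau_P barostat coupling time in fs
#' @param beta_P isothermal compressibility used by the Berendsen scaling,
#'   atm^-1
#' @param p_couple "z" (slab) or "iso"
#' @param ramp_T optional c(T0, T1) linear ramp
#' @param log_every thermodynamic log stride in steps (0 = no log)
#' @param traj_every trajectory stride in steps (0 = no frames)
#' @param track_min keep the minimum-potential-energy configuration seen at
#'   log points (used by annealing selection)
#' @return an object of class `md_run`: final `system`, `box`, a tibble
#'   `log`, trajectory frames, and engine bookkeeping
#' @export
run_md <- function(system, ff, box, n_steps, dt = 2,
                   ensemble = c("nve", "nvt", "npt"),
                   target_T = 300, tau_T = 100,
                   target_P = 1, tau_P = 1000, beta_P = 4.6e-5,
                   p_couple = c("z", "iso"),
                   ramp_T = NULL, log_every = 100, traj_every = 0,
                   track_min = FALSE) {
  ensemble <- match.arg(ensemble)
  p_couple <- match.arg(p_couple)
  if (dt <= 0) stop("dt must be > 0")
  if (ensemble != "nve") {
    if (target_T <= 0 && is.null(ramp_T)) stop("target_T must be > 0")
    if (tau_T <= 0) stop("thermostat coupling must be > 0")
  }
  if (ensemble == "npt" && tau_P <= 0) stop("barostat coupling must be > 0")
  T0 <- if (is.null(ramp_T)) target_T else ramp_T[1]
  T1 <- if (is.null(ramp_T)) target_T else ramp_T[2]
  n <- n_particles(system)
  ctrl <- list(n_steps = as.integer(n_steps), dt = dt,
               thermo = if (ensemble == "nve") 0L else 1L,
               T0 = T0, T1 = T1, tau_T = tau_T,
               baro = if (ensemble == "npt") 1L else 0L,
               target_P = target_P, tau_P = tau_P, beta_P = beta_P,
               p_axis = if (p_couple == "z") 1L else 0L,
               dof = 3 * n - 3,
               log_every = as.integer(log_every),
               traj_every = as.integer(traj_every),
               sample_every = 0L, n_layers = 0L,
               hot = -1L, cold = -1L, delta_e = 0, interval = 0L,
               track_min = isTRUE(track_min),
               group = integer(0), leaflet = integer(0))
  r <- cpp_run_md(system$positions, system$velocities, system$mass,
                  system$charge, system$type, .ff_cpp(ff),
                  unname(box$lengths), ctrl)
  .md_result(r, system, box, dt)
}

# internal: wrap a cpp_run_md return into an md_run object
.md_result <- function(r, system, box, dt) {
  out_sys <- system
  out_sys$positions <- r$positions
  out_sys$velocities <- r$velocities
  out_box <- box
  out_box$lengths[] <- r$box
  lg <- r$log
  colnames(lg) <- c("step", "time_fs", "T", "P_atm", "Pzz_atm", "volume_A3",
                    "evdw", "ecoul", "ebond", "eangle", "ekin", "etot")
  res <- list(system = out_sys, box = out_box,
              log = tibble::as_tibble(as.data.frame(lg)),
              traj_pos = r$traj_pos, traj_vel = r$traj_vel,
              traj_step = r$traj_step, dt = dt)
  if (!is.null(r$min_epot)) {
    res$min_epot <- r$min_epot
    res$min_system <- out_sys
    res$min_system$positions <- r$min_positions
    res$min_system$velocities <- r$min_velocities
  }
  class(res) <- "md_run"
  res
}

#' @export
print.md_run <- function(x, ...) {
  cat(sprintf("<md_run> %d log rows, %d frames, final box %.2f x %.2f x %.2f A\n",
              nrow(x$log), length(x$traj_pos),
              x$box$lengths[1], x$box$lengths[2], x$box$lengths[3]))
  invisible(x)
}

#' One or more plain velocity-Verlet (NVE) steps
#'
#' Thin convenience wrapper over [run_md()] with no thermostat/barostat.
#'
#' @inheritParams run_md
#' @export
velocity_verlet <- function(system, ff, box, n_steps = 1, dt = 2,
                            log_every = 0, traj_every = 0) {
  run_md(system, ff, box, n_steps = n_steps, dt = dt, ensemble = "nve",
         log_every = log_every, traj_every = traj_every)
}
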