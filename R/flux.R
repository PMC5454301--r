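#' Uniform slab partition along the flux axis
#'
#' The box is divided into `n_layers` equal-width bins along the flux axis;
#' every particle maps to exactly one bin after periodic wrapping.
#'
#' @param n_layers number of layers (default 100)
#' @param axis flux axis ("z")
#' @return object of class `slab_partition`
#' @export
slab_partition <- function(n_layers = 100, axis = "z") {
  stopifnot(n_layers >= 2)
  structure(list(n_layers = as.integer(n_layers),
                 axis = match.arg(axis, c("x", "y", "z"))),
            class = "slab_partition")
}

#' Assign particles to slab layers
#'
#' Layer index = floor(n * z / L) + 1 after wrapping z into [0, L).
#'
#' @param system a [particle_system()]
#' @param box a [sim_box()]
#' @param partition a [slab_partition()]
#' @return integer vector of 1-based layer indices in 1..n_layers
#' @export
assign_layers <- function(system, box, partition) {
  ax <- match(partition$axis, c("x", "y", "z"))
  L <- box$lengths[[ax]]
  z <- system$positions[, ax]
  z <- z - L * floor(z / L)
  idx <- floor(partition$n_layers * z / L) + 1L
  pmin(as.integer(idx), partition$n_layers)
}

#' Layer centre coordinates
#' @param box a [sim_box()]
#' @param partition a [slab_partition()]
#' @return numeric vector of bin-centre coordinates (A)
#' @export
layer_centers <- function(box, partition) {
  ax <- match(partition$axis, c("x", "y", "z"))
  L <- box$lengths[[ax]]
  w <- L / partition$n_layers
  (seq_len(partition$n_layers) - 0.5) * w
}

#' Apply one fixed-dE flux exchange to a pair of layers
#'
#' In each layer the velocities are rescaled about the layer's
#' centre-of-mass velocity, v' = v_com + alpha (v - v_com), with
#' alpha = sqrt(1 - dE/K_rel) in the cold layer and sqrt(1 + dE/K_rel) in
#' the hot layer, where K_rel is the layer kinetic energy in its own COM
#' frame. This changes each layer's total energy by exactly -dE/+dE and
#' leaves each layer's momentum unchanged. The exchange is skipped (with a
#' reason) when a layer has fewer than 2 particles or the cold layer's K_rel
#' does not exceed dE.
#'
#' @param system a [particle_system()]
#' @param hot_idx,cold_idx integer particle indices of the hot/cold layers
#' @param delta_e energy moved per exchange, kcal/mol (>= 0)
#' @return list(system, applied, reason, alpha_cold, alpha_hot)
#' @export
impose_flux_exchange <- function(system, hot_idx, cold_idx, delta_e) {
  if (delta_e < 0) stop("delta_e must be >= 0")
  out <- list(system = system, applied = FALSE, reason = "",
              alpha_cold = NA_real_, alpha_hot = NA_real_)
  if (delta_e == 0) { out$applied <- TRUE; out$reason <- "identity"; return(out) }
  if (length(hot_idx) < 2 || length(cold_idx) < 2) {
    out$reason <- "layer has fewer than 2 particles"; return(out)
  }
  v <- system$velocities; m <- system$mass
  rel_ke <- function(idx) {
    vc <- colSums(v[idx, , drop = FALSE] * m[idx]) / sum(m[idx])
    dv <- sweep(v[idx, , drop = FALSE], 2, vc)
    list(vcom = vc, k = 0.5 * sum(m[idx] * rowSums(dv^2)) * .mvsq2e, dv = dv)
  }
  cold <- rel_ke(cold_idx)
  if (cold$k <= delta_e) {
    out$reason <- "cold layer kinetic energy exhausted"; return(out)
  }
  hot <- rel_ke(hot_idx)
  a_c <- sqrt(1 - delta_e / cold$k)
  a_h <- sqrt(1 + delta_e / hot$k)
  v[cold_idx, ] <- sweep(cold$dv * a_c, 2, cold$vcom, "+")
  v[hot_idx, ]  <- sweep(hot$dv * a_h, 2, hot$vcom, "+")
  system$velocities <- v
  list(system = system, applied = TRUE, reason = "applied",
       alpha_cold = a_c, alpha_hot = a_h)
}

#' Heat flux from an exchange ledger
#'
#' J = sum(dE) / (2 A t): the factor 2 reflects the two periodic heat paths,
#' since half of the exchanged energy flows out of each side of the hot
#' layer.
#'
#' @param ledger an `exchange_ledger` (from [run_nemd()]) or a single number
#'   giving the cumulative exchanged energy in kcal/mol
#' @param area cross-sectional area perpendicular to the flux, A^2
#' @param elapsed_fs elapsed simulated time in fs (taken from the ledger if
#'   omitted)
#' @return list with `j_internal` (kcal mol^-1 A^-2 fs^-1) and `j_si`
#'   (W m^-2)
#' @export
measured_flux <- function(ledger, area, elapsed_fs = NULL) {
  if (inherits(ledger, "exchange_ledger")) {
    cum <- ledger$cum_energy
    if (is.null(elapsed_fs)) elapsed_fs <- ledger$elapsed_fs
  } else {
    cum <- as.numeric(ledger)
  }
  stopifnot(area > 0, elapsed_fs > 0)
  if (cum == 0) warning("empty ledger: zero flux")
  j <- cum / (2 * area * elapsed_fs)
  list(j_internal = j, j_si = flux_to_si(j))
}

#' Run imposed-flux nonequilibrium MD
#'
#' NVE integration (no thermostat: a global thermostat would be an
#' unaccounted heat sink) with a fixed energy dE moved from the cold layer
#' to the hot layer every `interval` steps by momentum-conserving velocity
#' rescaling. Per-layer kinetic energies are sampled every `sample_every`
#' steps for the temperature-profile analysis, along with per-layer group
#' composition.
#'
#' Steady state is flagged when, over the last two half-windows of the
#' sampled series, at least 90 percent of layers have temperatures agreeing
#' within twice their combined standard errors.
#'
#' @inheritParams run_md
#' @param partition a [slab_partition()]
#' @param hot_layer,cold_layer 1-based layer indices; defaults are layer 1
#'   and the layer half a box away (maximally separated symmetric paths)
#' @param delta_e energy per exchange, kcal/mol
#' @param interval steps between exchanges (default 50)
#' @param sample_every layer-sampling stride (default = interval)
#' @return object of class `nemd_run`: everything in `md_run` plus
#'   `ledger` (class `exchange_ledger`), per-layer sample matrices,
#'   composition, flux helpers and a steady-state flag
#' @export
run_nemd <- function(system, ff, box, partition, duration_steps, dt = 2,
                     hot_layer = 1L,
                     cold_layer = partition$n_layers %/% 2 + 1L,
                     delta_e = 0.5, interval = 50L,
                     sample_every = interval, log_every = 500,
                     traj_every = 0) {
  stopifnot(hot_layer >= 1, cold_layer >= 1,
            hot_layer <= partition$n_layers, cold_layer <= partition$n_layers,
            hot_layer != cold_layer, interval >= 1)
  n <- n_particles(system)
  grp <- match(system$group, c("WATER", "HEAD", "TAIL")) - 1L
  lf <- ifelse(is.na(system$leaflet), -1L, system$leaflet)
  ctrl <- list(n_steps = as.integer(duration_steps), dt = dt,
               thermo = 0L, T0 = 0, T1 = 0, tau_T = 1,
               baro = 0L, target_P = 0, tau_P = 1, beta_P = 0, p_axis = 0L,
               dof = 3 * n - 3,
               log_every = as.integer(log_every),
               traj_every = as.integer(traj_every),
               sample_every = as.integer(sample_every),
               n_layers = partition$n_layers,
               hot = as.integer(hot_layer) - 1L,
               cold = as.integer(cold_layer) - 1L,
               delta_e = delta_e, interval = as.integer(interval),
               track_min = FALSE, group = grp, leaflet = as.integer(lf))
  r <- cpp_run_md(system$positions, system$velocities, system$mass,
                  system$charge, system$type, .ff_cpp(ff),
                  unname(box$lengths), ctrl)
  res <- .md_result(r, system, box, dt)
  led <- r$ledger
  colnames(led) <- c("step", "applied", "ke_cold_before", "ke_cold_after",
                     "ke_hot_before", "ke_hot_after", "dp_max", "cum_energy")
  ledger <- structure(list(
    events = tibble::as_tibble(as.data.frame(led)),
    delta_e = delta_e, interval = as.integer(interval),
    hot_layer = as.integer(hot_layer), cold_layer = as.integer(cold_layer),
    cum_energy = r$cum_energy,
    n_exchanges = sum(led[, "applied"] == 1),
    n_skipped = sum(led[, "applied"] == 0),
    elapsed_fs = as.integer(duration_steps) * dt), class = "exchange_ledger")
  res$ledger <- ledger
  ns <- r$n_layer_samples
  res$layer_ke <- r$layer_ke[seq_len(ns), , drop = FALSE]
  res$layer_cnt <- r$layer_cnt[seq_len(ns), , drop = FALSE]
  comp <- r$composition
  tot <- rowSums(comp)
  res$composition <- sweep(comp, 1, pmax(tot, 1), "/")
  colnames(res$composition) <- c("WATER", "HEAD", "TAIL")
  lf2 <- r$leaflet_comp
  res$leaflet_comp <- sweep(lf2, 1, pmax(rowSums(lf2), 1), "/")
  res$partition <- partition
  res$hot_layer <- as.integer(hot_layer)
  res$cold_layer <- as.integer(cold_layer)
  res$flux <- measured_flux(ledger, box_area(res$box))
  res$steady <- .steady_state_flag(res$layer_ke, res$layer_cnt)
  class(res) <- c("nemd_run", "md_run")
  res
}

#' @export
print.exchange_ledger <- function(x, ...) {
  cat(sprintf("<exchange_ledger> %d exchanges (%d skipped), dE = %g kcal/mol, sum = %g kcal/mol over %g fs\n",
              x$n_exchanges, x$n_skipped, x$delta_e, x$cum_energy, x$elapsed_fs))
  invisible(x)
}

# steady-state check: compare per-layer T of the 3rd vs 4th quarter of the
# sampled series; steady when >= 90% of layers agree within 2 combined SE.
.steady_state_flag <- function(layer_ke, layer_cnt) {
  ns <- nrow(layer_ke)
  if (ns < 8) return(NA)
  i3 <- seq(floor(ns / 2) + 1, floor(3 * ns / 4))
  i4 <- seq(floor(3 * ns / 4) + 1, ns)
  Tm <- layer_ke / pmax(layer_cnt, 1) / (1.5 * kB_kcalmol)
  ok <- vapply(seq_len(ncol(Tm)), function(l) {
    a <- Tm[i3, l]; b <- Tm[i4, l]
    if (all(a == 0) || all(b == 0)) return(NA)
    se <- sqrt(sd(a)^2 / length(a) + sd(b)^2 / length(b))
    if (!is.finite(se) || se == 0) return(NA)
    abs(mean(a) - mean(b)) <= 2 * se
  }, logical(1))
  mean(ok, na.rm = TRUE) >= 0.9
}
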