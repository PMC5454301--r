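#' Coarse-grained surrogate lipid specification
#'
#' One lipid = a 2-bead zwitterionic head (charges +q/-q, net neutral) plus
#' two 4-bead apolar tails attached to the lower head bead, mirroring the
#' amphiphilic architecture of a phosphatidylcholine at desk scale.
#'
#' @param beads_per_head head beads (default 2)
#' @param beads_per_tail beads per tail (default 4)
#' @param n_tails number of tails (default 2)
#' @param head_charge magnitude q of the head dipole charges (e)
#' @param bead_mass mass per bead, amu (10 beads x 73.4 ~ one DPPC)
#' @param bond_r0 bond rest length, A
#' @param bond_k bond stiffness, kcal/mol/A^2 (half-k convention)
#' @param angle_k_gel,angle_k_fluid chain angle stiffness presets
#'   (kcal/mol/rad^2): stiff = ordered gel-like chains, soft = fluid-like
#' @param tail_offset lateral half-spacing between the two tails, A
#' @return object of class `lipid_spec`
#' @export
lipid_spec <- function(beads_per_head = 2, beads_per_tail = 4, n_tails = 2,
                       head_charge = 0.25, bead_mass = 73.4,
                       bond_r0 = 4.0, bond_k = 100,
                       angle_k_gel = 25, angle_k_fluid = 3,
                       tail_offset = 1.6) {
  stopifnot(beads_per_head >= 1, beads_per_tail >= 1, n_tails >= 1)
  n_beads <- beads_per_head + n_tails * beads_per_tail
  if (n_beads < 4) stop("need at least 4 beads per lipid")
  structure(list(beads_per_head = beads_per_head,
                 beads_per_tail = beads_per_tail, n_tails = n_tails,
                 head_charge = head_charge, bead_mass = bead_mass,
                 bond_r0 = bond_r0, bond_k = bond_k,
                 angle_k_gel = angle_k_gel, angle_k_fluid = angle_k_fluid,
                 tail_offset = tail_offset, n_beads = n_beads),
            class = "lipid_spec")
}

#' Nonbonded parameter set for the surrogate bilayer
#'
#' Bead types 1 = solvent (W), 2 = head (H), 3 = tail (T). The solvent is a
#' single neutral polar bead (1 bead ~ 1 water, 18 amu) whose attraction to
#' head beads is much stronger than to tail beads, encoding amphiphilicity;
#' tails cohere through moderate dispersion only. Electrostatics are
#' force-shifted at the cutoff so pairs crossing it do not inject energy,
#' and the LJ energy is shifted to zero at the cutoff for clean NVE
#' bookkeeping.
#'
#' @param spec a [lipid_spec()] (supplies bonded stiffness presets)
#' @param phase "fluid" or "gel" chain-stiffness preset
#' @param cutoff pair cutoff, A
#' @return a [forcefield_params()] without bonded terms (the builder adds
#'   per-system bonds/angles)
#' @export
bilayer_forcefield <- function(spec = lipid_spec(),
                               phase = c("fluid", "gel"), cutoff = 12) {
  phase <- match.arg(phase)
  eps <- matrix(c(0.70, 1.20, 0.08,
                  1.20, 0.50, 0.25,
                  0.08, 0.25, 0.65), 3, 3, byrow = TRUE)
  sig <- matrix(c(2.90, 3.55, 4.05,
                  3.55, 4.20, 4.70,
                  4.05, 4.70, 5.20), 3, 3, byrow = TRUE)
  ff <- forcefield_params(eps, sig, cutoff = cutoff,
                          coulomb_shift = "force", lj_shift = TRUE)
  attr(ff, "phase") <- phase
  attr(ff, "angle_k") <- if (phase == "gel") spec$angle_k_gel else spec$angle_k_fluid
  ff
}

# bead layout of one lipid in a leaflet; returns positions (local z from the
# head outward), group labels, charges and intra-lipid bonds/angles
.lipid_template <- function(spec) {
  bh <- spec$beads_per_head; bt <- spec$beads_per_tail; nt <- spec$n_tails
  r0 <- spec$bond_r0
  pos <- matrix(0, spec$n_beads, 3)
  grp <- character(spec$n_beads)
  chg <- numeric(spec$n_beads)
  # head stack
  for (b in seq_len(bh)) {
    pos[b, ] <- c(0, 0, (b - 1) * 3.5)
    grp[b] <- "HEAD"
  }
  chg[1] <- spec$head_charge
  if (bh >= 2) chg[2] <- -spec$head_charge
  anchor <- bh
  z0 <- pos[anchor, 3]
  idx <- bh
  bonds <- list(); angles <- list()
  for (b in seq_len(bh - 1)) bonds[[length(bonds) + 1]] <- c(b, b + 1)
  # tails are laid down pre-coiled (zigzag at bond length r0) so the built
  # leaflet thickness matches the chains' relaxed packing density
  dz <- 0.75 * r0
  zig <- sqrt(r0^2 - dz^2)
  dz1 <- sqrt(r0^2 - spec$tail_offset^2)
  for (t in seq_len(nt)) {
    xoff <- spec$tail_offset * (2 * t - nt - 1)
    prev <- anchor
    first_tail <- idx + 1
    for (b in seq_len(bt)) {
      idx <- idx + 1
      pos[idx, ] <- c(xoff + zig * ((b - 1) %% 2), 0,
                      z0 + dz1 + (b - 1) * dz)
      grp[idx] <- "TAIL"
      bonds[[length(bonds) + 1]] <- c(prev, idx)
      prev <- idx
    }
    chain <- c(anchor - 1, anchor, first_tail:(first_tail + bt - 1))
    chain <- chain[chain >= 1]
    if (length(chain) >= 3)
      for (k in seq_len(length(chain) - 2))
        angles[[length(angles) + 1]] <- chain[k:(k + 2)]
  }
  list(pos = pos, group = grp, charge = chg,
       bonds = do.call(rbind, bonds), angles = do.call(rbind, angles))
}

#' Build a hydrated coarse-grained bilayer slab
#'
#' Two opposed leaflets (tails inward, heads facing the solvent) on a square
#' lattice, with a single-bead solvent filling the slabs on both sides of
#' the membrane. The box cross-section follows from the requested area per
#' lipid: Lx = Ly = sqrt(n_lipids/2 * area_per_lipid). Small lateral jitter
#' (drawn from R's RNG; seed for reproducibility) breaks lattice symmetry.
#' Velocities start at zero.
#'
#' @param spec a [lipid_spec()]
#' @param n_lipids total lipid count, split evenly between leaflets
#'   (default 72)
#' @param n_solvent solvent bead count (default 2560, 1 bead ~ 1 water)
#' @param area_per_lipid target area per lipid, A^2 (default 62.5)
#' @param phase "fluid" or "gel" chain-stiffness preset
#' @param solvent_mass solvent bead mass, amu
#' @param jitter lateral jitter amplitude, A
#' @param midplane_gap tail-tail gap across the bilayer midplane, A
#' @return list(system, box, ff) ready for [run_md()]
#' @export
build_bilayer <- function(spec = lipid_spec(), n_lipids = 72,
                          n_solvent = 2560, area_per_lipid = 62.5,
                          phase = c("fluid", "gel"), solvent_mass = 18,
                          jitter = 0.25, midplane_gap = 5.2) {
  phase <- match.arg(phase)
  if (n_lipids %% 2 != 0) stop("n_lipids must be even (two equal leaflets)")
  n_leaf <- n_lipids / 2
  A <- n_leaf * area_per_lipid
  lx <- ly <- sqrt(A)
  n_side <- ceiling(sqrt(n_leaf))
  spacing <- lx / n_side
  sigma_t <- 5.2
  if (spacing - 2 * spec$tail_offset < 0.6 * sigma_t)
    stop("impossible packing: area per lipid too small for the bead sizes")
  tmpl <- .lipid_template(spec)
  leaflet_h <- max(tmpl$pos[, 3])
  bilayer_h <- 2 * leaflet_h + midplane_gap
  # water lattice
  ws <- 3.1
  nx <- max(1, floor(lx / ws)); ny <- max(1, floor(ly / ws))
  per_layer <- nx * ny
  n_wlayers <- ceiling(n_solvent / per_layer)
  n_bot <- ceiling(n_wlayers / 2); n_top <- n_wlayers - n_bot
  buffer <- 3.0
  water_h_bot <- n_bot * ws; water_h_top <- n_top * ws
  lz <- bilayer_h + 2 * buffer + water_h_bot + water_h_top
  z_mid <- water_h_bot + buffer + bilayer_h / 2

  pos <- list(); vel <- list(); mass <- list(); chg <- list()
  type <- list(); mol <- list(); grp <- list(); leaf <- list()
  bonds <- list(); angles <- list()
  nb <- spec$n_beads
  off <- 0L; mol_id <- 0L
  for (lf in 0:1) {
    placed <- 0
    for (gx in seq_len(n_side)) for (gy in seq_len(n_side)) {
      if (placed >= n_leaf) next
      placed <- placed + 1; mol_id <- mol_id + 1L
      cx <- (gx - 0.5) * spacing + runif(1, -jitter, jitter)
      cy <- (gy - 0.5) * spacing + runif(1, -jitter, jitter)
      p <- tmpl$pos
      if ((gx + gy) %% 2 == 1) p <- p[, c(2, 1, 3)]  # checkerboard tails

      if (lf == 0) {
        z <- z_mid - bilayer_h / 2 + p[, 3]          # heads at the bottom
      } else {
        z <- z_mid + bilayer_h / 2 - p[, 3]          # mirrored leaflet
      }
      pos[[length(pos) + 1]] <- cbind(p[, 1] + cx, p[, 2] + cy, z)
      mass[[length(mass) + 1]] <- rep(spec$bead_mass, nb)
      chg[[length(chg) + 1]] <- tmpl$charge
      type[[length(type) + 1]] <- ifelse(tmpl$group == "HEAD", 2L, 3L)
      mol[[length(mol) + 1]] <- rep(mol_id, nb)
      grp[[length(grp) + 1]] <- tmpl$group
      leaf[[length(leaf) + 1]] <- rep(lf, nb)
      bonds[[length(bonds) + 1]] <- tmpl$bonds + off
      angles[[length(angles) + 1]] <- tmpl$angles + off
      off <- off + nb
    }
  }
  # solvent slabs
  wpos <- matrix(NA_real_, n_solvent, 3)
  wi <- 0
  for (side in c("bot", "top")) {
    nl <- if (side == "bot") n_bot else n_top
    for (l in seq_len(nl)) {
      zz <- if (side == "bot") (l - 0.5) * ws else
        z_mid + bilayer_h / 2 + buffer + (l - 0.5) * ws
      for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
        if (wi >= n_solvent) next
        wi <- wi + 1
        wpos[wi, ] <- c((ix - 0.5) * lx / nx + runif(1, -0.15, 0.15),
                        (iy - 0.5) * ly / ny + runif(1, -0.15, 0.15),
                        zz)
      }
    }
  }
  wpos <- wpos[seq_len(wi), , drop = FALSE]
  positions <- rbind(do.call(rbind, pos), wpos)
  n_w <- nrow(wpos)
  system <- particle_system(
    positions,
    mass = c(unlist(mass), rep(solvent_mass, n_w)),
    charge = c(unlist(chg), rep(0, n_w)),
    type = c(unlist(type), rep(1L, n_w)),
    mol_id = c(unlist(mol), mol_id + seq_len(n_w)),
    group = c(unlist(grp), rep("WATER", n_w)),
    leaflet = c(unlist(leaf), rep(NA_integer_, n_w)))
  box <- sim_box(lx, ly, lz)
  ff <- bilayer_forcefield(spec, phase)
  bm <- do.call(rbind, bonds)
  am <- do.call(rbind, angles)
  r0 <- rep(spec$bond_r0, nrow(bm))
  r0[bm[, 2] - bm[, 1] == 1 & (bm[, 1] - 1) %% nb < spec$beads_per_head - 1] <- 3.5
  ff$bonds <- data.frame(i = bm[, 1], j = bm[, 2], k = spec$bond_k, r0 = r0)
  ff$angles <- data.frame(i = am[, 1], j = am[, 2], k = am[, 3],
                          k_theta = attr(ff, "angle_k"), theta0 = pi)
  md <- cpp_min_dist(system$positions, unname(box$lengths))
  if (md <= 0.85 * min(3.1, 4.2, 4.6) * 0.5)  # guard against gross overlap
    stop("builder produced steric overlaps; reduce jitter or increase area per lipid")
  list(system = system, box = box, ff = ff)
}

#' Duplicate a slab system along z
#'
#' Imposed-flux runs need each of the two periodic heat paths to cross one
#' membrane, so the simulation cell holds two bilayers: the original at a
#' quarter box and its copy at three quarters.
#'
#' @param system a [particle_system()]
#' @param box a [sim_box()]
#' @return list(system, box) with 2N particles and doubled Lz
#' @export
replicate_z <- function(system, box) {
  lz <- box$lengths[[3]]
  p2 <- system$positions
  p2[, 3] <- p2[, 3] + lz
  sys2 <- particle_system(
    rbind(system$positions, p2),
    rbind(system$velocities, system$velocities),
    c(system$mass, system$mass), c(system$charge, system$charge),
    c(system$type, system$type),
    c(system$mol_id, system$mol_id + max(system$mol_id)),
    c(system$group, system$group), c(system$leaflet, system$leaflet))
  list(system = sys2,
       box = sim_box(box$lengths[[1]], box$lengths[[2]], 2 * lz,
                     box$periodic, box$flux_axis))
}

#' Duplicate a forcefield's bonded terms for a replicated system
#' @param ff a [forcefield_params()] with bonds/angles for the original N
#'   particles
#' @param n original particle count
#' @export
replicate_ff <- function(ff, n) {
  out <- ff
  if (!is.null(ff$bonds)) {
    b2 <- ff$bonds; b2$i <- b2$i + n; b2$j <- b2$j + n
    out$bonds <- rbind(ff$bonds, b2)
  }
  if (!is.null(ff$angles)) {
    a2 <- ff$angles; a2$i <- a2$i + n; a2$j <- a2$j + n; a2$k <- a2$k + n
    out$angles <- rbind(ff$angles, a2)
  }
  out
}

#' Three-stage relaxation protocol
#'
#' Stage 1: NVT at 300 K; stage 2: NPT at 400 K and 1 atm (higher kinetic
#' energy helps convergence); stage 3: NPT cooling to the working
#' temperature (default 320 K) at 1 atm. Full-scale stage length is 0.3 ns;
#' `scale` shortens all three for desk-scale work (`scale = 0` returns the
#' input unchanged). A short steepest-descent relaxation precedes stage 1 to
#' remove builder close contacts.
#'
#' @param system,ff,box as elsewhere
#' @param scale duration scale factor (1 = 0.3 ns per stage)
#' @param final_T stage-3 target temperature, K
#' @param dt timestep, fs
#' @param descent_steps steepest-descent steps before dynamics
#' @param settle_steps strongly-coupled z-barostat steps that relax the
#'   lattice-built slab to its equilibrium thickness before stage 1
#' @param p_couple barostat coupling for stages 2-3
#' @return list(system, box, stages) where `stages` logs the realised
#'   schedule and stage-end state
#' @export
equilibrate <- function(system, ff, box, scale = 1, final_T = 320, dt = 2,
                        descent_steps = 200, settle_steps = 10000,
                        p_couple = "z") {
  if (scale == 0)
    return(list(system = system, box = box,
                stages = tibble::tibble(stage = integer(0))))
  full <- 150000 # 0.3 ns at 2 fs
  n_steps <- max(100L, as.integer(full * scale))
  if (descent_steps > 0) {
    r <- cpp_steepest_descent(system$positions, system$mass, system$charge,
                              system$type, .ff_cpp(ff), unname(box$lengths),
                              as.integer(descent_steps), 0.2)
    system$positions <- r$positions
  }
  if (all(system$velocities == 0))
    system$velocities <- maxwell_velocities(system$mass, 300)
  # settle: the lattice-built slab carries excess z extent; a brief
  # strongly-coupled barostatted run brings it to mechanical equilibrium so
  # the fixed-box NVT stage below runs at the right density
  if (settle_steps > 0) {
    r <- run_md(system, ff, box, n_steps = settle_steps, dt = dt,
                ensemble = "npt", target_T = 300, target_P = 1, tau_P = 150,
                p_couple = p_couple, log_every = max(50L, settle_steps %/% 20L))
    system <- r$system; box <- r$box
  }
  le <- max(1L, n_steps %/% 200L)
  stage_log <- list()
  do_stage <- function(i, sys, bx, ens, Tt) {
    r <- run_md(sys, ff, bx, n_steps = n_steps, dt = dt, ensemble = ens,
                target_T = Tt, target_P = 1, tau_P = 300,
                p_couple = p_couple, log_every = le)
    lt <- tail(r$log, 1)
    stage_log[[i]] <<- tibble::tibble(
      stage = i, ensemble = ens, target_T = Tt, steps = n_steps,
      mean_T = mean(tail(r$log$T, 50)), end_P = lt$P_atm,
      end_volume = lt$volume_A3)
    r
  }
  r1 <- do_stage(1, system, box, "nvt", 300)
  r2 <- do_stage(2, r1$system, r1$box, "npt", 400)
  r3 <- do_stage(3, r2$system, r2$box, "npt", final_T)
  list(system = r3$system, box = r3$box, stages = do.call(rbind, stage_log))
}

#' Simulated-annealing configuration selection
#'
#' Heats the system to `hi` and cools it back to `lo` at `rate` K/ps for
#' `cycles` cycles under NVT dynamics, tracking the minimum-potential-energy
#' configuration seen in each cycle (evaluated at log points); returns the
#' per-cycle argmin snapshots and their energies.
#'
#' @inheritParams equilibrate
#' @param cycles number of heat/cool cycles
#' @param rate ramp rate, K/ps
#' @param hi,lo ramp endpoints, K
#' @param scale duration scale factor
#' @return list(configs = list of systems, energies, cycle_logs)
#' @export
anneal_select <- function(system, ff, box, cycles = 2, rate = 1,
                          hi = 400, lo = 300, scale = 1, dt = 2) {
  leg <- max(100L, as.integer(abs(hi - lo) / rate * 1000 / dt * scale))
  le <- max(1L, leg %/% 100L)
  configs <- list(); energies <- numeric(0); logs <- list()
  state <- system
  for (cy in seq_len(cycles)) {
    up <- run_md(state, ff, box, n_steps = leg, dt = dt, ensemble = "nvt",
                 ramp_T = c(lo, hi), log_every = le, track_min = TRUE)
    down <- run_md(up$system, ff, box, n_steps = leg, dt = dt,
                   ensemble = "nvt", ramp_T = c(hi, lo), log_every = le,
                   track_min = TRUE)
    if (!is.null(up$min_epot) && !is.null(down$min_epot) &&
        up$min_epot < down$min_epot) {
      configs[[cy]] <- up$min_system; energies[cy] <- up$min_epot
    } else {
      configs[[cy]] <- down$min_system; energies[cy] <- down$min_epot
    }
    logs[[cy]] <- rbind(up$log, down$log)
    state <- down$system
  }
  list(configs = configs, energies = energies, cycle_logs = logs)
}
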