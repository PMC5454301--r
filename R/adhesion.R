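#' Adhesion energy between two particle groups
#'
#' E_adh = E_tot - (E_1 + E_2): the total potential energy of the full
#' configuration minus the energies of the two groups evaluated in isolation
#' (same coordinates, same box, no re-minimisation). For disjoint groups
#' with no bonded term spanning them this equals the cross-group nonbonded
#' pair energy, which is computed independently and returned as a
#' cross-check. Cross-group bonded terms, if a selection ever splits a
#' molecule, are shared 50/50 between E_1 and E_2 (or rejected with
#' `strict = TRUE`) so that E_adh still reflects nonbonded adhesion.
#'
#' @param system a [particle_system()]
#' @param ff a [forcefield_params()]
#' @param box a [sim_box()]
#' @param group1,group2 disjoint integer index vectors
#' @param strict error on cross-group bonded terms instead of splitting
#' @return object of class `adhesion_report`: `e_tot`, `e_1`, `e_2`,
#'   `e_adh`, and the independent `cross` = list(vdw, coulomb, total)
#' @export
adhesion_energy <- function(system, ff, box, group1, group2, strict = FALSE) {
  if (length(group1) == 0 || length(group2) == 0) stop("empty selection")
  if (length(intersect(group1, group2)) > 0) stop("selections must be disjoint")
  cross_bonded <- 0
  if (!is.null(ff$bonds)) {
    b <- ff$bonds
    cb <- (b$i %in% group1 & b$j %in% group2) | (b$i %in% group2 & b$j %in% group1)
    if (any(cb)) {
      if (strict) stop("bonded term spans the two selections")
      cross_bonded <- cross_bonded + sum(vapply(which(cb), function(k) {
        .bond_energy(system, box, b[k, ])
      }, numeric(1)))
    }
  }
  pot <- function(idx, f) {
    sub <- subset_system(system, idx)
    r <- compute_forces(sub, subset_forcefield(f, idx), box)
    r$energy$potential
  }
  all_idx <- seq_len(n_particles(system))
  e_tot <- pot(all_idx, ff)
  e_1 <- pot(group1, ff) + cross_bonded / 2
  e_2 <- pot(group2, ff) + cross_bonded / 2
  cr <- cpp_cross_energy(system$positions, system$charge, system$type,
                         .ff_cpp(ff), unname(box$lengths),
                         as.integer(group1), as.integer(group2))
  structure(list(e_tot = e_tot, e_1 = e_1, e_2 = e_2,
                 e_adh = e_tot - (e_1 + e_2),
                 cross = list(vdw = cr$evdw, coulomb = cr$ecoul,
                              total = cr$evdw + cr$ecoul)),
            class = "adhesion_report")
}

.bond_energy <- function(system, box, bond) {
  d <- system$positions[bond$i, ] - system$positions[bond$j, ]
  L <- unname(box$lengths)
  d <- d - L * round(d / L)
  r <- sqrt(sum(d^2))
  0.5 * bond$k * (r - bond$r0)^2
}

#' @export
print.adhesion_report <- function(x, ...) {
  cat(sprintf("<adhesion_report> E_adh = %.6g kcal/mol (E_tot %.6g, E_1 %.6g, E_2 %.6g)\n",
              x$e_adh, x$e_tot, x$e_1, x$e_2))
  cat(sprintf("  cross-pair check: vdW %.6g + Coulomb %.6g = %.6g kcal/mol\n",
              x$cross$vdw, x$cross$coulomb, x$cross$total))
  invisible(x)
}

#' Cross-group nonbonded interaction energy
#'
#' Direct sum over pairs (i in group1, j in group2) of the LJ and Coulomb
#' energies, with the same cutoff and exclusion rules as the engine.
#'
#' @inheritParams adhesion_energy
#' @return list(vdw, coulomb, total) in kcal/mol
#' @export
cross_interaction_energy <- function(system, ff, box, group1, group2) {
  r <- cpp_cross_energy(system$positions, system$charge, system$type,
                        .ff_cpp(ff), unname(box$lengths),
                        as.integer(group1), as.integer(group2))
  list(vdw = r$evdw, coulomb = r$ecoul, total = r$evdw + r$ecoul)
}

#' Group-group interaction energies over a trajectory window
#'
#' For each frame, sums the cross-group van der Waals and Coulomb energies
#' for each requested pair of selections (default: water vs head groups, and
#' tail beads of leaflet 0 vs leaflet 1). Returns the per-frame series and a
#' summary with means and standard errors; with fewer than 10 frames the SE
#' is not available. A qualitative flag records whether the water-head
#' interaction dominates the tail-tail one in every frame.
#'
#' @param run an `md_run`/`nemd_run` with stored trajectory frames, or a
#'   list of position matrices
#' @param system the template [particle_system()] (labels, masses, charges)
#' @param ff a [forcefield_params()]
#' @param box a [sim_box()]
#' @param pairs named list of `list(g1, g2)` index pairs; default water-head
#'   and tail(0)-tail(1)
#' @return list(series = tibble, summary = tibble, water_head_dominates)
#' @export
interaction_decomposition <- function(run, system, ff, box, pairs = NULL) {
  frames <- if (is.list(run) && !is.null(run$traj_pos)) run$traj_pos else run
  if (length(frames) == 0) stop("no trajectory frames supplied")
  if (is.null(pairs)) {
    pairs <- list(
      water_head = list(g1 = select_particles(system, "WATER"),
                        g2 = select_particles(system, "HEAD")),
      tail_tail = list(g1 = select_particles(system, "TAIL", leaflet = 0),
                       g2 = select_particles(system, "TAIL", leaflet = 1)))
  }
  ffc <- .ff_cpp(ff)
  L <- unname(box$lengths)
  rows <- list()
  for (fr in seq_along(frames)) {
    pos <- frames[[fr]]
    for (nm in names(pairs)) {
      p <- pairs[[nm]]
      r <- cpp_cross_energy(pos, system$charge, system$type, ffc, L,
                            as.integer(p$g1), as.integer(p$g2))
      rows[[length(rows) + 1]] <- tibble::tibble(
        frame = fr, pair = nm, vdw = r$evdw, coulomb = r$ecoul,
        total = r$evdw + r$ecoul)
    }
  }
  series <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(series, series$pair), function(d) {
    nf <- nrow(d)
    tibble::tibble(pair = d$pair[1],
                   mean_vdw = mean(d$vdw), mean_coulomb = mean(d$coulomb),
                   mean_total = mean(d$total),
                   se_total = if (nf >= 10) sd(d$total) / sqrt(nf) else NA_real_,
                   n_frames = nf)
  }))
  dom <- NA
  if (all(c("water_head", "tail_tail") %in% series$pair)) {
    wh <- abs(series$total[series$pair == "water_head"])
    tt <- abs(series$total[series$pair == "tail_tail"])
    dom <- all(wh > tt)
  }
  list(series = series, summary = summ, water_head_dominates = dom)
}

#' Area per lipid
#'
#' Bilayer cross-sectional area (perpendicular to the membrane normal)
#' divided by the number of lipids in one leaflet.
#'
#' @param box a [sim_box()] (the flux axis is the membrane normal)
#' @param n_lipids_per_leaflet number of lipids in one leaflet (> 0)
#' @return area per lipid in A^2
#' @export
area_per_lipid <- function(box, n_lipids_per_leaflet) {
  if (n_lipids_per_leaflet <= 0) stop("n_lipids_per_leaflet must be > 0")
  box_area(box) / n_lipids_per_leaflet
}
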