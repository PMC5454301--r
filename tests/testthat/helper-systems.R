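# shared fixture builders (all generated in code, seeded by the caller)

# argon-like LJ fluid on a cubic lattice with Maxwell velocities
make_lj_fluid <- function(nx = 6, ny = nx, nz = nx, a = 3.8, temperature = 120,
                          mass = 40, eps = 0.238, sigma = 3.4, cutoff = 8.5,
                          dt_safe = TRUE) {
  g <- expand.grid(x = 0:(nx - 1), y = 0:(ny - 1), z = 0:(nz - 1))
  pos <- as.matrix(g) * a + a / 2
  n <- nrow(pos)
  sys <- particle_system(pos, mass = rep(mass, n))
  sys$velocities <- maxwell_velocities(sys$mass, temperature)
  ff <- forcefield_params(eps = matrix(eps), sigma = matrix(sigma),
                          cutoff = cutoff, coulomb_k = 0, lj_shift = TRUE)
  list(sys = sys, ff = ff, box = sim_box(nx * a, ny * a, nz * a), n = n)
}

# n random beads with a minimum separation (rejection sampling)
make_random_beads <- function(n, L, min_sep = 1.8, charges = FALSE,
                              mass = 10) {
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- runif(3, 0, L)
  for (i in 2:n) {
    repeat {
      p <- runif(3, 0, L)
      d <- sweep(pos[seq_len(i - 1), , drop = FALSE], 2, p)
      d <- d - L * round(d / L)
      if (min(sqrt(rowSums(d^2))) > min_sep) break
    }
    pos[i, ] <- p
  }
  q <- if (charges) runif(n, -0.5, 0.5) else rep(0, n)
  particle_system(pos, mass = rep(mass, n), charge = q)
}

# R-side brute-force nonbonded oracle (plain truncated LJ + Coulomb),
# independent of the engine
brute_force_energy <- function(sys, ff, box, idx_a = NULL, idx_b = NULL) {
  pos <- sys$positions; L <- unname(box$lengths)
  n <- nrow(pos)
  pairs <- if (is.null(idx_a)) {
    cbind(rep(1:(n - 1), times = (n - 1):1),
          unlist(lapply(1:(n - 1), function(i) (i + 1):n)))
  } else {
    as.matrix(expand.grid(idx_a, idx_b))
  }
  E_vdw <- 0; E_coul <- 0
  F <- matrix(0, n, 3)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    d <- pos[i, ] - pos[j, ]
    d <- d - L * round(d / L)
    rr <- sqrt(sum(d^2))
    if (rr >= ff$cutoff) next
    ti <- sys$type[i]; tj <- sys$type[j]
    e <- ff$eps[ti, tj]; s <- ff$sigma[ti, tj]
    fm <- 0
    if (e > 0) {
      sr6 <- (s / rr)^6
      sh <- if (isTRUE(ff$lj_shift)) 4 * e * ((s / ff$cutoff)^12 - (s / ff$cutoff)^6) else 0
      E_vdw <- E_vdw + 4 * e * (sr6^2 - sr6) - sh
      fm <- fm + 24 * e * (2 * sr6^2 - sr6) / rr^2
    }
    qq <- sys$charge[i] * sys$charge[j]
    if (ff$coulomb_k != 0 && qq != 0) {
      E_coul <- E_coul + ff$coulomb_k * qq / rr
      fm <- fm + ff$coulomb_k * qq / rr^3
    }
    F[i, ] <- F[i, ] + fm * d
    F[j, ] <- F[j, ] - fm * d
  }
  list(vdw = E_vdw, coulomb = E_coul, total = E_vdw + E_coul, forces = F)
}
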