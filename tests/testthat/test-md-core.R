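test_that("Lennard-Jones pair energies hit the analytic landmarks", {
  ff <- forcefield_params(eps = matrix(1), sigma = matrix(3), cutoff = 12,
                          coulomb_k = 0)
  box <- sim_box(50, 50, 50)
  dimer <- function(r) particle_system(rbind(c(0, 0, 0), c(r, 0, 0)),
                                       mass = c(10, 10))
  expect_equal(compute_forces(dimer(3), ff, box)$energy$potential, 0)
  at_min <- compute_forces(dimer(2^(1 / 6) * 3), ff, box)
  expect_equal(at_min$energy$potential, -1)
  expect_lt(max(abs(at_min$forces)), 1e-12)
})

test_that("forces and energies match an independent brute-force pair sum", {
  withr::with_seed(11, {
    for (rep in 1:3) {
      sys <- make_random_beads(10, L = 20, min_sep = 1.6, charges = TRUE)
      ff <- forcefield_params(eps = matrix(0.3), sigma = matrix(2.0),
                              cutoff = 8, coulomb_k = 332.0637)
      box <- sim_box(20, 20, 20)
      got <- compute_forces(sys, ff, box)
      want <- brute_force_energy(sys, ff, box)
      expect_equal(got$energy$potential, want$total, tolerance = 1e-10)
      expect_lt(max(abs(got$forces - want$forces)) /
                  max(abs(want$forces)), 1e-10)
    }
  })
})

test_that("Newton's third law and force-energy consistency hold", {
  withr::with_seed(12, {
    sys <- make_random_beads(15, L = 18, min_sep = 2.2, charges = TRUE)
    ff <- forcefield_params(eps = matrix(0.3), sigma = matrix(2.4),
                            cutoff = 8, coulomb_k = 332.0637)
    box <- sim_box(18, 18, 18)
    got <- compute_forces(sys, ff, box)
    fscale <- max(abs(got$forces))
    expect_lt(max(abs(colSums(got$forces))) / fscale, 1e-9)
    # central-difference gradient on a few random coordinates
    h <- 1e-5
    for (k in 1:6) {
      i <- sample(15, 1); a <- sample(3, 1)
      sp <- sys; sp$positions[i, a] <- sp$positions[i, a] + h
      sm <- sys; sm$positions[i, a] <- sm$positions[i, a] - h
      num <- -(compute_forces(sp, ff, box)$energy$potential -
                 compute_forces(sm, ff, box)$energy$potential) / (2 * h)
      expect_equal(num, got$forces[i, a], tolerance = 1e-6)
    }
  })
})

test_that("overlapping particles raise a degenerate-configuration error", {
  sys <- particle_system(rbind(c(0, 0, 0), c(1e-8, 0, 0)), mass = c(1, 1))
  ff <- forcefield_params(eps = matrix(1), sigma = matrix(3), cutoff = 12,
                          coulomb_k = 0)
  expect_error(compute_forces(sys, ff, sim_box(30, 30, 30)), "degenerate")
})

test_that("kinetic temperature matches its definition and a summation oracle", {
  n <- 8
  m <- rep(20, n)
  # velocities built so total KE = (3n/2) kB 300
  withr::with_seed(13, v <- maxwell_velocities(m, 300, zero_momentum = FALSE))
  expect_equal(kinetic_temperature(v, m, 3 * n), 300)
  expect_equal(kinetic_temperature(matrix(0, n, 3), m, 3 * n), 0)
  withr::with_seed(14, {
    v <- matrix(rnorm(15, sd = 0.01), 5, 3)
    m5 <- runif(5, 1, 50)
    ke_hand <- 0.5 * sum(m5 * rowSums(v^2)) * 2390.0573615334906
    expect_equal(kinetic_temperature(v, m5, 15),
                 2 * ke_hand / (15 * kB_kcalmol))
  })
  expect_error(kinetic_temperature(v, m5, 0), "dof")
})

test_that("free flight, harmonic period and the LJ equilibrium point integrate correctly", {
  box <- sim_box(100, 100, 100)
  # free flight: zero interactions
  ff0 <- forcefield_params(eps = matrix(0), sigma = matrix(1), cutoff = 5,
                           coulomb_k = 0)
  sys <- particle_system(rbind(c(10, 10, 10), c(20, 20, 20)), mass = c(5, 5))
  sys$velocities <- rbind(c(0.01, -0.02, 0.005), c(0, 0.01, 0))
  r <- velocity_verlet(sys, ff0, box, n_steps = 1, dt = 2)
  expect_equal(r$system$positions, sys$positions + 2 * sys$velocities)
  # harmonic bond period 2 pi sqrt(m / 2k) (half-k convention, equal masses)
  k <- 10; m <- 10; r0 <- 3
  ffb <- forcefield_params(eps = matrix(0), sigma = matrix(1), cutoff = 5,
                           coulomb_k = 0,
                           bonds = data.frame(i = 1, j = 2, k = k, r0 = r0))
  sysb <- particle_system(rbind(c(48, 50, 50), c(48 + r0 + 0.3, 50, 50)),
                          mass = c(m, m))
  dt <- 0.25
  rb <- run_md(sysb, ffb, box, n_steps = 1000, dt = dt, ensemble = "nve",
               log_every = 0, traj_every = 1)
  sep <- vapply(rb$traj_pos, function(p) p[2, 1] - p[1, 1], numeric(1)) - r0
  crossings <- which(diff(sign(sep)) != 0)
  period_meas <- 2 * mean(diff(crossings)) * dt
  mvsq2e <- 2390.0573615334906
  period_true <- 2 * pi * sqrt(m * mvsq2e / (2 * k))
  expect_lt(abs(period_meas - period_true) / period_true, 0.01)
  # LJ dimer at its minimum stays put
  ff1 <- forcefield_params(eps = matrix(1), sigma = matrix(3), cutoff = 12,
                           coulomb_k = 0)
  sysm <- particle_system(rbind(c(40, 50, 50), c(40 + 2^(1 / 6) * 3, 50, 50)),
                          mass = c(10, 10))
  rm <- velocity_verlet(sysm, ff1, box, n_steps = 100, dt = 2)
  expect_lt(max(abs(rm$system$positions - sysm$positions)), 1e-12)
})

test_that("NVE conserves energy and momentum on an interacting fluid", {
  withr::with_seed(15, f <- make_lj_fluid(nx = 5, temperature = 110))
  r <- run_md(f$sys, f$ff, f$box, n_steps = 10000, dt = 2, ensemble = "nve",
              log_every = 200)
  et <- r$log$etot
  expect_lt(max(abs(et - et[1])) / abs(et[1]), 1e-4)
  p0 <- colSums(f$sys$velocities * f$sys$mass)
  p1 <- colSums(r$system$velocities * f$sys$mass)
  expect_lt(max(abs(p1 - p0)), 1e-9)
})

test_that("the thermostat holds an LJ fluid at target and the barostat is a no-op at its setpoint", {
  withr::with_seed(16, f <- make_lj_fluid(nx = 6, temperature = 120))
  r <- run_md(f$sys, f$ff, f$box, n_steps = 25000, dt = 4, ensemble = "nvt",
              target_T = 120, tau_T = 200, log_every = 50)
  mean_T <- mean(tail(r$log$T, 300))
  expect_lt(abs(mean_T - 120) / 120, 0.02)
  expect_error(run_md(f$sys, f$ff, f$box, 10, ensemble = "nvt", tau_T = -1),
               "coupling")
  # one tiny-dt NPT step with the target equal to the current pressure
  fr <- compute_forces(f$sys, f$ff, f$box)
  kz <- sum(f$sys$mass * f$sys$velocities[, 3]^2) * 2390.0573615334906
  pz <- (kz + fr$virial[3]) / box_volume(f$box) * 68568.415
  rp <- run_md(f$sys, f$ff, f$box, n_steps = 1, dt = 0.01, ensemble = "npt",
               target_T = 120, target_P = pz, tau_P = 1000, p_couple = "z",
               log_every = 1)
  expect_equal(rp$box$lengths[[3]] / f$box$lengths[[3]], 1, tolerance = 1e-6)
})
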