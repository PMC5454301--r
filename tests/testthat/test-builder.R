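test_that("the bilayer builder delivers the requested census without overlaps", {
  withr::with_seed(61, b <- build_bilayer(n_lipids = 32, n_solvent = 300))
  s <- b$system
  expect_equal(sum(s$group == "WATER"), 300)
  expect_equal(sum(s$group == "HEAD"), 32 * 2)
  expect_equal(sum(s$group == "TAIL"), 32 * 8)
  expect_equal(sum(s$leaflet == 0, na.rm = TRUE), 16 * 10)
  expect_equal(sum(s$leaflet == 1, na.rm = TRUE), 16 * 10)
  expect_equal(area_per_lipid(b$box, 16), 62.5, tolerance = 1e-9)
  md <- lipidheat:::cpp_min_dist(s$positions, unname(b$box$lengths))
  expect_gt(md, 0.85 * 2.9 * 0.5)
  expect_error(build_bilayer(n_lipids = 32, n_solvent = 100,
                             area_per_lipid = 20), "packing")
})

test_that("a mirrored build has identical energy and relaxation tames the forces", {
  withr::with_seed(62, b <- build_bilayer(n_lipids = 32, n_solvent = 300))
  e0 <- compute_forces(b$system, b$ff, b$box)$energy$potential
  mirrored <- b$system
  mirrored$positions[, 3] <- b$box$lengths[[3]] - mirrored$positions[, 3]
  e1 <- compute_forces(mirrored, b$ff, b$box)$energy$potential
  expect_equal(e1, e0, tolerance = 1e-8)
  r <- lipidheat:::cpp_steepest_descent(
    b$system$positions, b$system$mass, b$system$charge, b$system$type,
    lipidheat:::.ff_cpp(b$ff), unname(b$box$lengths), 200L, 0.2)
  f0 <- compute_forces(b$system, b$ff, b$box)$forces
  expect_lt(r$fmax, max(abs(f0)))
  expect_lt(r$fmax, 50) # stable under dt = 2 fs dynamics
})

test_that("equilibrate follows its schedule and a zero scale is the identity", {
  withr::with_seed(63, b <- build_bilayer(n_lipids = 32, n_solvent = 300))
  eq0 <- equilibrate(b$system, b$ff, b$box, scale = 0)
  expect_identical(eq0$system$positions, b$system$positions)
  expect_equal(nrow(eq0$stages), 0)
  withr::with_seed(64,
    eq <- equilibrate(b$system, b$ff, b$box, scale = 0.01,
                      settle_steps = 2000, final_T = 320))
  expect_identical(eq$stages$ensemble, c("nvt", "npt", "npt"))
  expect_identical(eq$stages$target_T, c(300, 400, 320))
  expect_identical(eq$stages$steps, rep(1500L, 3))
  expect_lt(abs(eq$stages$mean_T[1] - 300) / 300, 0.03)
})

test_that("annealing selection returns per-cycle energy minima", {
  # frozen, interaction-free system: the input comes straight back
  sys <- particle_system(matrix(c(5, 5, 5, 10, 10, 10), 2, 3, byrow = TRUE),
                         mass = c(10, 10))
  ff0 <- forcefield_params(eps = matrix(0), sigma = matrix(1), cutoff = 5,
                           coulomb_k = 0)
  a0 <- anneal_select(sys, ff0, sim_box(20, 20, 20), cycles = 1, scale = 0.01)
  expect_identical(a0$configs[[1]]$positions, sys$positions)
  # interacting fluid: argmin contract against the cycle log
  withr::with_seed(65, f <- make_lj_fluid(nx = 4, temperature = 120))
  a <- anneal_select(f$sys, f$ff, f$box, cycles = 2, rate = 1,
                     hi = 160, lo = 120, scale = 0.1, dt = 4)
  expect_length(a$configs, 2)
  for (cy in 1:2) {
    epots <- a$cycle_logs[[cy]]$etot - a$cycle_logs[[cy]]$ekin
    expect_lte(a$energies[cy], min(epots) + 1e-9)
  }
  rmsd <- sqrt(mean((a$configs[[1]]$positions - a$configs[[2]]$positions)^2))
  expect_gt(rmsd, 0)
})

test_that("profile fixtures carry their truth and regenerate bit-identically", {
  prof <- make_profile_fixture(noise = 0)
  truth <- attr(prof, "truth")
  reg <- attr(prof, "regions")
  dec <- resistance_decomposition(prof, reg, truth$j_si)
  expect_equal(dec$segments$R_si, truth$r_segments, tolerance = 1e-9)
  expect_equal(dec$interfaces$R_si, truth$r_interfaces, tolerance = 1e-7)
  withr::with_seed(66, p1 <- make_profile_fixture(noise = 0.02))
  withr::with_seed(66, p2 <- make_profile_fixture(noise = 0.02))
  expect_identical(p1, p2)
  expect_error(make_profile_fixture(noise = -1), "noise")
})

test_that("replication along z doubles the system and preserves the census", {
  withr::with_seed(67, b <- build_bilayer(n_lipids = 32, n_solvent = 200))
  d <- replicate_z(b$system, b$box)
  expect_equal(n_particles(d$system), 2 * n_particles(b$system))
  expect_equal(d$box$lengths[[3]], 2 * b$box$lengths[[3]])
  ff2 <- replicate_ff(b$ff, n_particles(b$system))
  expect_equal(nrow(ff2$bonds), 2 * nrow(b$ff$bonds))
  # the copy sits one box above the original
  n <- n_particles(b$system)
  expect_equal(unname(d$system$positions[n + 1, 3] - d$system$positions[1, 3]),
               b$box$lengths[[3]])
})
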