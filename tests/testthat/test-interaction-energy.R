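test_that("adhesion energy matches closed forms and vanishes beyond the cutoff", {
  ff <- forcefield_params(eps = matrix(0.2), sigma = matrix(3), cutoff = 12,
                          coulomb_k = 332.0637)
  box <- sim_box(60, 60, 60)
  # two groups entirely beyond the cutoff
  far <- particle_system(rbind(c(5, 5, 5), c(6, 5, 5), c(35, 35, 35),
                               c(36, 35, 35)), mass = rep(1, 4))
  rf <- adhesion_energy(far, ff, box, 1:2, 3:4)
  expect_equal(rf$e_adh, 0)
  expect_equal(rf$cross$total, 0)
  # opposite unit charges at 10 A, no LJ: plain Coulomb closed form
  ffq <- forcefield_params(eps = matrix(0), sigma = matrix(1), cutoff = 12,
                           coulomb_k = 332.0637)
  two <- particle_system(rbind(c(20, 20, 20), c(30, 20, 20)),
                         mass = c(1, 1), charge = c(1, -1))
  rq <- adhesion_energy(two, ffq, box, 1, 2)
  expect_equal(rq$e_adh, -33.20637, tolerance = 1e-6)
  expect_equal(rq$cross$coulomb, rq$e_adh, tolerance = 1e-12)
})

test_that("the subtraction route equals the brute-force cross-pair sum", {
  ff <- forcefield_params(eps = matrix(0.3), sigma = matrix(2.2), cutoff = 9,
                          coulomb_k = 332.0637)
  box <- sim_box(24, 24, 24)
  withr::with_seed(51, {
    for (rep in 1:5) {
      sys <- make_random_beads(20, L = 24, min_sep = 1.8, charges = TRUE)
      g1 <- 1:8; g2 <- 9:20
      r <- adhesion_energy(sys, ff, box, g1, g2)
      oracle <- brute_force_energy(sys, ff, box, g1, g2)
      expect_equal(r$e_adh, oracle$total, tolerance = 1e-10)
      expect_equal(r$cross$total, oracle$total, tolerance = 1e-10)
      expect_equal(r$cross$vdw + r$cross$coulomb, r$cross$total)
      # invariances: rigid translation and group-label exchange
      sys_t <- sys
      sys_t$positions <- sweep(sys$positions, 2, c(3.1, -2.7, 11.9), "+")
      expect_equal(adhesion_energy(sys_t, ff, box, g1, g2)$e_adh, r$e_adh,
                   tolerance = 1e-9)
      expect_equal(adhesion_energy(sys, ff, box, g2, g1)$e_adh, r$e_adh,
                   tolerance = 1e-12)
    }
  })
  expect_error(adhesion_energy(sys <- make_random_beads(4, 24), ff, box,
                               1:2, 2:3), "disjoint")
  expect_error(adhesion_energy(sys, ff, box, integer(0), 1:2), "empty")
})

test_that("trajectory decomposition agrees frame-wise with single-configuration calls", {
  ff <- forcefield_params(eps = matrix(0.3), sigma = matrix(2.2), cutoff = 9,
                          coulomb_k = 332.0637)
  box <- sim_box(24, 24, 24)
  withr::with_seed(52, {
    sys <- make_random_beads(16, L = 24, min_sep = 1.8, charges = TRUE)
    sys$group <- rep(c("WATER", "HEAD"), each = 8)
    sys$leaflet <- c(rep(NA_integer_, 8), rep(0L, 8))
    f2 <- sys$positions + matrix(rnorm(48, 0, 0.05), 16, 3)
    frames <- list(sys$positions, f2)
    pairs <- list(water_head = list(g1 = 1:8, g2 = 9:16))
    dec <- interaction_decomposition(frames, sys, ff, box, pairs = pairs)
    for (fr in 1:2) {
      s <- sys; s$positions <- frames[[fr]]
      ref <- adhesion_energy(s, ff, box, 1:8, 9:16)
      row <- dec$series[dec$series$frame == fr, ]
      expect_equal(row$total, ref$cross$total, tolerance = 1e-12)
    }
    expect_true(is.na(dec$summary$se_total[1])) # < 10 frames: means only
  })
  # zero-charge system: Coulomb component identically zero
  withr::with_seed(53, {
    sys0 <- make_random_beads(10, L = 24, min_sep = 1.8, charges = FALSE)
    dec0 <- interaction_decomposition(list(sys0$positions), sys0, ff, box,
                                      pairs = list(ab = list(g1 = 1:5, g2 = 6:10)))
    expect_identical(dec0$series$coulomb, 0)
  })
})

test_that("area per lipid is simple geometry", {
  box <- sim_box(47.245, 42.319, 80)
  expect_equal(area_per_lipid(box, 32), 62.48, tolerance = 1e-3)
  expect_equal(area_per_lipid(sim_box(1, 1, 1), 1), 1)
  expect_equal(area_per_lipid(sim_box(2 * 47.245, 42.319, 80), 32),
               2 * area_per_lipid(box, 32))
  expect_error(area_per_lipid(box, 0), "> 0")
})
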