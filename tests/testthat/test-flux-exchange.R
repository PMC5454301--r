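test_that("layer assignment wraps periodically and fills uniformly", {
  part <- slab_partition(100)
  box <- sim_box(30, 30, 100)
  sys <- particle_system(rbind(c(0, 0, 0), c(0, 0, -0.5), c(0, 0, 99.99)),
                         mass = rep(1, 3))
  expect_identical(assign_layers(sys, box, part), c(1L, 100L, 100L))
  withr::with_seed(21, {
    n <- 1000
    sysr <- particle_system(cbind(runif(n, 0, 30), runif(n, 0, 30),
                                  runif(n, -50, 150)), mass = rep(1, n))
    occ <- tabulate(assign_layers(sysr, box, part), 100)
    # multinomial: mean 10, sd sqrt(n p (1-p)) ~ 3.15; allow 4 sigma
    expect_true(all(abs(occ - 10) <= 4 * sqrt(1000 * 0.01 * 0.99)))
  })
})

test_that("a single flux exchange moves exactly dE and conserves layer momentum", {
  withr::with_seed(22, {
    sys <- make_random_beads(12, L = 20, min_sep = 1.5)
    sys$velocities <- maxwell_velocities(sys$mass, 200, zero_momentum = FALSE)
    hot <- 1:5; cold <- 6:12
    # identity at dE = 0
    r0 <- impose_flux_exchange(sys, hot, cold, 0)
    expect_identical(r0$system$velocities, sys$velocities)
    # closed-form alpha: K_rel = 10, dE = 1 -> alpha = sqrt(0.9)
    krel <- function(s, idx) {
      vc <- colSums(s$velocities[idx, ] * s$mass[idx]) / sum(s$mass[idx])
      dv <- sweep(s$velocities[idx, ], 2, vc)
      0.5 * sum(s$mass[idx] * rowSums(dv^2)) * 2390.0573615334906
    }
    k0 <- krel(sys, cold)
    scl <- sqrt(10 / k0)
    sys$velocities[cold, ] <- {
      vc <- colSums(sys$velocities[cold, ] * sys$mass[cold]) / sum(sys$mass[cold])
      sweep(sweep(sys$velocities[cold, ], 2, vc) * scl, 2, vc, "+")
    }
    expect_equal(krel(sys, cold), 10, tolerance = 1e-12)
    r1 <- impose_flux_exchange(sys, hot, cold, 1)
    expect_equal(r1$alpha_cold, sqrt(0.9), tolerance = 1e-12)
    expect_equal(krel(r1$system, cold), 9, tolerance = 1e-10)
    # momentum and total-energy bookkeeping on a 3-particle layer
    sys3 <- make_random_beads(6, L = 15, min_sep = 1.5)
    sys3$velocities <- matrix(rnorm(18, sd = 0.005), 6, 3)
    kc <- krel(sys3, 4:6)
    de <- 0.3 * kc
    r2 <- impose_flux_exchange(sys3, 1:3, 4:6, de)
    ke <- function(s, idx) 0.5 * sum(s$mass[idx] * rowSums(s$velocities[idx, ]^2)) * 2390.0573615334906
    expect_equal(ke(sys3, 4:6) - ke(r2$system, 4:6), de, tolerance = 1e-10 * de)
    p0 <- colSums(sys3$velocities[4:6, ] * sys3$mass[4:6])
    p1 <- colSums(r2$system$velocities[4:6, ] * sys3$mass[4:6])
    expect_lt(max(abs(p1 - p0)), 1e-12)
    # exhausted cold layer is skipped, not fatal
    r3 <- impose_flux_exchange(sys3, 1:3, 4:6, 10 * kc)
    expect_false(r3$applied)
    expect_match(r3$reason, "exhausted")
  })
})

test_that("measured flux follows sum(dE)/(2At) with correct SI conversion", {
  # unit-conversion oracle: 100 kcal/mol over 2000 A^2, 1 ns
  f <- measured_flux(100, area = 2000, elapsed_fs = 1e6)
  expect_equal(f$j_internal, 100 / (2 * 2000 * 1e6))
  expect_equal(f$j_si, 1.737e7, tolerance = 5e-4)
  expect_equal(measured_flux(200, 2000, 1e6)$j_si, 2 * f$j_si)
  expect_warning(fz <- measured_flux(0, 2000, 1e6), "zero flux")
  expect_equal(fz$j_si, 0)
})

test_that("a zero-dE NEMD run is bitwise identical to plain NVE", {
  withr::with_seed(23, f <- make_lj_fluid(nx = 4, nz = 8, temperature = 110))
  part <- slab_partition(16)
  r_nemd <- run_nemd(f$sys, f$ff, f$box, part, duration_steps = 500, dt = 4,
                     delta_e = 0, interval = 20, log_every = 100)
  r_nve <- run_md(f$sys, f$ff, f$box, n_steps = 500, dt = 4,
                  ensemble = "nve", log_every = 100)
  expect_identical(r_nemd$system$positions, r_nve$system$positions)
  expect_identical(r_nemd$system$velocities, r_nve$system$velocities)
})

test_that("imposing a flux produces a monotone ramp that flips under hot/cold swap", {
  withr::with_seed(24, f <- make_lj_fluid(nx = 5, nz = 10, temperature = 120))
  part <- slab_partition(20)
  r <- run_nemd(f$sys, f$ff, f$box, part, duration_steps = 30000, dt = 4,
                delta_e = 0.1, interval = 20, sample_every = 20,
                log_every = 1000)
  prof <- layer_temperatures(r, layers = 1:11)
  expect_lt(cor(prof$temperature, prof$z, method = "spearman"), -0.9)
  # energy bookkeeping: total drift well under the exchanged energy
  et <- r$log$etot
  expect_lt(abs(et[length(et)] - et[1]), 1e-3 * r$ledger$cum_energy)
  # swap hot and cold: the gradient reverses
  r2 <- run_nemd(f$sys, f$ff, f$box, part, duration_steps = 30000, dt = 4,
                 hot_layer = 11, cold_layer = 1,
                 delta_e = 0.1, interval = 20, sample_every = 20,
                 log_every = 1000)
  prof2 <- layer_temperatures(r2, layers = 1:11)
  s1 <- coef(lm(temperature ~ z, prof))[2]
  s2 <- coef(lm(temperature ~ z, prof2))[2]
  expect_lt(s1, 0)
  expect_gt(s2, 0)
})
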