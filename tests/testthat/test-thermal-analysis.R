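# minimal stand-in for an nemd_run: stationary per-layer KE samples with a
# known temperature profile
fake_nemd <- function(temps, n_samples = 200, n_per_layer = 20, sd_frac = 0,
                      lz = length(temps), j_si = 1e9) {
  nl <- length(temps)
  ke_mean <- 1.5 * n_per_layer * kB_kcalmol * temps
  ke <- matrix(rep(ke_mean, each = n_samples), n_samples, nl)
  if (sd_frac > 0) ke <- ke * (1 + matrix(rnorm(n_samples * nl, 0, sd_frac),
                                          n_samples, nl))
  structure(list(layer_ke = ke,
                 layer_cnt = matrix(n_per_layer, n_samples, nl),
                 box = sim_box(30, 30, lz),
                 partition = slab_partition(nl),
                 flux = list(j_si = j_si)),
            class = c("nemd_run", "md_run"))
}

test_that("layer temperatures reproduce flat and ramped constructions", {
  nd <- fake_nemd(rep(300, 20))
  prof <- layer_temperatures(nd)
  expect_equal(prof$temperature, rep(300, 20))
  expect_equal(prof$se, rep(0, 20))
  # linear KE ramp: recovered slope within 1 percent
  temps <- seq(350, 250, length.out = 40)
  withr::with_seed(31, nd2 <- fake_nemd(temps, sd_frac = 0.02, lz = 40))
  prof2 <- layer_temperatures(nd2)
  s_fit <- coef(lm(temperature ~ z, prof2))[2]
  s_true <- (250 - 350) / (prof2$z[40] - prof2$z[1])
  expect_equal(unname(s_fit), s_true, tolerance = 0.01)
})

test_that("block standard errors shrink like 1/sqrt(frames)", {
  withr::with_seed(32, {
    se_of <- function(ns) {
      nd <- fake_nemd(rep(300, 12), n_samples = ns, sd_frac = 0.05)
      mean(layer_temperatures(nd)$se)
    }
    # average the ratio over replicates to tame block-estimate noise
    ratios <- replicate(8, se_of(200) / se_of(800))
    expect_equal(mean(ratios), 2, tolerance = 0.2)
  })
})

test_that("conductivity inverts the printed water benchmark and scales linearly", {
  # J = 904 MW/m^2 with K = 0.60 W/m/K implies |dT/dz| = 0.1507 K/A
  slope <- 9.04e8 / (0.60 * 1e10)
  expect_equal(slope, 0.1507, tolerance = 1e-3)
  fit <- list(slope = -slope, se_slope = 0)
  expect_equal(segment_conductivity(fit, 9.04e8)$K_si, 0.60, tolerance = 1e-12)
  expect_equal(segment_conductivity(fit, 2 * 9.04e8)$K_si, 1.20,
               tolerance = 1e-12)
  expect_equal(segment_conductivity(list(slope = -0.10, se_slope = 0),
                                    6.9477e8)$K_si, 0.69477,
               tolerance = 1e-12)
  expect_error(segment_conductivity(list(slope = 0, se_slope = 0), 1e9),
               "zero temperature gradient")
  # unit round trip K -> R -> K
  expect_equal(resistance_to_conductivity(
    conductivity_to_resistance(0.47, 25.25), 25.25), 0.47, tolerance = 1e-12)
})

test_that("interface resistance recovers jumps by both routes", {
  prof <- make_profile_fixture(noise = 0)
  reg <- attr(prof, "regions")
  f1 <- fit_segment(prof, reg$z0[1], reg$z1[1], interior = c(FALSE, TRUE))
  f2 <- fit_segment(prof, reg$z0[2], reg$z1[2], interior = c(TRUE, TRUE))
  jmp <- interface_resistance(f1, f2, reg$z1[1], attr(prof, "j_si"), "jump")
  # R = 0.40e-9 at J = 9.04e8 is a 0.362 K drop
  expect_equal(jmp$dT_jump, 0.40e-9 * 9.04e8, tolerance = 1e-9)
  expect_equal(jmp$dT_jump, 0.362, tolerance = 2e-3)
  expect_equal(jmp$R_si, 0.40e-9, tolerance = 1e-9 * 0.4)
  sub <- interface_resistance(f1, f2, reg$z1[1], attr(prof, "j_si"),
                              "subtraction")
  expect_equal(sub$R_si, jmp$R_si, tolerance = 1e-9)
  # continuous profile: zero interface resistance
  prof0 <- make_profile_fixture(r_interfaces = c(0, 0, 0), noise = 0)
  g1 <- fit_segment(prof0, 0, 11.31, interior = c(FALSE, TRUE))
  g2 <- fit_segment(prof0, 11.31, 36.56, interior = c(TRUE, TRUE))
  expect_equal(interface_resistance(g1, g2, 11.31, 9.04e8)$R_si, 0,
               tolerance = 1e-15)
  # the subtraction identity on plain numbers: R_int = R_tot - R_i - R_j
  expect_equal(10 - 3 - 4, 3)
})

test_that("resistance decomposition closes and is label-invariant", {
  # two clean segments, no jumps: R_total = dT/J split by segment
  prof <- make_profile_fixture(widths = c(20, 20), conductivities = c(1, 1),
                               r_interfaces = 5e-10, t_start = 310,
                               labels = c("SEG_A", "SEG_B"),
                               j_si = 1e9, n_layers = 80, noise = 0)
  reg <- attr(prof, "regions")
  dec <- resistance_decomposition(prof, reg, 1e9)
  truth <- attr(prof, "truth")
  expect_equal(dec$segments$R_si, truth$r_segments, tolerance = 1e-9)
  expect_equal(dec$interfaces$R_si, truth$r_interfaces, tolerance = 1e-9)
  expect_equal(dec$R_total, truth$r_total, tolerance = 1e-9)
  expect_lt(abs(dec$closure) / dec$R_total, 1e-9)
  # permuting labels leaves the totals unchanged
  reg2 <- reg; reg2$label <- rev(reg2$label)
  dec2 <- resistance_decomposition(prof, reg2, 1e9)
  expect_equal(dec2$R_total, dec$R_total)
  expect_error(resistance_decomposition(prof, reg[1, ], 1e9), "2 segments")
})

test_that("region detection follows composition blocks and degrades gracefully", {
  z <- (1:50 - 0.5)
  prof <- temperature_profile(z, rep(300, 50), j_si = 1e9)
  comp <- matrix(0, 50, 3)
  comp[1:10, 1] <- 1; comp[11:40, 3] <- 1; comp[41:50, 1] <- 1
  comp[11:13, 2] <- 0.6; comp[11:13, 3] <- 0.4  # heads at the interface
  lf <- matrix(0, 50, 2); lf[11:25, 1] <- 1; lf[26:40, 2] <- 1
  reg <- detect_regions(prof, comp, lf)
  expect_identical(reg$label,
                   c("WATER_HOT", "LEAFLET_A", "LEAFLET_B", "WATER_COLD"))
  expect_equal(reg$z1[1], 10, tolerance = 1e-9)
  expect_equal(reg$z1[2], 25, tolerance = 1e-9)   # tail-tail midplane
  expect_equal(reg$z1[3], 40, tolerance = 1e-9)
  # 10 percent composition noise moves boundaries by at most one layer
  withr::with_seed(33, {
    compn <- pmax(comp + matrix(rnorm(150, 0, 0.1), 50, 3), 0)
    compn <- compn / rowSums(compn)
    regn <- detect_regions(prof, compn, lf)
    expect_lt(max(abs(regn$z1[1:3] - reg$z1[1:3])), 1.01)
  })
  # all-water: single region with a warning
  compw <- matrix(0, 50, 3); compw[, 1] <- 1
  expect_warning(regw <- detect_regions(prof, compw), "fallback")
  expect_equal(nrow(regw), 1)
})
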