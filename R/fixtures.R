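#' Synthetic temperature-profile fixture with known ground truth
#'
#' A piecewise-linear steady-state profile over four contiguous segments
#' (hot water, leaflet A, leaflet B, cold water by default) with specified
#' interfacial temperature drops at the three interior boundaries, plus
#' i.i.d. Gaussian layer noise. Defaults follow the canonical analysis:
#' water/lipid thicknesses 11.31/25.25 A, a flux of 9.04e8 W/m^2, water
#' slopes matching K = 0.60 W/m/K and lipid slopes matching K = 0.39
#' W/m/K, interface resistances {0.40, 2.11, 0.40}e-9 m^2 K/W.
#'
#' The injected truth (slopes, jumps, per-segment and per-interface
#' resistances) is attached as attribute `"truth"`; regeneration with the
#' same RNG seed is bit-identical.
#'
#' @param widths segment widths, A (hot to cold)
#' @param conductivities per-segment conductivities, W/m/K (set slopes via
#'   dT/dz = J/K)
#' @param r_interfaces interfacial resistances at the interior boundaries,
#'   m^2 K/W (set jumps via dT = R J)
#' @param labels segment labels
#' @param t_start hot-end temperature, K
#' @param j_si heat flux, W/m^2
#' @param n_layers number of layers across the whole domain
#' @param noise Gaussian noise s.d. on each layer temperature, expressed as
#'   a fraction of the mean per-layer temperature increment
#'   (`noise_ref = "layer_step"`, the default) or directly in K
#'   (`noise_ref = "absolute"`)
#' @param noise_ref "layer_step" or "absolute"
#' @return a [temperature_profile()] with attributes `truth` and `regions`
#' @export
make_profile_fixture <- function(widths = c(11.31, 25.25, 25.25, 11.31),
                                 conductivities = c(0.60, 0.39, 0.39, 0.60),
                                 r_interfaces = c(0.40e-9, 2.11e-9, 0.40e-9),
                                 labels = c("WATER_HOT", "LEAFLET_A",
                                            "LEAFLET_B", "WATER_COLD"),
                                 t_start = 316, j_si = 9.04e8,
                                 n_layers = 100, noise = 0,
                                 noise_ref = c("layer_step", "absolute")) {
  noise_ref <- match.arg(noise_ref)
  if (noise < 0) stop("noise must be >= 0")
  ns <- length(widths)
  stopifnot(length(conductivities) == ns, length(r_interfaces) == ns - 1,
            length(labels) == ns, all(is.finite(widths)),
            all(conductivities > 0))
  slopes <- -j_si / (conductivities * 1e10)  # K/A, decreasing toward cold
  jumps <- r_interfaces * j_si               # K drops at boundaries
  z1 <- cumsum(widths); z0 <- c(0, head(z1, -1))
  t_seg0 <- t_start + cumsum(c(0, slopes[-ns] * widths[-ns] - jumps))
  W <- sum(widths)
  w <- W / n_layers
  z <- (seq_len(n_layers) - 0.5) * w
  seg_of <- findInterval(z, z0, rightmost.closed = TRUE)
  temp <- t_seg0[seg_of] + slopes[seg_of] * (z - z0[seg_of])
  sd_abs <- if (noise_ref == "layer_step") noise * mean(abs(slopes)) * w else noise
  if (sd_abs > 0) temp <- temp + rnorm(n_layers, 0, sd_abs)
  prof <- temperature_profile(z, temp, se = rep(sd_abs, n_layers),
                              n_samples = rep(1L, n_layers), j_si = j_si)
  attr(prof, "layer_width") <- w
  regions <- region_spec(labels, z0, z1)
  truth <- list(slopes = slopes, jumps = jumps, j_si = j_si,
                r_segments = abs(slopes) * widths / j_si,
                r_interfaces = r_interfaces,
                r_total = sum(abs(slopes) * widths / j_si) + sum(r_interfaces),
                noise_sd = sd_abs)
  attr(prof, "regions") <- regions
  attr(prof, "truth") <- truth
  prof
}

#' Synthetic specific-volume-vs-temperature fixture
#'
#' A continuous two-segment piecewise-linear v(T) with one slope break,
#' sampled at `n_points` random temperatures (mirroring a cooling scan that
#' keeps structures at random temperatures), plus Gaussian noise scaled to
#' the curve's volume range. The low-temperature (gel) slope must exceed the
#' high-temperature (fluid) slope; the generator rejects inputs violating
#' that ordering. Sampling is retried (with a warning) until at least 3
#' points land on each side of the break.
#'
#' @param t_break true transition temperature, K
#' @param slope_gel,slope_fluid slopes below/above the break, cm^3/g/K
#'   (gel > fluid > 0)
#' @param v_break specific volume at the break, cm^3/g
#' @param n_points number of sampled temperatures (default 23)
#' @param t_range sampling range, K
#' @param noise Gaussian s.d. as a fraction of the noiseless volume range
#' @return a [vt_curve()] with attribute `truth`
#' @export
make_vt_fixture <- function(t_break = 318, slope_gel = 1.2e-3,
                            slope_fluid = 3e-4, v_break = 0.98,
                            n_points = 23, t_range = c(280, 360),
                            noise = 0.02) {
  if (slope_gel <= slope_fluid)
    stop("gel-side slope must exceed fluid-side slope")
  if (t_break <= t_range[1] || t_break >= t_range[2])
    stop("t_break must lie inside t_range")
  retries <- 0
  for (try in 1:100) {
    tt <- runif(n_points, t_range[1], t_range[2])
    if (sum(tt < t_break) >= 3 && sum(tt > t_break) >= 3) break
    if (try == 100) stop("could not sample 3 points per side of the break")
    retries <- retries + 1
  }
  if (retries > 0)
    warning(sprintf("resampled %d time(s) to get 3 points per side", retries))
  vv <- ifelse(tt < t_break,
               v_break - slope_gel * (t_break - tt),
               v_break + slope_fluid * (tt - t_break))
  rng <- diff(range(vv))
  sd_abs <- noise * rng
  if (sd_abs > 0) vv <- vv + rnorm(n_points, 0, sd_abs)
  out <- vt_curve(tt, vv, se = rep(sd_abs, n_points))
  attr(out, "truth") <- list(t_break = t_break, slope_gel = slope_gel,
                             slope_fluid = slope_fluid, v_break = v_break,
                             noise_sd = sd_abs)
  out
}
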