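#' Construct a temperature profile object
#'
#' A per-layer steady-state temperature profile with uncertainties, tied to
#' the heat flux that produced it.
#'
#' @param z layer-centre coordinates (A)
#' @param temperature mean layer temperatures (K); NA marks layers that were
#'   empty and are excluded from fits
#' @param se standard errors (K)
#' @param n_samples samples per layer
#' @param j_si associated heat flux, W m^-2
#' @return a tibble of class `temperature_profile` with attribute `j_si`
#' @export
temperature_profile <- function(z, temperature, se = rep(0, length(z)),
                                n_samples = rep(1L, length(z)), j_si = NA_real_) {
  stopifnot(length(z) == length(temperature), all(se >= 0, na.rm = TRUE))
  out <- tibble::tibble(layer = seq_along(z), z = z,
                        temperature = temperature, se = se,
                        n_samples = n_samples)
  attr(out, "j_si") <- j_si
  class(out) <- c("temperature_profile", class(out))
  out
}

#' Per-layer steady-state temperatures from an NEMD run
#'
#' Layer temperatures use T = 2 KE / (3 n kB) with 3n degrees of freedom per
#' layer (no per-layer COM subtraction; the bias is below 1 percent for the
#' layer occupancies used here). Only samples after the steady-state onset
#' (a fraction of the run, default the second half) enter the averages;
#' standard errors come from block averaging over `n_blocks` blocks.
#'
#' @param nemd an `nemd_run` from [run_nemd()]
#' @param steady_onset fraction of the sampled series to discard (default
#'   0.5); alternatively a length-2 vector of fractions giving an explicit
#'   sampling window
#' @param n_blocks number of blocks for the SE estimate (default 5)
#' @param layers optional subset of layer indices (e.g. the hot-to-cold half
#'   path); z is reported relative to the first selected layer's lower edge
#' @return a [temperature_profile()]
#' @export
layer_temperatures <- function(nemd, steady_onset = 0.5, n_blocks = 5,
                               layers = NULL) {
  ke <- nemd$layer_ke; cnt <- nemd$layer_cnt
  ns <- nrow(ke)
  if (ns < n_blocks) stop("not enough layer samples for block averaging")
  use <- if (length(steady_onset) == 2)
    seq(floor(ns * steady_onset[1]) + 1, floor(ns * steady_onset[2]))
  else seq(floor(ns * steady_onset) + 1, ns)
  ke <- ke[use, , drop = FALSE]; cnt <- cnt[use, , drop = FALSE]
  Tm <- ke / pmax(cnt, 1) / (1.5 * kB_kcalmol)
  Tm[cnt == 0] <- NA
  blocks <- cut(seq_along(use), n_blocks, labels = FALSE)
  mean_T <- colMeans(Tm, na.rm = TRUE)
  mean_T[colSums(!is.na(Tm)) == 0] <- NA
  se_T <- vapply(seq_len(ncol(Tm)), function(l) {
    bm <- tapply(Tm[, l], blocks, mean, na.rm = TRUE)
    bm <- bm[is.finite(bm)]
    if (length(bm) < 2) return(NA_real_)
    sd(bm) / sqrt(length(bm))
  }, numeric(1))
  zc <- layer_centers(nemd$box, nemd$partition)
  nvalid <- colSums(!is.na(Tm))
  if (!is.null(layers)) {
    w <- nemd$box$lengths[[match(nemd$partition$axis, c("x", "y", "z"))]] /
      nemd$partition$n_layers
    z0 <- (min(layers) - 1) * w
    prof <- temperature_profile(zc[layers] - z0, mean_T[layers], se_T[layers],
                                nvalid[layers], j_si = nemd$flux$j_si)
  } else {
    prof <- temperature_profile(zc, mean_T, se_T, nvalid,
                                j_si = nemd$flux$j_si)
  }
  attr(prof, "layer_width") <- zc[2] - zc[1]
  prof
}

#' Ordered contiguous regions along the flux axis
#'
#' @param labels segment labels, hot side first (e.g. WATER_HOT, LEAFLET_A,
#'   LEAFLET_B, WATER_COLD)
#' @param z0,z1 segment interval bounds (A); consecutive segments share a
#'   boundary
#' @param provenance "user" or "composition"
#' @return a tibble of class `region_spec`
#' @export
region_spec <- function(labels, z0, z1, provenance = "user") {
  stopifnot(length(labels) == length(z0), length(z0) == length(z1))
  if (any(z1 <= z0)) stop("segments must have z1 > z0")
  if (length(z0) > 1 && any(z0[-1] < z1[-length(z1)] - 1e-9))
    stop("segments must be ordered and non-overlapping")
  out <- tibble::tibble(label = labels, z0 = z0, z1 = z1)
  attr(out, "provenance") <- provenance
  class(out) <- c("region_spec", class(out))
  out
}

#' Detect water/leaflet regions from per-layer composition
#'
#' Boundaries are placed at bin edges where the per-layer majority group
#' changes between water and lipid; the leaflet A / leaflet B boundary sits
#' at the tail-tail midplane (from the per-layer tail leaflet fractions when
#' available, else the geometric centre of the lipid block).
#'
#' @param profile a [temperature_profile()] (supplies layer z centres)
#' @param composition n_layers x 3 matrix of WATER/HEAD/TAIL fractions
#' @param leaflet_comp optional n_layers x 2 matrix of tail leaflet fractions
#' @param fallback optional [region_spec()] returned (with a warning) when
#'   fewer than four majority regions are found
#' @return a [region_spec()] with provenance "composition"
#' @export
detect_regions <- function(profile, composition, leaflet_comp = NULL,
                           fallback = NULL) {
  z <- profile$z
  w <- if (length(z) > 1) z[2] - z[1] else 1
  lipfrac <- rowSums(composition[, 2:3, drop = FALSE])
  lip <- which(lipfrac > 0.5)
  ok <- length(lip) >= 4 &&
    min(lip) > 2 && max(lip) < length(z) - 1 &&
    mean(lipfrac[min(lip):max(lip)] > 0.5) >= 0.7
  if (!ok) {
    warning("could not identify a water | lipid | water layout; using fallback regions")
    if (!is.null(fallback)) return(fallback)
    return(region_spec("WATER_HOT", min(z) - w / 2, max(z) + w / 2,
                       provenance = "composition"))
  }
  zl0 <- z[min(lip)] - w / 2    # water->lipid bin edge
  zl1 <- z[max(lip)] + w / 2    # lipid->water bin edge
  if (!is.null(leaflet_comp)) {
    lip_layers <- min(lip):max(lip)
    f0 <- leaflet_comp[lip_layers, 1]
    cross <- which(f0[-length(f0)] >= 0.5 & f0[-1] < 0.5)
    zmid <- if (length(cross)) z[lip_layers[cross[1]]] + w / 2 else (zl0 + zl1) / 2
  } else {
    zmid <- (zl0 + zl1) / 2
  }
  region_spec(c("WATER_HOT", "LEAFLET_A", "LEAFLET_B", "WATER_COLD"),
              z0 = c(min(z) - w / 2, zl0, zmid, zl1),
              z1 = c(zl0, zmid, zl1, max(z) + w / 2),
              provenance = "composition")
}

#' Fit a linear temperature gradient within a segment
#'
#' Ordinary least squares of layer temperature on z over the layers inside
#' `[z0, z1]`, excluding layers within `gap` layer widths of an interior
#' boundary (interfacial discontinuities contaminate adjacent bins) and any
#' layer flagged missing.
#'
#' @param profile a [temperature_profile()]
#' @param z0,z1 segment bounds (A)
#' @param gap number of layers to exclude next to each interior boundary
#' @param interior logical length 2: whether z0 / z1 are interior boundaries
#' @return object of class `segment_fit`: slope (K/A), intercept, their SEs,
#'   R^2, and endpoint temperatures extrapolated to z0 and z1
#' @export
fit_segment <- function(profile, z0, z1, gap = 2, interior = c(TRUE, TRUE)) {
  w <- attr(profile, "layer_width")
  if (is.null(w)) w <- if (nrow(profile) > 1) profile$z[2] - profile$z[1] else 0
  lo <- z0 + if (interior[1]) gap * w else 0
  hi <- z1 - if (interior[2]) gap * w else 0
  keep <- profile$z >= lo - 1e-9 & profile$z <= hi + 1e-9 &
    !is.na(profile$temperature)
  m <- sum(keep)
  if (m < 3) stop("segment fit needs at least 3 non-missing layers")
  x <- profile$z[keep]; y <- profile$temperature[keep]
  X <- cbind(1, x)
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  s2 <- rss / max(m - 2, 1)
  XtXi <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXi) * s2)
  endpoint <- function(zz) {
    v <- c(1, zz)
    list(t = sum(v * fit$coefficients),
         se = sqrt(max(0, t(v) %*% XtXi %*% v * s2)))
  }
  e0 <- endpoint(z0); e1 <- endpoint(z1)
  structure(list(slope = fit$coefficients[[2]],
                 intercept = fit$coefficients[[1]],
                 se_slope = se[2], se_intercept = se[1],
                 r2 = if (tss > 0) 1 - rss / tss else 1,
                 n_layers = m, z0 = z0, z1 = z1,
                 t0 = e0$t, se_t0 = e0$se, t1 = e1$t, se_t1 = e1$se,
                 XtXi_s2 = XtXi * s2, coef = fit$coefficients),
            class = "segment_fit")
}

#' Extrapolate a segment fit to a coordinate
#' @param fit a [fit_segment()] result
#' @param z coordinate (A)
#' @return list(t, se)
#' @export
predict_segment <- function(fit, z) {
  v <- c(1, z)
  list(t = sum(v * fit$coef),
       se = sqrt(max(0, t(v) %*% fit$XtXi_s2 %*% v)))
}

#' Thermal conductivity of a segment
#'
#' K = J / |dT/dz|. The uncertainty is first-order propagation from the
#' slope standard error.
#'
#' @param fit a [fit_segment()] result (or anything with `slope`/`se_slope`)
#' @param j_si heat flux in W m^-2
#' @return list(K_si, se) in W m^-1 K^-1
#' @export
segment_conductivity <- function(fit, j_si) {
  sl <- fit$slope
  if (!is.finite(sl) || sl == 0)
    stop("undefined conductivity: zero temperature gradient in segment")
  K <- conductivity_si(j_si, sl)
  se <- if (is.finite(fit$se_slope)) K * fit$se_slope / abs(sl) else NA_real_
  list(K_si = K, se = se)
}

#' Interfacial (Kapitza) thermal resistance at a boundary
#'
#' Two equivalent routes, both exposed: `"jump"` takes the temperature
#' discontinuity between the two segment fits extrapolated to the boundary,
#' R_int = dT_jump / J; `"subtraction"` computes the total resistance of the
#' two adjacent segments end-to-end and subtracts each segment's own
#' resistance. At steady state heat flows hot to cold, so the jump must be a
#' drop; a negative jump raises a sign-convention warning.
#'
#' @param fit_left,fit_right [fit_segment()] results for the segments
#'   meeting at the boundary (left = hot side)
#' @param z boundary coordinate (A); must lie within both fits' ranges
#' @param j_si heat flux, W m^-2
#' @param method "jump" or "subtraction"
#' @return list(R_si, dT_jump, se) with R in m^2 K W^-1
#' @export
interface_resistance <- function(fit_left, fit_right, z, j_si,
                                 method = c("jump", "subtraction")) {
  method <- match.arg(method)
  if (z < fit_left$z0 - 1e-9 || z > fit_right$z1 + 1e-9)
    stop("boundary outside the segments' extrapolation range")
  pl <- predict_segment(fit_left, z)
  pr <- predict_segment(fit_right, z)
  if (method == "jump") {
    dT <- pl$t - pr$t
    R <- dT / j_si
  } else {
    r_tot <- (predict_segment(fit_left, fit_left$z0)$t -
                predict_segment(fit_right, fit_right$z1)$t) / j_si
    r_i <- (predict_segment(fit_left, fit_left$z0)$t - pl$t) / j_si
    r_j <- (pr$t - predict_segment(fit_right, fit_right$z1)$t) / j_si
    R <- r_tot - r_i - r_j
    dT <- R * j_si
  }
  if (is.finite(dT) && dT < 0)
    warning("negative temperature jump at interface: check hot/cold orientation")
  se <- sqrt(pl$se^2 + pr$se^2) / j_si
  list(R_si = R, dT_jump = dT, se = se)
}

#' Decompose a temperature profile into segment and interface resistances
#'
#' Fits each region, converts slopes to conductivities and temperature drops
#' to resistances (R = dT / J), computes every interior interface resistance
#' by both routes, and reports the series-closure residual
#' R_total - sum(R_seg) - sum(R_int), where R_total comes from the
#' end-to-end extrapolated temperature drop. Segment resistances are also
#' reported via the thickness/conductivity route d/K (identical analytically;
#' both appear in the output).
#'
#' @param profile a [temperature_profile()]
#' @param regions a [region_spec()] with at least 2 segments
#' @param j_si heat flux, W m^-2 (default: the profile's own flux)
#' @param gap layers excluded next to each interior boundary (default 2)
#' @return object of class `resistance_decomposition` with tibbles
#'   `segments` and `interfaces`, `R_total`, `closure` and the fits
#' @export
resistance_decomposition <- function(profile, regions,
                                     j_si = attr(profile, "j_si"), gap = 2) {
  ns <- nrow(regions)
  if (ns < 2) stop("need at least 2 segments")
  if (!all(abs(regions$z0[-1] - regions$z1[-ns]) < 1e-6))
    stop("regions must be contiguous and ordered")
  fits <- lapply(seq_len(ns), function(i)
    fit_segment(profile, regions$z0[i], regions$z1[i], gap = gap,
                interior = c(i > 1, i < ns)))
  seg <- lapply(seq_len(ns), function(i) {
    f <- fits[[i]]
    dT <- f$t0 - f$t1
    Kc <- segment_conductivity(f, j_si)
    thick <- f$z1 - f$z0
    tibble::tibble(label = regions$label[i], z0 = f$z0, z1 = f$z1,
                   thickness_A = thick, slope_K_per_A = f$slope, r2 = f$r2,
                   K_si = Kc$K_si, se_K = Kc$se,
                   R_si = dT / j_si,
                   se_R = sqrt(f$se_t0^2 + f$se_t1^2) / j_si,
                   R_from_K = conductivity_to_resistance(Kc$K_si, thick))
  })
  seg <- do.call(rbind, seg)
  ifc <- lapply(seq_len(ns - 1), function(i) {
    zb <- regions$z1[i]
    jmp <- interface_resistance(fits[[i]], fits[[i + 1]], zb, j_si, "jump")
    sub <- interface_resistance(fits[[i]], fits[[i + 1]], zb, j_si, "subtraction")
    tibble::tibble(between = paste(regions$label[i], regions$label[i + 1], sep = "|"),
                   z = zb, dT_jump = jmp$dT_jump,
                   R_si = jmp$R_si, R_subtraction = sub$R_si, se_R = jmp$se)
  })
  ifc <- do.call(rbind, ifc)
  R_total <- (predict_segment(fits[[1]], regions$z0[1])$t -
                predict_segment(fits[[ns]], regions$z1[ns])$t) / j_si
  closure <- R_total - sum(seg$R_si) - sum(ifc$R_si)
  structure(list(segments = seg, interfaces = ifc, R_total = R_total,
                 closure = closure, j_si = j_si, fits = fits,
                 regions = regions),
            class = "resistance_decomposition")
}

#' @export
print.resistance_decomposition <- function(x, ...) {
  cat(sprintf("<resistance_decomposition> J = %.4g W/m^2\n", x$j_si))
  s <- x$segments
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s K = %.3f W/m/K   R = %.3f e-9 m^2K/W (d = %.2f A)\n",
                s$label[i], s$K_si[i], s$R_si[i] * 1e9, s$thickness_A[i]))
  f <- x$interfaces
  for (i in seq_len(nrow(f)))
    cat(sprintf("  %-22s R_int = %.3f e-9 m^2K/W (jump %.3f K)\n",
                f$between[i], f$R_si[i] * 1e9, f$dT_jump[i]))
  cat(sprintf("  R_total = %.3f e-9, closure residual = %.2e\n",
              x$R_total * 1e9, x$closure))
  invisible(x)
}

#' Plot a temperature profile with fitted segments
#'
#' @param x a [temperature_profile()]
#' @param decomposition optional [resistance_decomposition()] whose fits are
#'   overlaid
#' @param ... unused
#' @export
plot.temperature_profile <- function(x, decomposition = NULL, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    plot(x$z, x$temperature, xlab = "z (A)", ylab = "T (K)")
    return(invisible(x))
  }
  p <- ggplot2::ggplot(x, ggplot2::aes(.data$z, .data$temperature)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$temperature - .data$se,
                                        ymax = .data$temperature + .data$se),
                           width = 0, alpha = 0.5) +
    ggplot2::labs(x = "z (Å)", y = "T (K)")
  if (!is.null(decomposition)) {
    segdf <- do.call(rbind, lapply(decomposition$fits, function(f)
      data.frame(z = c(f$z0, f$z1), temperature = c(f$t0, f$t1),
                 id = paste0(f$z0, "-", f$z1))))
    p <- p + ggplot2::geom_line(data = segdf,
                                ggplot2::aes(group = .data$id),
                                colour = "red")
  }
  p
}
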