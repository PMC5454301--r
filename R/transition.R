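#' Annealing / cooling schedule
#'
#' A monotone temperature ramp with a rate in K/ps; the number of MD steps
#' follows from the rate and the timestep.
#'
#' @param start_T,end_T ramp endpoints in K
#' @param rate ramp rate in K per ps (> 0)
#' @param dt timestep in fs
#' @return object of class `anneal_schedule`
#' @export
anneal_schedule <- function(start_T, end_T, rate = 0.2, dt = 2) {
  stopifnot(rate > 0, start_T > 0, end_T > 0, start_T != end_T)
  n_steps <- ceiling(abs(start_T - end_T) / rate * 1000 / dt)
  structure(list(start_T = start_T, end_T = end_T, rate = rate, dt = dt,
                 n_steps = as.integer(n_steps)),
            class = "anneal_schedule")
}

#' Specific-volume-vs-temperature curve
#'
#' @param temperature sample temperatures (K)
#' @param volume specific volumes (cm^3 g^-1, > 0)
#' @param se volume uncertainties
#' @return a tibble of class `vt_curve`
#' @export
vt_curve <- function(temperature, volume, se = rep(0, length(volume))) {
  stopifnot(length(temperature) == length(volume), all(volume > 0))
  out <- tibble::tibble(temperature = temperature, volume = volume, se = se)
  class(out) <- c("vt_curve", class(out))
  out
}

#' Cooling scan under pressure control
#'
#' Ramps the system from `schedule$start_T` down (or up) to `schedule$end_T`
#' under NPT (Nose-Hoover thermostat, Berendsen barostat), recording the
#' specific volume v = V / M along the way. Structures are sampled at
#' `n_samples` random temperatures inside the ramp (seed the R RNG for
#' reproducibility): mode `"onfly"` averages the logged volume over a short
#' window around each sampling temperature; mode `"requench"` re-equilibrates
#' at each sampled temperature with a short NPT run before measuring.
#'
#' @param system a [particle_system()]
#' @param ff a [forcefield_params()]
#' @param box a [sim_box()]
#' @param schedule an [anneal_schedule()]
#' @param n_samples number of sampled temperatures (default 23)
#' @param target_P barostat target, atm
#' @param mode "onfly" or "requench"
#' @param tau_P,beta_P barostat coupling time (fs) and compressibility
#'   (atm^-1) passed to the integrator
#' @param scale duration scale factor for desk-scale runs (multiplies the
#'   schedule's step count)
#' @param p_couple barostat coupling, "iso" or "z"
#' @param requench_steps NPT steps per sampled temperature in requench mode
#' @return a [vt_curve()] with attribute `log` (the full NPT log)
#' @export
run_cooling_scan <- function(system, ff, box, schedule, n_samples = 23,
                             target_P = 1, mode = c("onfly", "requench"),
                             scale = 1, p_couple = "iso",
                             tau_P = 500, beta_P = 4.6e-5,
                             requench_steps = 500) {
  mode <- match.arg(mode)
  n_steps <- max(50L, as.integer(schedule$n_steps * scale))
  log_every <- max(1L, n_steps %/% 2000L)
  mass_tot <- sum(system$mass)
  t_samp <- sort(runif(n_samples, min(schedule$start_T, schedule$end_T),
                       max(schedule$start_T, schedule$end_T)),
                 decreasing = schedule$start_T > schedule$end_T)
  run <- run_md(system, ff, box, n_steps = n_steps, dt = schedule$dt,
                ensemble = "npt", ramp_T = c(schedule$start_T, schedule$end_T),
                target_P = target_P, tau_P = tau_P, beta_P = beta_P,
                p_couple = p_couple, log_every = log_every, traj_every = 0)
  lg <- run$log
  # barostat divergence guard: volume change within any 10-row window
  v <- lg$volume_A3
  if (length(v) > 10) {
    w <- 10
    vr <- v[seq(w + 1, length(v))] / v[seq_len(length(v) - w)]
    if (any(vr > 1.5 | vr < 0.5))
      stop("barostat divergence: volume changed by more than 50% in one window")
  }
  ramp_T_at <- schedule$start_T +
    (schedule$end_T - schedule$start_T) * lg$step / n_steps
  if (mode == "onfly") {
    vols <- vapply(t_samp, function(tt) {
      i <- which.min(abs(ramp_T_at - tt))
      win <- max(1, i - 10):min(length(v), i + 10)
      c(mean(v[win]), sd(v[win]) / sqrt(length(win)))
    }, numeric(2))
  } else {
    state <- system
    bx <- box
    vols <- matrix(NA_real_, 2, length(t_samp))
    for (k in seq_along(t_samp)) {
      r <- run_md(state, ff, bx, n_steps = requench_steps, dt = schedule$dt,
                  ensemble = "npt", target_T = t_samp[k], target_P = target_P,
                  tau_P = tau_P, beta_P = beta_P, p_couple = p_couple,
                  log_every = max(1L, requench_steps %/% 50L))
      state <- r$system; bx <- r$box
      tailv <- tail(r$log$volume_A3, 25)
      vols[, k] <- c(mean(tailv), sd(tailv) / sqrt(length(tailv)))
    }
  }
  out <- vt_curve(t_samp, specific_volume(vols[1, ], mass_tot),
                  specific_volume(vols[2, ], mass_tot))
  attr(out, "log") <- lg
  out
}

# continuous two-segment piecewise-linear SSE at break c:
# v = a + b1*min(t-c,0) + b2*max(t-c,0)
.pwl_fit <- function(tt, vv, cbrk) {
  X <- cbind(1, pmin(tt - cbrk, 0), pmax(tt - cbrk, 0))
  f <- lm.fit(X, vv)
  list(sse = sum(f$residuals^2), coef = f$coefficients)
}

.pwl_best <- function(tt, vv, grid_n = 200) {
  ts <- sort(tt)
  n <- length(ts)
  lo <- ts[3]; hi <- ts[n - 2]
  if (hi <= lo) return(NULL)
  grid <- unique(sort(c(seq(lo, hi, length.out = grid_n),
                        ts[ts >= lo & ts <= hi])))
  sse <- vapply(grid, function(cc) .pwl_fit(tt, vv, cc)$sse, numeric(1))
  best <- grid[which.min(sse)]
  span <- max(diff(grid))
  op <- optimize(function(cc) .pwl_fit(tt, vv, cc)$sse,
                 lower = max(lo, best - 2 * span),
                 upper = min(hi, best + 2 * span), tol = 1e-8)
  if (op$objective <= min(sse)) best <- op$minimum
  fit <- .pwl_fit(tt, vv, best)
  list(t_break = best, sse = fit$sse,
       slope_low = fit$coef[[2]], slope_high = fit$coef[[3]],
       level = fit$coef[[1]])
}

#' Detect a phase transition as a slope change in v(T)
#'
#' Fits a continuous two-segment piecewise-linear model over a dense grid of
#' candidate break temperatures (restricted so at least 3 points lie on each
#' side) and takes the break minimising the total SSE. The fit is accepted
#' only if its AIC improves on a single straight line; otherwise no
#' transition is reported. The confidence interval comes from a seeded
#' bootstrap over points (resampling with replacement).
#'
#' @param curve a [vt_curve()]
#' @param n_boot bootstrap resamples for the CI (default 1000; 0 disables)
#' @param level CI level (default 0.95)
#' @return object of class `transition_estimate` with `t_m`, `slope_gel`
#'   (low-T side), `slope_fluid` (high-T side), `ci`, `sse`, and
#'   `transition_detected`
#' @export
detect_transition <- function(curve, n_boot = 1000, level = 0.95) {
  tt <- curve$temperature; vv <- curve$volume
  n <- length(tt)
  if (n < 6) stop("need at least 6 points (3 per side of a candidate break)")
  two <- .pwl_best(tt, vv)
  X1 <- cbind(1, tt)
  f1 <- lm.fit(X1, vv)
  sse1 <- sum(f1$residuals^2)
  aic <- function(sse, k) n * log(max(sse, 1e-300) / n) + 2 * k
  aic1 <- aic(sse1, 3)
  aic2 <- if (is.null(two)) Inf else aic(two$sse, 5)
  # a numerically perfect straight line needs no break
  line_perfect <- sse1 <= 1e-16 * n * stats::var(vv)
  if (is.null(two) || line_perfect || aic2 >= aic1) {
    return(structure(list(transition_detected = FALSE, t_m = NA_real_,
                          slope_gel = NA_real_, slope_fluid = NA_real_,
                          ci = c(NA_real_, NA_real_), sse = sse1,
                          message = "no transition detected"),
                     class = "transition_estimate"))
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    bs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) < 6) return(NA_real_)
      r <- tryCatch(.pwl_best(tt[idx], vv[idx], grid_n = 60),
                    error = function(e) NULL)
      if (is.null(r)) NA_real_ else r$t_break
    }, numeric(1))
    bs <- bs[is.finite(bs)]
    if (length(bs) >= 50) {
      a <- (1 - level) / 2
      ci <- unname(quantile(bs, c(a, 1 - a)))
      ci[1] <- min(ci[1], two$t_break)  # the CI always contains the estimate
      ci[2] <- max(ci[2], two$t_break)
    }
  }
  structure(list(transition_detected = TRUE, t_m = two$t_break,
                 slope_gel = two$slope_low, slope_fluid = two$slope_high,
                 ci = ci, sse = two$sse, message = "ok"),
            class = "transition_estimate")
}

#' @export
print.transition_estimate <- function(x, ...) {
  if (!x$transition_detected) {
    cat("<transition_estimate> no transition detected\n")
  } else {
    cat(sprintf("<transition_estimate> T_m = %.2f K (CI %.2f-%.2f), slopes %.3g / %.3g\n",
                x$t_m, x$ci[1], x$ci[2], x$slope_gel, x$slope_fluid))
  }
  invisible(x)
}
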