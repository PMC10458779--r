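# Forward chamber simulator: a canopy absorption model drives chamber CO2
# drawdown, with optional first-order leakage, scheduled injections and
# additive sensor noise, and carries exact ground truth so every estimator
# can be validated closed-loop without external data.

#' Scenario configuration for the chamber simulator
#'
#' The default scenario emulates a 20-day tuber-formation run in a sealed
#' 40 m^3 growth chamber at 22 degC: whole-plant uptake ramps up with a
#' logistic canopy-growth multiplier, switches sign to dark respiration
#' outside the photoperiod, and draws an initially elevated 1200 ppm
#' atmosphere down by several hundred ppm.
#'
#' @param chamber A \code{chamber_spec}.
#' @param plant A \code{plant_params} (stoichiometric mode used for the
#'   ground-truth tuber series).
#' @param duration Run length, s (default 20 days).
#' @param step Integration/sampling step, s (default 60; must be < duration).
#' @param initial_co2 Initial chamber CO2 mole fraction, ppm.
#' @param a_max Peak whole-plant CO2 uptake, molecules/s.
#' @param canopy_half_time Time at which the logistic canopy multiplier
#'   reaches 1/2, s (default 6 days).
#' @param canopy_steepness Logistic steepness, 1/s (default 1/(1.5 days)).
#' @param photoperiod_hours Light hours per 24 h day (0-24, default 16).
#' @param respiration_fraction Dark respiration as a fraction of the
#'   canopy-scaled uptake (default 0.1); flips net uptake negative at night.
#' @param noise_sd Sensor noise standard deviation, ppm (default 2).
#' @param seed Integer seed for the noise generator.
#' @return An object of class \code{scenario_config}.
#' @export
scenario_config <- function(chamber = chamber_spec(volume = 40,
                                                   temperature = 295.15,
                                                   pressure = 101325),
                            plant = plant_params(eta_starch = 0.2,
                                                 m_tubers0 = 0.225),
                            duration = 20 * 86400, step = 60,
                            initial_co2 = 1200, a_max = 1.2e18,
                            canopy_half_time = 6 * 86400,
                            canopy_steepness = 1 / (1.5 * 86400),
                            photoperiod_hours = 16,
                            respiration_fraction = 0.1,
                            noise_sd = 2, seed = 1L) {
  stopifnot(inherits(chamber, "chamber_spec"),
            inherits(plant, "plant_params"),
            duration > step, step > 0, a_max >= 0,
            photoperiod_hours >= 0, photoperiod_hours <= 24,
            respiration_fraction >= 0, noise_sd >= 0,
            initial_co2 >= 0)
  structure(list(chamber = chamber, plant = plant, duration = duration,
                 step = step, initial_co2 = initial_co2, a_max = a_max,
                 canopy_half_time = canopy_half_time,
                 canopy_steepness = canopy_steepness,
                 photoperiod_hours = photoperiod_hours,
                 respiration_fraction = respiration_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario> %.3g days @ %g s step, %g ppm start, A_max %.3g molec/s\n",
    x$duration / 86400, x$step, x$initial_co2, x$a_max))
  cat(sprintf("  photoperiod %g h, respiration %g, noise sd %g ppm, seed %d\n",
              x$photoperiod_hours, x$respiration_fraction, x$noise_sd,
              x$seed))
  print(x$chamber)
  invisible(x)
}

#' Whole-plant absorption rate at a set of times
#'
#' A_max times a logistic canopy-growth multiplier, times +1 during the
#' photoperiod and minus the respiration fraction during darkness. Light
#' hours start at the beginning of each 24 h day.
#'
#' @param cfg A \code{scenario_config}.
#' @param times Numeric vector of times, s.
#' @return Net uptake rate, molecules/s (negative during dark respiration).
#' @export
absorption_rate <- function(cfg, times) {
  canopy <- 1 / (1 + exp(-cfg$canopy_steepness *
                           (times - cfg$canopy_half_time)))
  light <- (times %% 86400) < cfg$photoperiod_hours * 3600
  cfg$a_max * canopy * ifelse(light, 1, -cfg$respiration_fraction)
}

#' Simulate a chamber CO2 trace with ground truth
#'
#' Explicit Euler stepping of the chamber balance
#' dn/dt = -A(t)/V - k (n - n_amb), with scheduled injections applied as
#' impulses at their step boundary and absorption saturating at the CO2
#' actually available (n never goes below zero). Sensor noise is added
#' i.i.d. Gaussian in ppm under the configured seed; the ground-truth tuber
#' series is computed from the exactly accumulated absorption, not from the
#' trace.
#'
#' @param cfg A \code{scenario_config}.
#' @return An object of class \code{synthetic_experiment}: list with
#'   \code{trace} (noisy ppm \code{gas_series}), \code{clean_trace},
#'   \code{truth} (a \code{tuber_mass_series}), \code{cumulative_absorbed}
#'   (final molecule count) and \code{config}.
#' @export
simulate_chamber <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  ch <- cfg$chamber
  V <- ch$volume
  k <- ch$leak_coefficient
  dt <- cfg$step
  times <- seq(0, cfg$duration, by = dt)
  nsteps <- length(times) - 1L
  n0 <- ppm_to_number_concentration(cfg$initial_co2, ch$temperature,
                                    ch$pressure)
  rate <- absorption_rate(cfg, times[seq_len(nsteps)])

  inj_conc <- rep(0, nsteps)  # concentration added at the END of step i
  if (!is.null(ch$injections)) {
    inj <- ch$injections
    if (any(inj$time <= 0) || any(inj$time > cfg$duration))
      stop("injection times must lie in (0, duration]", call. = FALSE)
    idx <- pmin(pmax(ceiling(inj$time / dt), 1L), nsteps)
    for (i in seq_along(idx))
      inj_conc[idx[i]] <- inj_conc[idx[i]] + inj$molecules[i] / V
  }

  n <- numeric(nsteps + 1L)
  n[1] <- n0
  absorbed <- numeric(nsteps + 1L)  # cumulative molecules, exact bookkeeping
  for (i in seq_len(nsteps)) {
    uptake <- rate[i] * dt / V           # concentration units
    leak <- k * (n[i] - ch$ambient_co2) * dt
    new_n <- n[i] - uptake - leak
    if (new_n < 0 && uptake > 0) {       # absorption saturates at available CO2
      uptake <- max(uptake + new_n, 0)
      new_n <- n[i] - uptake - leak
    }
    if (new_n < 0) new_n <- 0            # leak overshoot at coarse steps
    n[i + 1L] <- new_n + inj_conc[i]
    absorbed[i + 1L] <- absorbed[i] + uptake * V
  }

  clean_ppm <- number_concentration_to_ppm(n, ch$temperature, ch$pressure)
  clean_trace <- gas_series(times, clean_ppm, unit = "ppm")
  noisy_ppm <- clean_ppm
  if (cfg$noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(cfg$seed)
    noisy_ppm <- pmax(clean_ppm + stats::rnorm(length(clean_ppm),
                                               sd = cfg$noise_sd), 0)
  }
  trace <- gas_series(times, noisy_ppm, unit = "ppm")
  truth <- .tuber_series(times, absorbed, cfg$plant, note = "ground truth")
  structure(list(trace = trace, clean_trace = clean_trace, truth = truth,
                 cumulative_absorbed = absorbed[length(absorbed)],
                 config = cfg),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("<synthetic_experiment>\n")
  n <- nrow(x$trace)
  cat(sprintf("  trace: %d samples, %g -> %.1f ppm\n", n, x$trace$co2[1],
              x$trace$co2[n]))
  cat(sprintf("  truth: final mass %.4g kg, absorbed %.4g molecules\n",
              x$truth$mass[nrow(x$truth)], x$cumulative_absorbed))
  invisible(x)
}

#' Packaged area-specific leaf CO2 flux profile
#'
#' A smooth 20-day hump-shaped profile of the area-specific CO2 mass
#' absorption rate over the tuber-formation period, peaking mid-period, for
#' exercising the integral leaf-flux estimator. The default leaf area is
#' 0.38 m^2 (3800 cm^2). This is a synthetic stand-in profile constructed
#' by the package, scaled so a plant with the default parameters absorbs
#' roughly a quarter kilogram of CO2 over the period.
#'
#' @param leaf_area Leaf area S, m^2 (default 0.38).
#' @param peak Peak flux, kg m^-2 s^-1 (default 7.6e-7).
#' @param duration Profile length, s (default 20 days).
#' @param step Sample spacing, s (default 3600).
#' @return A \code{flux_series}.
#' @export
bundled_flux_profile <- function(leaf_area = 0.38, peak = 7.6e-7,
                                 duration = 20 * 86400, step = 3600) {
  times <- seq(0, duration, by = step)
  flux <- peak * sin(pi * times / duration)^2
  flux_series(times, flux, leaf_area = leaf_area)
}
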