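# Core estimators: sealed-chamber tuber mass from CO2 drawdown, tuber mass
# from integrated area-specific leaf flux, starch/tuber conversions, the
# biomass-partition correction and model-vs-observation comparison.

#' Whole-plant biomass to tuber biomass ratio at 20-24 degC
#'
#' Literature value used to correct the estimator for carbon sinks other
#' than tubers (stem, leaves, roots) and metabolic CO2 costs.
#' @export
PARTITION_RATIO_20_24C <- 1.46

.stoich_modes <- c("mass_balance", "as_published_drawdown", "as_published_flux")

#' Plant parameters for the tuber-mass estimators
#'
#' @param eta_starch Starch mass fraction of tuber fresh mass, in (0, 1].
#'   Varietal range is roughly 0.10-0.25; values outside it trigger a
#'   warning. Default 0.2.
#' @param m_tubers0 Tuber mass at planting (t = 0), kg (>= 0).
#' @param partition_ratio Whole-plant biomass / tuber biomass, >= 1. The
#'   predicted mass increment is divided by this ratio; 1 disables the
#'   correction. The constant \code{PARTITION_RATIO_20_24C} (1.46) is
#'   provided.
#' @param mode Stoichiometric mode, see Details.
#'
#' @details The net starch-synthesis reaction stores ONE C6H10O5 monomer per
#' SIX absorbed CO2 molecules. \code{"mass_balance"} (the default) uses that
#' elementally conserving reading: each absorbed CO2 molecule contributes
#' m1/(6 eta) of tuber mass. The published rate equation instead multiplies
#' the CO2 drawdown by six, so \code{"as_published_drawdown"} (factor 6 m1 / eta
#' per molecule) and \code{"as_published_flux"} (factor 6/eta applied to the
#' absorbed CO2 MASS, the integral leaf-flux form) reproduce the printed
#' formulas literally and emit a warning when active.
#'
#' @return An object of class \code{plant_params}.
#' @export
plant_params <- function(eta_starch = 0.2, m_tubers0 = 0,
                         partition_ratio = 1,
                         mode = c("mass_balance", "as_published_drawdown",
                                  "as_published_flux")) {
  mode <- match.arg(mode)
  stopifnot(eta_starch > 0, eta_starch <= 1, m_tubers0 >= 0,
            partition_ratio >= 1)
  if (eta_starch < 0.10 || eta_starch > 0.25)
    warning(sprintf(
      "eta_starch = %g is outside the varietal range 0.10-0.25", eta_starch),
      call. = FALSE)
  structure(list(eta_starch = eta_starch, m_tubers0 = m_tubers0,
                 partition_ratio = partition_ratio, mode = mode),
            class = "plant_params")
}

#' @export
print.plant_params <- function(x, ...) {
  cat(sprintf(
    "<plant> eta_starch = %g, m_tubers0 = %g kg, partition = %g, mode = %s\n",
    x$eta_starch, x$m_tubers0, x$partition_ratio, x$mode))
  invisible(x)
}

.warn_if_published <- function(p) {
  if (p$mode != "mass_balance")
    warning(sprintf(
      "stoichiometric mode '%s' reproduces the published formula literally; ",
      p$mode), "it is not elementally conserving", call. = FALSE)
}

#' Tuber mass gained per absorbed CO2 molecule
#'
#' The conversion factor between absorbed CO2 molecule count and tuber fresh
#' mass, before any partition correction.
#'
#' @param p A \code{plant_params}.
#' @return kg tuber per absorbed CO2 molecule.
#' @examples
#' per_molecule_factor(plant_params(eta_starch = 0.2))  # ~2.24e-25 kg
#' @export
per_molecule_factor <- function(p) {
  stopifnot(inherits(p, "plant_params"))
  m1 <- molecule_mass_kg("C6H10O5")
  switch(p$mode,
    mass_balance = m1 / (6 * p$eta_starch),
    as_published_drawdown = 6 * m1 / p$eta_starch,
    as_published_flux = (6 / p$eta_starch) * molecule_mass_kg("CO2")
  )
}

#' Tuber mass gained per kilogram of absorbed CO2
#'
#' \code{per_molecule_factor} divided by the mass of one CO2 molecule; the
#' factor applied to the integrated CO2 mass in the leaf-flux estimator.
#'
#' @inheritParams per_molecule_factor
#' @return kg tuber per kg CO2.
#' @export
per_mass_factor <- function(p) {
  per_molecule_factor(p) / molecule_mass_kg("CO2")
}

.tuber_series <- function(times, absorbed_molecules, p, note = NULL) {
  gain <- per_molecule_factor(p) * absorbed_molecules / p$partition_ratio
  mass <- p$m_tubers0 + gain
  out <- data.frame(time = times, mass = mass,
                    starch_mass = p$eta_starch * mass,
                    absorbed_co2_molecules = absorbed_molecules)
  structure(out, class = c("tuber_mass_series", "data.frame"),
            params = p, note = note,
            negative_segments = any(diff(absorbed_molecules) < 0))
}

#' @export
print.tuber_mass_series <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<tuber_mass_series> %d samples over %g s\n", n, max(x$time)))
  cat(sprintf("  final mass %.4g kg (%.4g g), absorbed %.4g CO2 molecules\n",
              x$mass[n], x$mass[n] * 1000, x$absorbed_co2_molecules[n]))
  if (isTRUE(attr(x, "negative_segments")))
    cat("  note: series contains negative-drawdown (net release) segments\n")
  invisible(x)
}

#' Clamp a tuber-mass series at zero
#'
#' The raw estimate retains sign (net CO2 release drives the increment
#' negative); this view floors mass and starch mass at zero for reporting.
#'
#' @param x A \code{tuber_mass_series}.
#' @return The series with \code{mass} and \code{starch_mass} floored at 0.
#' @export
clamp_nonnegative <- function(x) {
  stopifnot(inherits(x, "tuber_mass_series"))
  x$mass <- pmax(x$mass, 0)
  x$starch_mass <- pmax(x$starch_mass, 0)
  attr(x, "clamped") <- TRUE
  x
}

#' Tuber mass from a sealed-chamber CO2 drawdown
#'
#' In a sealed chamber the drawdown n(0) - n(t) times the volume is exactly
#' the net number of CO2 molecules absorbed by the plant, so
#' m(t) = m0 + f * V * (n(0) - n(t)) / partition_ratio with f the
#' per-molecule factor of the active stoichiometric mode.
#'
#' @param s A \code{gas_series} with at least 2 samples.
#' @param chamber A sealed \code{chamber_spec} (zero leak, no injections).
#' @param p A \code{plant_params}.
#' @return A \code{tuber_mass_series}.
#' @export
tuber_mass_sealed <- function(s, chamber, p) {
  stopifnot(inherits(s, "gas_series"), inherits(chamber, "chamber_spec"),
            inherits(p, "plant_params"))
  if (!is_sealed(chamber))
    stop("chamber spec has a leak coefficient or injections; ",
         "use tuber_mass_unsealed()", call. = FALSE)
  if (nrow(s) < 2) stop("need at least 2 samples", call. = FALSE)
  .warn_if_published(p)
  n <- to_number_concentration(s, chamber)$co2
  absorbed <- chamber$volume * (n[1] - n)
  .tuber_series(s$time, absorbed, p, note = "sealed")
}

#' Area-specific CO2 flux series
#'
#' @param times Seconds, strictly increasing.
#' @param flux Area-specific CO2 mass absorption rate, kg m^-2 s^-1; may be
#'   negative (net respiration).
#' @param leaf_area Leaf area S, m^2 (> 0).
#' @return A data frame of class \code{flux_series} with attribute
#'   \code{leaf_area}.
#' @export
flux_series <- function(times, flux, leaf_area) {
  stopifnot(is.numeric(times), is.numeric(flux),
            length(times) == length(flux), leaf_area > 0)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  structure(data.frame(time = times, flux = flux),
            leaf_area = leaf_area,
            class = c("flux_series", "data.frame"))
}

#' @export
print.flux_series <- function(x, ...) {
  cat(sprintf("<flux_series> %d samples over %g s, S = %g m^2\n",
              nrow(x), max(x$time), attr(x, "leaf_area")))
  invisible(x)
}

#' Tuber mass from integrated leaf CO2 flux
#'
#' Integral form of the sealed-chamber estimator: the cumulative absorbed CO2
#' mass M(t) = S * integral of the area-specific flux is obtained by
#' composite trapezoid quadrature on the native sample grid, then converted
#' to tuber mass with the active mode's per-mass factor.
#'
#' @param f A \code{flux_series} with at least 2 samples.
#' @param p A \code{plant_params}.
#' @return A \code{tuber_mass_series}.
#' @export
tuber_mass_from_flux <- function(f, p) {
  stopifnot(inherits(f, "flux_series"), inherits(p, "plant_params"))
  if (nrow(f) < 2) stop("need at least 2 samples", call. = FALSE)
  .warn_if_published(p)
  S <- attr(f, "leaf_area")
  co2_mass <- S * pracma::cumtrapz(f$time, f$flux)[, 1]
  absorbed_molecules <- co2_mass / molecule_mass_kg("CO2")
  .tuber_series(f$time, absorbed_molecules, p, note = "flux")
}

#' Starch mass stored in a given tuber mass
#'
#' @param m_tubers Tuber mass, kg (>= 0).
#' @param p A \code{plant_params}.
#' @return Starch mass, kg (eta_starch * m_tubers).
#' @export
starch_from_tubers <- function(m_tubers, p) {
  stopifnot(inherits(p, "plant_params"))
  if (any(m_tubers < 0)) stop("tuber mass must be >= 0", call. = FALSE)
  p$eta_starch * m_tubers
}

#' Tuber mass holding a given starch mass
#' @param m_starch Starch mass, kg (>= 0).
#' @param p A \code{plant_params}.
#' @return Tuber mass, kg (m_starch / eta_starch).
#' @export
tubers_from_starch <- function(m_starch, p) {
  stopifnot(inherits(p, "plant_params"))
  if (any(m_starch < 0)) stop("starch mass must be >= 0", call. = FALSE)
  m_starch / p$eta_starch
}

#' CO2 drawdown required for a target tuber-mass gain
#'
#' Inverse of the sealed estimator, for experiment design: the drop in
#' number concentration that corresponds to a given mass gain in a given
#' chamber under the active mode and partition ratio.
#'
#' @param target_gain Target tuber mass gain, kg (>= 0).
#' @param chamber A \code{chamber_spec}.
#' @param p A \code{plant_params}.
#' @return Required drawdown n(0) - n(T), molecules/m^3.
#' @export
required_drawdown <- function(target_gain, chamber, p) {
  stopifnot(inherits(chamber, "chamber_spec"), inherits(p, "plant_params"))
  if (target_gain < 0) stop("target gain must be >= 0", call. = FALSE)
  target_gain * p$partition_ratio /
    (per_molecule_factor(p) * chamber$volume)
}

#' Compare a predicted final mass with an observed one
#'
#' @param predicted_final Model-predicted final tuber mass, kg.
#' @param observed_final Experimentally measured final tuber mass, kg (> 0).
#' @param digits Decimals for the reported ratio (default 2).
#' @return A list of class \code{model_comparison}: \code{ratio} (raw),
#'   \code{ratio_rounded}, \code{abs_error} (predicted - observed, kg) and
#'   \code{rel_error} (signed, relative to observed).
#' @examples
#' compare_to_observation(7.82, 5.24)  # ratio 1.49
#' @export
compare_to_observation <- function(predicted_final, observed_final,
                                   digits = 2) {
  if (observed_final <= 0)
    stop("observed mass must be > 0", call. = FALSE)
  ratio <- predicted_final / observed_final
  structure(list(predicted = predicted_final, observed = observed_final,
                 ratio = ratio, ratio_rounded = round(ratio, digits),
                 abs_error = predicted_final - observed_final,
                 rel_error = (predicted_final - observed_final) /
                   observed_final),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "predicted %.4g kg vs observed %.4g kg: ratio %.2f (error %+.3g kg, %+.1f%%)\n",
    x$predicted, x$observed, x$ratio_rounded, x$abs_error,
    100 * x$rel_error))
  invisible(x)
}
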