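# Unsealed-chamber extensions: first-order leakage towards ambient CO2 and
# scheduled instantaneous injections. The plant-absorbed CO2 is recovered
# from the measured trace by chamber mass balance:
#   V (n(0) - n(t)) = absorbed(t) + leaked(t) - injected(t)

#' Recover plant CO2 absorption from an unsealed-chamber trace
#'
#' The cumulative leak is k V * integral of (n - n_ambient) dt (composite
#' trapezoid on the sample grid); injections are counted as step increments
#' at their scheduled times; the cumulative absorption is whatever is left
#' of the observed drawdown after crediting both.
#'
#' @param s A \code{gas_series} with at least 2 samples.
#' @param chamber A \code{chamber_spec}; its \code{leak_coefficient},
#'   \code{ambient_co2} and \code{injections} define the exchange model.
#'   Injection times must lie within the series time span.
#' @return A data frame of class \code{absorption_estimate} with columns
#'   \code{time}, \code{absorbed_molecules}, \code{leaked_molecules} and
#'   \code{injected_molecules} (all cumulative; leaked is signed).
#' @export
recover_absorption <- function(s, chamber) {
  stopifnot(inherits(s, "gas_series"), inherits(chamber, "chamber_spec"))
  if (nrow(s) < 2) stop("need at least 2 samples", call. = FALSE)
  n <- to_number_concentration(s, chamber)$co2
  t <- s$time
  V <- chamber$volume
  k <- chamber$leak_coefficient
  leaked <- if (k > 0) {
    k * V * pracma::cumtrapz(t, n - chamber$ambient_co2)[, 1]
  } else rep(0, length(t))
  injected <- rep(0, length(t))
  if (!is.null(chamber$injections)) {
    inj <- chamber$injections
    if (any(inj$time < t[1]) || any(inj$time > t[length(t)]))
      stop("injection time(s) outside the series time span", call. = FALSE)
    for (i in seq_len(nrow(inj)))
      injected <- injected + ifelse(t >= inj$time[i], inj$molecules[i], 0)
  }
  absorbed <- V * (n[1] - n) + injected - leaked
  structure(data.frame(time = t, absorbed_molecules = absorbed,
                       leaked_molecules = leaked,
                       injected_molecules = injected),
            class = c("absorption_estimate", "data.frame"))
}

#' @export
print.absorption_estimate <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<absorption_estimate> %d samples over %g s\n", n, x$time[n]))
  cat(sprintf("  absorbed %.4g, leaked %.4g, injected %.4g molecules\n",
              x$absorbed_molecules[n], x$leaked_molecules[n],
              x$injected_molecules[n]))
  invisible(x)
}

#' Tuber mass from an unsealed-chamber CO2 trace
#'
#' Runs \code{recover_absorption} and converts the cumulative absorbed
#' molecule count to tuber mass exactly as the sealed estimator does. With a
#' zero leak and no injections this reduces to \code{tuber_mass_sealed}.
#'
#' @inheritParams recover_absorption
#' @param p A \code{plant_params}.
#' @return A \code{tuber_mass_series}.
#' @export
tuber_mass_unsealed <- function(s, chamber, p) {
  stopifnot(inherits(p, "plant_params"))
  .warn_if_published(p)
  est <- recover_absorption(s, chamber)
  .tuber_series(est$time, est$absorbed_molecules, p, note = "unsealed")
}

#' Estimate a chamber leak coefficient from a plant-free decay trace
#'
#' Convenience fit beyond the mass-balance model itself: with no plant in
#' the chamber, n(t) relaxes as n_amb + (n0 - n_amb) exp(-k t), so a
#' log-linear regression of n - n_ambient on time yields k as minus the
#' slope.
#'
#' @param s A \code{gas_series} from a plant-free chamber.
#' @param chamber A \code{chamber_spec} supplying T, P and
#'   \code{ambient_co2}.
#' @return Estimated leak coefficient k, 1/s.
#' @export
estimate_leak_coefficient <- function(s, chamber) {
  stopifnot(inherits(s, "gas_series"), inherits(chamber, "chamber_spec"))
  n <- to_number_concentration(s, chamber)$co2
  excess <- n - chamber$ambient_co2
  keep <- excess > 0
  if (sum(keep) < 3)
    stop("need at least 3 samples above ambient to fit a decay",
         call. = FALSE)
  fit <- stats::lm(log(excess[keep]) ~ s$time[keep])
  k <- -unname(stats::coef(fit)[2])
  if (k < 0)
    warning("fitted leak coefficient is negative; trace is not a decay",
            call. = FALSE)
  k
}
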