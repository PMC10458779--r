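# Chamber state and CO2 time series: mole fraction (ppm), number
# concentration (molecules/m^3), mass concentration (kg/m^3), and total
# molecule count N = n * V. Ideal-gas behaviour throughout.

#' Boltzmann constant (exact SI), J/K
#' @keywords internal
.k_B <- 1.380649e-23

.gas_units <- c("ppm", "molec_m3", "kg_m3")

#' Chamber specification
#'
#' Geometry and environment of a cultivation chamber: volume, temperature and
#' pressure (treated as constant over a run), plus the unsealed-chamber
#' extensions — a first-order leak coefficient towards an ambient CO2 level,
#' and a schedule of instantaneous CO2 injections.
#'
#' @param volume Chamber volume, m^3 (> 0).
#' @param temperature Air temperature, K (> 0).
#' @param pressure Air pressure, Pa (> 0).
#' @param leak_coefficient First-order leak rate constant, 1/s (>= 0;
#'   0 = sealed).
#' @param ambient_co2 Ambient CO2 number concentration the leak relaxes
#'   towards, molecules/m^3 (or ppm if \code{ambient_unit = "ppm"}).
#' @param ambient_unit Unit of \code{ambient_co2}: \code{"molec_m3"} or
#'   \code{"ppm"}.
#' @param injections Optional data frame with columns \code{time} (s,
#'   strictly increasing) and \code{molecules} (CO2 molecule count added
#'   instantaneously, > 0).
#' @return An object of class \code{chamber_spec}.
#' @examples
#' chamber_spec(volume = 40, temperature = 295.15, pressure = 101325)
#' @export
chamber_spec <- function(volume, temperature = 295.15, pressure = 101325,
                         leak_coefficient = 0, ambient_co2 = 0,
                         ambient_unit = c("molec_m3", "ppm"),
                         injections = NULL) {
  ambient_unit <- match.arg(ambient_unit)
  stopifnot(is.numeric(volume), length(volume) == 1L, volume > 0,
            temperature > 0, pressure > 0, leak_coefficient >= 0,
            ambient_co2 >= 0)
  if (ambient_unit == "ppm")
    ambient_co2 <- ppm_to_number_concentration(ambient_co2, temperature,
                                               pressure)
  if (!is.null(injections)) {
    stopifnot(is.data.frame(injections),
              all(c("time", "molecules") %in% names(injections)))
    injections <- injections[order(injections$time), , drop = FALSE]
    if (nrow(injections) > 1 && any(diff(injections$time) <= 0))
      stop("injection times must be strictly increasing", call. = FALSE)
    stopifnot(all(injections$molecules > 0))
  }
  structure(list(volume = volume, temperature = temperature,
                 pressure = pressure, leak_coefficient = leak_coefficient,
                 ambient_co2 = ambient_co2, injections = injections),
            class = "chamber_spec")
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat(sprintf("<chamber> V = %g m^3, T = %.2f K, P = %g Pa\n",
              x$volume, x$temperature, x$pressure))
  if (x$leak_coefficient > 0)
    cat(sprintf("  leak k = %g 1/s towards ambient %.4g molecules/m^3\n",
                x$leak_coefficient, x$ambient_co2))
  if (!is.null(x$injections))
    cat(sprintf("  %d scheduled injection(s)\n", nrow(x$injections)))
  invisible(x)
}

#' Is a chamber spec sealed?
#' @param c A \code{chamber_spec}.
#' @return TRUE when the leak coefficient is zero and no injections are
#'   scheduled.
#' @export
is_sealed <- function(c) {
  stopifnot(inherits(c, "chamber_spec"))
  c$leak_coefficient == 0 && is.null(c$injections)
}

#' CO2 time series
#'
#' @param times Numeric timestamps in seconds, strictly increasing (they are
#'   shifted so the first sample is t = 0), or POSIXct / ISO-8601 strings,
#'   normalised to seconds from the first sample.
#' @param values CO2 level per timestamp, >= 0.
#' @param unit One of \code{"ppm"} (mole fraction), \code{"molec_m3"}
#'   (number concentration) or \code{"kg_m3"} (mass concentration).
#' @return A data frame of class \code{gas_series} with columns \code{time}
#'   and \code{co2} and attribute \code{unit}.
#' @export
gas_series <- function(times, values, unit = c("ppm", "molec_m3", "kg_m3")) {
  unit <- match.arg(unit)
  if (inherits(times, "POSIXt")) times <- as.numeric(times)
  if (is.character(times)) {
    parsed <- as.POSIXct(times, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                        "%Y-%m-%d %H:%M:%OS",
                                        "%Y-%m-%d %H:%M",
                                        "%Y-%m-%d"))
    if (anyNA(parsed))
      stop("unparseable timestamp(s): ",
           paste(utils::head(times[is.na(parsed)], 3), collapse = ", "),
           call. = FALSE)
    times <- as.numeric(parsed)
  }
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(values < 0)) stop("CO2 values must be >= 0", call. = FALSE)
  structure(data.frame(time = times - times[1], co2 = as.numeric(values)),
            unit = unit, class = c("gas_series", "data.frame"))
}

#' @export
print.gas_series <- function(x, ...) {
  cat(sprintf("<gas_series> %d samples over %g s, unit = %s\n",
              nrow(x), if (nrow(x)) max(x$time) else 0, attr(x, "unit")))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Convert a CO2 mole fraction to a number concentration
#'
#' Ideal-gas conversion n = x * 1e-6 * P / (k_B * T).
#'
#' @param x Mole fraction in ppm (>= 0).
#' @param temperature Temperature, K (> 0).
#' @param pressure Pressure, Pa (> 0).
#' @return Number concentration, molecules/m^3.
#' @examples
#' ppm_to_number_concentration(400, 293.15, 101325)  # ~1.001e22
#' @export
ppm_to_number_concentration <- function(x, temperature, pressure) {
  if (any(x < 0)) stop("mole fraction must be >= 0", call. = FALSE)
  if (any(temperature <= 0) || any(pressure <= 0))
    stop("temperature and pressure must be > 0", call. = FALSE)
  x * 1e-6 * pressure / (.k_B * temperature)
}

#' Convert a number concentration to a CO2 mole fraction in ppm
#' @param n Number concentration, molecules/m^3 (>= 0).
#' @inheritParams ppm_to_number_concentration
#' @return Mole fraction, ppm.
#' @export
number_concentration_to_ppm <- function(n, temperature, pressure) {
  if (any(n < 0)) stop("number concentration must be >= 0", call. = FALSE)
  if (any(temperature <= 0) || any(pressure <= 0))
    stop("temperature and pressure must be > 0", call. = FALSE)
  n * .k_B * temperature / pressure * 1e6
}

#' Convert a gas series to number concentration
#'
#' Mole fractions use the chamber's temperature and pressure; mass
#' concentrations divide by the mass of one CO2 molecule.
#'
#' @param s A \code{gas_series}.
#' @param chamber A \code{chamber_spec} supplying T and P.
#' @return A \code{gas_series} in \code{"molec_m3"}, same times.
#' @export
to_number_concentration <- function(s, chamber) {
  stopifnot(inherits(s, "gas_series"), inherits(chamber, "chamber_spec"))
  unit <- attr(s, "unit")
  vals <- switch(unit,
    molec_m3 = s$co2,
    ppm = ppm_to_number_concentration(s$co2, chamber$temperature,
                                      chamber$pressure),
    kg_m3 = s$co2 / molecule_mass_kg("CO2"),
    stop("unknown gas series unit: ", unit, call. = FALSE)
  )
  gas_series(s$time, vals, unit = "molec_m3")
}

#' Total CO2 molecule count in the chamber
#'
#' N(t) = n(t) * V for every sample of the series.
#'
#' @inheritParams to_number_concentration
#' @return Numeric vector of molecule counts, one per sample.
#' @export
molecule_count <- function(s, chamber) {
  n <- to_number_concentration(s, chamber)
  n$co2 * chamber$volume
}

#' Read a delimited CO2 time series
#'
#' Comma- or tab-separated text with a header; required columns \code{time}
#' and \code{co2}, optional \code{temperature} and \code{pressure} columns
#' are carried along as attributes (their means) for convenience. A comment
#' line of the form \code{# unit: ppm} may declare the unit, otherwise it
#' must be supplied.
#'
#' @param path File path.
#' @param unit Unit of the co2 column; overrides any header directive.
#' @return A \code{gas_series}.
#' @export
read_gas_series <- function(path, unit = NULL) {
  lines <- readLines(path, warn = FALSE)
  directive <- grep("^#\\s*unit\\s*:", lines, value = TRUE)
  if (is.null(unit) && length(directive)) {
    unit <- trimws(sub("^#\\s*unit\\s*:", "", directive[1]))
  }
  if (is.null(unit))
    stop("no unit given and no '# unit:' directive in ", path, call. = FALSE)
  unit <- match.arg(unit, .gas_units)
  body <- lines[!grepl("^#", lines)]
  sep <- if (grepl("\t", body[1])) "\t" else ","
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("time", "co2") %in% names(df)))
    stop("series file must have columns 'time' and 'co2': ", path,
         call. = FALSE)
  s <- gas_series(df$time, df$co2, unit = unit)
  if ("temperature" %in% names(df))
    attr(s, "temperature") <- mean(df$temperature)
  if ("pressure" %in% names(df))
    attr(s, "pressure") <- mean(df$pressure)
  s
}

#' Write a gas series as delimited text
#'
#' Emits a \code{# unit:} directive followed by a comma-separated table with
#' columns \code{time} and \code{co2}, the dialect \code{read_gas_series}
#' accepts.
#'
#' @param s A \code{gas_series}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_gas_series <- function(s, path) {
  stopifnot(inherits(s, "gas_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# unit: ", attr(s, "unit")), con)
  utils::write.table(as.data.frame(s), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
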