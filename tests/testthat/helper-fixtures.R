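# Shared fixtures: hand-computed atomic-weight sums used as independent
# oracles, generators for random balanced reactions and random monotone
# drawdown traces.

# independent hand sums of IUPAC standard atomic weights
# (C 12.011, H 1.008, O 15.999, Mg 24.305, N 14.007)
ORACLE_MM <- list(
  starch_monomer = 6 * 12.011 + 10 * 1.008 + 5 * 15.999,   # 162.141
  glucose        = 6 * 12.011 + 12 * 1.008 + 6 * 15.999,   # 180.156
  co2            = 12.011 + 2 * 15.999,                    # 44.009
  water          = 2 * 1.008 + 15.999,                     # 18.015
  chlorophyll    = 55 * 12.011 + 72 * 1.008 + 24.305 + 4 * 14.007 + 5 * 15.999
)
AVOGADRO <- 6.02214076e23
BOLTZMANN <- 1.380649e-23

default_chamber <- function(...) {
  chamber_spec(volume = 40, temperature = 295.15, pressure = 101325, ...)
}

# a pool of balanced reactions to draw random positive combinations from
balanced_pool <- function() {
  st <- stage_reactions()
  list(
    st$glucose_synthesis,
    st$glucose_breakdown,
    st$starch_polymerisation,
    reaction(c(CH4 = 1, O2 = 2), c(CO2 = 1, H2O = 2)),
    reaction(c(C6H12O6 = 1, O2 = 6), c(CO2 = 6, H2O = 6))
  )
}

random_balanced_combination <- function(pool) {
  k <- sample(2:4, 1)
  picks <- sample(seq_along(pool), k, replace = TRUE)
  terms <- lapply(picks, function(i) {
    r <- pool[[i]]
    if (stats::runif(1) < 0.3) r <- reverse_reaction(r)
    list(sample(1:4, 1), r)
  })
  combine_reactions(terms)
}

# strictly decreasing (or flat) random ppm trace in a sealed chamber
random_monotone_trace <- function(n = 50, start_ppm = 1200) {
  t <- cumsum(stats::runif(n, 30, 120))
  drops <- c(0, cumsum(stats::runif(n - 1, 0, 5)))
  gas_series(t, start_ppm - drops, unit = "ppm")
}
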