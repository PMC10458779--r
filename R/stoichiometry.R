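# Chemical formula parsing, molar masses, and exact reaction algebra for the
# four lumped photosynthesis stages that together synthesise one starch
# monomer (C6H10O5) from CO2.

# IUPAC standard atomic weights (conventional values, 2-3 d.p.), bundled so
# molar masses never depend on an external service. Covers the biogenic
# elements plus common crop-nutrition elements.
.atomic_weights <- c(
  H = 1.008, He = 4.003, Li = 6.94, B = 10.81, C = 12.011, N = 14.007,
  O = 15.999, F = 18.998, Na = 22.990, Mg = 24.305, Al = 26.982,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
  Ca = 40.078, Mn = 54.938, Fe = 55.845, Co = 58.933, Ni = 58.693,
  Cu = 63.546, Zn = 65.38, Se = 78.971, Mo = 95.95, I = 126.904
)

#' Avogadro constant (exact SI), molecules per mole
#' @keywords internal
.N_A <- 6.02214076e23

#' Parse a chemical formula
#'
#' Parses a Hill-style formula without parentheses or charges, e.g.
#' \code{"C6H10O5"} (starch monomer) or \code{"C55H72MgN4O5"} (chlorophyll),
#' into a named element-count vector.
#'
#' @param text A single formula string. Element symbols must carry a leading
#'   capital; counts are positive integers, an omitted count meaning 1.
#' @return An object of class \code{chem_formula}: a named integer vector of
#'   element counts, in Hill order (C, then H, then the rest alphabetically).
#' @examples
#' parse_formula("C6H10O5")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) return(chem_formula(integer(0)))
  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[1]))
      stop(sprintf("malformed formula '%s' at position %d ('%s')",
                   text, pos, substr(text, pos, pos)), call. = FALSE)
    sym <- m[2]
    if (!sym %in% names(.atomic_weights)) {
      # a two-letter guess may have swallowed a lowercase char wrongly;
      # there is no backtracking case among tabulated symbols we support,
      # so reject outright
      stop(sprintf("unknown element symbol '%s' in '%s' at position %d",
                   sym, text, pos), call. = FALSE)
    }
    k <- if (nzchar(m[3])) as.integer(m[3]) else 1L
    if (is.na(k) || k < 1L)
      stop(sprintf("invalid count for element '%s' in '%s'", sym, text),
           call. = FALSE)
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + k
    pos <- pos + nchar(m[1])
  }
  chem_formula(counts)
}

#' Construct a chem_formula from a named count vector
#' @param counts named integer vector, element symbol -> count >= 1
#' @return A \code{chem_formula} in canonical Hill order.
#' @export
chem_formula <- function(counts) {
  if (length(counts)) {
    stopifnot(!is.null(names(counts)), all(nzchar(names(counts))))
    nm <- names(counts)
    counts <- as.integer(round(counts))
    names(counts) <- nm
    if (any(counts < 1L)) stop("element counts must be >= 1", call. = FALSE)
    bad <- setdiff(names(counts), names(.atomic_weights))
    if (length(bad))
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    counts <- counts[.hill_order(names(counts))]
  }
  structure(as.integer(counts), names = names(counts), class = "chem_formula")
}

.hill_order <- function(symbols) {
  rest <- sort(setdiff(symbols, c("C", "H")))
  out <- c(intersect(c("C", "H"), symbols), rest)
  match(out, symbols)
}

#' @export
format.chem_formula <- function(x, ...) {
  if (!length(x)) return("")
  paste0(names(x), ifelse(x == 1L, "", x), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Molar mass of a formula
#'
#' Sum of element counts times IUPAC standard atomic weights.
#'
#' @param f A \code{chem_formula} or a formula string.
#' @return Molar mass in g/mol.
#' @examples
#' molar_mass("C6H10O5")  # 162.14
#' @export
molar_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "chem_formula"))
  if (!length(f)) return(0)
  sum(unname(f) * .atomic_weights[names(f)])
}

#' Mass of a single molecule in kilograms
#'
#' Molar mass divided by the Avogadro constant. For the starch monomer
#' C6H10O5 this is about 2.69e-25 kg (27e-26 kg).
#'
#' @inheritParams molar_mass
#' @return Mass of one molecule, kg.
#' @examples
#' molecule_mass_kg("C6H10O5")
#' @export
molecule_mass_kg <- function(f) {
  molar_mass(f) / .N_A / 1000
}

# ---- rational arithmetic for reaction coefficients -------------------------
# Coefficients are exact rationals (integer num/den) so that stage-reaction
# cancellation is exact, never a floating-point near-zero.

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

.rat <- function(num, den = 1L) {
  stopifnot(den != 0)
  if (den < 0) { num <- -num; den <- -den }
  g <- .gcd(num, den)
  if (g > 0) { num <- num / g; den <- den / g }
  c(num = num, den = den)
}

.rat_add <- function(x, y) .rat(x[1] * y[2] + y[1] * x[2], x[2] * y[2])
.rat_mul <- function(x, y) .rat(x[1] * y[1], x[2] * y[2])
.rat_num <- function(x) x[[1]] / x[[2]]

.as_rat <- function(x) {
  # accept integers, or simple fractions expressed as doubles (den <= 1e6)
  if (length(x) == 2L && !is.null(names(x))) return(.rat(x[["num"]], x[["den"]]))
  if (x == round(x)) return(.rat(round(x)))
  for (den in 2:1000000) {
    num <- x * den
    if (abs(num - round(num)) < 1e-9) return(.rat(round(num), den))
  }
  stop("coefficient is not representable as a small rational: ", x,
       call. = FALSE)
}

# ---- reactions -------------------------------------------------------------

#' Construct a chemical reaction
#'
#' A reaction is two multisets of (coefficient, species) terms. Species are
#' either parsed element-count formulas or opaque tokens such as \code{"ATP"}
#' and \code{"E_hv"}, which carry through the algebra but are excluded from
#' elemental balance.
#'
#' @param reactants,products Named numeric vectors: names are formula strings
#'   or opaque tokens, values are positive coefficients (integers or simple
#'   fractions).
#' @param tokens Character vector of species names to treat as opaque tokens
#'   rather than parse as formulas. Defaults to \code{c("ATP", "E_hv")}.
#' @return An object of class \code{reaction}.
#' @examples
#' glucose_synthesis <- reaction(
#'   c(CO2 = 6, H2O = 6, ATP = 1),
#'   c(C6H12O6 = 1, O2 = 6)
#' )
#' @export
reaction <- function(reactants, products, tokens = c("ATP", "E_hv")) {
  mk_side <- function(v, side) {
    if (!length(v)) return(list())
    stopifnot(!is.null(names(v)), all(nzchar(names(v))))
    lapply(seq_along(v), function(i) {
      coef <- .as_rat(unname(v[i]))
      if (.rat_num(coef) <= 0)
        stop("coefficients must be > 0", call. = FALSE)
      sp <- names(v)[i]
      opaque <- sp %in% tokens
      list(species = if (opaque) sp else format(parse_formula(sp)),
           opaque = opaque, coef = coef)
    })
  }
  r <- structure(list(reactants = mk_side(reactants, "reactant"),
                      products = mk_side(products, "product")),
                 class = "reaction")
  .canonicalise(r)
}

# merge duplicate species within each side, cancel species present on both
# sides down to the net amount, drop zero coefficients
.canonicalise <- function(r) {
  net <- list()   # species -> list(opaque, coef) ; coef > 0 reactant side
  absorb <- function(terms, sign) {
    for (tm in terms) {
      key <- tm$species
      cur <- if (key %in% names(net)) net[[key]]$coef else .rat(0L)
      add <- if (sign > 0) tm$coef else .rat(-tm$coef[1], tm$coef[2])
      net[[key]] <<- list(opaque = tm$opaque, coef = .rat_add(cur, add))
    }
  }
  absorb(r$reactants, +1)
  absorb(r$products, -1)
  reactants <- list(); products <- list()
  for (key in names(net)) {
    v <- .rat_num(net[[key]]$coef)
    if (v > 0) {
      reactants[[length(reactants) + 1L]] <-
        list(species = key, opaque = net[[key]]$opaque, coef = net[[key]]$coef)
    } else if (v < 0) {
      cf <- net[[key]]$coef
      products[[length(products) + 1L]] <-
        list(species = key, opaque = net[[key]]$opaque,
             coef = .rat(-cf[1], cf[2]))
    }
  }
  structure(list(reactants = reactants, products = products),
            class = "reaction")
}

.side_string <- function(terms) {
  if (!length(terms)) return("(nothing)")
  paste(vapply(terms, function(tm) {
    v <- .rat_num(tm$coef)
    cstr <- if (tm$coef[2] == 1L) {
      if (tm$coef[1] == 1L) "" else paste0(tm$coef[1], " ")
    } else paste0(tm$coef[1], "/", tm$coef[2], " ")
    paste0(cstr, tm$species)
  }, character(1)), collapse = " + ")
}

#' @export
format.reaction <- function(x, ...) {
  paste(.side_string(x$reactants), "->", .side_string(x$products))
}

#' @export
print.reaction <- function(x, ...) {
  cat("<reaction> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Reverse a reaction
#' @param r A \code{reaction}.
#' @return The reaction with reactant and product sides swapped.
#' @export
reverse_reaction <- function(r) {
  stopifnot(inherits(r, "reaction"))
  structure(list(reactants = r$products, products = r$reactants),
            class = "reaction")
}

#' Linearly combine reactions with positive multipliers
#'
#' Scales each reaction by its multiplier, sums coefficients per species, and
#' cancels any species appearing on both sides down to the net amount. This is
#' the operation that collapses the glucose-synthesis, glucose-breakdown and
#' starch-polymerisation stages into the net starch-synthesis reaction.
#'
#' @param terms A list of \code{list(multiplier, reaction)} pairs (multiplier
#'   a positive integer or simple fraction).
#' @return The combined, canonicalised \code{reaction}.
#' @examples
#' st <- stage_reactions()
#' combine_reactions(list(list(2, st$glucose_synthesis),
#'                        list(1, st$glucose_breakdown),
#'                        list(1, st$starch_polymerisation)))
#' @export
combine_reactions <- function(terms) {
  stopifnot(is.list(terms), length(terms) >= 1L)
  all_r <- list(); all_p <- list()
  for (tm in terms) {
    mult <- .as_rat(tm[[1]])
    if (.rat_num(mult) <= 0) stop("multipliers must be > 0", call. = FALSE)
    r <- tm[[2]]
    stopifnot(inherits(r, "reaction"))
    scale_side <- function(side) lapply(side, function(t2) {
      t2$coef <- .rat_mul(t2$coef, mult); t2
    })
    all_r <- c(all_r, scale_side(r$reactants))
    all_p <- c(all_p, scale_side(r$products))
  }
  .canonicalise(structure(list(reactants = all_r, products = all_p),
                          class = "reaction"))
}

#' Per-element balance report for a reaction
#'
#' Opaque energy-carrier tokens (ATP, E_hv) are excluded from the elemental
#' ledger. Imbalance is reported, not thrown.
#'
#' @param r A \code{reaction}.
#' @return A data frame with columns \code{element}, \code{reactants},
#'   \code{products}, \code{balanced}, plus attribute \code{balanced} (logical
#'   scalar: every element balances).
#' @export
check_balanced <- function(r) {
  stopifnot(inherits(r, "reaction"))
  tally <- function(terms) {
    tot <- numeric(0)
    for (tm in terms) {
      if (tm$opaque) next
      f <- parse_formula(tm$species)
      for (el in names(f)) {
        tot[el] <- (if (el %in% names(tot)) tot[[el]] else 0) +
          .rat_num(tm$coef) * f[[el]]
      }
    }
    tot
  }
  lhs <- tally(r$reactants); rhs <- tally(r$products)
  els <- union(names(lhs), names(rhs))
  els <- els[.hill_order(els)]
  get0n <- function(v, el) if (el %in% names(v)) v[[el]] else 0
  out <- data.frame(
    element = els,
    reactants = vapply(els, get0n, numeric(1), v = lhs),
    products = vapply(els, get0n, numeric(1), v = rhs),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$balanced <- abs(out$reactants - out$products) < 1e-9
  attr(out, "balanced") <- all(out$balanced)
  out
}

#' Coefficient of a species in a reaction
#'
#' @param r A \code{reaction}.
#' @param species Formula string or token naming the species.
#' @param side \code{"reactants"} or \code{"products"}.
#' @return Numeric coefficient (0 if absent from that side).
#' @export
species_coefficient <- function(r, species, side = c("reactants", "products")) {
  side <- match.arg(side)
  key <- if (species %in% c("ATP", "E_hv")) species else
    format(parse_formula(species))
  for (tm in r[[side]]) if (tm$species == key) return(.rat_num(tm$coef))
  0
}

#' The four lumped photosynthesis stage reactions
#'
#' Stage 1 stores light energy in ATP via chlorophyll (quantitatively inert:
#' the light-energy term is an opaque token with no magnitude). Stage 2
#' synthesises glucose from CO2 and water in the canopy; in the tuber, glucose
#' is either respired back to CO2 releasing ATP (stage 3) or polymerised into
#' a starch monomer using that ATP (stage 4).
#'
#' @return Named list of \code{reaction} objects:
#'   \code{atp_synthesis}, \code{glucose_synthesis}, \code{glucose_breakdown},
#'   \code{starch_polymerisation}.
#' @export
stage_reactions <- function() {
  list(
    atp_synthesis = reaction(
      c(C55H72MgN4O5 = 1, E_hv = 1), c(ATP = 1)),
    glucose_synthesis = reaction(
      c(CO2 = 6, H2O = 6, ATP = 1), c(C6H12O6 = 1, O2 = 6)),
    glucose_breakdown = reaction(
      c(C6H12O6 = 1, O2 = 6), c(CO2 = 6, H2O = 6, ATP = 1)),
    starch_polymerisation = reaction(
      c(C6H12O6 = 1, ATP = 1), c(C6H10O5 = 1, H2O = 1))
  )
}

#' Derive the net starch-synthesis stoichiometry
#'
#' Combines two units of glucose synthesis with one unit each of glucose
#' breakdown and starch polymerisation, eliminating glucose and closing the
#' ATP budget. The result is the net reaction
#' 6 CO2 + 5 H2O + 2 ATP -> C6H10O5 + 6 O2: six CO2 molecules are consumed
#' per starch monomer stored.
#'
#' @return An object of class \code{net_stoichiometry} with fields
#'   \code{co2_per_monomer}, \code{h2o_per_monomer}, \code{atp_per_monomer},
#'   \code{o2_released_per_monomer}, \code{monomer_mass_kg}, and
#'   \code{net_reaction}.
#' @export
derive_net_stoichiometry <- function() {
  st <- stage_reactions()
  net <- combine_reactions(list(
    list(2, st$glucose_synthesis),
    list(1, st$glucose_breakdown),
    list(1, st$starch_polymerisation)
  ))
  bal <- check_balanced(net)
  if (!attr(bal, "balanced"))
    stop("internal error: bundled stage reactions do not cancel to a ",
         "balanced net reaction", call. = FALSE)
  out <- list(
    co2_per_monomer = species_coefficient(net, "CO2", "reactants"),
    h2o_per_monomer = species_coefficient(net, "H2O", "reactants"),
    atp_per_monomer = species_coefficient(net, "ATP", "reactants"),
    o2_released_per_monomer = species_coefficient(net, "O2", "products"),
    monomer_mass_kg = molecule_mass_kg("C6H10O5"),
    net_reaction = net,
    balance = bal
  )
  if (out$co2_per_monomer != out$o2_released_per_monomer ||
      species_coefficient(net, "C6H10O5", "products") != 1)
    stop("internal error: net reaction does not yield one starch monomer ",
         "with matched CO2/O2 counts", call. = FALSE)
  class(out) <- "net_stoichiometry"
  out
}

#' @export
print.net_stoichiometry <- function(x, ...) {
  cat("Net starch-synthesis stoichiometry\n")
  cat("  ", format(x$net_reaction), "\n", sep = "")
  cat(sprintf("  CO2 per monomer:  %d\n", x$co2_per_monomer))
  cat(sprintf("  H2O per monomer:  %d\n", x$h2o_per_monomer))
  cat(sprintf("  ATP per monomer:  %d\n", x$atp_per_monomer))
  cat(sprintf("  O2 released:      %d\n", x$o2_released_per_monomer))
  cat(sprintf("  monomer mass m1:  %.4g kg (%.2f x 1e-26 kg)\n",
              x$monomer_mass_kg, x$monomer_mass_kg / 1e-26))
  invisible(x)
}
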