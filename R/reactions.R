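# Reactions are stored with exact rational coefficients (integer numerator /
# denominator pairs) so that element and charge balance can be checked with
# integer arithmetic rather than floating-point tolerances. Energies are the
# only place floats enter.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}

lcm2 <- function(a, b) a / gcd2(a, b) * b

parse_coef <- function(txt) {
  # "5" or "3/2" (optionally negative) -> c(num, den), reduced
  if (grepl("^-?[0-9]+$", txt)) return(c(as.numeric(txt), 1))
  m <- regmatches(txt, regexec("^(-?[0-9]+)/([0-9]+)$", txt))[[1]]
  if (length(m) != 3) stop("cannot parse coefficient: ", txt)
  num <- as.numeric(m[2]); den <- as.numeric(m[3])
  g <- gcd2(num, den)
  c(num / g, den / g)
}

#' Construct a reaction from species names and rational coefficients
#'
#' Reactants carry negative coefficients, products positive. Coefficients may
#' be integers or strings like `"1/2"`; they are stored exactly.
#'
#' @param species character vector of species names.
#' @param coef numeric or character vector of signed coefficients.
#' @param description free text.
#' @return an object of class `chem_reaction`.
#' @export
reaction <- function(species, coef, description = "") {
  stopifnot(length(species) == length(coef))
  parsed <- lapply(as.character(coef), parse_coef)
  structure(list(species = species,
                 num = vapply(parsed, `[`, numeric(1), 1),
                 den = vapply(parsed, `[`, numeric(1), 2),
                 description = description),
            class = "chem_reaction")
}

#' Parse a plain-text reaction equation
#'
#' Grammar: terms separated by `" + "`, sides separated by `"->"`; each term
#' is an optional coefficient (integer or `a/b` fraction) followed by a
#' species name; charges are written as trailing signed integers on the name
#' (`"SO4-2"`, `"H+"`). Example:
#' `"5 HS- + 8 NO3- + 3 H+ -> 5 SO4-2 + 4 N2 + 4 H2O"`.
#'
#' @param equation equation string.
#' @param description free text stored on the reaction.
#' @return a [reaction()].
#' @export
parse_reaction <- function(equation, description = equation) {
  sides <- strsplit(equation, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) stop("equation must contain exactly one '->': ", equation)
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(list(species = character(0), coef = character(0)))
    terms <- trimws(strsplit(txt, " + ", fixed = TRUE)[[1]])
    sp <- character(length(terms)); cf <- character(length(terms))
    for (i in seq_along(terms)) {
      toks <- strsplit(terms[i], "[[:space:]]+")[[1]]
      if (length(toks) == 1) {
        sp[i] <- toks; cf[i] <- if (sign > 0) "1" else "-1"
      } else if (length(toks) == 2) {
        parse_coef(toks[1])  # validates
        sp[i] <- toks[2]
        cf[i] <- if (sign > 0) toks[1] else paste0("-", toks[1])
      } else stop("cannot parse reaction term: ", terms[i])
    }
    list(species = sp, coef = cf)
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  reaction(c(lhs$species, rhs$species), c(lhs$coef, rhs$coef), description)
}

#' @export
print.chem_reaction <- function(x, ...) {
  fmt <- ifelse(x$den == 1, format(abs(x$num)), paste0(abs(x$num), "/", x$den))
  lhs <- paste(fmt[x$num < 0], x$species[x$num < 0], collapse = " + ")
  rhs <- paste(fmt[x$num > 0], x$species[x$num > 0], collapse = " + ")
  cat(lhs, "->", rhs, "\n")
  invisible(x)
}

#' Check element and charge balance of a reaction
#'
#' Residuals are computed with exact integer arithmetic over the least common
#' denominator of the coefficients; `ok` is TRUE iff every residual is
#' exactly zero. A report is always returned, never an error.
#'
#' @param rxn a [reaction()].
#' @param lib a [species_library()].
#' @return list with `ok`, named `element_residuals`, and `charge_residual`
#'   (per reaction as written).
#' @export
check_balance <- function(rxn, lib = species_library()) {
  if (length(rxn$species) == 0) {
    return(list(ok = TRUE, element_residuals = numeric(0), charge_residual = 0))
  }
  sp <- lapply(rxn$species, lookup_species, lib = lib)
  D <- Reduce(lcm2, rxn$den, accumulate = FALSE)
  scaled <- rxn$num * (D / rxn$den)  # exact integers (doubles below 2^53)
  elements <- unique(unlist(lapply(sp, function(s) names(s$composition))))
  resid <- vapply(elements, function(el) {
    sum(scaled * vapply(sp, function(s) {
      n <- s$composition[el]; if (is.na(n)) 0 else as.numeric(n)
    }, numeric(1)))
  }, numeric(1))
  charge <- sum(scaled * vapply(sp, function(s) as.numeric(s$charge), numeric(1)))
  list(ok = all(resid == 0) && charge == 0,
       element_residuals = resid / D,
       charge_residual = charge / D)
}

#' Standard-state Gibbs free energy of a balanced reaction
#'
#' Pure state-function sum, `dG0 = sum(coef * dGf0)`, at 298 K, 1 atm, 1 M
#' (including H+ at 1 M, i.e. pH 0); no activity corrections. When the
#' reaction consumes nitrate the energy per mol nitrate reduced is reported
#' alongside.
#'
#' @param rxn a [reaction()]; must pass [check_balance()].
#' @param lib a [species_library()]; every species needs a `dGf0`.
#' @return list of class `reaction_energy`: `reaction`, `dG0` (kJ per
#'   reaction as written), `dG0_per_nitrate` (kJ per mol NO3- reduced, or NA).
#' @export
delta_g_standard <- function(rxn, lib = species_library()) {
  bal <- check_balance(rxn, lib)
  if (!bal$ok) {
    stop("reaction is not balanced; element residuals: ",
         paste(names(bal$element_residuals), bal$element_residuals,
               sep = "=", collapse = ", "),
         "; charge residual: ", bal$charge_residual)
  }
  dgf <- vapply(rxn$species, function(nm) lookup_species(lib, nm)$dGf0, numeric(1))
  if (anyNA(dgf)) {
    stop("missing dGf0 for species: ",
         paste(rxn$species[is.na(dgf)], collapse = ", "))
  }
  dG0 <- sum(rxn$num / rxn$den * dgf)
  i <- match("NO3-", rxn$species)
  per_no3 <- if (!is.na(i) && rxn$num[i] < 0) {
    dG0 / abs(rxn$num[i] / rxn$den[i])
  } else NA_real_
  structure(list(reaction = rxn, dG0 = dG0, dG0_per_nitrate = per_no3),
            class = "reaction_energy")
}

#' Transformed standard free energy at pH 7
#'
#' Shifts H+ from 1 M to 1e-7 M activity: `dG0' = dG0 + nu_H * RT * ln(1e-7)`
#' where `nu_H` is the signed H+ coefficient. Provided for convenience; the
#' package default convention everywhere is pH 0.
#'
#' @param energy a [delta_g_standard()] result.
#' @param temperature_K temperature, default 298.15.
#' @return kJ per reaction as written.
#' @export
delta_g_ph7 <- function(energy, temperature_K = 298.15) {
  rxn <- energy$reaction
  i <- match("H+", rxn$species)
  nu <- if (is.na(i)) 0 else rxn$num[i] / rxn$den[i]
  R <- 8.31446e-3  # kJ/mol/K
  energy$dG0 + nu * R * temperature_K * log(1e-7)
}

#' Add two reactions coefficient-wise
#'
#' @param r1,r2 [reaction()]s.
#' @return the coefficient-wise sum (species union), exact rationals.
#' @export
reaction_add <- function(r1, r2) {
  sp <- union(r1$species, r2$species)
  num <- den <- numeric(length(sp))
  for (i in seq_along(sp)) {
    a <- match(sp[i], r1$species); b <- match(sp[i], r2$species)
    n1 <- if (is.na(a)) 0 else r1$num[a]; d1 <- if (is.na(a)) 1 else r1$den[a]
    n2 <- if (is.na(b)) 0 else r2$num[b]; d2 <- if (is.na(b)) 1 else r2$den[b]
    D <- lcm2(d1, d2)
    n <- n1 * (D / d1) + n2 * (D / d2)
    g <- if (n == 0) D else gcd2(n, D)
    num[i] <- n / g; den[i] <- D / g
  }
  keep <- num != 0
  reaction(sp[keep], ifelse(den[keep] == 1, as.character(num[keep]),
                            paste0(num[keep], "/", den[keep])),
           description = paste(r1$description, "+", r2$description))
}

#' Scale a reaction's coefficients by an integer factor
#' @param rxn a [reaction()].
#' @param k integer scale factor.
#' @return scaled [reaction()].
#' @export
reaction_scale <- function(rxn, k) {
  stopifnot(k == round(k))
  num <- rxn$num * k
  g <- mapply(function(n, d) if (n == 0) d else gcd2(n, d), num, rxn$den)
  reaction(rxn$species, ifelse(rxn$den / g == 1, as.character(num / g),
                               paste0(num / g, "/", rxn$den / g)),
           rxn$description)
}

#' Candidate denitrification reaction reconstructions
#'
#' Balanced whole-cell equations for the energy comparisons between
#' heterotrophic, chemolithoautotrophic and mixotrophic denitrification.
#' These are reconstructions: the acetate/sulfide speciation choices are this
#' package's (HS- for total sulfide at circumneutral pH; acetate as the model
#' organic substrate; CO2 as gas), exposed so users can substitute their own.
#'
#' @return named list of [reaction()]s.
#' @export
reaction_presets <- function() {
  list(
    heterotrophic_denitrification = parse_reaction(
      "5 CH3COO- + 8 NO3- + 13 H+ -> 10 CO2 + 4 N2 + 14 H2O",
      "acetate-driven complete denitrification"),
    autotrophic_sulfide_denitrification = parse_reaction(
      "5 HS- + 8 NO3- + 3 H+ -> 5 SO4-2 + 4 N2 + 4 H2O",
      "sulfide-driven complete denitrification to sulfate"),
    sulfide_to_s0_denitrification = parse_reaction(
      "5 HS- + 2 NO3- + 7 H+ -> 5 S0 + 1 N2 + 6 H2O",
      "incomplete sulfide oxidation (zero-valent sulfur) with denitrification"),
    dnra_acetate = parse_reaction(
      "1 CH3COO- + 1 NO3- + 3 H+ -> 2 CO2 + 1 NH4+ + 1 H2O",
      "acetate-driven dissimilatory nitrate reduction to ammonium")
  )
}
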