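#' Parse a chemical formula into element counts
#'
#' Formulas are plain element-symbol/count strings such as `"C2H3O2"`,
#' `"SO4"` or `"S"`. No parentheses, hydrates or isotope labels.
#'
#' @param formula character scalar.
#' @return named integer vector of element counts.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (paste(parts, collapse = "") != formula) {
    stop("cannot parse formula: ", formula)
  }
  elems <- sub("[0-9]*$", "", parts)
  counts <- as.integer(ifelse(grepl("[0-9]+$", parts),
                              sub("^[A-Za-z]+", "", parts), "1"))
  out <- tapply(counts, elems, sum)
  counts <- as.integer(out)
  names(counts) <- names(out)
  if (any(counts < 1)) stop("composition counts must be >= 1: ", formula)
  counts
}

#' Define a chemical species
#'
#' @param name identifier used in reaction equations (charge written as a
#'   trailing signed integer, e.g. `"SO4-2"`, `"H+"`).
#' @param formula element-count formula, see [parse_formula()].
#' @param charge signed integer charge.
#' @param dGf0 standard Gibbs formation energy, kJ/mol (298 K, 1 atm, 1 M).
#' @param phase one of `"aqueous"`, `"gas"`, `"solid"`.
#' @param source free-text provenance note for `dGf0`.
#' @return an object of class `chem_species`.
#' @export
chem_species <- function(name, formula, charge = 0L, dGf0 = NA_real_,
                         phase = c("aqueous", "gas", "solid"), source = "") {
  phase <- match.arg(phase)
  structure(list(name = name, composition = parse_formula(formula),
                 charge = as.integer(charge), dGf0 = as.numeric(dGf0),
                 phase = phase, source = source),
            class = "chem_species")
}

#' Load the bundled formation-energy species library
#'
#' Literature standard formation energies (CRC-handbook-style values at
#' 298 K, 1 atm, 1 M; elemental references at 0) for the aqueous N, S and C
#' species handled by the reaction-energy engine. Each row carries a source
#' note. A user table with the same columns can be supplied instead.
#'
#' @param path TSV with columns `name`, `formula`, `charge`, `phase`,
#'   `dGf0_kJ_mol`, `source`. Defaults to the bundled table.
#' @return named list of [chem_species()] objects (a species library).
#' @export
species_library <- function(path = system.file("extdata", "formation_energies.tsv",
                                               package = "sipflux")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "charge", "phase", "dGf0_kJ_mol", "source")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("species table missing columns: ", paste(miss, collapse = ", "))
  lib <- lapply(seq_len(nrow(tab)), function(i) {
    chem_species(tab$name[i], tab$formula[i], tab$charge[i],
                 tab$dGf0_kJ_mol[i], tab$phase[i], tab$source[i])
  })
  names(lib) <- tab$name
  structure(lib, class = "species_library")
}

lookup_species <- function(lib, name) {
  sp <- lib[[name]]
  if (is.null(sp)) stop("unknown species: ", name)
  sp
}

#' Mean oxidation state of an element within a species
#'
#' Uses the H = +1, O = -2 convention with charge closure: the key element's
#' mean oxidation state is whatever balances the net charge. Species with
#' chemically inequivalent atoms of the key element (e.g. thiosulfate) thus
#' get the mean state, which is the convention the per-atom electron
#' coefficients assume.
#'
#' @param species a [chem_species()].
#' @param element element symbol whose mean oxidation state is wanted.
#' @return numeric oxidation state (may be fractional).
#' @export
oxidation_state <- function(species, element) {
  comp <- species$composition
  if (!element %in% names(comp)) {
    stop("element ", element, " absent from species ", species$name)
  }
  fixed <- c(H = 1, O = -2)
  others <- setdiff(names(comp), element)
  unknown <- setdiff(others, names(fixed))
  if (length(unknown)) {
    stop("no oxidation-state convention for element(s) ",
         paste(unknown, collapse = ", "), " in ", species$name)
  }
  contrib <- sum(fixed[others] * comp[others])
  (species$charge - contrib) / comp[[element]]
}

#' Electrons transferred per atom of the key element in a redox couple
#'
#' Mol e- released per mol of key-element atom when `reduced` is oxidized to
#' `oxidized`, computed from mean oxidation states (H = +1 / O = -2 with
#' charge closure). Sulfide -> sulfate over S gives 8; nitrate -> dinitrogen
#' over N gives 5 (as a reduction, the same count consumed).
#'
#' @param reduced,oxidized species names registered in `lib`.
#' @param element key element symbol.
#' @param lib a [species_library()].
#' @return positive numeric; integer-valued for whole-state couples.
#' @examples
#' lib <- species_library()
#' electrons_per_atom("HS-", "SO4-2", "S", lib)  # 8
#' @export
electrons_per_atom <- function(reduced, oxidized, element, lib = species_library()) {
  red <- lookup_species(lib, reduced)
  oxi <- lookup_species(lib, oxidized)
  d <- oxidation_state(oxi, element) - oxidation_state(red, element)
  if (d <= 0) {
    stop("couple ", reduced, " -> ", oxidized, " over ", element,
         " does not release electrons (state change ", d, ")")
  }
  d
}

#' Electron content of organic matter per carbon
#'
#' Mol e- released per mol C on full oxidation to CO2, i.e. 4 minus the mean
#' carbon oxidation state. The field's generic organic-matter convention of
#' exactly 4 e-/C is available as `mode = "generic4"`.
#'
#' @param species a [chem_species()] containing carbon, or its name in `lib`.
#' @param mode `"per_compound"` (from the compound's mean C oxidation state)
#'   or `"generic4"` (exactly 4).
#' @param lib species library used when `species` is a name.
#' @return numeric electrons per carbon (e.g. glucose 4, propionate 14/3).
#' @export
om_electron_content <- function(species, mode = c("per_compound", "generic4"),
                                lib = species_library()) {
  mode <- match.arg(mode)
  if (mode == "generic4") return(4)
  if (is.character(species)) species <- lookup_species(lib, species)
  if (!"C" %in% names(species$composition)) {
    stop("species ", species$name, " contains no carbon")
  }
  4 - oxidation_state(species, "C")
}
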