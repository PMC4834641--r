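# Element and ionic-radius tables are shipped as CSV under inst/extdata and
# cached per session; both can be overridden by passing a data.frame.

.calciq_cache <- new.env(parent = emptyenv())

#' Element property table
#'
#' Atomic numbers and atomic masses for the elements handled by the
#' composition models. The table ships with the package as plain CSV and can
#' be replaced wholesale (e.g. to add elements) via `table`.
#'
#' @param table Optional replacement `data.frame` with columns
#'   `symbol`, `Z`, `atomic_mass`. When supplied it becomes the session table.
#' @return A `data.frame` with columns `symbol` (chemical symbol),
#'   `Z` (atomic number) and `atomic_mass` (g/mol).
#' @export
element_table <- function(table = NULL) {
  if (!is.null(table)) {
    stopifnot(all(c("symbol", "Z", "atomic_mass") %in% names(table)))
    .calciq_cache$elements <- table
  }
  if (is.null(.calciq_cache$elements)) {
    path <- system.file("extdata", "elements.csv", package = "calciq")
    .calciq_cache$elements <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .calciq_cache$elements
}

#' Ionic radius table
#'
#' Effective ionic radii (pm) used to derive per-species densities for the
#' solution density mixing rule. Values for monatomic ions follow Shannon's
#' effective ionic radii; polyatomic units carry thermochemical-style
#' effective radii. Overridable like [element_table()].
#'
#' @param table Optional replacement `data.frame` with columns
#'   `species`, `radius_pm`.
#' @return A `data.frame` with columns `species` and `radius_pm`.
#' @export
ion_radius_table <- function(table = NULL) {
  if (!is.null(table)) {
    stopifnot(all(c("species", "radius_pm") %in% names(table)))
    .calciq_cache$radii <- table
  }
  if (is.null(.calciq_cache$radii)) {
    path <- system.file("extdata", "ion_radii.csv", package = "calciq")
    .calciq_cache$radii <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .calciq_cache$radii
}

.element_row <- function(symbol) {
  tab <- element_table()
  i <- match(symbol, tab$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(symbol[is.na(i)], collapse = ", "))
  }
  tab[i, , drop = FALSE]
}

#' Parse a chemical formula into element counts
#'
#' Handles simple formulas of the form `CaCO3`, `CH2`, `H2O`, `PO3`;
#' fractional counts (e.g. `CH1.8`) are allowed. No parentheses.
#'
#' @param formula Formula string.
#' @return Named numeric vector of atom counts per formula unit.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (!nzchar(gsub("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", "", formula))) {
    counts <- numeric(0)
    for (tok in tokens) {
      sym <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
      num <- sub("^[A-Z][a-z]?", "", tok)
      n <- if (nzchar(num)) as.numeric(num) else 1
      counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0) + n
    }
    .element_row(names(counts))  # validates symbols
    return(counts)
  }
  stop("cannot parse formula: ", formula)
}

#' Molar mass of a formula unit
#'
#' @param formula Formula string, e.g. `"CaCO3"`.
#' @return Molar mass in g/mol.
#' @export
formula_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(counts * .element_row(names(counts))$atomic_mass)
}

#' Heinrich backscatter coefficient
#'
#' Atomic backscatter coefficient eta_i from the standard cubic polynomial
#' fit to Heinrich's backscattered-electron data,
#' eta(Z) = -0.0254 + 1.6e-2 Z - 1.86e-4 Z^2 + 8.3e-7 Z^3,
#' assumed independent of primary beam energy for the light elements
#' (Z < 20) that dominate biological matrices. The polynomial dips slightly
#' below zero at Z = 1; the value is floored at `floor_eta` there so that
#' eta stays in (0, 1) and strictly increasing over Z = 1..92.
#'
#' @param Z Atomic number(s), integers in 1..92.
#' @param coef Polynomial coefficients (intercept first); exposed so an
#'   alternative fit can be swapped in.
#' @param floor_eta Lower floor applied where the polynomial is
#'   non-positive (affects hydrogen only with the default fit).
#' @return Backscatter coefficient(s) in (0, 1).
#' @export
#' @examples
#' heinrich_eta(6)   # carbon, ~0.064
#' heinrich_eta(20)  # calcium
heinrich_eta <- function(Z, coef = c(-0.0254, 1.6e-2, -1.86e-4, 8.3e-7),
                         floor_eta = 1e-3) {
  if (any(Z < 1 | Z > 92) || any(Z != round(Z))) {
    stop("Z must be integer(s) in 1..92")
  }
  eta <- coef[1] + coef[2] * Z + coef[3] * Z^2 + coef[4] * Z^3
  eta[eta <= floor_eta] <- floor_eta
  eta
}

#' Define a material by elemental mass fractions
#'
#' @param name Material name.
#' @param mass_fractions Named numeric vector of elemental weight fractions
#'   (the c_i); must lie in \[0, 1\] and sum to 1 within 1e-9.
#' @param density Mass density in g/cm^3, or `NULL` for solutions whose
#'   density is later computed by the mixing rule.
#' @return An object of class `"material"`.
#' @export
material <- function(name, mass_fractions, density = NULL) {
  stopifnot(is.numeric(mass_fractions), !is.null(names(mass_fractions)))
  if (any(mass_fractions < 0 | mass_fractions > 1)) {
    stop("mass fractions must lie in [0, 1]")
  }
  if (abs(sum(mass_fractions) - 1) > 1e-9) {
    stop("mass fractions must sum to 1 (got ",
         format(sum(mass_fractions), digits = 12), ")")
  }
  .element_row(names(mass_fractions))  # validates symbols
  structure(
    list(name = name, mass_fractions = mass_fractions, density = density),
    class = "material"
  )
}

#' Define a material from a chemical formula
#'
#' @param name Material name.
#' @param formula Formula string, e.g. `"CaCO3"` for calcite or `"CH2"` for
#'   a linear-hydrocarbon lipid model.
#' @param density Mass density in g/cm^3 or `NULL`.
#' @return A `"material"` object with mass fractions from the formula.
#' @export
#' @examples
#' calcite <- material_from_formula("calcite", "CaCO3", density = 2.71)
material_from_formula <- function(name, formula, density = NULL) {
  counts <- parse_formula(formula)
  masses <- counts * .element_row(names(counts))$atomic_mass
  material(name, masses / sum(masses), density = density)
}

#' @export
print.material <- function(x, ...) {
  cat("<material>", x$name, "\n")
  cat("  mass fractions:",
      paste(sprintf("%s=%.4f", names(x$mass_fractions), x$mass_fractions),
            collapse = " "), "\n")
  if (!is.null(x$density)) cat("  density:", x$density, "g/cm^3\n")
  invisible(x)
}

#' Effective backscatter coefficient of a material
#'
#' Mixture rule: eta_eff = sum_i eta_i c_i over the material's elements,
#' with eta_i from [heinrich_eta()]. Linear in the mass fractions and
#' bounded by the component coefficients.
#'
#' @param x A `"material"` object (or a named mass-fraction vector).
#' @param ... Passed on to [heinrich_eta()] (e.g. alternative coefficients).
#' @return Effective backscatter coefficient (dimensionless).
#' @export
eta_eff <- function(x, ...) {
  fr <- if (inherits(x, "material")) x$mass_fractions else x
  stopifnot(is.numeric(fr), !is.null(names(fr)))
  Z <- .element_row(names(fr))$Z
  sum(heinrich_eta(Z, ...) * fr)
}

#' Density of a dissolved species from its ionic radius
#'
#' Species density rho_i = m / (4/3 pi r^3 N_A) with the tabulated effective
#' ionic radius; used by the density mixing rule for concentrated
#' electrolytes. Water is special-cased to its bulk density.
#'
#' @param species Species formula, e.g. `"Ca"`, `"PO3"`, `"H2O"`.
#' @param radius_pm Optional radius override in pm.
#' @param water_density Bulk water density, g/cm^3.
#' @return Density in g/cm^3.
#' @export
species_density <- function(species, radius_pm = NULL, water_density = 0.9982) {
  if (identical(species, "H2O")) return(water_density)
  if (is.null(radius_pm)) {
    tab <- ion_radius_table()
    i <- match(species, tab$species)
    if (is.na(i)) stop("no tabulated radius for species: ", species)
    radius_pm <- tab$radius_pm[i]
  }
  avogadro <- 6.02214076e23
  r_cm <- radius_pm * 1e-10  # pm -> cm
  m_g <- formula_mass(species) / avogadro
  m_g / (4 / 3 * pi * r_cm^3)
}

#' Molarity of a target species in a solution (density mixing rule)
#'
#' Solution density from the harmonic mixing rule
#' 1/rho_s = sum_i c_i / rho_i (water included as one species), then
#' molarity = 1000 rho_s c_target / M_target, multiplied by the number of
#' target-element atoms per formula unit when `target_element` is given.
#'
#' @param mass_fractions Named numeric vector of species weight fractions
#'   (include `"H2O"` for the water fraction); must sum to 1 within 1e-9.
#' @param densities Named numeric vector of species densities (g/cm^3);
#'   missing entries are filled from [species_density()].
#' @param target_species Name of the species whose molarity is requested.
#' @param target_element Optional element symbol: the reported molarity is
#'   then of that element (counts atoms per formula unit of the target).
#' @return Molar concentration in mol/L, with the computed solution density
#'   attached as attribute `"rho_s"`.
#' @export
#' @examples
#' # pure calcite treated as the "solution": 1000 * 2.71 / 100.09 ~ 27 M Ca
#' molarity_of_solution(c(CaCO3 = 1), c(CaCO3 = 2.71), "CaCO3", "Ca")
molarity_of_solution <- function(mass_fractions, densities = NULL,
                                 target_species, target_element = NULL) {
  stopifnot(is.numeric(mass_fractions), !is.null(names(mass_fractions)))
  if (abs(sum(mass_fractions) - 1) > 1e-9) {
    stop("species mass fractions (incl. water) must sum to 1")
  }
  if (!target_species %in% names(mass_fractions)) {
    stop("target species '", target_species, "' not among the mass fractions")
  }
  rho <- vapply(names(mass_fractions), function(sp) {
    if (!is.null(densities) && sp %in% names(densities)) {
      densities[[sp]]
    } else {
      species_density(sp)
    }
  }, numeric(1))
  if (any(rho <= 0)) stop("all species densities must be positive")
  rho_s <- 1 / sum(mass_fractions / rho)
  c_t <- mass_fractions[[target_species]]
  mol <- 1000 * rho_s * c_t / formula_mass(target_species)
  if (!is.null(target_element)) {
    counts <- parse_formula(target_species)
    if (!target_element %in% names(counts)) {
      stop("target element '", target_element, "' not in species '",
           target_species, "'")
    }
    mol <- mol * counts[[target_element]]
  }
  structure(unname(mol), rho_s = rho_s)
}

#' Ca:P electrolyte model for the Ca-rich body
#'
#' Composition model for a concentrated calcium/polyphosphate electrolyte
#' with a fixed Ca:P atomic ratio (default 1:2). Phosphorus is carried as
#' metaphosphate chain units (`"PO3"`, the polyphosphate repeat) by default,
#' configurable to orthophosphate (`"PO4"`). No counterions are added:
#' charge imbalance is tolerated in the density model.
#'
#' @param ca_p_ratio Length-2 positive numeric, Ca:P atomic ratio.
#' @param phosphate_unit Formula of the P-bearing unit (one P per unit).
#' @param water_density Bulk water density, g/cm^3.
#' @param densities Optional named density overrides for species (g/cm^3).
#' @return An object of class `"electrolyte_model"`.
#' @export
electrolyte_model <- function(ca_p_ratio = c(1, 2), phosphate_unit = "PO3",
                              water_density = 0.9982, densities = NULL) {
  stopifnot(length(ca_p_ratio) == 2, all(ca_p_ratio > 0))
  counts <- parse_formula(phosphate_unit)
  if (!"P" %in% names(counts) || counts[["P"]] != 1) {
    stop("phosphate unit must contain exactly one P atom")
  }
  structure(
    list(ca_p_ratio = unname(ca_p_ratio), phosphate_unit = phosphate_unit,
         water_density = water_density, densities = densities),
    class = "electrolyte_model"
  )
}

# Mass of phosphate units per unit mass of Ca at the configured atomic ratio.
.unit_per_ca <- function(model) {
  r <- model$ca_p_ratio[2] / model$ca_p_ratio[1]  # P atoms per Ca atom
  r * formula_mass(model$phosphate_unit) / formula_mass("Ca")
}

#' Largest self-consistent Ca mass fraction of an electrolyte model
#'
#' The Ca mass fraction at which the water fraction reaches zero.
#'
#' @param model An `"electrolyte_model"`.
#' @return Mass fraction in (0, 1).
#' @export
ca_mass_fraction_limit <- function(model = electrolyte_model()) {
  1 / (1 + .unit_per_ca(model))
}

#' Build the electrolyte material at a given Ca mass fraction
#'
#' Fills water up to total mass 1 around Ca and phosphate units at the
#' configured Ca:P atomic ratio, and returns the resulting material with its
#' per-species breakdown attached (attribute `"species_fractions"`).
#'
#' @param ca_mass_fraction Calcium weight fraction, in
#'   \[0, [ca_mass_fraction_limit()]\].
#' @param model An `"electrolyte_model"`.
#' @return A `"material"` named `"electrolyte"` whose elemental fractions sum
#'   to 1; attribute `"species_fractions"` holds the Ca / phosphate / H2O
#'   split used by the density mixing rule.
#' @export
build_electrolyte <- function(ca_mass_fraction, model = electrolyte_model()) {
  stopifnot(is.numeric(ca_mass_fraction), length(ca_mass_fraction) == 1)
  if (ca_mass_fraction < 0) stop("ca_mass_fraction must be >= 0")
  c_unit <- ca_mass_fraction * .unit_per_ca(model)
  c_w <- 1 - ca_mass_fraction - c_unit
  if (c_w < -1e-12) {
    stop("ca_mass_fraction ", format(ca_mass_fraction),
         " exceeds the consistency limit ",
         format(ca_mass_fraction_limit(model)))
  }
  c_w <- max(c_w, 0)
  elems <- c(Ca = ca_mass_fraction)
  add_species <- function(elems, formula, frac) {
    counts <- parse_formula(formula)
    masses <- counts * .element_row(names(counts))$atomic_mass
    share <- frac * masses / sum(masses)
    for (s in names(share)) {
      elems[s] <- (if (s %in% names(elems)) elems[[s]] else 0) + share[[s]]
    }
    elems
  }
  elems <- add_species(elems, model$phosphate_unit, c_unit)
  elems <- add_species(elems, "H2O", c_w)
  mat <- material("electrolyte", elems / sum(elems))
  attr(mat, "species_fractions") <-
    stats::setNames(c(ca_mass_fraction, c_unit, c_w),
                    c("Ca", model$phosphate_unit, "H2O"))
  attr(mat, "model") <- model
  mat
}

#' Calcium molarity of an electrolyte at a given Ca mass fraction
#'
#' @param ca_mass_fraction Calcium weight fraction.
#' @param model An `"electrolyte_model"`.
#' @return Ca molarity in mol/L.
#' @export
electrolyte_molarity <- function(ca_mass_fraction,
                                 model = electrolyte_model()) {
  mat <- build_electrolyte(ca_mass_fraction, model)
  sp <- attr(mat, "species_fractions")
  dens <- c(model$densities,
            stats::setNames(model$water_density, "H2O"))
  molarity_of_solution(sp, dens, target_species = "Ca")
}

#' Ca mass fraction realizing a target molarity
#'
#' Inverts [electrolyte_molarity()] by bisection (the molarity is strictly
#' increasing in the mass fraction).
#'
#' @param molarity_M Target Ca molarity (mol/L).
#' @param model An `"electrolyte_model"`.
#' @param tol Bisection tolerance on the mass fraction.
#' @return Ca mass fraction.
#' @export
ca_fraction_for_molarity <- function(molarity_M, model = electrolyte_model(),
                                     tol = 1e-12) {
  stopifnot(molarity_M >= 0)
  if (molarity_M == 0) return(0)
  hi <- ca_mass_fraction_limit(model)
  max_m <- electrolyte_molarity(hi, model)
  if (molarity_M > max_m) {
    stop("molarity ", molarity_M, " M exceeds the model maximum ",
         format(max_m, digits = 4), " M")
  }
  f <- function(c) as.numeric(electrolyte_molarity(c, model)) - molarity_M
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
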