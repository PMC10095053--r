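#' Perfusion-fluid composition
#'
#' A table of dissolved species with molar masses, concentrations and
#' chloride stoichiometry, plus the glucose content and solution density
#' used when converting chloride per litre to chlorinity (per kg).
#'
#' @param species data.frame with columns `name`, `molar_mass_g_mol`,
#'   `conc_mM`, `cl_stoich` (chloride ions per formula unit; 0 for
#'   chloride-free species).
#' @param glucose_molar glucose concentration, mol/L.
#' @param solution_density solution density, kg/L (default 1.005).
#' @return An object of class `fluid_composition`.
#' @seealso [acsf_composition()] for the built-in recipes.
#' @export
fluid_composition <- function(species, glucose_molar = 0,
                              solution_density = 1.005) {
  stopifnot(is.data.frame(species),
            all(c("name", "molar_mass_g_mol", "conc_mM", "cl_stoich") %in%
                  names(species)),
            all(species$conc_mM >= 0),
            solution_density > 0.9, solution_density < 1.2)
  structure(list(species = species, glucose_molar = glucose_molar,
                 solution_density = solution_density),
            class = "fluid_composition")
}

#' Built-in aCSF recipes
#'
#' Standard ("normal") and magnesium-free artificial cerebrospinal fluid as
#' used in thin-slice perfusion work. The no-Mg variant (130 NaCl, 5 KCl,
#' 2 CaCl2, 2.5 NaHCO3, 3.5 NaOH, 10 HEPES, 20 glucose, all mM) carries
#' 4.928 g/L of chloride. Buffering agents contribute no chloride and are
#' assumed inert for oxygen transport.
#'
#' @param preset `"no_mg_acsf"` (default) or `"normal_acsf"`.
#' @param solution_density kg/L used for the g/L to g/kg conversion.
#' @return A [fluid_composition()].
#' @export
acsf_composition <- function(preset = c("no_mg_acsf", "normal_acsf"),
                             solution_density = 1.005) {
  preset <- match.arg(preset)
  base <- data.frame(
    name = c("NaCl", "KCl", "MgCl2", "CaCl2", "NaHCO3", "NaOH", "HEPES"),
    molar_mass_g_mol = c(58.44, 74.55, 95.21, 110.98, 84.01, 40.00, 238.30),
    cl_stoich = c(1, 1, 2, 2, 0, 0, 0),
    stringsAsFactors = FALSE)
  base$conc_mM <- if (preset == "no_mg_acsf")
    c(130, 5, 0, 2, 2.5, 3.5, 10) else c(130, 2.5, 1, 2, 2.5, 3.5, 10)
  fluid_composition(base, glucose_molar = 0.020,
                    solution_density = solution_density)
}

CL_MOLAR_MASS <- 35.453  # g/mol

#' Total chloride and chlorinity of a composition
#'
#' Sums chloride over the chloride-bearing salts
#' (`conc [mol/L] x stoichiometry x 35.453 g/mol`) and divides by the
#' solution density to express chlorinity in g of Cl- per kg of solution.
#'
#' @param comp a [fluid_composition()].
#' @return Named list `g_per_L`, `g_per_kg`.
#' @examples
#' chlorinity(acsf_composition("no_mg_acsf"))  # ~4.928 g/L, ~4.90 g/kg
#' @export
chlorinity <- function(comp) {
  stopifnot(inherits(comp, "fluid_composition"))
  sp <- comp$species
  if (any(is.na(sp$cl_stoich)))
    stop("species without chloride stoichiometry: ",
         paste(sp$name[is.na(sp$cl_stoich)], collapse = ", "))
  g_per_l <- sum(sp$conc_mM / 1000 * sp$cl_stoich * CL_MOLAR_MASS)
  list(g_per_L = g_per_l, g_per_kg = g_per_l / comp$solution_density)
}

#' Read a composition from a JSON config
#'
#' Expects a JSON object with a `species` array of
#' `{name, molar_mass_g_mol, conc_mM, cl_stoich}` records and optional
#' `glucose_molar` and `solution_density` scalars.
#'
#' @param path path to a JSON file.
#' @return A [fluid_composition()].
#' @export
read_composition <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  fluid_composition(as.data.frame(cfg$species),
                    glucose_molar = cfg$glucose_molar %||% 0,
                    solution_density = cfg$solution_density %||% 1.005)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
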