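#' Compound specifications for dose-equivalence arithmetic
#'
#' Molar masses are shipped as constants and can be overridden via
#' [compound_spec()]:
#' \itemize{
#'   \item acamprosate free base (N-acetylhomotaurine,
#'     3-(acetylamino)-1-propanesulfonic acid), 181.21 g/mol. Acamprosate is
#'     dosed as the hemicalcium salt, so each free-base molecule carries
#'     0.5 calcium ions.
#'   \item acamprosate calcium (the hemicalcium salt,
#'     Ca(C5H10NO4S)2), 400.48 g/mol, 1 calcium per formula unit.
#'   \item calcium chloride dihydrate (CaCl2.2H2O), 147.01 g/mol, 1 calcium
#'     per formula unit.
#' }
#'
#' @param name Compound name.
#' @param molar_mass_g_per_mol Molar mass (> 0).
#' @param ca_ions_per_formula Calcium ions per formula unit (>= 0; 0.5 for
#'   a free-base equivalent of a hemicalcium salt).
#' @return A list of class `compound_spec`.
#' @examples
#' compounds()$cacl2_2h2o
#' @export
compound_spec <- function(name, molar_mass_g_per_mol, ca_ions_per_formula) {
  stopifnot(is.character(name), molar_mass_g_per_mol > 0,
            ca_ions_per_formula >= 0)
  structure(list(name = name,
                 molar_mass_g_per_mol = molar_mass_g_per_mol,
                 ca_ions_per_formula = ca_ions_per_formula),
            class = "compound_spec")
}

#' @rdname compound_spec
#' @export
compounds <- function() {
  list(
    acamprosate_free_base = compound_spec(
      "acamprosate (free base, N-acetylhomotaurine)", 181.21, 0.5),
    acamprosate_calcium = compound_spec(
      "acamprosate calcium (hemicalcium salt)", 400.48, 1),
    cacl2_2h2o = compound_spec(
      "calcium chloride dihydrate", 147.01, 1)
  )
}

#' Calcium molar dose of a compound
#'
#' Converts a mg/kg/day dose to mmol of calcium ions per kg per day:
#' `dose / molar_mass * ca_ions_per_formula`. With the shipped constants,
#' 122.2 mg/kg CaCl2.2H2O and 300 mg/kg acamprosate expressed as the free
#' base both give ~0.83 mmol/kg/day -- the calcium-matched control design.
#'
#' @param dose_mg_per_kg Dose in mg/kg/day (>= 0).
#' @param compound A [compound_spec()] or the name of a shipped compound
#'   (see [compounds()]).
#' @return Calcium dose in mmol/kg/day.
#' @examples
#' calcium_molar_dose(122.2, "cacl2_2h2o")            # ~0.83
#' calcium_molar_dose(300, "acamprosate_free_base")   # ~0.83
#' @export
calcium_molar_dose <- function(dose_mg_per_kg, compound) {
  if (is.character(compound)) {
    all <- compounds()
    if (!compound %in% names(all)) {
      stop("unknown compound '", compound, "'; see compounds()")
    }
    compound <- all[[compound]]
  }
  stopifnot(inherits(compound, "compound_spec"), dose_mg_per_kg >= 0)
  if (compound$molar_mass_g_per_mol <= 0) stop("molar mass must be positive")
  dose_mg_per_kg / compound$molar_mass_g_per_mol *
    compound$ca_ions_per_formula
}

#' Human equivalent dose by body-surface-area scaling
#'
#' Scales a mouse mg/kg dose to a human daily dose in grams:
#' `mouse_mg_per_kg * km_ratio * human_mass_kg / 1000`, with the standard
#' mouse-to-human conversion ratio 3/37 and a 70 kg adult by default
#' (333 mg/kg -> 27 mg/kg -> 1.89 g/day).
#'
#' @param mouse_mg_per_kg Mouse dose in mg/kg/day (> 0 or 0).
#' @param km_ratio Mouse-to-human body-surface-area ratio (default 3/37).
#' @param human_mass_kg Human body mass in kg (default 70).
#' @return Human dose in g/day.
#' @examples
#' human_equivalent_dose(333)  # ~1.89
#' @export
human_equivalent_dose <- function(mouse_mg_per_kg, km_ratio = 3 / 37,
                                  human_mass_kg = 70) {
  stopifnot(mouse_mg_per_kg >= 0, km_ratio > 0, human_mass_kg > 0)
  mouse_mg_per_kg * km_ratio * human_mass_kg / 1000
}

#' Per-kilogram dose from a daily human dose
#'
#' `g_per_day * 1000 / mass_kg`: e.g. the ~2 g/day therapeutic regimen in a
#' 70 kg adult is 28.6 mg/kg.
#'
#' @param g_per_day Daily dose in grams (>= 0).
#' @param mass_kg Body mass in kg (> 0).
#' @return Dose in mg/kg.
#' @examples
#' mg_per_kg_from_daily(2)  # ~28.6
#' @export
mg_per_kg_from_daily <- function(g_per_day, mass_kg = 70) {
  stopifnot(g_per_day >= 0)
  if (mass_kg <= 0) stop("mass_kg must be positive")
  g_per_day * 1000 / mass_kg
}
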