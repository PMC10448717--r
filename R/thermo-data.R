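#' Packaged standard-state formation energies and enthalpies
#'
#' Standard Gibbs free energies and enthalpies of formation at 298.15 K for
#' the species of the acetate-to-methane reaction system, from the classical
#' biochemical compilation of Thauer, Jungermann and Decker (1977), with
#' CODATA-consistent enthalpies. Conventions: gases against 1 atm, solutes
#' against 1 M, elemental reference species (H2, O2) and the proton at zero.
#'
#' @param path optional TSV with columns `name`, `phase`, `gf0_kj_mol`,
#'   `hf0_kj_mol` overriding the packaged table.
#' @return data.frame with columns `name`, `phase` (one of `gas`, `aqueous`,
#'   `liquid-water`, `proton`), `gf0_kj_mol`, `hf0_kj_mol`.
#' @examples
#' thermoSpeciesTable()
#' @export
thermoSpeciesTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "thermo_species.tsv",
                        package = "nanaerobics", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "phase", "gf0_kj_mol", "hf0_kj_mol")
  if (!all(need %in% names(df)))
    stop("species table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$gf0_kj_mol)) || any(!is.finite(df$hf0_kj_mol)))
    stop("non-finite formation energies in species table")
  df
}

#' Packaged acetate-to-methane reactions R1-R4
#'
#' The four elementary reactions of the three acetate-to-methane pathways:
#' \describe{
#'   \item{R1}{acetoclastic methanogenesis, CH3COO- + H+ -> CH4 + CO2}
#'   \item{R2}{hydrogenotrophic methanogenesis, 8H2 + 2CO2 -> 2CH4 + 4H2O}
#'   \item{R3}{syntrophic acetate oxidation, CH3COO- + H+ + 2H2O -> 4H2 + 2CO2}
#'   \item{R4}{complete acetate oxidation (nanaerobic respiration),
#'     CH3COO- + H+ + 2O2 -> 2H2O + 2CO2}
#' }
#' All four are element- and charge-balanced as packaged.
#'
#' @return named list of [ReactionSpec-class] objects (`R1`, `R2`, `R3`, `R4`).
#' @examples
#' methanogenesisReactions()$R1
#' @export
methanogenesisReactions <- function() {
  list(
    R1 = reactionSpec("R1",
      c(acetate = -1, "H+" = -1, CH4 = 1, CO2 = 1),
      "CH3COO- + H+ -> CH4 + CO2"),
    R2 = reactionSpec("R2",
      c(H2 = -8, CO2 = -2, CH4 = 2, H2O = 4),
      "8H2 + 2CO2 -> 2CH4 + 4H2O"),
    R3 = reactionSpec("R3",
      c(acetate = -1, "H+" = -1, H2O = -2, H2 = 4, CO2 = 2),
      "CH3COO- + H+ + 2H2O -> 4H2 + 2CO2"),
    R4 = reactionSpec("R4",
      c(acetate = -1, "H+" = -1, O2 = -2, H2O = 2, CO2 = 2),
      "CH3COO- + H+ + 2O2 -> 2H2O + 2CO2"))
}

#' Fig. 3 base condition set
#'
#' The environmental conditions used for the H2/CO2 constraint analysis:
#' 35 C, pH 6.5, CH4 at 0.5 atm, O2 at 1e-8 atm, acetate at 20 mM, 1 atm
#' total pressure. H2 and CO2 partial pressures are left free (grid axes).
#'
#' @param ph2 optional H2 partial pressure, atm.
#' @param pco2 optional CO2 partial pressure, atm.
#' @return A [ConditionSet-class].
#' @export
figure3Conditions <- function(ph2 = NULL, pco2 = NULL) {
  pp <- c(CH4 = 0.5, O2 = 1e-8)
  if (!is.null(ph2)) pp["H2"] <- ph2
  if (!is.null(pco2)) pp["CO2"] <- pco2
  conditionSet(temperature = 308.15, partialPressures = pp,
               concentrations = c(acetate = 0.02), pH = 6.5,
               totalPressure = 1)
}
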