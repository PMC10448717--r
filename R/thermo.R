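# Universal gas constant, kJ/(K mol)
.RGAS <- 8.314e-3
.TREF <- 298.15

.lookupFormation <- function(reaction, speciesTable, column) {
  s <- reaction@stoichiometry
  idx <- match(names(s), speciesTable$name)
  if (anyNA(idx))
    stop("no thermodynamic entry for species: ",
         paste(names(s)[is.na(idx)], collapse = ", "))
  list(coef = s, values = speciesTable[[column]][idx],
       phase = speciesTable$phase[idx])
}

#' Standard Gibbs free energy of reaction at 298.15 K
#'
#' Signed sum of formation free energies, products minus reactants, in
#' kJ per mole of reaction as written.
#'
#' @param reaction a [ReactionSpec-class].
#' @param speciesTable formation-constant table, see [thermoSpeciesTable()].
#' @return kJ/reaction.
#' @examples
#' standardDeltaG(methanogenesisReactions()$R1, thermoSpeciesTable())
#' @export
standardDeltaG <- function(reaction, speciesTable = thermoSpeciesTable()) {
  if (length(reaction@stoichiometry) == 0L) return(0)
  f <- .lookupFormation(reaction, speciesTable, "gf0_kj_mol")
  sum(f$coef * f$values)
}

#' Standard enthalpy of reaction at 298.15 K
#'
#' @inheritParams standardDeltaG
#' @return kJ/reaction.
#' @export
standardDeltaH <- function(reaction, speciesTable = thermoSpeciesTable()) {
  if (length(reaction@stoichiometry) == 0L) return(0)
  f <- .lookupFormation(reaction, speciesTable, "hf0_kj_mol")
  sum(f$coef * f$values)
}

#' Gibbs-Helmholtz temperature correction
#'
#' Converts a reaction free energy from a reference temperature to an actual
#' temperature assuming a temperature-independent reaction enthalpy:
#' `dG(Tact) = dG(Tref) * Tact/Tref + dH(Tref) * (Tref - Tact)/Tref`.
#'
#' @param dgRef free energy at `tRef`, kJ.
#' @param dhRef enthalpy at `tRef`, kJ.
#' @param tRef,tAct reference and actual temperatures, K.
#' @return kJ at `tAct`.
#' @examples
#' temperatureCorrect(-75.8, 17.7, 298.15, 308.15)
#' @export
temperatureCorrect <- function(dgRef, dhRef, tRef = .TREF, tAct) {
  if (any(tRef <= 0) || any(tAct <= 0))
    stop("temperatures must be positive (K)")
  dgRef * tAct / tRef + dhRef * (tRef - tAct) / tRef
}

.activity <- function(species, phase, condition) {
  switch(phase,
    gas = {
      p <- condition@partialPressures[species]
      if (is.na(p)) stop("no partial pressure for gas species ", species)
      unname(p)
    },
    aqueous = {
      cc <- condition@concentrations[species]
      if (is.na(cc)) stop("no concentration for aqueous species ", species)
      unname(cc)
    },
    proton = 10^(-condition@pH),
    `liquid-water` = 1,
    stop("unknown phase ", phase))
}

#' Reaction-quotient free-energy term
#'
#' `RT ln Q` in kJ with `R = 8.314 J/(K mol)`, where Q is the activity
#' quotient products over reactants. Gases enter as partial pressure (atm),
#' solutes as mol/L, the proton as `10^-pH`, liquid water as 1.
#'
#' @param reaction a [ReactionSpec-class].
#' @param condition a [ConditionSet-class].
#' @param speciesTable formation table supplying the phase of each species.
#' @return kJ/reaction; zero when every activity is 1.
#' @export
reactionQuotientTerm <- function(reaction, condition,
                                 speciesTable = thermoSpeciesTable()) {
  s <- reaction@stoichiometry
  if (length(s) == 0L) return(0)
  f <- .lookupFormation(reaction, speciesTable, "gf0_kj_mol")
  a <- vapply(seq_along(s),
              function(i) .activity(names(s)[i], f$phase[i], condition),
              numeric(1))
  if (any(!is.finite(a)) || any(a <= 0))
    stop("activities must be finite and strictly positive")
  .RGAS * condition@temperature * sum(s * log(a))
}

#' Condition-specific Gibbs free energy
#'
#' The full three-step evaluation: standard free energy at 298.15 K,
#' Gibbs-Helmholtz corrected to the condition temperature, plus the
#' `RT ln Q` activity correction.
#'
#' @inheritParams reactionQuotientTerm
#' @return kJ/reaction under the given conditions.
#' @examples
#' cond <- figure3Conditions(ph2 = 1e-4, pco2 = 0.3)
#' actualDeltaG(methanogenesisReactions()$R2, cond)
#' @export
actualDeltaG <- function(reaction, condition,
                         speciesTable = thermoSpeciesTable()) {
  dgT <- temperatureCorrect(standardDeltaG(reaction, speciesTable),
                            standardDeltaH(reaction, speciesTable),
                            .TREF, condition@temperature)
  dgT + reactionQuotientTerm(reaction, condition, speciesTable)
}

#' Reverse a reaction
#'
#' @param reaction a [ReactionSpec-class].
#' @return The reaction with all coefficients negated.
#' @export
reverseReaction <- function(reaction) {
  reactionSpec(paste0("-", reaction@reactionId), -reaction@stoichiometry)
}

#' Compose reactions into a net reaction
#'
#' Stoichiometries are added species-wise; species cancelling to zero are
#' removed. The free energy of the composite equals the sum of the component
#' free energies under identical conditions.
#'
#' @param ... [ReactionSpec-class] objects, or a single list of them.
#' @param reactionId identifier for the composite; defaults to the component
#'   ids joined with `+`.
#' @return A [ReactionSpec-class].
#' @examples
#' rx <- methanogenesisReactions()
#' composeReactions(rx$R3, rx$R2)   # net: CH3COO- + H+ + 4H2 -> 2CH4 + 2H2O
#' @export
composeReactions <- function(..., reactionId = NULL) {
  rs <- list(...)
  if (length(rs) == 1L && is.list(rs[[1]]) && !is(rs[[1]], "ReactionSpec"))
    rs <- rs[[1]]
  if (length(rs) == 0L) stop("need at least one reaction")
  stopifnot(all(vapply(rs, is, logical(1), "ReactionSpec")))
  species <- unique(unlist(lapply(rs, function(r) names(r@stoichiometry))))
  total <- stats::setNames(numeric(length(species)), species)
  for (r in rs) {
    s <- r@stoichiometry
    total[names(s)] <- total[names(s)] + s
  }
  total <- total[abs(total) > 1e-12]
  if (is.null(reactionId))
    reactionId <- paste(vapply(rs, function(r) r@reactionId, character(1)),
                        collapse = "+")
  reactionSpec(reactionId, total)
}

#' Pathway free-energy table for acetate-to-methane conversion
#'
#' Standard (298.15 K), temperature-corrected (308.15 K) and, optionally,
#' condition-specific free energies for the three pathways: I acetoclastic
#' (R1); II syntrophic acetate oxidation + hydrogenotrophic methanogenesis
#' (R3, R2, sum 3+2); III complete acetate oxidation + hydrogenotrophic
#' methanogenesis (R4, R2, sum 4+2).
#'
#' @param speciesTable formation-constant table.
#' @param conditions optional named list of [ConditionSet-class] objects;
#'   each adds a condition-specific free-energy column.
#' @return data.frame with one row per reaction/composite and columns
#'   `pathway`, `reaction_id`, `reaction`, `dg298_kj`, `dg308_kj` and one
#'   `dg_<name>_kj` per supplied condition.
#' @examples
#' pathwayTable()
#' @export
pathwayTable <- function(speciesTable = thermoSpeciesTable(),
                         conditions = NULL) {
  rx <- methanogenesisReactions()
  s32 <- composeReactions(rx$R3, rx$R2, reactionId = "3+2")
  s42 <- composeReactions(rx$R4, rx$R2, reactionId = "4+2")
  rows <- list(
    list("I",   rx$R1), list("II",  rx$R3), list("II",  rx$R2),
    list("II",  s32),   list("III", rx$R4), list("III", rx$R2),
    list("III", s42))
  out <- do.call(rbind, lapply(rows, function(pr) {
    r <- pr[[2]]
    dg <- standardDeltaG(r, speciesTable)
    dh <- standardDeltaH(r, speciesTable)
    data.frame(pathway = pr[[1]], reaction_id = r@reactionId,
               reaction = r@label, dg298_kj = dg,
               dg308_kj = temperatureCorrect(dg, dh, .TREF, 308.15),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(conditions)) {
    if (is.null(names(conditions)) || any(!nzchar(names(conditions))))
      stop("conditions must be a named list of ConditionSet objects")
    for (nm in names(conditions)) {
      cond <- conditions[[nm]]
      vals <- vapply(rows, function(pr)
        actualDeltaG(pr[[2]], cond, speciesTable), numeric(1))
      out[[paste0("dg_", nm, "_kj")]] <- vals
    }
  }
  rownames(out) <- NULL
  out
}

#' Solve a partial-pressure threshold where the free energy vanishes
#'
#' Holds every activity fixed except the partial pressure of one gas species
#' and solves `actualDeltaG = 0` for it by closed-form rearrangement of the
#' `RT ln Q` term. A bisection fallback over a log-space bracket
#' `[1e-12, 1e2]` atm is available for cross-checks.
#'
#' @param reaction a [ReactionSpec-class] containing `freeSpecies` as a gas.
#' @param condition a [ConditionSet-class]; the entry for `freeSpecies` (if
#'   any) is ignored.
#' @param freeSpecies gas species name to solve for.
#' @param speciesTable formation-constant table.
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @return threshold partial pressure, atm. Plugging it back into
#'   [actualDeltaG()] yields |dG| < 1e-6 kJ.
#' @examples
#' solveThreshold(methanogenesisReactions()$R2, figure3Conditions(pco2 = 0.3),
#'                "H2")
#' @export
solveThreshold <- function(reaction, condition, freeSpecies,
                           speciesTable = thermoSpeciesTable(),
                           method = c("closed_form", "bisection")) {
  method <- match.arg(method)
  nu <- reaction@stoichiometry[freeSpecies]
  if (is.na(nu) || nu == 0)
    stop("free species ", freeSpecies,
         " does not participate in reaction ", reaction@reactionId)
  ph <- speciesTable$phase[match(freeSpecies, speciesTable$name)]
  if (is.na(ph) || ph != "gas")
    stop("free species must be a gas with a species-table entry")
  atP <- function(p) {
    cond <- condition
    cond@partialPressures[freeSpecies] <- p
    actualDeltaG(reaction, cond, speciesTable)
  }
  if (method == "bisection") {
    root <- stats::uniroot(function(lp) atP(10^lp), c(-12, 2),
                           tol = .Machine$double.eps^0.75)
    return(10^root$root)
  }
  # dG(p) = dG_T + RT*(lnQ_rest + nu*ln p); set activity 1 to isolate lnQ_rest
  cond1 <- condition
  cond1@partialPressures[freeSpecies] <- 1
  rt <- .RGAS * condition@temperature
  g1 <- actualDeltaG(reaction, cond1, speciesTable)
  unname(exp(-g1 / (rt * nu)))
}

#' Dissolved oxygen at equilibrium with a diluted atmosphere
#'
#' Henry's-law dissolved O2 concentration for water in equilibrium with
#' `fraction` of the atmospheric O2 level (0.21 atm). The packaged constant
#' is 1.26 mmol/(L atm) at 25 C (Sander's compilation); temperature
#' dependence of the constant is out of scope and `temperature` is accepted
#' for interface symmetry only.
#'
#' @param fraction fraction of atmospheric oxygen, in (0, 1].
#' @param temperature kelvin (documented reference value 298.15).
#' @param henryConstant mmol/(L atm).
#' @return dissolved oxygen, micromolar.
#' @examples
#' doFromAtmosphericFraction(0.01)   # ~2.6 uM, the nanaerobic ceiling region
#' @export
doFromAtmosphericFraction <- function(fraction, temperature = 298.15,
                                      henryConstant = 1.26) {
  if (any(!is.finite(fraction)) || any(fraction <= 0) || any(fraction > 1))
    stop("fraction must lie in (0, 1]")
  if (temperature <= 0) stop("temperature must be positive (K)")
  0.21 * fraction * henryConstant * 1000
}
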