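#' H2/CO2 thermodynamic constraint grid
#'
#' Evaluates the condition-specific free energy of R1-R4 and the composite
#' pathways over a log10 grid of H2 and CO2 partial pressures, marks the
#' feasibility regions (syntrophic window: R3 and R2 both exergonic;
#' nanaerobic region: R4 and R2 both exergonic) and extracts the dG = 0
#' threshold curves for the H2-dependent reactions.
#'
#' @param condition base [ConditionSet-class]; defaults to the 35 C / pH 6.5 /
#'   0.5 atm CH4 / 1e-8 atm O2 / 20 mM acetate setting of
#'   [figure3Conditions()]. Any H2/CO2 entries are overridden by the grid.
#' @param h2Range,co2Range log10 atm axis limits (length-2).
#' @param resolution cells per axis, at least 2.
#' @param speciesTable formation-constant table.
#' @return list with elements
#'   \describe{
#'     \item{grid}{long data.frame: `log10_ph2`, `log10_pco2`, `reaction_id`,
#'       `delta_g_kj`.}
#'     \item{regions}{data.frame per cell with logical `syntrophic` (R3 and
#'       R2 exergonic) and `nanaerobic` (R4 and R2 exergonic).}
#'     \item{thresholds}{data.frame per `log10_pco2` and reaction (R2, R3,
#'       composites containing H2): `log10_ph2_zero`, the H2 partial pressure
#'       where dG crosses zero.}
#'     \item{window}{data.frame per `log10_pco2`: syntrophic H2 window bounds
#'       `h2_lower_atm` (from R2 = 0) and `h2_upper_atm` (from R3 = 0), NA
#'       where the window is empty.}
#'   }
#' @examples
#' g <- constraintGrid(resolution = 40)
#' head(g$window)
#' @export
constraintGrid <- function(condition = figure3Conditions(),
                           h2Range = c(-8, 0), co2Range = c(-4, 0),
                           resolution = 200,
                           speciesTable = thermoSpeciesTable()) {
  stopifnot(length(h2Range) == 2, length(co2Range) == 2)
  if (resolution < 2) stop("resolution must be at least 2")
  lh2 <- seq(h2Range[1], h2Range[2], length.out = resolution)
  lco2 <- seq(co2Range[1], co2Range[2], length.out = resolution)
  rx <- methanogenesisReactions()
  rx <- c(rx, list(`3+2` = composeReactions(rx$R3, rx$R2, reactionId = "3+2"),
                   `4+2` = composeReactions(rx$R4, rx$R2, reactionId = "4+2")))

  # dG(ph2, pco2) is affine in the log pressures: dG0_T + RT lnQ_rest
  # + RT (nuH2 ln pH2 + nuCO2 ln pCO2); evaluate vectorised per reaction.
  rt <- .RGAS * condition@temperature
  cells <- expand.grid(log10_ph2 = lh2, log10_pco2 = lco2,
                       KEEP.OUT.ATTRS = FALSE)
  gridList <- lapply(names(rx), function(id) {
    r <- rx[[id]]
    nuH2 <- if ("H2" %in% names(r@stoichiometry))
      r@stoichiometry[["H2"]] else 0
    nuCO2 <- if ("CO2" %in% names(r@stoichiometry))
      r@stoichiometry[["CO2"]] else 0
    cond1 <- condition
    cond1@partialPressures[c("H2", "CO2")] <- 1
    g1 <- actualDeltaG(r, cond1, speciesTable)
    dg <- g1 + rt * (nuH2 * cells$log10_ph2 + nuCO2 * cells$log10_pco2) *
      log(10)
    data.frame(cells, reaction_id = id, delta_g_kj = dg,
               stringsAsFactors = FALSE)
  })
  names(gridList) <- names(rx)
  grid <- do.call(rbind, gridList)
  rownames(grid) <- NULL

  regions <- data.frame(cells,
    syntrophic = gridList$R3$delta_g_kj < 0 & gridList$R2$delta_g_kj < 0,
    nanaerobic = gridList$R4$delta_g_kj < 0 & gridList$R2$delta_g_kj < 0)

  h2rx <- names(rx)[vapply(rx, function(r)
    "H2" %in% names(r@stoichiometry), logical(1))]
  thresholds <- do.call(rbind, lapply(h2rx, function(id) {
    p <- vapply(lco2, function(lc)
      solveThreshold(rx[[id]], {
        cond <- condition; cond@partialPressures["CO2"] <- 10^lc; cond
      }, "H2", speciesTable), numeric(1))
    data.frame(log10_pco2 = lco2, reaction_id = id, log10_ph2_zero = log10(p),
               stringsAsFactors = FALSE)
  }))
  rownames(thresholds) <- NULL

  lo <- thresholds$log10_ph2_zero[thresholds$reaction_id == "R2"]
  hi <- thresholds$log10_ph2_zero[thresholds$reaction_id == "R3"]
  empty <- lo >= hi
  window <- data.frame(log10_pco2 = lco2,
                       h2_lower_atm = ifelse(empty, NA, 10^lo),
                       h2_upper_atm = ifelse(empty, NA, 10^hi))

  list(grid = grid, regions = regions, thresholds = thresholds,
       window = window)
}

#' CO2 partial-pressure sensitivity of the two methanogenesis routes
#'
#' Condition-specific free energies of acetoclastic (R1) and hydrogenotrophic
#' (R2) methanogenesis across CO2 partial pressures, with the energy gap
#' `dG(R2) - dG(R1)`. Because R2 consumes CO2 while R1 produces it, the gap
#' decreases strictly with pCO2: CO2 accumulation favours the
#' hydrogenotrophic route.
#'
#' @param condition base [ConditionSet-class]; must carry a fixed H2 partial
#'   pressure for R2.
#' @param co2Values numeric vector of CO2 partial pressures, atm.
#' @param speciesTable formation-constant table.
#' @return data.frame: `pco2_atm`, `dg_r1_kj`, `dg_r2_kj`, `gap_kj`.
#' @examples
#' co2Sensitivity(figure3Conditions(ph2 = 1e-4), co2Values = c(0.1, 0.3, 1))
#' @export
co2Sensitivity <- function(condition, co2Values,
                           speciesTable = thermoSpeciesTable()) {
  if (any(!is.finite(co2Values)) || any(co2Values <= 0))
    stop("co2Values must be positive")
  if (is.na(condition@partialPressures["H2"]))
    stop("condition must fix an H2 partial pressure for R2")
  rx <- methanogenesisReactions()
  out <- do.call(rbind, lapply(co2Values, function(p) {
    cond <- condition
    cond@partialPressures["CO2"] <- p
    g1 <- actualDeltaG(rx$R1, cond, speciesTable)
    g2 <- actualDeltaG(rx$R2, cond, speciesTable)
    data.frame(pco2_atm = p, dg_r1_kj = g1, dg_r2_kj = g2, gap_kj = g2 - g1)
  }))
  rownames(out) <- NULL
  out
}
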