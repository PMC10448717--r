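rx <- methanogenesisReactions()
st <- thermoSpeciesTable()

test_that("standard free energies of R1-R4 match the printed pathway values", {
  expect_equal(standardDeltaG(rx$R1, st), -75.8, tolerance = 0.5 / 75.8)
  expect_equal(standardDeltaG(rx$R3, st), 54.9, tolerance = 0.5 / 54.9)
  expect_equal(standardDeltaG(rx$R2, st), -261.6, tolerance = 0.5 / 261.6)
  expect_equal(standardDeltaG(rx$R4, st), -893.7, tolerance = 0.5 / 893.7)
})

test_that("signed-sum formulation: empty reaction, reversal, missing species", {
  empty <- reactionSpec("none", numeric())
  expect_identical(standardDeltaG(empty, st), 0)
  expect_identical(standardDeltaH(empty, st), 0)
  expect_equal(standardDeltaG(reverseReaction(rx$R1), st),
               -standardDeltaG(rx$R1, st))
  bogus <- reactionSpec("x", c(unobtainium = 1))
  expect_error(standardDeltaG(bogus, st), "unobtainium")
})

test_that("reaction enthalpies match hand sums of formation enthalpies", {
  # R1: -74.81 - 393.509 + 486.01
  expect_equal(standardDeltaH(rx$R1, st), 17.691, tolerance = 1e-6)
  # R2: 2(-74.81) + 4(-285.83) - 2(-393.509)
  expect_equal(standardDeltaH(rx$R2, st), -505.922, tolerance = 1e-6)
})

test_that("Gibbs-Helmholtz correction reproduces printed 308 K values and identities", {
  dg1 <- standardDeltaG(rx$R1, st); dh1 <- standardDeltaH(rx$R1, st)
  expect_equal(temperatureCorrect(dg1, dh1, tAct = 308.15), -78.9,
               tolerance = 1.0 / 78.9)
  expect_identical(temperatureCorrect(-75.8, 17.7, 298.15, 298.15), -75.8)
  # dH = dG is the algebraic fixed point
  expect_equal(temperatureCorrect(-10, -10, 298.15, 350), -10)
  expect_error(temperatureCorrect(-10, 5, 298.15, -5), "positive")
})

test_that("reaction quotient term: unit activities, hand value, log-additivity", {
  allOnes <- conditionSet(308.15, c(CH4 = 1, CO2 = 1, H2 = 1, O2 = 1),
                          c(acetate = 1), pH = 0)
  expect_equal(reactionQuotientTerm(rx$R1, allOnes, st), 0)
  cond <- conditionSet(308.15, c(CH4 = 0.5, CO2 = 0.3), c(acetate = 0.02),
                       pH = 6.5)
  expect_equal(reactionQuotientTerm(rx$R1, cond, st),
               8.314e-3 * 308.15 * log((0.5 * 0.3) / (0.02 * 10^-6.5)),
               tolerance = 1e-12)
  cond2 <- cond
  cond2@partialPressures["CH4"] <- 1.0
  expect_equal(reactionQuotientTerm(rx$R1, cond2, st) -
                 reactionQuotientTerm(rx$R1, cond, st),
               8.314e-3 * 308.15 * log(2), tolerance = 1e-12)
  bad <- conditionSet(308.15, c(CH4 = 0.5), c(acetate = 0.02), pH = 6.5)
  expect_error(reactionQuotientTerm(rx$R1, bad, st), "CO2")
})

test_that("condition-specific dG equals the brute-force oracle on random conditions", {
  set.seed(42)
  for (i in 1:100) {
    cond <- randomCondition()
    r <- sample(rx, 1)[[1]]
    expect_equal(actualDeltaG(r, cond, st), bruteForceDeltaG(r, cond, st),
                 tolerance = 1e-12)
  }
  # both corrections vanish at the reference state
  ref <- conditionSet(298.15, c(CH4 = 1, CO2 = 1, H2 = 1, O2 = 1),
                      c(acetate = 1), pH = 0)
  expect_equal(actualDeltaG(rx$R1, ref, st), standardDeltaG(rx$R1, st))
})

test_that("composition is additive and cancels cleanly", {
  s32 <- composeReactions(rx$R3, rx$R2)
  expect_equal(standardDeltaG(s32, st), -206.7, tolerance = 0.5 / 206.7)
  expect_setequal(names(s32@stoichiometry),
                  c("acetate", "H+", "H2", "CH4", "H2O"))
  expect_equal(s32@stoichiometry[["H2"]], -4)
  # single reaction passes through unchanged
  one <- composeReactions(rx$R1)
  expect_equal(one@stoichiometry, rx$R1@stoichiometry)
  # cancellation against the reverse
  null <- composeReactions(rx$R1, reverseReaction(rx$R1))
  expect_length(null@stoichiometry, 0)
  expect_identical(standardDeltaG(null, st), 0)
  # additivity under arbitrary conditions for random reaction lists
  set.seed(11)
  for (i in 1:20) {
    pick <- sample(rx, sample(2:4, 1), replace = TRUE)
    cond <- randomCondition()
    expect_equal(actualDeltaG(composeReactions(pick), cond, st),
                 sum(vapply(pick, actualDeltaG, numeric(1), cond, st)),
                 tolerance = 1e-9)
  }
})

test_that("packaged pathways are internally consistent: R1 = R3 + R2/2", {
  expect_equal(standardDeltaG(rx$R1, st),
               standardDeltaG(rx$R3, st) + standardDeltaG(rx$R2, st) / 2,
               tolerance = 0.2 / 75)
})

test_that("pathway table reproduces the composite free energies", {
  pt <- pathwayTable(st)
  expect_equal(pt$dg298_kj[pt$reaction_id == "4+2"], -1155.3,
               tolerance = 0.5 / 1155.3)
  # composite rows equal the sum of their components
  expect_equal(pt$dg298_kj[pt$reaction_id == "3+2"],
               pt$dg298_kj[pt$reaction_id == "R3"] +
                 pt$dg298_kj[pt$reaction_id == "R2"][1], tolerance = 1e-9)
  # a supplied condition column matches the independent oracle
  cond <- figure3Conditions(ph2 = 1e-4, pco2 = 0.3)
  ptc <- pathwayTable(st, conditions = list(fig3 = cond))
  expect_equal(ptc$dg_fig3_kj[ptc$reaction_id == "R2"][1],
               bruteForceDeltaG(rx$R2, cond, st), tolerance = 1e-9)
})

test_that("Le Chatelier monotonicity: products raise dG, reactants lower it", {
  cond <- figure3Conditions(ph2 = 1e-4, pco2 = 0.3)
  bump <- function(r, species, f = 2) {
    c2 <- cond
    c2@partialPressures[species] <- c2@partialPressures[species] * f
    actualDeltaG(r, c2, st) - actualDeltaG(r, cond, st)
  }
  expect_gt(bump(rx$R2, "CH4"), 0)   # product of R2
  expect_lt(bump(rx$R2, "CO2"), 0)   # reactant of R2
  expect_lt(bump(rx$R2, "H2"), 0)    # reactant of R2
  expect_gt(bump(rx$R3, "H2"), 0)    # product of R3
  expect_lt(bump(rx$R4, "O2"), 0)    # reactant of R4
})

test_that("threshold solving: defining property, bisection oracle, CO2 coupling", {
  set.seed(99)
  for (i in 1:25) {
    cond <- randomCondition()
    r <- sample(list(rx$R2, rx$R3, composeReactions(rx$R3, rx$R2)), 1)[[1]]
    p <- solveThreshold(r, cond, "H2", st)
    cond@partialPressures["H2"] <- p
    expect_lt(abs(actualDeltaG(r, cond, st)), 1e-6)
  }
  cond <- figure3Conditions(pco2 = 0.3)
  pClosed <- solveThreshold(rx$R2, cond, "H2", st)
  pBisect <- solveThreshold(rx$R2, cond, "H2", st, method = "bisection")
  expect_equal(pClosed, pBisect, tolerance = 1e-10)
  # raising pCO2 relaxes the H2 requirement of CO2 reduction
  pHigh <- solveThreshold(rx$R2, figure3Conditions(pco2 = 0.9), "H2", st)
  expect_lt(pHigh, pClosed)
  expect_error(solveThreshold(rx$R1, cond, "H2", st), "participate")
  expect_error(solveThreshold(rx$R1, cond, "acetate", st), "gas")
})

test_that("dissolved oxygen from a diluted atmosphere is linear and ~2 uM at 1%", {
  do1pct <- doFromAtmosphericFraction(0.01)
  expect_gt(do1pct, 2); expect_lt(do1pct, 3)
  expect_equal(doFromAtmosphericFraction(1), 100 * do1pct)
  expect_equal(doFromAtmosphericFraction(0.01, henryConstant = 1.26), 2.646)
  expect_error(doFromAtmosphericFraction(0), "fraction")
})
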