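#' Terminal-oxidase gene ontology
#'
#' Catalytic-subunit gene symbols of the seven terminal oxidases, with their
#' oxygen-affinity class and a flag for the cytochrome bd family. Low
#' affinity: cytochrome bb3 (coxN), bo3 (cyoB), aa3-600 (qoxB), aa3 (ctaD).
#' High affinity: ba3 type (cbaA), cbb3 type (fixN, ccoN) and cytochrome bd
#' type I (cydA), type II (appC) and putative type (ythA). Only the bd types
#' support respiration at nanomolar dissolved oxygen.
#'
#' @return data.frame: `symbol`, `oxidase_type`, `affinity` (`low`/`high`),
#'   `bd_flag`.
#' @examples
#' oxidaseOntology()
#' @export
oxidaseOntology <- function() {
  data.frame(
    symbol = c("coxN", "cyoB", "qoxB", "ctaD",
               "cbaA", "fixN", "ccoN", "cydA", "appC", "ythA"),
    oxidase_type = c("cytochrome bb3", "cytochrome bo3",
                     "cytochrome aa3-600", "cytochrome aa3",
                     "cytochrome ba3", "cytochrome cbb3 (fixN)",
                     "cytochrome cbb3 (ccoN)", "cytochrome bd-I",
                     "cytochrome bd-II", "cytochrome bd putative"),
    affinity = c(rep("low", 4), rep("high", 6)),
    bd_flag = c(rep(FALSE, 7), rep(TRUE, 3)),
    stringsAsFactors = FALSE)
}

#' Universal single-copy housekeeping genes used for normalization
#'
#' @return character vector: rpoA, rpoB, rpoC, recA.
#' @export
housekeepingGenes <- function() c("rpoA", "rpoB", "rpoC", "recA")

#' Gene sets of the nanaerobic respiration and anaerobic fermentation pathways
#'
#' Respiration: pyruvate dehydrogenase (poxB, pdhABCD), NADH-quinone
#' oxidoreductase (nuoA-N), succinate dehydrogenase (sdhAB) and the
#' cytochrome bd oxidase subunits (cydAB, appBC, ythAB). Fermentation:
#' pyruvate-ferredoxin/flavodoxin oxidoreductases (por/nifJ, porABCD,
#' korAB) and formate C-acetyltransferase (pflB).
#'
#' @return named list with character vectors `respiration` and `fermentation`.
#' @export
pathwayGeneSets <- function() {
  list(
    respiration = c("poxB", paste0("pdh", c("A", "B", "C", "D")),
                    paste0("nuo", LETTERS[1:14]), "sdhA", "sdhB",
                    "cydA", "cydB", "appB", "appC", "ythA", "ythB"),
    fermentation = c("por", "nifJ", paste0("por", c("A", "B", "C", "D")),
                     "korA", "korB", "pflB"))
}

#' Assign the functional category of a gene symbol
#'
#' A symbol maps to exactly one category; oxidase catalytic subunits take
#' precedence over pathway membership (cydA/appC/ythA are counted as
#' oxidases here, while [pathwaySummary()] selects pathway genes by symbol).
#'
#' @param symbol character vector of gene symbols.
#' @return character vector of categories: `oxidase`, `housekeeping`,
#'   `respiration_pathway`, `fermentation_pathway` or `other`.
#' @export
classifySymbol <- function(symbol) {
  sets <- pathwayGeneSets()
  out <- rep("other", length(symbol))
  out[symbol %in% sets$fermentation] <- "fermentation_pathway"
  out[symbol %in% sets$respiration] <- "respiration_pathway"
  out[symbol %in% housekeepingGenes()] <- "housekeeping"
  out[symbol %in% oxidaseOntology()$symbol] <- "oxidase"
  out
}
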