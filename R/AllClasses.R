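#' @import methods
NULL

#' Chemical reaction with signed stoichiometry
#'
#' A reaction over named chemical species. Coefficients are signed: products
#' positive, reactants negative, so that free-energy summation and reaction
#' composition are plain signed sums.
#'
#' @slot reactionId single identifier, e.g. `"R1"` or `"R3+R2"`.
#' @slot stoichiometry named numeric vector of nonzero signed coefficients.
#' @slot label human-readable equation string.
#'
#' @export
setClass("ReactionSpec",
  representation(reactionId = "character",
                 stoichiometry = "numeric",
                 label = "character"))

setValidity("ReactionSpec", function(object) {
  msg <- character()
  if (length(object@reactionId) != 1L)
    msg <- c(msg, "reactionId must be a single string")
  s <- object@stoichiometry
  if (length(s) > 0L) {
    if (is.null(names(s)) || any(!nzchar(names(s))))
      msg <- c(msg, "stoichiometry must be a named vector")
    if (anyDuplicated(names(s)))
      msg <- c(msg, "duplicated species in stoichiometry")
    if (any(!is.finite(s)) || any(s == 0))
      msg <- c(msg, "stoichiometric coefficients must be finite and nonzero")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReactionSpec
#'
#' @param reactionId identifier for the reaction.
#' @param stoichiometry named numeric vector, products positive and reactants
#'   negative. Zero coefficients are dropped.
#' @param label optional equation string; built from the stoichiometry when
#'   missing.
#' @return A [ReactionSpec-class] object.
#' @examples
#' r1 <- reactionSpec("R1", c(acetate = -1, "H+" = -1, CH4 = 1, CO2 = 1))
#' r1
#' @export
reactionSpec <- function(reactionId, stoichiometry, label = NULL) {
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (is.null(label)) label <- .formatEquation(stoichiometry)
  new("ReactionSpec", reactionId = as.character(reactionId),
      stoichiometry = stoichiometry, label = label)
}

.formatEquation <- function(s) {
  if (length(s) == 0L) return("(empty)")
  side <- function(coef, nm) {
    paste(ifelse(abs(coef) == 1, nm, paste0(abs(coef), " ", nm)),
          collapse = " + ")
  }
  lhs <- s[s < 0]; rhs <- s[s > 0]
  paste(side(lhs, names(lhs)), "->", side(rhs, names(rhs)))
}

setMethod("show", "ReactionSpec", function(object) {
  cat("ReactionSpec", object@reactionId, "\n  ", object@label, "\n", sep = "")
})

#' Environmental condition set for free-energy corrections
#'
#' Temperature and species activities used in the reaction-quotient
#' correction. Gases enter as partial pressures (atm, against a 1 atm
#' standard state), solutes as concentrations (mol/L against 1 M), the
#' proton as `10^-pH`, and liquid water at unit activity.
#'
#' @slot temperature kelvin.
#' @slot partialPressures named numeric, atm, gas species.
#' @slot concentrations named numeric, mol/L, aqueous species.
#' @slot pH dimensionless.
#' @slot totalPressure atm (bookkeeping only; no fugacity correction).
#'
#' @export
setClass("ConditionSet",
  representation(temperature = "numeric",
                 partialPressures = "numeric",
                 concentrations = "numeric",
                 pH = "numeric",
                 totalPressure = "numeric"))

setValidity("ConditionSet", function(object) {
  msg <- character()
  if (length(object@temperature) != 1L || !is.finite(object@temperature) ||
      object@temperature <= 0)
    msg <- c(msg, "temperature must be a single positive value (K)")
  for (nm in c("partialPressures", "concentrations")) {
    v <- slot(object, nm)
    if (length(v) && (is.null(names(v)) || any(!is.finite(v)) || any(v <= 0)))
      msg <- c(msg, paste(nm, "must be named, finite and strictly positive"))
  }
  if (length(object@pH) != 1L || !is.finite(object@pH))
    msg <- c(msg, "pH must be a single finite value")
  if (length(msg)) msg else TRUE
})

#' Construct a ConditionSet
#'
#' @param temperature kelvin.
#' @param partialPressures named numeric vector of gas partial pressures, atm.
#' @param concentrations named numeric vector of solute concentrations, mol/L.
#' @param pH dimensionless; proton activity is `10^-pH`.
#' @param totalPressure atm.
#' @return A [ConditionSet-class] object.
#' @examples
#' conditionSet(308.15, c(CH4 = 0.5, O2 = 1e-8), c(acetate = 0.02), pH = 6.5)
#' @export
conditionSet <- function(temperature = 298.15, partialPressures = numeric(),
                         concentrations = numeric(), pH = 7,
                         totalPressure = 1) {
  new("ConditionSet", temperature = temperature,
      partialPressures = partialPressures, concentrations = concentrations,
      pH = pH, totalPressure = totalPressure)
}

setMethod("show", "ConditionSet", function(object) {
  cat("ConditionSet: ", object@temperature, " K, pH ", object@pH, "\n",
      sep = "")
  if (length(object@partialPressures))
    cat("  gas (atm): ",
        paste(names(object@partialPressures), signif(object@partialPressures, 3),
              sep = "=", collapse = ", "), "\n", sep = "")
  if (length(object@concentrations))
    cat("  aqueous (mol/L): ",
        paste(names(object@concentrations), signif(object@concentrations, 3),
              sep = "=", collapse = ", "), "\n", sep = "")
})

.CATALOG_COLS <- c("sample_id", "gene_id", "symbol", "length_nt",
                   "category", "taxon_family")
.CATEGORIES <- c("oxidase", "housekeeping", "respiration_pathway",
                 "fermentation_pathway", "other")

#' Annotated gene catalog
#'
#' Per-sample annotated gene records (one row per ORF). Each gene belongs to
#' exactly one sample (catalogs emulate per-sample assemblies) and exactly one
#' functional category, assigned from the packaged oxidase/housekeeping/
#' pathway ontology by [geneCatalog()].
#'
#' @slot records data.frame with columns `sample_id`, `gene_id`, `symbol`,
#'   `length_nt`, `category`, `taxon_family` (NA allowed) plus optional
#'   generator provenance columns.
#' @slot nDropped number of records removed by the 180 nt catalog filter.
#'
#' @export
setClass("GeneCatalog",
  representation(records = "data.frame", nDropped = "integer"))

setValidity("GeneCatalog", function(object) {
  df <- object@records
  msg <- character()
  missing <- setdiff(.CATALOG_COLS, names(df))
  if (length(missing))
    return(paste("missing catalog columns:", paste(missing, collapse = ", ")))
  if (nrow(df)) {
    if (any(df$length_nt < 180))
      msg <- c(msg, "catalog contains genes shorter than 180 nt")
    if (!all(df$category %in% .CATEGORIES))
      msg <- c(msg, "invalid category label")
    if (anyDuplicated(df[c("sample_id", "gene_id")]))
      msg <- c(msg, "duplicated (sample_id, gene_id)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneCatalog", function(object) {
  df <- object@records
  cat("GeneCatalog with ", nrow(df), " genes in ",
      length(unique(df$sample_id)), " sample(s)\n", sep = "")
  if (nrow(df))
    print(table(category = df$category))
  if (object@nDropped > 0L)
    cat("  (", object@nDropped, " records < 180 nt dropped at import)\n",
        sep = "")
})

#' @describeIn GeneCatalog-class the underlying records as a data.frame.
#' @param x,object a `GeneCatalog`.
#' @export
catalogRecords <- function(x) {
  stopifnot(is(x, "GeneCatalog"))
  x@records
}

#' @describeIn GeneCatalog-class sample identifiers present in the catalog.
#' @export
sampleIds <- function(x) {
  stopifnot(is(x, "GeneCatalog"))
  unique(x@records$sample_id)
}

#' Mapped-read count table
#'
#' Per (sample, gene) metagenome and (optionally) metatranscriptome mapped
#' read counts.
#'
#' @slot counts data.frame with columns `sample_id`, `gene_id`,
#'   `metagenome_count`, `metatranscriptome_count` (NA when the sample has no
#'   metatranscriptome).
#'
#' @export
setClass("CountTable", representation(counts = "data.frame"))

setValidity("CountTable", function(object) {
  df <- object@counts
  need <- c("sample_id", "gene_id", "metagenome_count",
            "metatranscriptome_count")
  missing <- setdiff(need, names(df))
  if (length(missing))
    return(paste("missing count columns:", paste(missing, collapse = ", ")))
  msg <- character()
  if (nrow(df)) {
    mg <- df$metagenome_count
    mt <- df$metatranscriptome_count
    if (any(!is.finite(mg)) || any(mg < 0))
      msg <- c(msg, "metagenome counts must be finite and non-negative")
    if (any(!is.na(mt) & (mt < 0 | !is.finite(mt))))
      msg <- c(msg, "metatranscriptome counts must be non-negative")
    if (anyDuplicated(df[c("sample_id", "gene_id")]))
      msg <- c(msg, "duplicated (sample_id, gene_id)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CountTable
#'
#' @param counts data.frame with `sample_id`, `gene_id`, `metagenome_count`
#'   and optionally `metatranscriptome_count` columns.
#' @param catalog optional [GeneCatalog-class]; when given, every
#'   (sample, gene) key must resolve in the catalog.
#' @return A [CountTable-class] object.
#' @export
countTable <- function(counts, catalog = NULL) {
  if (!"metatranscriptome_count" %in% names(counts))
    counts$metatranscriptome_count <- NA_real_
  counts <- as.data.frame(counts)[c("sample_id", "gene_id",
                                    "metagenome_count",
                                    "metatranscriptome_count")]
  if (!is.null(catalog)) {
    key <- paste(counts$sample_id, counts$gene_id)
    ckey <- paste(catalogRecords(catalog)$sample_id,
                  catalogRecords(catalog)$gene_id)
    bad <- setdiff(key, ckey)
    if (length(bad))
      stop("count rows not present in catalog: ",
           paste(utils::head(bad, 5), collapse = "; "))
  }
  new("CountTable", counts = counts)
}

setMethod("show", "CountTable", function(object) {
  df <- object@counts
  cat("CountTable: ", nrow(df), " rows, ",
      length(unique(df$sample_id)), " sample(s); metatranscriptome for ",
      sum(!is.na(df$metatranscriptome_count)), " rows\n", sep = "")
})

#' @describeIn CountTable-class the underlying counts as a data.frame.
#' @param x a `CountTable`.
#' @export
countRecords <- function(x) {
  stopifnot(is(x, "CountTable"))
  x@counts
}
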