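#' Read a pipeline run configuration
#'
#' YAML key-value configuration. Exactly one of `inputs:` (paths `catalog`,
#' `counts`, `samples`) or `synthetic:` (`archetypes`, `n_per_archetype`,
#' `target_r`, `noise_sd`) must be present; optional blocks: `conditions:`
#' (named condition sets with `temperature_K`, `ph`, `partial_pressures`,
#' `concentrations`), `seed`, `outdir`. A configuration round-trips
#' losslessly through YAML.
#'
#' @param path YAML file.
#' @return config list as consumed by [runPipeline()].
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  .validateConfig(cfg)
  cfg
}

.validateConfig <- function(cfg) {
  hasIn <- !is.null(cfg$inputs)
  hasSyn <- !is.null(cfg$synthetic)
  if (hasIn == hasSyn && (hasIn || hasSyn))
    stop("config must contain exactly one of 'inputs' and 'synthetic'")
  invisible(cfg)
}

.conditionFromConfig <- function(cc) {
  conditionSet(
    temperature = if (is.null(cc$temperature_K)) 298.15 else cc$temperature_K,
    partialPressures = unlist(cc$partial_pressures),
    concentrations = unlist(cc$concentrations),
    pH = if (is.null(cc$ph)) 7 else cc$ph,
    totalPressure = if (is.null(cc$total_pressure)) 1 else cc$total_pressure)
}

.writeTsv <- function(df, path, digits = NULL) {
  if (!is.null(digits)) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, digits = digits)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full nanaerobic-digestion analysis
#'
#' Orchestrates the stages: data generation or ingestion, oxidase/pathway
#' profiling, methane correlation statistics and the thermodynamic tables.
#' Writes figure-ready TSV outputs plus a JSON manifest recording the seed,
#' the full configuration, package version and produced/omitted outputs.
#' Identical configuration and seed give byte-identical outputs.
#'
#' Outputs (in `outdir`): `table2.tsv` (pathway free energies, 1 decimal),
#' `fig3a_grid.tsv` (long-format constraint grid), `fig3b.tsv` (CO2
#' sensitivity), `fig1_table.tsv` (sample x oxidase relative abundance),
#' `fig2b_table.tsv` (pathway gene/transcript summary), `family_table.tsv`,
#' `correlations.tsv`, `group_tests.tsv`, `manifest.json`.
#'
#' @param config config list (see [readRunConfig()]); may also be a path to
#'   a YAML file. With `stages` a subset of
#'   `c("simulate", "profile", "thermo", "correlate")` can be run.
#' @param outdir output directory, created if needed; overrides
#'   `config$outdir`.
#' @param seed integer seed; overrides `config$seed`.
#' @param stages stages to run; `"all"` expands to every stage applicable to
#'   the configuration.
#' @param gridResolution resolution of the constraint grid.
#' @return (invisibly) the manifest list.
#' @export
runPipeline <- function(config, outdir = NULL, seed = NULL,
                        stages = "all", gridResolution = 120) {
  if (is.character(config) && length(config) == 1L)
    config <- readRunConfig(config)
  .validateConfig(config)
  if (is.null(seed)) seed <- if (is.null(config$seed)) 1L else config$seed
  if (is.null(outdir))
    outdir <- if (is.null(config$outdir)) "nanaerobics_run" else config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  thermoOnly <- is.null(config$inputs) && is.null(config$synthetic)
  if (identical(stages, "all"))
    stages <- if (thermoOnly) "thermo" else
      c("simulate", "profile", "thermo", "correlate")

  produced <- character(); omitted <- character(); notes <- character()
  if (thermoOnly) {
    omitted <- c("fig1_table.tsv", "fig2b_table.tsv", "family_table.tsv",
                 "correlations.tsv", "group_tests.tsv")
    notes <- "thermodynamics-only run: no omics inputs configured"
  }
  manifest <- list(package = "nanaerobics",
                   version = as.character(utils::packageVersion("nanaerobics")),
                   seed = seed, stages = stages, config = config)

  catalog <- NULL; counts <- NULL; samples <- NULL
  if ("simulate" %in% stages && !is.null(config$synthetic)) {
    syn <- config$synthetic
    archNames <- if (is.null(syn$archetypes)) "rumen_sheep" else
      unlist(syn$archetypes)
    arch <- digesterArchetypes()[archNames]
    if (anyNA(names(arch))) stop("unknown archetype in config")
    cohort <- generateCohort(
      arch,
      nPerArchetype = if (is.null(syn$n_per_archetype)) 4 else
        syn$n_per_archetype,
      targetR = if (is.null(syn$target_r)) 0.99 else syn$target_r,
      noiseSd = if (is.null(syn$noise_sd)) 1 else syn$noise_sd,
      seed = seed)
    catalog <- cohort$catalog; counts <- cohort$counts
    samples <- cohort$samples
    manifest$cohort <- cohort$manifest
    produced <- c(produced,
      .writeTsv(catalogRecords(catalog), file.path(outdir, "catalog.tsv")),
      .writeTsv(countRecords(counts), file.path(outdir, "counts.tsv")),
      .writeTsv(samples, file.path(outdir, "samples.tsv")))
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    catalog <- readGeneCatalog(inp$catalog)
    counts <- readCountTable(inp$counts, catalog = catalog)
    if (!is.null(inp$samples))
      samples <- utils::read.delim(inp$samples, stringsAsFactors = FALSE)
  }

  if ("profile" %in% stages) {
    if (is.null(catalog)) {
      omitted <- c(omitted, "fig1_table.tsv", "fig2b_table.tsv",
                   "family_table.tsv")
      notes <- c(notes, "profile stage skipped: no omics inputs")
    } else {
      prof <- oxidaseProfile(catalog, counts)
      fig1 <- merge(prof$profile, prof$flags, by = "sample_id")
      produced <- c(produced,
        .writeTsv(fig1, file.path(outdir, "fig1_table.tsv"), digits = 6),
        .writeTsv(pathwaySummary(catalog, counts),
                  file.path(outdir, "fig2b_table.tsv"), digits = 6),
        .writeTsv(familySummary(catalog),
                  file.path(outdir, "family_table.tsv"), digits = 6))
    }
  }

  if ("thermo" %in% stages) {
    conds <- NULL
    if (!is.null(config$conditions))
      conds <- lapply(config$conditions, .conditionFromConfig)
    produced <- c(produced,
      .writeTsv(pathwayTable(conditions = conds),
                file.path(outdir, "table2.tsv"), digits = 1))
    grid <- constraintGrid(resolution = gridResolution)
    produced <- c(produced,
      .writeTsv(grid$grid, file.path(outdir, "fig3a_grid.tsv"), digits = 4),
      .writeTsv(co2Sensitivity(figure3Conditions(ph2 = 1e-4),
                               co2Values = 10^seq(-4, 0, by = 0.25)),
                file.path(outdir, "fig3b.tsv"), digits = 4))
  }

  if ("correlate" %in% stages) {
    okCorr <- !is.null(samples) && !is.null(catalog) &&
      sum(!is.na(samples$methane_yield)) >= 3
    if (okCorr) {
      corr <- methaneBdCorrelation(samples, catalog = catalog,
                                   counts = counts)
      produced <- c(produced,
        .writeTsv(corr, file.path(outdir, "correlations.tsv"), digits = 6))
    } else {
      omitted <- c(omitted, "correlations.tsv")
      notes <- c(notes, "correlate stage skipped: need >= 3 samples with methane yield")
    }
    grouped <- !is.null(samples) && !is.null(catalog) &&
      length(unique(samples$ecosystem)) >= 2
    if (grouped) {
      flags <- oxidaseProfile(catalog, counts)$flags
      tot <- flags$total_oxidase_abundance[match(samples$sample_id,
                                                 flags$sample_id)]
      ecos <- unique(samples$ecosystem)
      pairs <- utils::combn(ecos, 2, simplify = FALSE)
      gt <- do.call(rbind, lapply(pairs, function(pr) {
        g1 <- tot[samples$ecosystem == pr[1]]
        g2 <- tot[samples$ecosystem == pr[2]]
        if (length(g1) < 2 || length(g2) < 2) return(NULL)
        res <- groupCompare(g1, g2)
        data.frame(group1 = pr[1], group2 = pr[2], t = res$t,
                   p_value = res$p_value, significant = res$significant,
                   stringsAsFactors = FALSE)
      }))
      if (!is.null(gt) && nrow(gt)) {
        produced <- c(produced,
          .writeTsv(gt, file.path(outdir, "group_tests.tsv"), digits = 6))
      } else {
        omitted <- c(omitted, "group_tests.tsv")
        notes <- c(notes, "group tests skipped: need >= 2 samples per ecosystem")
      }
    } else {
      omitted <- c(omitted, "group_tests.tsv")
      notes <- c(notes, "group tests skipped: fewer than 2 ecosystems")
    }
  }

  manifest$outputs <- basename(produced)
  manifest$omitted <- omitted
  manifest$notes <- notes
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
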