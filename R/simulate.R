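#' Construct a synthetic ecosystem archetype
#'
#' An archetype fixes the expected functional composition of a simulated
#' microbiome: the terminal-oxidase complement (expected relative abundance
#' per catalytic-subunit symbol, on the housekeeping-normalized scale),
#' pathway gene rates and transcript multipliers, background catalog size,
#' negative-binomial dispersion and per-omic sequencing depth.
#'
#' @param name ecosystem label.
#' @param oxidaseComplement named numeric vector, expected relative abundance
#'   per oxidase symbol (subset of [oxidaseOntology()] symbols).
#' @param respirationRate,fermentationRate expected per-gene abundance of
#'   pathway genes relative to housekeeping genes (rate 1).
#' @param respirationTx,fermentationTx transcript-rate multipliers of the two
#'   pathways (fermentation > respiration plants the expression ordering
#'   observed in rumen systems).
#' @param bdTx baseline transcript multiplier of the cytochrome bd genes.
#' @param bdTxSdlog lognormal sdlog of the per-sample variability of the bd
#'   transcript multiplier (drives realistic transcript/gene-ratio spread
#'   across a cohort).
#' @param nGenesOther background catalog size (genes with no packaged role).
#' @param dispersion negative-binomial dispersion (0 gives Poisson counts).
#' @param depth expected total mapped reads per omic.
#' @param familyProbs named probability vector for family labels of bd genes.
#' @return classed list (`archetypeSpec`).
#' @export
archetypeSpec <- function(name, oxidaseComplement,
                          respirationRate = 0.6, fermentationRate = 0.8,
                          respirationTx = 1, fermentationTx = 4,
                          bdTx = 1.5, bdTxSdlog = 0.5,
                          nGenesOther = 200, dispersion = 0.3, depth = 3e5,
                          familyProbs = c(Prevotellaceae = 0.6,
                                          Selenomonadaceae = 0.2,
                                          Eggerthellaceae = 0.12,
                                          Lachnospiraceae = 0.08)) {
  ont <- oxidaseOntology()
  bad <- setdiff(names(oxidaseComplement), ont$symbol)
  if (length(bad))
    stop("unknown oxidase symbols: ", paste(bad, collapse = ", "))
  if (any(oxidaseComplement < 0) || dispersion < 0 || depth < 0)
    stop("abundances, dispersion and depth must be non-negative")
  structure(list(name = name, oxidaseComplement = oxidaseComplement,
                 respirationRate = respirationRate,
                 fermentationRate = fermentationRate,
                 respirationTx = respirationTx,
                 fermentationTx = fermentationTx,
                 bdTx = bdTx, bdTxSdlog = bdTxSdlog,
                 nGenesOther = nGenesOther, dispersion = dispersion,
                 depth = depth,
                 familyProbs = familyProbs / sum(familyProbs)),
            class = "archetypeSpec")
}

#' Packaged ecosystem archetypes
#'
#' Seven archetypes mirroring the qualitative structure of methanogenic
#' ecosystems: rumen archetypes carry only cytochrome bd oxidases, the oil
#' reservoir has the minimum total oxidase abundance (strict-anaerobic
#' control), and lab-scale digesters carry more oxidase signal than
#' full-scale ones. These orderings hold by construction of the expected
#' complements.
#'
#' @return named list of [archetypeSpec()] objects: `rumen_sheep`,
#'   `rumen_cattle`, `lab_AD`, `lab_ORP_AD`, `full_AD`, `thermophilic_AD`,
#'   `oil_reservoir`.
#' @export
digesterArchetypes <- function() {
  rumenFam <- c(Prevotellaceae = 0.65, Selenomonadaceae = 0.18,
                Eggerthellaceae = 0.12, Lachnospiraceae = 0.05)
  labOx <- c(cydA = 0.85, appC = 0.20, ythA = 0.08, ctaD = 0.12,
             cbaA = 0.08, fixN = 0.06, ccoN = 0.05, coxN = 0.04,
             cyoB = 0.03, qoxB = 0.02)
  arch <- list(
    rumen_sheep = archetypeSpec("rumen_sheep",
      c(cydA = 1.0, appC = 0.25, ythA = 0.12), familyProbs = rumenFam),
    rumen_cattle = archetypeSpec("rumen_cattle",
      c(cydA = 1.1, appC = 0.30, ythA = 0.15), familyProbs = rumenFam),
    lab_AD = archetypeSpec("lab_AD", labOx),
    lab_ORP_AD = archetypeSpec("lab_ORP_AD", labOx * 1.35),
    full_AD = archetypeSpec("full_AD",
      c(cydA = 0.45, appC = 0.10, ythA = 0.05, ctaD = 0.05, cbaA = 0.04,
        fixN = 0.03, ccoN = 0.02, coxN = 0.015, cyoB = 0.01, qoxB = 0.008)),
    thermophilic_AD = archetypeSpec("thermophilic_AD",
      c(cydA = 0.30, appC = 0.05, ythA = 0.02, ctaD = 0.02, fixN = 0.01)),
    oil_reservoir = archetypeSpec("oil_reservoir",
      c(cydA = 0.03, appC = 0.01)))
  ont <- oxidaseOntology()
  totals <- vapply(arch, function(a) sum(a$oxidaseComplement), numeric(1))
  stopifnot(
    all(names(arch$rumen_sheep$oxidaseComplement) %in%
          ont$symbol[ont$bd_flag]),
    all(names(arch$rumen_cattle$oxidaseComplement) %in%
          ont$symbol[ont$bd_flag]),
    totals["oil_reservoir"] == min(totals),
    totals["lab_AD"] >= totals["full_AD"],
    totals["lab_ORP_AD"] >= totals["full_AD"])
  arch
}

#' Generate a synthetic annotated gene catalog
#'
#' Deterministic for a fixed seed. The catalog contains exactly one copy of
#' each housekeeping gene (rpoA/rpoB/rpoC/recA, rate 1 — the normalization
#' anchor), one gene per oxidase symbol of the archetype complement with
#' rate equal to its expected relative abundance, the respiration and
#' fermentation pathway genes, and `nGenesOther` background genes with
#' lognormal rates. Gene lengths are uniform on [300, 3000] nt; bd genes get
#' family labels drawn from the archetype's family distribution. Expected
#' count rates (`rate`) and transcript rates (`tx_rate`) are carried as
#' provenance columns for [generateCounts()].
#'
#' @param archetype an [archetypeSpec()].
#' @param seed integer RNG seed.
#' @param sampleId sample identifier for the generated records.
#' @param bdTxFactor extra per-sample multiplier on the bd transcript rate
#'   (used by [generateCohort()] to spread transcript/gene ratios).
#' @return A [GeneCatalog-class].
#' @export
generateCatalog <- function(archetype, seed, sampleId = archetype$name,
                            bdTxFactor = 1) {
  stopifnot(inherits(archetype, "archetypeSpec"))
  set.seed(seed)
  ont <- oxidaseOntology()
  sets <- pathwayGeneSets()
  bdSymbols <- ont$symbol[ont$bd_flag]

  symbols <- housekeepingGenes()
  rates <- rep(1, length(symbols))
  oxSym <- names(archetype$oxidaseComplement)
  symbols <- c(symbols, oxSym)
  rates <- c(rates, unname(archetype$oxidaseComplement))
  # oxidase genes come solely from the archetype complement; the remaining
  # respiration genes are the non-oxidase subunits (poxB, pdh, nuo, sdh,
  # cydB/appB/ythB)
  respExtra <- setdiff(sets$respiration, ont$symbol)
  symbols <- c(symbols, respExtra)
  rates <- c(rates, rep(archetype$respirationRate, length(respExtra)))
  symbols <- c(symbols, sets$fermentation)
  rates <- c(rates, rep(archetype$fermentationRate,
                        length(sets$fermentation)))
  nOther <- archetype$nGenesOther
  if (nOther > 0) {
    symbols <- c(symbols, sprintf("hyp_%04d", seq_len(nOther)))
    rates <- c(rates, stats::rlnorm(nOther, meanlog = -1, sdlog = 1))
  }

  n <- length(symbols)
  txMult <- rep(1, n)
  txMult[symbols %in% sets$fermentation] <- archetype$fermentationTx
  txMult[symbols %in% setdiff(sets$respiration, bdSymbols)] <-
    archetype$respirationTx
  txMult[symbols %in% bdSymbols] <- archetype$bdTx * bdTxFactor

  lengths <- sample.int(2701L, n, replace = TRUE) + 299L
  fam <- rep(NA_character_, n)
  isBd <- symbols %in% bdSymbols
  if (any(isBd))
    fam[isBd] <- sample(names(archetype$familyProbs), sum(isBd),
                        replace = TRUE, prob = archetype$familyProbs)
  records <- data.frame(
    sample_id = sampleId,
    gene_id = sprintf("%s_g%04d", sampleId, seq_len(n)),
    symbol = symbols, length_nt = lengths, taxon_family = fam,
    rate = rates, tx_rate = rates * txMult, stringsAsFactors = FALSE)
  geneCatalog(records)
}

#' Generate negative-binomial mapped-read counts for a catalog
#'
#' Per-gene counts are negative binomial with mean
#' `depth * rate * length / sum(rate * length)` (transcript rates for the
#' metatranscriptome) and the archetype's dispersion (`size = 1/dispersion`;
#' dispersion 0 gives Poisson counts). Deterministic for a fixed seed;
#' metagenome and metatranscriptome use consecutive sub-seeds.
#'
#' @param catalog a [GeneCatalog-class] from [generateCatalog()] (must carry
#'   the `rate` and `tx_rate` provenance columns).
#' @param archetype the [archetypeSpec()] used to generate the catalog.
#' @param seed integer RNG seed.
#' @param omics which read sets to simulate; omitted omics are emitted as NA.
#' @return A [CountTable-class].
#' @export
generateCounts <- function(catalog, archetype, seed,
                           omics = c("metagenome", "metatranscriptome")) {
  stopifnot(inherits(archetype, "archetypeSpec"))
  omics <- match.arg(omics, several.ok = TRUE)
  df <- catalogRecords(catalog)
  if (!all(c("rate", "tx_rate") %in% names(df)))
    stop("catalog lacks generator rate columns; use generateCatalog()")
  drawOmic <- function(rateCol, subSeed) {
    set.seed(subSeed)
    w <- df[[rateCol]] * df$length_nt
    if (archetype$depth == 0 || sum(w) == 0)
      return(rep(0L, nrow(df)))
    mu <- archetype$depth * w / sum(w)
    if (archetype$dispersion <= 0) stats::rpois(nrow(df), mu)
    else stats::rnbinom(nrow(df), mu = mu, size = 1 / archetype$dispersion)
  }
  mg <- if ("metagenome" %in% omics) drawOmic("rate", seed) else NA_real_
  mt <- if ("metatranscriptome" %in% omics) drawOmic("tx_rate", seed + 1L)
        else NA_real_
  countTable(data.frame(sample_id = df$sample_id, gene_id = df$gene_id,
                        metagenome_count = mg, metatranscriptome_count = mt,
                        stringsAsFactors = FALSE))
}

#' Generate a synthetic cohort with a planted methane correlation
#'
#' Generates per-sample catalogs and counts for the requested archetypes,
#' then constructs methane yields as an affine function of each sample's
#' realized cytochrome bd transcript/gene ratio plus Gaussian noise, with
#' the slope calibrated so the population correlation equals `targetR`.
#' Because the yield is built on the realized (post-sampling) ratio, the
#' correlation recovered by [methaneBdCorrelation()] is a true end-to-end
#' test of the normalization and statistics stages.
#'
#' @param archetypes list of [archetypeSpec()] objects (or one archetype).
#' @param nPerArchetype samples per archetype, >= 1.
#' @param targetR planted population correlation in [-1, 1].
#' @param noiseSd Gaussian noise standard deviation of the yield (must be 0
#'   when |targetR| = 1 and positive when |targetR| < 1; otherwise the
#'   target is infeasible and an error is raised).
#' @param seed integer RNG seed; all sample-level randomness is derived from
#'   it.
#' @param baseYield positive offset keeping yields > 0 (arbitrary consistent
#'   unit, e.g. mL CH4 / g VS; Pearson r is affine-invariant).
#' @return list with `catalog` ([GeneCatalog-class]), `counts`
#'   ([CountTable-class]), `samples` (data.frame sample_id, ecosystem,
#'   methane_yield, methane_units) and `manifest` (seed and parameters).
#' @export
generateCohort <- function(archetypes, nPerArchetype = 4, targetR = 0.99,
                           noiseSd = 1, seed = 1, baseYield = 20) {
  if (inherits(archetypes, "archetypeSpec")) archetypes <- list(archetypes)
  stopifnot(all(vapply(archetypes, inherits, logical(1), "archetypeSpec")),
            nPerArchetype >= 1)
  if (!is.finite(targetR) || abs(targetR) > 1)
    stop("targetR must lie in [-1, 1]")
  if (abs(targetR) == 1 && noiseSd != 0)
    stop("targetR of +/-1 is infeasible with positive noise")
  if (abs(targetR) < 1 && noiseSd <= 0)
    stop("|targetR| < 1 requires positive noiseSd")

  n <- length(archetypes) * nPerArchetype
  set.seed(seed)
  catSeeds <- sample.int(2147483646L, n)
  cntSeeds <- sample.int(2147483646L, n)
  bdFactors <- stats::rlnorm(n, 0,
    max(vapply(archetypes, `[[`, numeric(1), "bdTxSdlog")))
  eps <- stats::rnorm(n)

  idx <- 0L
  cats <- list(); cnts <- list(); eco <- character(n); ids <- character(n)
  for (a in archetypes) {
    for (k in seq_len(nPerArchetype)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", a$name, k)
      ids[idx] <- sid; eco[idx] <- a$name
      cat_i <- generateCatalog(a, catSeeds[idx], sampleId = sid,
                               bdTxFactor = bdFactors[idx])
      cats[[idx]] <- catalogRecords(cat_i)
      cnts[[idx]] <- countRecords(generateCounts(cat_i, a, cntSeeds[idx]))
    }
  }
  catalog <- geneCatalog(do.call(rbind, cats))
  counts <- countTable(do.call(rbind, cnts), catalog = catalog)

  bd <- bdClassSummary(catalog, counts)
  x <- bd$transcript_gene_ratio[match(ids, bd$sample_id)]
  if (anyNA(x)) stop("undefined bd transcript/gene ratio in cohort")
  sdx <- stats::sd(x)
  if (targetR == 0) {
    slope <- 0
  } else if (abs(targetR) == 1) {
    slope <- sign(targetR)
  } else {
    if (sdx == 0)
      stop("bd ratio has zero variance; planted correlation infeasible")
    slope <- sign(targetR) * (noiseSd / sdx) *
      abs(targetR) / sqrt(1 - targetR^2)
  }
  y0 <- slope * x + noiseSd * eps
  yield <- y0 - min(y0) + baseYield
  samples <- data.frame(sample_id = ids, ecosystem = eco,
                        methane_yield = yield,
                        methane_units = "mL_CH4_per_gVS",
                        stringsAsFactors = FALSE)
  manifest <- list(seed = seed, n_samples = n,
                   n_per_archetype = nPerArchetype,
                   archetypes = vapply(archetypes, `[[`, character(1),
                                       "name"),
                   target_r = targetR, noise_sd = noiseSd,
                   base_yield = baseYield)
  list(catalog = catalog, counts = counts, samples = samples,
       manifest = manifest)
}
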