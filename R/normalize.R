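#' Length-normalized read count (reads per kilobase)
#'
#' @param count mapped reads.
#' @param lengthNt gene length in nucleotides, > 0.
#' @return `count / (lengthNt / 1000)`.
#' @examples
#' lengthNormalizedCount(33, 660)   # 50
#' @export
lengthNormalizedCount <- function(count, lengthNt) {
  if (any(!is.finite(lengthNt)) || any(lengthNt <= 0))
    stop("gene length must be positive")
  count / (lengthNt / 1000)
}

.countColumn <- function(which = c("metagenome", "metatranscriptome")) {
  paste0(match.arg(which, c("metagenome", "metatranscriptome")), "_count")
}

# joined catalog+counts records for one omic; count NA rows kept as NA
.joined <- function(catalog, counts) {
  cat <- catalogRecords(catalog)
  cnt <- countRecords(counts)
  m <- match(paste(cat$sample_id, cat$gene_id),
             paste(cnt$sample_id, cnt$gene_id))
  if (anyNA(m))
    stop("counts missing for catalog genes: ",
         paste(utils::head(cat$gene_id[is.na(m)], 5), collapse = ", "))
  cat$metagenome_count <- cnt$metagenome_count[m]
  cat$metatranscriptome_count <- cnt$metatranscriptome_count[m]
  cat
}

#' Per-sample housekeeping normalization baseline
#'
#' Mean of the length-normalized counts (reads per kilobase) over all copies
#' of the universal single-copy housekeeping genes rpoA, rpoB, rpoC and recA
#' present in the sample's catalog. This is the denominator that makes
#' relative abundances comparable across samples of different sequencing
#' depth.
#'
#' @param catalog a [GeneCatalog-class].
#' @param counts a [CountTable-class].
#' @param which `"metagenome"` or `"metatranscriptome"`.
#' @param sampleId optional subset of samples.
#' @return named numeric vector, one baseline per sample (RPK).
#' @export
housekeepingBaseline <- function(catalog, counts,
                                 which = "metagenome", sampleId = NULL) {
  col <- .countColumn(which)
  df <- .joined(catalog, counts)
  if (!is.null(sampleId)) df <- df[df$sample_id %in% sampleId, , drop = FALSE]
  hk <- df[df$category == "housekeeping", , drop = FALSE]
  samples <- unique(df$sample_id)
  out <- vapply(samples, function(s) {
    rows <- hk[hk$sample_id == s, , drop = FALSE]
    cnt <- rows[[col]]
    if (nrow(rows) == 0L || all(is.na(cnt)))
      stop("sample ", s, " has no housekeeping genes with ", which,
           " counts; normalization is undefined")
    rpk <- lengthNormalizedCount(cnt[!is.na(cnt)],
                                 rows$length_nt[!is.na(cnt)])
    b <- mean(rpk)
    if (b <= 0)
      stop("housekeeping baseline is zero for sample ", s,
           "; normalization is undefined")
    b
  }, numeric(1))
  stats::setNames(out, samples)
}

#' Per-gene relative abundances and transcript/gene ratios
#'
#' Divides each gene's length-normalized count by the same-omic housekeeping
#' baseline of its sample. Metagenome counts yield the normalized gene
#' abundance, metatranscriptome counts (normalized against the
#' metatranscriptome baseline) the normalized transcript abundance; their
#' ratio is the per-gene activity proxy. Samples without a metatranscriptome
#' get NA transcript columns; a zero gene abundance yields an NA ratio
#' (undefined, not zero).
#'
#' @param catalog a [GeneCatalog-class].
#' @param counts a [CountTable-class].
#' @param sampleId optional subset of samples.
#' @return data.frame: `sample_id`, `gene_id`, `symbol`, `category`,
#'   `taxon_family`, `normalized_gene_abundance`,
#'   `normalized_transcript_abundance`, `transcript_gene_ratio`.
#' @export
relativeAbundance <- function(catalog, counts, sampleId = NULL) {
  df <- .joined(catalog, counts)
  if (!is.null(sampleId)) df <- df[df$sample_id %in% sampleId, , drop = FALSE]
  gB <- housekeepingBaseline(catalog, counts, "metagenome",
                             unique(df$sample_id))
  df$normalized_gene_abundance <-
    lengthNormalizedCount(df$metagenome_count, df$length_nt) /
    gB[df$sample_id]
  df$normalized_transcript_abundance <- NA_real_
  hasMT <- tapply(!is.na(df$metatranscriptome_count), df$sample_id, any)
  mtSamples <- names(hasMT)[hasMT]
  if (length(mtSamples)) {
    tB <- housekeepingBaseline(catalog, counts, "metatranscriptome",
                               mtSamples)
    sel <- df$sample_id %in% mtSamples
    df$normalized_transcript_abundance[sel] <-
      lengthNormalizedCount(df$metatranscriptome_count[sel],
                            df$length_nt[sel]) / tB[df$sample_id[sel]]
  }
  df$transcript_gene_ratio <- transcriptGeneRatio(
    df$normalized_transcript_abundance, df$normalized_gene_abundance)
  out <- df[c("sample_id", "gene_id", "symbol", "category", "taxon_family",
              "normalized_gene_abundance", "normalized_transcript_abundance",
              "transcript_gene_ratio")]
  rownames(out) <- NULL
  out
}

#' Transcript-to-gene activity ratio
#'
#' @param transcriptAbundance normalized transcript abundance.
#' @param geneAbundance normalized gene abundance.
#' @return element-wise `transcriptAbundance / geneAbundance`; NA (undefined)
#'   where the gene abundance is zero or either input is missing.
#' @export
transcriptGeneRatio <- function(transcriptAbundance, geneAbundance) {
  out <- ifelse(!is.na(geneAbundance) & geneAbundance > 0,
                transcriptAbundance / geneAbundance, NA_real_)
  as.numeric(out)
}

# sum of per-gene relative abundances for a symbol set, per sample
.classSum <- function(ab, symbols) {
  sel <- ab[ab$symbol %in% symbols, , drop = FALSE]
  samples <- unique(ab$sample_id)
  gene <- vapply(samples, function(s)
    sum(sel$normalized_gene_abundance[sel$sample_id == s]), numeric(1))
  tx <- vapply(samples, function(s) {
    v <- sel$normalized_transcript_abundance[sel$sample_id == s]
    if (length(v) == 0L) 0 else if (all(is.na(v))) NA_real_ else
      sum(v, na.rm = TRUE)
  }, numeric(1))
  data.frame(sample_id = samples, gene_abundance = gene,
             transcript_abundance = tx,
             transcript_gene_ratio = transcriptGeneRatio(tx, gene),
             stringsAsFactors = FALSE)
}

#' Terminal-oxidase relative-abundance profile
#'
#' Per-sample relative metagenome abundance of each terminal-oxidase type
#' (gene copies summed per symbol), affinity-class subtotals, and the
#' nanaerobe indicator `bd_only` (TRUE iff every non-bd oxidase abundance is
#' zero). Samples with no oxidase signal at all additionally get
#' `no_oxidase = TRUE` (bd_only is then vacuous).
#'
#' @param catalog a [GeneCatalog-class].
#' @param counts a [CountTable-class].
#' @param sampleId optional subset of samples.
#' @return list with `profile` (data.frame sample_id, symbol, oxidase_type,
#'   affinity, bd_flag, abundance), `classTotals` (sample_id, affinity,
#'   abundance) and `flags` (sample_id, bd_only, no_oxidase,
#'   total_oxidase_abundance).
#' @export
oxidaseProfile <- function(catalog, counts, sampleId = NULL) {
  ont <- oxidaseOntology()
  ab <- relativeAbundance(catalog, counts, sampleId)
  samples <- unique(ab$sample_id)
  profile <- do.call(rbind, lapply(samples, function(s) {
    sub <- ab[ab$sample_id == s & ab$symbol %in% ont$symbol, , drop = FALSE]
    val <- vapply(ont$symbol, function(sym)
      sum(sub$normalized_gene_abundance[sub$symbol == sym]), numeric(1))
    data.frame(sample_id = s, ont, abundance = unname(val),
               stringsAsFactors = FALSE)
  }))
  rownames(profile) <- NULL
  classTotals <- do.call(rbind, lapply(split(profile, profile$sample_id),
    function(p) data.frame(sample_id = p$sample_id[1],
                           affinity = c("low", "high"),
                           abundance = c(sum(p$abundance[p$affinity == "low"]),
                                         sum(p$abundance[p$affinity == "high"])),
                           stringsAsFactors = FALSE)))
  rownames(classTotals) <- NULL
  flags <- do.call(rbind, lapply(split(profile, profile$sample_id),
    function(p) {
      total <- sum(p$abundance)
      nonBd <- sum(p$abundance[!p$bd_flag])
      data.frame(sample_id = p$sample_id[1],
                 bd_only = nonBd == 0,
                 no_oxidase = total == 0,
                 total_oxidase_abundance = total,
                 stringsAsFactors = FALSE)
    }))
  rownames(flags) <- NULL
  list(profile = profile, classTotals = classTotals, flags = flags)
}

#' Respiration vs fermentation pathway summary
#'
#' Per sample and pathway (nanaerobic respiration, anaerobic fermentation):
#' summed relative gene abundance, summed relative transcript abundance, and
#' the pathway-level transcript/gene ratio.
#'
#' @inheritParams oxidaseProfile
#' @return data.frame: `sample_id`, `pathway`, `gene_abundance`,
#'   `transcript_abundance`, `transcript_gene_ratio`.
#' @export
pathwaySummary <- function(catalog, counts, sampleId = NULL) {
  sets <- pathwayGeneSets()
  ab <- relativeAbundance(catalog, counts, sampleId)
  resp <- .classSum(ab, sets$respiration)
  ferm <- .classSum(ab, sets$fermentation)
  resp$pathway <- "nanaerobic_respiration"
  ferm$pathway <- "anaerobic_fermentation"
  out <- rbind(resp, ferm)
  out <- out[order(out$sample_id, out$pathway),
             c("sample_id", "pathway", "gene_abundance",
               "transcript_abundance", "transcript_gene_ratio")]
  rownames(out) <- NULL
  out
}

#' Cytochrome bd class summary per sample
#'
#' Summed relative abundance, expression and class-level transcript/gene
#' ratio over the cytochrome bd genes (cydA, appC, ythA) — the quantities
#' correlated with methane yield.
#'
#' @inheritParams oxidaseProfile
#' @return data.frame: `sample_id`, `gene_abundance`, `transcript_abundance`,
#'   `transcript_gene_ratio`.
#' @export
bdClassSummary <- function(catalog, counts, sampleId = NULL) {
  ont <- oxidaseOntology()
  ab <- relativeAbundance(catalog, counts, sampleId)
  out <- .classSum(ab, ont$symbol[ont$bd_flag])
  out[c("sample_id", "gene_abundance", "transcript_abundance",
        "transcript_gene_ratio")]
}

#' Family composition of cytochrome bd genes
#'
#' Relative frequency distribution of family-level taxonomy labels among the
#' bd-flagged (cydA/appC/ythA) genes of each sample. Frequencies sum to 1
#' per sample whenever any bd gene exists; samples without bd genes are
#' omitted (empty distribution).
#'
#' @param catalog a [GeneCatalog-class] with `taxon_family` labels on bd
#'   genes.
#' @param sampleId optional subset of samples.
#' @return data.frame: `sample_id`, `taxon_family`, `n_genes`, `frequency`.
#' @export
familySummary <- function(catalog, sampleId = NULL) {
  ont <- oxidaseOntology()
  df <- catalogRecords(catalog)
  if (!is.null(sampleId)) df <- df[df$sample_id %in% sampleId, , drop = FALSE]
  bd <- df[df$symbol %in% ont$symbol[ont$bd_flag], , drop = FALSE]
  if (nrow(bd) == 0L)
    return(data.frame(sample_id = character(), taxon_family = character(),
                      n_genes = integer(), frequency = numeric()))
  bd$taxon_family[is.na(bd$taxon_family)] <- "unclassified"
  out <- do.call(rbind, lapply(split(bd, bd$sample_id), function(p) {
    tab <- table(p$taxon_family)
    data.frame(sample_id = p$sample_id[1], taxon_family = names(tab),
               n_genes = as.integer(tab),
               frequency = as.numeric(tab) / sum(tab),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
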