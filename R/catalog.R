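#' Build a gene catalog from annotated records
#'
#' Assigns each record a functional category from the packaged ontology and
#' applies the catalog-level length filter: sequences shorter than 180 nt
#' are excluded (their count is retained in the object and reported by
#' `show`).
#'
#' @param records data.frame with columns `sample_id`, `gene_id`, `symbol`,
#'   `length_nt` and optionally `taxon_family` (NA allowed) and extra
#'   columns, which are preserved.
#' @param minLength catalog length filter, nt.
#' @return A [GeneCatalog-class].
#' @examples
#' geneCatalog(data.frame(sample_id = "s1", gene_id = "g1", symbol = "cydA",
#'                        length_nt = 1200))
#' @export
geneCatalog <- function(records, minLength = 180) {
  records <- as.data.frame(records)
  need <- c("sample_id", "gene_id", "symbol", "length_nt")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("catalog records need columns: ", paste(missing, collapse = ", "))
  if (!"taxon_family" %in% names(records))
    records$taxon_family <- NA_character_
  bad <- which(!is.finite(records$length_nt) | records$length_nt <= 0)
  if (length(bad))
    stop("invalid gene lengths at rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  short <- records$length_nt < minLength
  nDropped <- sum(short)
  if (nDropped > 0)
    message(nDropped, " record(s) shorter than ", minLength, " nt dropped")
  records <- records[!short, , drop = FALSE]
  records$category <- classifySymbol(records$symbol)
  front <- .CATALOG_COLS
  records <- records[c(front, setdiff(names(records), front))]
  rownames(records) <- NULL
  new("GeneCatalog", records = records, nDropped = as.integer(nDropped))
}

#' Read a gene catalog from TSV or Prokka-style GFF3
#'
#' The TSV format has columns `sample_id`, `gene_id`, `symbol`, `length_nt`,
#' `taxon_family` (empty allowed). The GFF3 reader (requires rtracklayer)
#' consumes CDS/gene features with a `gene` attribute carrying the symbol;
#' gene length is computed from the 1-based inclusive coordinates
#' (`end - start + 1`). An optional contig FASTA is accepted for provenance
#' but lengths come from the coordinates.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gff3"`.
#' @param sampleId sample identifier for GFF3 input (one assembly per file).
#' @param fasta optional contig FASTA path (GFF3 input only, unused for
#'   length computation).
#' @return A [GeneCatalog-class]; records below 180 nt are dropped with a
#'   message.
#' @export
readGeneCatalog <- function(path, format = c("tsv", "gff3"),
                            sampleId = NULL, fasta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    need <- c("sample_id", "gene_id", "symbol", "length_nt")
    missing <- setdiff(need, names(df))
    if (length(missing))
      stop("catalog TSV is missing columns: ",
           paste(missing, collapse = ", "))
    bad <- which(is.na(df$gene_id) | is.na(df$symbol) |
                   !is.finite(df$length_nt))
    if (length(bad))
      stop("malformed catalog rows at lines: ",
           paste(utils::head(bad + 1L, 10), collapse = ", "))
    return(geneCatalog(df))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  if (is.null(sampleId)) stop("sampleId is required for GFF3 input")
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type %in% c("CDS", "gene")]
  md <- as.data.frame(gr)
  sym <- if ("gene" %in% names(md)) md$gene else NA_character_
  if (all(is.na(sym)))
    stop("GFF3 features carry no 'gene' attribute with gene symbols")
  id <- if ("ID" %in% names(md) && !all(is.na(md$ID))) md$ID else
    paste0("gene_", seq_len(nrow(md)))
  df <- data.frame(sample_id = sampleId, gene_id = id,
                   symbol = ifelse(is.na(sym), "unknown", sym),
                   length_nt = md$end - md$start + 1,
                   taxon_family = NA_character_,
                   stringsAsFactors = FALSE)
  geneCatalog(df)
}

#' Read a mapped-read count table from TSV
#'
#' Columns: `sample_id`, `gene_id`, `metagenome_count`,
#' `metatranscriptome_count` (empty allowed for samples without a
#' metatranscriptome).
#'
#' @param path file path.
#' @param catalog optional [GeneCatalog-class] for key validation.
#' @return A [CountTable-class].
#' @export
readCountTable <- function(path, catalog = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("sample_id", "gene_id", "metagenome_count")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("count TSV is missing columns: ", paste(missing, collapse = ", "))
  bad <- which(is.na(df$metagenome_count))
  if (length(bad))
    stop("malformed count rows at lines: ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  countTable(df, catalog = catalog)
}
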