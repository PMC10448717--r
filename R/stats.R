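#' Pearson correlation with t-transform p-value
#'
#' Sample Pearson correlation with the two-sided p-value from the
#' t-distribution with n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#' @return list with `r`, `p_value`, `n`.
#' @examples
#' pearsonCorrelation(1:4, c(1, 2, 3, 5))
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Correlations between methane yield and cytochrome bd quantities
#'
#' Pearson correlations of per-sample methane yield against the cytochrome
#' bd class (cydA + appC + ythA) relative gene abundance, transcript
#' abundance (expression) and transcript/gene ratio. Correlations are
#' computed on untransformed values; no multiple-testing correction is
#' applied and the number of tests is reported.
#'
#' @param samples data.frame with columns `sample_id`, `methane_yield`
#'   (positive; any consistent unit) and optionally `ecosystem`.
#' @param bdSummary per-sample bd class summary, see [bdClassSummary()];
#'   alternatively pass `catalog` and `counts` to compute it.
#' @param catalog,counts optional [GeneCatalog-class] / [CountTable-class]
#'   used when `bdSummary` is missing.
#' @return data.frame with rows `abundance`, `expression`, `ratio`: columns
#'   `metric`, `r`, `p_value`, `n`, `n_tests`.
#' @export
methaneBdCorrelation <- function(samples, bdSummary = NULL,
                                 catalog = NULL, counts = NULL) {
  if (is.null(bdSummary)) {
    if (is.null(catalog) || is.null(counts))
      stop("supply either bdSummary or catalog + counts")
    bdSummary <- bdClassSummary(catalog, counts)
  }
  if (!all(c("sample_id", "methane_yield") %in% names(samples)))
    stop("samples must have sample_id and methane_yield columns")
  sm <- samples[!is.na(samples$methane_yield), , drop = FALSE]
  m <- match(sm$sample_id, bdSummary$sample_id)
  if (anyNA(m)) {
    miss <- sm$sample_id[is.na(m)]
    stop("no bd abundance for sample(s): ", paste(miss, collapse = ", "))
  }
  merged <- cbind(sm, bdSummary[m, setdiff(names(bdSummary), "sample_id"),
                                drop = FALSE])
  if (nrow(merged) < 3)
    stop("need at least 3 samples with methane yield and bd abundances; ",
         "have ", nrow(merged))
  metrics <- c(abundance = "gene_abundance",
               expression = "transcript_abundance",
               ratio = "transcript_gene_ratio")
  out <- do.call(rbind, lapply(names(metrics), function(nm) {
    v <- merged[[metrics[[nm]]]]
    ok <- !is.na(v)
    res <- pearsonCorrelation(v[ok], merged$methane_yield[ok])
    data.frame(metric = nm, r = res$r, p_value = res$p_value, n = res$n,
               stringsAsFactors = FALSE)
  }))
  out$n_tests <- nrow(out)
  rownames(out) <- NULL
  out
}

#' Two-group comparison by t-test
#'
#' Two-sided two-sample t-test, Welch (unequal-variance) by default with a
#' switch for the pooled-variance variant, flagging significance at
#' p < 0.05.
#'
#' @param group1,group2 numeric vectors, each of length >= 2.
#' @param varEqual use the pooled-variance t-test instead of Welch.
#' @param alpha significance level for the flag.
#' @return list with `t`, `p_value`, `significant`, `method`.
#' @examples
#' groupCompare(c(0, 0, 0.01), c(10, 11, 12))
#' @export
groupCompare <- function(group1, group2, varEqual = FALSE, alpha = 0.05) {
  group1 <- group1[is.finite(group1)]
  group2 <- group2[is.finite(group2)]
  if (length(group1) < 2 || length(group2) < 2)
    stop("each group needs at least 2 observations")
  tt <- stats::t.test(group1, group2, var.equal = varEqual)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < alpha, method = tt$method)
}
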