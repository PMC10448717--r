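cat <- toyCatalog()
cnt <- toyCounts()

test_that("length normalization is reads per kilobase", {
  expect_equal(lengthNormalizedCount(100, 1000), 100)
  expect_equal(lengthNormalizedCount(0, 777), 0)
  expect_equal(lengthNormalizedCount(33, 660), 50)
  expect_error(lengthNormalizedCount(5, 0), "positive")
})

test_that("housekeeping baseline is the mean RPK over present copies", {
  b <- housekeepingBaseline(cat, cnt, "metagenome")
  expect_equal(unname(b[c("s1", "s2")]), c(10, 10))
  expect_equal(unname(housekeepingBaseline(cat, cnt, "metatranscriptome",
                                           "s1")), 20)
  # mean over only the copies present
  two <- suppressMessages(geneCatalog(data.frame(
    sample_id = "x", gene_id = c("a", "b"), symbol = c("rpoA", "recA"),
    length_nt = c(1000, 1000))))
  twoCnt <- countTable(data.frame(sample_id = "x", gene_id = c("a", "b"),
                                  metagenome_count = c(2, 4)))
  expect_equal(unname(housekeepingBaseline(two, twoCnt)), 3)
  # no housekeeping genes is a hard error
  none <- suppressMessages(geneCatalog(data.frame(
    sample_id = "x", gene_id = "a", symbol = "cydA", length_nt = 1000)))
  noneCnt <- countTable(data.frame(sample_id = "x", gene_id = "a",
                                   metagenome_count = 5))
  expect_error(housekeepingBaseline(none, noneCnt), "housekeeping")
  expect_error(housekeepingBaseline(cat, cnt, "metatranscriptome", "s2"),
               "undefined")
})

test_that("relative abundances match hand-computed ratios on the fixture", {
  ab <- relativeAbundance(cat, cnt)
  s1 <- ab[ab$sample_id == "s1", ]
  pick <- function(sym, col) s1[[col]][s1$symbol == sym]
  # housekeeping self-normalization: single-copy equal-RPK genes sit at 1
  expect_equal(pick("rpoA", "normalized_gene_abundance"), 1)
  expect_equal(mean(s1$normalized_gene_abundance[s1$category ==
                                                   "housekeeping"]), 1)
  expect_equal(pick("cydA", "normalized_gene_abundance"), 2)    # 20 RPK / 10
  expect_equal(pick("cydA", "normalized_transcript_abundance"), 4)
  expect_equal(pick("cydA", "transcript_gene_ratio"), 2)
  expect_equal(pick("pflB", "transcript_gene_ratio"), 4)
  # zero gene abundance: ratio is an undefined marker, not 0
  expect_true(is.na(pick("hyp_1", "transcript_gene_ratio")))
  expect_equal(pick("hyp_1", "normalized_gene_abundance"), 0)
  # missing metatranscriptome: transcript columns are missing, not zero
  s2 <- ab[ab$sample_id == "s2", ]
  expect_true(all(is.na(s2$normalized_transcript_abundance)))
  expect_equal(s2$normalized_gene_abundance[s2$symbol == "cydA"], 3)
})

test_that("relative abundance is invariant to depth scaling and length doubling", {
  ab <- relativeAbundance(cat, cnt)
  scaled <- countRecords(cnt)
  scaled$metagenome_count <- scaled$metagenome_count * 7
  scaled$metatranscriptome_count <- scaled$metatranscriptome_count * 3
  ab2 <- relativeAbundance(cat, countTable(scaled))
  expect_equal(ab2$normalized_gene_abundance, ab$normalized_gene_abundance)
  expect_equal(ab2$normalized_transcript_abundance,
               ab$normalized_transcript_abundance)
  # doubling one gene's length and count changes nothing
  rec <- catalogRecords(cat); cr <- countRecords(cnt)
  i <- which(rec$symbol == "cydA" & rec$sample_id == "s1")
  rec$length_nt[i] <- rec$length_nt[i] * 2
  j <- which(cr$gene_id == rec$gene_id[i])
  cr$metagenome_count[j] <- cr$metagenome_count[j] * 2
  cr$metatranscriptome_count[j] <- cr$metatranscriptome_count[j] * 2
  ab3 <- relativeAbundance(suppressMessages(geneCatalog(rec)),
                           countTable(cr))
  expect_equal(ab3$normalized_gene_abundance[ab3$gene_id == rec$gene_id[i]],
               ab$normalized_gene_abundance[ab$gene_id == rec$gene_id[i]])
})

test_that("oxidase profile sums copies, subtotals add up, bd_only flags", {
  prof <- oxidaseProfile(cat, cnt)
  p1 <- prof$profile[prof$profile$sample_id == "s1", ]
  expect_equal(p1$abundance[p1$symbol == "cydA"], 2)
  expect_equal(p1$abundance[p1$symbol == "ctaD"], 0.2)
  ct1 <- prof$classTotals[prof$classTotals$sample_id == "s1", ]
  expect_equal(ct1$abundance[ct1$affinity == "high"],
               sum(p1$abundance[p1$affinity == "high"]))
  expect_equal(ct1$abundance[ct1$affinity == "low"], 0.2)
  f <- prof$flags
  expect_false(f$bd_only[f$sample_id == "s1"])   # ctaD has signal
  expect_true(f$bd_only[f$sample_id == "s2"])    # cydA only
  expect_false(any(f$no_oxidase))
  # degenerate input: no oxidase genes at all
  hkOnly <- suppressMessages(geneCatalog(data.frame(
    sample_id = "x", gene_id = paste0("g", 1:4),
    symbol = housekeepingGenes(), length_nt = 1000)))
  hkCnt <- countTable(data.frame(sample_id = "x", gene_id = paste0("g", 1:4),
                                 metagenome_count = 10))
  f0 <- oxidaseProfile(hkOnly, hkCnt)$flags
  expect_true(f0$no_oxidase); expect_true(f0$bd_only)
  expect_equal(f0$total_oxidase_abundance, 0)
})

test_that("multi-copy symbols are summed per oxidase type", {
  rec <- rbind(catalogRecords(cat),
               data.frame(sample_id = "s1", gene_id = "s1_gX",
                          symbol = "cydA", length_nt = 1000,
                          taxon_family = "Prevotellaceae", category = "oxidase"))
  cr <- rbind(countRecords(cnt),
              data.frame(sample_id = "s1", gene_id = "s1_gX",
                         metagenome_count = 5,
                         metatranscriptome_count = NA))
  prof <- oxidaseProfile(suppressMessages(geneCatalog(rec)), countTable(cr))
  p1 <- prof$profile[prof$profile$sample_id == "s1", ]
  expect_equal(p1$abundance[p1$symbol == "cydA"], 2 + 0.5)
})

test_that("pathway summary equals brute-force aggregation of per-gene rows", {
  ps <- pathwaySummary(cat, cnt, sampleId = "s1")
  ab <- relativeAbundance(cat, cnt, sampleId = "s1")
  sets <- pathwayGeneSets()
  map <- c(nanaerobic_respiration = "respiration",
           anaerobic_fermentation = "fermentation")
  for (pwName in names(map)) {
    row <- ps[ps$pathway == pwName, ]
    sel <- ab[ab$symbol %in% sets[[map[[pwName]]]], ]
    expect_equal(row$gene_abundance, sum(sel$normalized_gene_abundance))
    expect_equal(row$transcript_abundance,
                 sum(sel$normalized_transcript_abundance))
  }
  # hand values: respiration genes in s1 are cydA, appC, poxB
  resp <- ps[ps$pathway == "nanaerobic_respiration", ]
  expect_equal(resp$gene_abundance, 2 + 0.5 + 1)
  expect_equal(resp$transcript_abundance, 4 + 0.5 + 1)
  ferm <- ps[ps$pathway == "anaerobic_fermentation", ]
  expect_equal(ferm$transcript_gene_ratio, 4)
  # a sample with zero counts for all fermentation genes reports 0
  expect_equal(pathwaySummary(cat, cnt, "s2")$gene_abundance[
    pathwaySummary(cat, cnt, "s2")$pathway == "anaerobic_fermentation"], 0)
})

test_that("bd class summary aggregates cydA+appC+ythA", {
  bd <- bdClassSummary(cat, cnt, "s1")
  expect_equal(bd$gene_abundance, 2.5)
  expect_equal(bd$transcript_abundance, 4.5)
  expect_equal(bd$transcript_gene_ratio, 4.5 / 2.5)
})

test_that("family summary is a proper frequency distribution over bd genes", {
  fs <- familySummary(cat)
  s1 <- fs[fs$sample_id == "s1", ]
  expect_equal(sort(s1$frequency), c(0.5, 0.5))
  expect_equal(sum(s1$frequency), 1, tolerance = 1e-12)
  expect_equal(fs$frequency[fs$sample_id == "s2"], 1)   # all Prevotellaceae
  # no bd genes: empty distribution
  hkOnly <- suppressMessages(geneCatalog(data.frame(
    sample_id = "x", gene_id = "g1", symbol = "rpoA", length_nt = 1000)))
  expect_equal(nrow(familySummary(hkOnly)), 0)
  # 3:1 labels give 0.75 / 0.25
  four <- suppressMessages(geneCatalog(data.frame(
    sample_id = "x", gene_id = paste0("g", 1:4), symbol = "cydA",
    length_nt = 1000,
    taxon_family = c(rep("Prevotellaceae", 3), "Selenomonadaceae"))))
  f4 <- familySummary(four)
  expect_equal(f4$frequency[f4$taxon_family == "Prevotellaceae"], 0.75)
})
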