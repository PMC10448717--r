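# Hand-built two-sample fixture with arithmetically transparent counts.
# Sample s1: housekeeping baseline 10 RPK (metagenome) / 20 RPK
# (metatranscriptome); s2 has no metatranscriptome.
toyCatalog <- function() {
  suppressMessages(geneCatalog(data.frame(
    sample_id = c(rep("s1", 10), rep("s2", 5)),
    gene_id = c(paste0("s1_g", 1:10), paste0("s2_g", 1:5)),
    symbol = c("rpoA", "rpoB", "rpoC", "recA", "cydA", "appC", "ctaD",
               "pflB", "poxB", "hyp_1",
               "rpoA", "rpoB", "rpoC", "recA", "cydA"),
    length_nt = c(1000, 2000, 500, 1000, 500, 1000, 1000, 1000, 1000, 250,
                  rep(1000, 5)),
    taxon_family = c(rep(NA, 4), "Prevotellaceae", "Selenomonadaceae",
                     rep(NA, 4), rep(NA, 4), "Prevotellaceae"),
    stringsAsFactors = FALSE)))
}

toyCounts <- function() {
  countTable(data.frame(
    sample_id = c(rep("s1", 10), rep("s2", 5)),
    gene_id = c(paste0("s1_g", 1:10), paste0("s2_g", 1:5)),
    metagenome_count = c(10, 20, 5, 10, 10, 5, 2, 10, 10, 0,
                         10, 10, 10, 10, 30),
    metatranscriptome_count = c(20, 40, 10, 20, 40, 10, 0, 80, 20, 0,
                                rep(NA, 5)),
    stringsAsFactors = FALSE))
}

# independent single-expression free-energy oracle used across thermo tests
bruteForceDeltaG <- function(reaction, condition,
                             st = thermoSpeciesTable()) {
  s <- reaction@stoichiometry
  i <- match(names(s), st$name)
  act <- mapply(function(nm, ph) switch(ph,
      gas = condition@partialPressures[[nm]],
      aqueous = condition@concentrations[[nm]],
      proton = 10^(-condition@pH), `liquid-water` = 1),
    names(s), st$phase[i])
  tA <- condition@temperature
  dg0 <- sum(s * st$gf0_kj_mol[i])
  dh0 <- sum(s * st$hf0_kj_mol[i])
  dg0 * tA / 298.15 + dh0 * (298.15 - tA) / 298.15 +
    8.314e-3 * tA * log(prod(act^s))
}

randomCondition <- function() {
  conditionSet(
    temperature = runif(1, 280, 330),
    partialPressures = c(CH4 = 10^runif(1, -4, 0), CO2 = 10^runif(1, -4, 0),
                         H2 = 10^runif(1, -8, 0), O2 = 10^runif(1, -9, -2)),
    concentrations = c(acetate = 10^runif(1, -4, 0)),
    pH = runif(1, 5, 8))
}
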