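---
title: "Methods: bioenergetics and meta-omic profiling of nanaerobic digestion"
author: "nanaerobics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bioenergetics and meta-omic profiling of nanaerobic digestion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanaerobics)
```

## Scientific setting

Methanogenic ecosystems have long been treated as strictly anaerobic, yet
rumina and micro-oxygenated digesters harbour *nanaerobes*: bacteria whose
sole terminal oxidase is the high-oxygen-affinity cytochrome *bd* type
(genes *cydA*, *appC* and the putative *ythA*), able to respire at nanomolar
dissolved oxygen but not viable above roughly 2 µM. This package provides
the two quantitative pillars needed to evaluate that picture: a
bioenergetics engine for the competing acetate-to-methane routes, and a
normalization/statistics workflow for terminal-oxidase genes and transcripts
in metagenome and metatranscriptome count data.

## The free-energy model

Every free energy is evaluated in three steps.

1. **Standard free energy.** For a reaction with signed stoichiometric
   coefficients $\nu_i$ (products positive),
   $\Delta G^0 = \sum_i \nu_i\, G^0_{f,i}$ at 298.15 K. The packaged
   formation constants (`thermoSpeciesTable()`) come from the classical
   biochemical compilation of Thauer, Jungermann & Decker (1977) with
   CODATA-consistent enthalpies: acetate⁻ (aq) $G^0_f$ = −369.41,
   $H^0_f$ = −486.01; CH₄ (g) −50.75 / −74.81; CO₂ (g) −394.359 / −393.509;
   H₂O (l) −237.178 / −285.83 kJ/mol; H₂, O₂ and H⁺ are zero by convention.
2. **Temperature.** $\Delta G_{T_2} = \Delta G_{T_1} \frac{T_2}{T_1} +
   \Delta H_{T_1}\frac{T_1 - T_2}{T_1}$ (Gibbs–Helmholtz with
   temperature-independent $\Delta H$ — adequate over the 298→308 K span of
   mesophilic digestion; see Limitations).
3. **Activities.** $\Delta G = \Delta G^0_T + RT \ln Q$ with
   $R = 8.314\,\mathrm{J\,K^{-1}\,mol^{-1}}$. Conventions: gases as partial
   pressure in atm against a 1 atm standard state; solutes in mol/L against
   1 M; proton activity $10^{-\mathrm{pH}}$; liquid water at unit activity.
   CO₂ is treated as a gas-phase species throughout — no carbonate
   speciation — which is the convention under which the packaged pathway
   table reproduces the published standard columns.

The `ReactionSpec` representation stores products-minus-reactants signed
coefficients, so composition (`composeReactions()`) is a plain species-wise
sum and free energies are exactly additive; the acetoclastic reaction is the
stoichiometric sum R3 + ½R2, which the tests use as an internal-consistency
check of the constant table.

### Thresholds and the constraint grid

For a gas species with coefficient $\nu$, $\Delta G(p) = \Delta G_{p=1} +
RT\,\nu \ln p$ is affine in $\ln p$, so the $\Delta G = 0$ threshold has the
closed form $p^* = \exp(-\Delta G_{p=1} / (RT\nu))$. A bisection fallback
over the log-space bracket $[10^{-12}, 10^{2}]$ atm is kept as an
independent cross-check (the two agree to 1e-10 relative in the tests).

`constraintGrid()` evaluates R1–R4 and both composites over a
log₁₀ pH₂ ∈ [−8, 0] × log₁₀ pCO₂ ∈ [−4, 0] grid under the base conditions
35 °C, pH 6.5, CH₄ at 0.5 atm, O₂ at 10⁻⁸ atm, acetate at 20 mM and 1 atm
total pressure. Two couplings are marked per cell: the *syntrophic window*
(R3 and R2 both exergonic) and the *nanaerobic region* (R4 and R2 both
exergonic). Because complete acetate oxidation is overwhelmingly exergonic
even at 10⁻⁸ atm O₂, the nanaerobic region strictly contains the syntrophic
window wherever the latter exists.

A design note on the window geometry: the upper H₂ bound (from R3 = 0)
decreases and the lower bound (from R2 = 0) increases with pCO₂, each
sweeping across the 10⁻⁵–10⁻⁴ atm band within the plotted pCO₂ range, but
no single pCO₂ places both bounds inside that band simultaneously (at
pCO₂ = 0.3 atm the window is ≈ 5×10⁻⁶ to 1.6×10⁻⁴ atm). The packaged checks
therefore assert the per-bound crossing of the band together with window
non-emptiness and region containment, which is the reading of the
"10⁻⁵–10⁻⁴ atm window" description that the thermodynamics supports.

`doFromAtmosphericFraction()` converts a fraction of atmospheric O₂
(0.21 atm) to dissolved O₂ with a Henry constant of 1.26 mmol L⁻¹ atm⁻¹ at
25 °C (Sander's compilation); 1 % of air gives ≈ 2.6 µM, the scale of the
nanaerobe viability ceiling. Temperature dependence of the constant is out
of scope.

## Count normalization

Mapped-read counts are normalized in two stages: reads per kilobase
(`count / (length_nt/1000)`), then division by the per-sample, per-omic
*housekeeping baseline* — the mean RPK over all copies of the universal
single-copy genes *rpoA*, *rpoB*, *rpoC*, *recA* present in the sample's
catalog. Design choices, each forced by the requirement that ratios be
comparable across samples of different depth:

- Housekeeping genes are length-normalized identically to target genes
  before averaging, making the ratio unit-free and exactly invariant to
  depth rescaling and to doubling a gene's length together with its count
  (both are asserted as exact tests).
- Transcript abundances are normalized against the *metatranscriptome*
  housekeeping baseline, never the metagenome one, since the two read sets
  are mapped independently.
- Multi-copy symbols are summed per oxidase type; multi-subunit operons
  (pdhABCD, nuoA–N) appear as per-ORF records and pathway summaries sum the
  subunits.
- A sample without a metatranscriptome gets missing transcript columns, not
  zeros; a zero housekeeping baseline is a hard error; a zero gene
  abundance makes the transcript/gene ratio undefined (NA), not zero.
- Catalog records shorter than 180 nt are excluded at import, with the
  dropped count retained on the object.

The oxidase ontology is fixed: low-affinity *coxN*, *cyoB*, *qoxB*, *ctaD*;
high-affinity *cbaA*, *fixN*, *ccoN* plus the cytochrome *bd* types *cydA*,
*appC*, *ythA*. A sample is flagged `bd_only` when every non-*bd* oxidase
abundance is zero (with a separate `no_oxidase` flag for the vacuous case).

## Statistics

Pearson correlations use the exact *t*-transform p-value with $n-2$ degrees
of freedom and require $n \ge 3$ non-constant vectors; correlations are
computed on untransformed values. Group comparisons default to the Welch
unequal-variance *t*-test (ecosystem groups differ in size and spread) with
a switch for the pooled-variance variant; significance is flagged at
p < 0.05. No multiple-testing correction is applied; instead the number of
tests performed is reported alongside every correlation table.

## The synthetic-data generator

The generator emulates what the analysis consumes — per-sample annotated
gene catalogs with mapped-read counts — not reads, assemblies or annotation
errors. Archetypes encode the qualitative ecosystem structure as expected
complements: rumen archetypes carry only *bd*-type oxidases, the oil
reservoir has the minimal oxidase signal, lab-scale complements exceed
full-scale ones. Defaults, chosen once as realistic desk-scale settings:

- **Counts**: negative binomial, dispersion 0.3 (a typical between-sample
  overdispersion for mapped-read counts; dispersion 0 selects Poisson),
  depth 3×10⁵ mapped reads per omic, gene lengths uniform on [300, 3000] nt.
  Expected counts are proportional to rate × length so that length
  normalization is genuinely exercised.
- **Catalog**: exactly one copy of each housekeeping gene (rate 1, the
  normalization anchor), one gene per oxidase symbol at its expected
  relative abundance, the respiration/fermentation pathway genes (gene
  rates 0.6/0.8; transcript multipliers 1 vs 4, planting the higher
  fermentation expression seen in rumen data), and 200 background genes
  with lognormal rates.
- **Cohorts**: a per-sample lognormal factor (sdlog 0.5) on the *bd*
  transcript rate spreads transcript/gene ratios; methane yields are an
  affine function of the *realized* ratio plus Gaussian noise, the slope
  calibrated so the population correlation equals `targetR`
  ($\beta = (\sigma/s_x)\, r/\sqrt{1-r^2}$). Building on the realized
  rather than expected ratio makes correlation recovery a true end-to-end
  test of normalization plus statistics. Infeasible combinations
  (|r| = 1 with noise, |r| < 1 without noise) raise errors.

Determinism: every public generator call seeds R's default RNG from its
`seed` argument, and cohort-level sub-seeds are drawn up front, so equal
seeds give byte-identical catalogs, counts and yields.

What passing tests do **not** show about real data: the generator has no
annotation error, no chimeras or frameshifts, no phylogenetic signal in
family labels, no compositional coupling between samples, and its
housekeeping genes are exactly single-copy — real catalogs violate all of
these to some degree, so recovery rates here bound the method's behaviour
under its own assumptions only.

## Problem sizes and runtimes

The packaged checks use a 120×120 constraint grid (14,400 cells × 6
reactions), 100 randomized conditions for oracle equivalence at 1e-9 kJ,
200 four-sample cohorts for planted-correlation recovery (median recovered
r ≥ 0.95 for a planted 0.99), 1,000 null cohorts for p-value calibration
(expected 5 % ± 2 % at the 0.05 level), and 200 cohorts of 14 samples per
ecosystem for the lab- vs full-scale comparison — a group size set by a
power analysis at the default dispersion (class-total CV ≈ 0.45, effect
d ≈ 1.7 gives ≈ 90 % Welch power near n = 14).

## Limitations

- No carbonate/ammonia speciation, ionic-strength or activity-coefficient
  corrections, or fugacity corrections; ΔH is treated as
  temperature-independent, so temperature corrections degrade away from the
  298–313 K range.
- Condition-specific free-energy columns depend entirely on the
  user-supplied condition sets; the package asserts no reference values for
  them.
- The normalization assumes the four housekeeping genes are present and
  single-copy per genome on average; heavily incomplete catalogs bias the
  baseline.
- Family summaries describe pre-annotated labels; no taxonomy is inferred.
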