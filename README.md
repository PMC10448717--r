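# nanaerobics

Tools for evaluating **nanaerobic digestion** — methanogenic systems (animal
rumina, micro-oxygenated anaerobic digesters) in which bacteria carrying only
the high-oxygen-affinity cytochrome *bd* oxidase ("nanaerobes") respire at
nanomolar dissolved oxygen alongside active methanogens.

The package is aimed at environmental microbiologists and anaerobic-digestion
engineers who want to (i) compare the bioenergetics of the possible
acetate-to-methane routes under realistic digester conditions and (ii) profile
terminal-oxidase genes and transcripts in metagenome/metatranscriptome count
data with housekeeping-gene normalization.

## What it computes

**Bioenergetics.** Gibbs free energies of the three acetate-to-methane
pathways, built from four reactions:

| id | reaction | role |
|----|----------|------|
| R1 | CH₃COO⁻ + H⁺ → CH₄ + CO₂ | acetoclastic methanogenesis |
| R2 | 8H₂ + 2CO₂ → 2CH₄ + 4H₂O | hydrogenotrophic methanogenesis |
| R3 | CH₃COO⁻ + H⁺ + 2H₂O → 4H₂ + 2CO₂ | syntrophic acetate oxidation |
| R4 | CH₃COO⁻ + H⁺ + 2O₂ → 2H₂O + 2CO₂ | complete (nanaerobic) acetate oxidation |

The evaluation is the standard three-step scheme: ΔG⁰ = Σ G⁰f(products) −
Σ G⁰f(reactants) from a packaged formation-constant table; temperature
correction by the Gibbs–Helmholtz relation ΔG(T₂) = ΔG(T₁)·T₂/T₁ +
ΔH·(T₁ − T₂)/T₁; and the activity correction ΔG = ΔG⁰(T) + RT ln Q with
gases in atm, solutes in mol/L, proton activity 10^(−pH) and water at unit
activity. Thresholds are found by setting ΔG = 0 and solving for one partial
pressure in closed form; `constraintGrid()` maps the feasibility regions of
all routes over the (pH₂, pCO₂) plane.

**Omics profiling.** Per-gene relative abundance = (reads per kilobase) /
(mean reads per kilobase of the universal single-copy genes *rpoA*, *rpoB*,
*rpoC*, *recA*), computed separately for metagenome and metatranscriptome
reads; oxidase-type and pathway-level summaries; transcript/gene activity
ratios; family composition of cytochrome *bd* genes; Pearson correlations of
methane yield against cytochrome *bd* abundance, expression and
transcript/gene ratio; Welch *t*-tests between ecosystem groups.

**Synthetic cohorts.** A negative-binomial generator produces annotated gene
catalogs and counts for ecosystem archetypes (rumen = *bd*-only oxidase
complement, oil reservoir = minimal oxidase signal, lab- vs full-scale
digesters) and plants a configurable methane–*bd* correlation, so the whole
pipeline is testable end to end without sequence downloads.

## Worked example

```r
library(nanaerobics)

pathwayTable()[, c("pathway", "reaction_id", "dg298_kj", "dg308_kj")]
#>   pathway reaction_id dg298_kj dg308_kj
#> 1       I          R1   -75.70   -78.83
#> 2      II          R3    55.05    47.82
#> 3      II          R2  -261.49  -253.30
#> 4      II         3+2  -206.45  -205.48
#> 5     III          R4  -893.66  -894.37
#> 6     III          R2  -261.49  -253.30
#> 7     III         4+2 -1155.16 -1147.66
```

At standard conditions acetoclastic methanogenesis (R1) releases −75.7
kJ/reaction, syntrophic acetate oxidation (R3) alone is endergonic (+55.0 kJ)
and only proceeds coupled to CO₂ reduction (3+2, −206.4 kJ), while the
nanaerobic route (4+2) is by far the most exergonic (−1155.2 kJ). The third
and fourth columns show the same quantities at 35 °C.

```r
g <- constraintGrid()            # 35 °C, pH 6.5, 0.5 atm CH4, 1e-8 atm O2, 20 mM acetate
w <- g$window
i <- which.min(abs(10^w$log10_pco2 - 0.3))
c(lower = w$h2_lower_atm[i], upper = w$h2_upper_atm[i])
#>        lower        upper
#> 4.918875e-06 1.558077e-04
```

The syntrophic window — H₂ pressures where acetate oxidation and CO₂
reduction are simultaneously exergonic — spans only about 1.5 orders of
magnitude around 10⁻⁵–10⁻⁴ atm, while the nanaerobic coupling is feasible in
a strictly larger region of the grid.

```r
co <- generateCohort(digesterArchetypes()$rumen_sheep, nPerArchetype = 4,
                     targetR = 0.99, noiseSd = 1, seed = 1)
methaneBdCorrelation(co$samples, catalog = co$catalog, counts = co$counts)
#>       metric      r p_value n n_tests
#> 1  abundance -0.733  0.2672 4       3
#> 2 expression  0.473  0.5273 4       3
#> 3      ratio  0.988  0.0118 4       3
```

A four-sample sheep-rumen cohort generated with a planted correlation of
0.99 between methane yield and the cytochrome *bd* transcript/gene ratio
recovers r = 0.988 (p < 0.05) on that ratio; abundance and expression alone
are noisier, as expected when only the ratio is planted.

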