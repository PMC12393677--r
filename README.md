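# lbptrial

Statistical analysis of randomized trials of a vaginal live biotherapeutic
product (LBP) containing *Lactobacillus crispatus* CTV-05, given after
metronidazole (MTZ) treatment for bacterial vaginosis (BV). The package
implements, as tested and reusable functions, the bespoke statistical
machinery such a trial needs, and ships a synthetic cohort generator so the
entire pipeline can be exercised, validated and benchmarked without access
to participant-level trial data.

## What the package computes

**Constrained microbiome topic model.** *Lactobacillus* topics are defined
independently of non-*Lactobacillus* topics: any *Lactobacillus* species
that reaches ≥50% relative abundance in at least 10 samples becomes its own
pure topic, the remaining species pool into one "Other L." topic, and a
latent Dirichlet allocation (LDA) model is fitted by variational Bayes to
the non-*Lactobacillus* species counts alone. With π̂<sub>ki</sub> the
LDA topic proportions within the non-*Lactobacillus* fraction and
Π̂<sub>i</sub> the total non-*Lactobacillus* proportion of sample *i*, the
whole-community topic proportions are p̂<sub>ki</sub> = π̂<sub>ki</sub>·Π̂<sub>i</sub>,
so that *Lactobacillus* topic proportions plus rescaled non-*Lactobacillus*
topic proportions sum to 1 in every sample. The number of topics K is
chosen by aligning models across a grid of resolutions: a topic is spurious
when it is transient (it does not reappear at the next resolution) or
redundant (its species profile shadows a sibling topic), and the selected
K is the smallest resolution with no spurious topic whose successor
introduces one.

**Cytokine size-effect adjustment.** Mucosal cytokine panels carry a "size
effect": the amount of material on a swab inflates all analyte
concentrations jointly, so PC1 of the standardized log10 concentrations
reflects biomass rather than biology. After imputing censored values
(below-LLOQ at LLOQ/2, above-ULOQ at the ULOQ) and excluding analytes
censored low in ≥60% or high in ≥30% of samples, the PC1 scores are set to
zero and the data are rotated back — `pc1_subtract()` — before computing
per-participant baseline deltas.

**Association machinery.** RV coefficient between the topic table and the
cytokine table with an add-one permutation test; PERMANOVA (via vegan) for
arm balance; DiSTATIS to build a compromise of the Bray-Curtis microbiota
dissimilarity and the Euclidean cytokine dissimilarity, with correlation
circles for the original variables.

**Treatment effects.** Benefit ratios (risk ratios of a favorable outcome)
with Wald log-scale confidence intervals, Wilson score intervals for
stratum rates, Newcombe rate-difference intervals, heterogeneity-of-effect
tests comparing nested logistic models with an analysis-of-deviance F test
(BH-corrected across outcomes), and counterfactual per-participant
predicted probabilities and odds ratios.

**Strain dynamics.** Classification of samples with ≥5% *L. crispatus*
into >90% CTV-05 ("High"), 10–90% ("Mixed", boundaries inclusive) and
<10% ("Low") categories, transition tables across consecutive scheduled
visits, and histograms of distinct native strains per participant.

**Multiblock PLS-DA.** Super-block NIPALS with thematic predictor blocks,
one-hot encoding with sparse-level jitter, PLS residualization of
correlated blocks, 40× stratified 75/25 cross-validation selecting the
component count by macro-F1, relative cumulative block importance
(1 = importance proportional to block size), and bootstrap percentile
intervals.

## Worked example

```r
library(lbptrial)

# a 2:1-randomized synthetic cohort: 60 participants, 6 scheduled visits
co <- generate_cohort(cohort_config(n_participants = 60, seed = 1))

prop <- relative_abundance(co$counts)
cats <- classify_colonization(prop, co$taxonomy)
table(cats[co$metadata$visit == "wk12"], co$metadata$arm[co$metadata$visit == "wk12"])
#>                   LBP placebo
#>   LC_DOM            8       3
#>   OTHER_LACTO_DOM  12       8
#>   NON_LACTO_DOM   13       8

# benefit ratio at the primary endpoint on the printed trial counts
benefit_ratio(37, 123, 5, 56)
#>      ratio   ci_low  ci_high     p_value method
#> 1 3.369106 1.399128 8.112819 0.001958976   wald
```

The ratio 3.37 (95% CI 1.40–8.11) says LBP recipients were 3.4 times as
likely as placebo recipients to have an *L. crispatus*-dominant microbiota
at week 12; the chi-square p-value (< 0.005) rejects equal rates.

The numbered scripts under `analysis/` run the full workflow on a larger
simulated cohort — `01_simulate.R` through `08_mbplsda.R` — each writing
its tables under `results/` and printing a short narrative of what it
found (selected K and alignment diagnostics, PC1 variance share, RV and
per-visit RVs, heterogeneity F tests, strain transition proportions, block
importance with bootstrap CIs).

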