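---
title: "Models and design choices in lbptrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in lbptrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `lbptrial`, the
parameters that matter, what the synthetic cohort generator does and does
not emulate, and the numerical and design choices made where the methods
left genuine latitude.

## The setting

A randomized trial gives women with bacterial vaginosis (BV) a course of
metronidazole (MTZ) and then randomizes them 2:1 to a vaginally applied
live biotherapeutic product (LBP) containing *Lactobacillus crispatus*
CTV-05, or placebo. Samples are collected at six scheduled visits (preMTZ,
postMTZ, weeks 4, 8, 12, 24): 16S species-level count tables, a Luminex
cytokine panel, vaginal pH and total bacterial load, and — for samples
with enough *L. crispatus* — metagenomic strain-proportion estimates
separating CTV-05 from a participant's native strains. The scientific
questions are whether the LBP establishes *L. crispatus* dominance,
how the microbiota and mucosal immune markers covary, for whom the
intervention works, and whether the probiotic strain persists or is
replaced by native strains.

## Constrained topic model

Vaginal communities are dominated by a handful of *Lactobacillus* species;
a vanilla LDA fit mixes those with the anaerobe consortia and produces
topics that are hard to read. The model here constrains the topic space:

* any *Lactobacillus* species reaching ≥ 50% relative abundance in ≥ 10
  samples is its own pure topic (thresholds inclusive, a plain reading of
  "at least"); the remaining *Lactobacillus* species pool into an
  "Other L." topic whose composition is their mean relative abundance
  across the cohort (renormalized) — "average prevalence" is ambiguous
  between prevalence and abundance and the mean-abundance reading keeps
  the topic a proper distribution;
* LDA is fitted only to the non-*Lactobacillus* counts, and its topic
  proportions π̂ are rescaled by the sample's total non-*Lactobacillus*
  proportion Π̂: p̂ = π̂ · Π̂. Samples with zero non-*Lactobacillus* reads
  are excluded from the likelihood (π̂ undefined) and get all-zero p̂,
  consistent with Π̂ = 0.

The LDA engine is batch variational Bayes with symmetric Dirichlet priors
(α = 1/K on sample-topic proportions, η = 0.1 on topics), mean-field E
steps run to a 10⁻³ mean-change tolerance, a relative-bound convergence
tolerance of 10⁻⁶ and at most 500 sweeps. The variational bound is
monotone over sweeps and is used both for convergence and for selecting
among random restarts: LDA posteriors at this scale have local optima, so
every fit runs `n_starts` restarts (4 by default, 8 across a K grid,
where over-resolved fits are most fragile) and keeps the best bound.

### Choosing K by topic alignment

Models are fitted across a grid of resolutions (K = 2 … 7 by default) and
aligned pairwise between consecutive K. The alignment weight of a topic
pair is the sample-summed product of their topic proportions, normalized
over all pairs (the "product" scheme); path membership is built by greedy
maximum-weight matching, with a duplicate-attachment rule (cosine ≥ 0.85
joins an existing path) and a link floor (cosine < 0.3 breaks a
continuation).

Two diagnostics flag a topic as spurious:

* **transience** — its sample-proportion vector has best cosine < 0.6 to
  every topic of the next resolution: the subcommunity does not reappear
  when the model is refitted with one more topic;
* **redundancy** — its species profile has cosine ≥ 0.7 to a sibling topic
  of the same model: the extra resolution split or duplicated an existing
  subcommunity rather than discovering a new one.

The selected K is the smallest resolution with no spurious topic whose
successor introduces at least one — the point where the number of genuine
topic lineages plateaus. The two flags capture complementary failure
modes of over-resolved models (unstable blends versus stable splits), and
their thresholds sit in the middle of the gap observed across simulated
cohorts: topics of models at or below the true K persist with cosine
≥ 0.84 and have within-model profile cosine ≤ 0.39, while every
over-resolved model contained a topic failing at least one flag. We chose
the one-step persistence statistic over a min-along-the-whole-path
coherence because the latter punishes a genuine topic for degradation
happening three resolutions away. If no resolution satisfies both rules
the selector falls back to the K minimizing the spurious-topic count, with
a warning.

## Cytokine preprocessing

Concentrations are log10-transformed after imputing censored entries:
below the lower limit of quantification (LLOQ) at LLOQ/2, above the upper
limit at the ULOQ. Analytes censored low in ≥ 60% of samples or high in
≥ 30% (both inclusive) are excluded before any multivariate step.

Swab sampling introduces a **size effect**: swabs that collect more
material yield proportionally higher concentrations for every analyte, so
the first principal component of the standardized log panel reflects
biomass. `pc1_subtract()` standardizes columns, zeroes the PC1 scores,
back-transforms with the transposed rotation matrix, and de-standardizes,
returning values on the log scale so baseline deltas remain interpretable
in log10 units (whether adjusted values should stay standardized is not
dictated by the method; the log-scale choice is recorded in the function
metadata). The adjustment can be switched off (`adjust = FALSE`) to run
the whole pipeline as a sensitivity analysis. Missing (unmeasured) entries
are disallowed in the PCA input; assay-dropout imputation is out of scope.

## Association machinery

The RV coefficient — tr(XXᵀYYᵀ)/√(tr((XXᵀ)²)·tr((YYᵀ)²)) on
column-centered tables — measures global covariation between the topic
table and the cytokine table; its p-value comes from row permutations of
one table with the add-one estimator (1 + #{RV\* ≥ RV})/(1 + B), which can
never return zero. PERMANOVA for arm balance delegates to
`vegan::adonis2`.

DiSTATIS double-centers each dissimilarity matrix into a cross-product
matrix, normalizes by the first eigenvalue (MFA-style; trace normalization
is switchable), weights tables by the first eigenvector of their RV
congruence matrix, and eigendecomposes the weighted compromise. For
squared-Euclidean-embeddable inputs this is classical; Bray-Curtis is only
a semimetric, so the compromise may have small negative eigenvalues, which
are truncated at zero for the factor scores. Double centering is applied
to squared dissimilarities by default (`mode = "squared"`), with a direct
mode exposed; the choice is logged in the result. The number of displayed
dimensions is a human scree-plot judgment, so `n_dims` is explicit
(4 by default).

## Treatment effects

The benefit ratio of a 2×2 table is (a/n₁)/(b/n₂) with the Wald interval
exp(log RR ± z·√(1/a − 1/n₁ + 1/b − 1/n₂)), z = Φ⁻¹(0.975) at 95%. The
p-value reported alongside is the Pearson chi-square test of the table:
the chi-square p (0.0020 for the primary endpoint's counts) is what
standard epidemiological software prints with Wald ratio intervals,
whereas a log-scale Wald z would give 0.0067. Printed percentages use
round-half-even at integer precision. Degenerate tables (zero comparator
successes) signal an infinite ratio explicitly rather than silently
continuing.

Stratified rates carry Wilson score intervals (good small-stratum
coverage; the lower bound is exactly 0 at k = 0 and the upper exactly 1 at
k = n) and rate differences carry Newcombe's hybrid interval built from
the two Wilson bounds. Strata with fewer than two participants per arm are
excluded with a message.

Heterogeneity of the treatment effect is tested by comparing the null
logistic model (outcome ~ arm) with the full model (outcome ~ arm ×
baseline microbiota) through an analysis-of-deviance F test: F = (ΔD/Δdf)
divided by the full model's Pearson dispersion, referred to
F(Δdf, n − p). The F form (rather than a chi-square likelihood-ratio test)
tolerates mild over/under-dispersion; its type-I error at n = 180 with 4
strata is 0.03–0.07 in simulation. Before fitting quantitative
(topic-proportion) covariates, *Lactobacillus* topics should be
agglomerated to a total-*Lactobacillus* proportion — species-level
*Lactobacillus* topics are near-empty at the pre-MTZ baseline and break
convergence. Perfect separation is detected (fitted probabilities at the
boundary) and the model p is reported as NA rather than trusting a
penalized refit. BH correction is applied across the outcome family of
one invocation. Counterfactual predictions set every participant's arm to
each level, with delta-method intervals on the linear predictor mapped
through the inverse logit.

## Strain dynamics

Strain inference is attempted only on samples with ≥ 5% *L. crispatus*
relative abundance (below that the strain mixture is not reliably
estimable) and a 10% fractional abundance floor defines confident strain
detection. Categories: > 90% CTV-05 "High", < 10% "Low", otherwise
"Mixed" — values exactly at 0.9 or 0.1 fall to Mixed, since the stated
bands are "10–90%" inclusive against strict ">90%"/"<10%". Transition
tables pair consecutive scheduled post-randomization visits only, exclude
pairs touching a technically failed inference, and keep the
below-eligibility state as a legitimate destination. Strain identity
across visits is taken from the input table's strain IDs; genotype
similarity matching is upstream tooling and out of scope.

## Multiblock PLS-DA

Predictors are grouped into thematic blocks (previous-visit environment,
demographics, behavior, …). Variables are standardized, each block is
scaled to unit total variance (so a 20-variable block cannot swamp a
3-variable block), and the one-hot response is centered. Per component,
super-block NIPALS combines block scores through super weights maximizing
covariance with the response score; deflation acts on the (unit-norm)
super score. Categorical predictors are one-hot encoded with Gaussian
jitter of variance 10⁻³·S² added to sparse columns (fewer than 5
positives), which keeps resampled fits from degenerating on constant
indicators while leaving dense levels exact. Blocks confounded with the
microbiota can be residualized: a PLS2 regression on the confounding block
replaces observed values by residuals.

Block importance per component is the squared super weight; the
cumulative index (BIPC) accumulates over components weighted by the
response variance each explains, and the *relative* index divides by the
block's share of the variable count, so 1 means "importance proportional
to block size" and the variable-share-weighted mean of the indices is 1
by construction. Cross-validation uses 40 stratified 75/25 splits
(stratified, to keep every class in every calibration set; plain random
splits would need redraws anyway), macro-averaged F1 on the validation
predictions (argmax of the predicted response scores), and picks the
component count maximizing mean F1 with ties to the smaller count.
Bootstrap intervals are percentile intervals over participant resamples,
redrawing resamples in which a class vanishes.

## The synthetic cohort generator

`generate_cohort()` draws, per participant: an arm (2:1), a latent
post-antibiotic *receptivity* factor, and a colonization-category sequence
— screening almost entirely non-*Lactobacillus* (everyone has BV), the
randomization visit mostly *L. iners*-dominant (the usual post-antibiotic
bloom), a week-4 category whose *L. crispatus*-dominance probability is
0.30 (LBP) vs 0.09 (placebo) shifted on the logit scale by the receptivity
factor, and then a Markov chain that stays with probability 0.8 per visit
and otherwise jumps to another category in proportion to the arm's base
rates. The week-4 logit intercept is calibrated (logistic ≈ probit/1.7) so
the configured probabilities are the *marginal* rates after integrating
out receptivity. Receptivity also lowers post-MTZ pH and bacterial load,
which is what makes the previous-visit environment block genuinely
predictive of week-4 colonization.

Compositions come from a category-conditioned topic mixture: the
*Lactobacillus* part of the mean topic vector is fixed per category, the
non-*Lactobacillus* mass is split across the four planted subcommunity
profiles by a per-sample Dirichlet(0.8, …, 0.8) draw (samples are
dominated by one consortium but genuinely admixed — heavier admixture
obscures the topics at realistic depths, near-pure samples make the data
degenerate to clustering), and the final topic weights are drawn from a
Dirichlet with concentration 50 × the mean vector, keeping categories
separable with realistic within-category noise. Species counts are
multinomial at a log-normal depth with median 31,000 reads (sdlog 0.35).
Bacterial load collapses to a wide, low-median distribution at the
post-MTZ visit and recovers to a narrow, high-median distribution later.
Missing visits are dropped completely at random (10% by default);
missingness mechanisms are not modeled.

Cytokines: log10 concentration = analyte mean + swab-size factor
(SD 0.5 log10 units) + effect × (*Lactobacillus* proportion − ½) + noise
(SD 0.15), censored at per-analyte limits; the default effect signs mirror
the usual biology (MIG/IP-10/ITAC positive with *Lactobacillus*,
IL-1α/IL-1β/TNF-α negative) and are deliberately mixed-sign so the
biological signal is nearly orthogonal to the all-positive size direction.
Two analytes sit close to their lower limit to exercise the exclusion
rule. Strains: LBP recipients start High (or Mixed, 20%, when native
strains exist), High admits natives at 10% per visit, Mixed resolves to
native dominance with probability 0.35 per visit (and back to High with
0.05), and native dominance is absorbing; placebo samples carry native
strains only, up to a configurable false-positive rate (0 by default).
Participants carry 0–3 native strains (mostly one).

All randomness flows from one master seed through fixed stream-splitting,
so cytokines or strains can be regenerated independently and two runs with
the same configuration are byte-identical.

**What passing tests do and do not show.** The generator reproduces the
*statistical structure* the methods assume — topic-simplex compositions,
Markov category persistence, a rank-1 size contamination, threshold-driven
strain categories — not real data's ASV-level noise, taxonomic
misassignment, plate effects, informative missingness, or participant-level
confounding beyond the single receptivity factor. Recovery results on this
cohort therefore validate the implementations and their calibration, not
the biological conclusions one would draw from a real cohort.

## Problem sizes and numerical choices

Tests and the acceptance script run on deliberately scaled problems chosen
to resolve each property without waste: topic recovery on 300 samples at
depth 30,000 over a K = 2…7 grid with 8 restarts; RV calibration with 500
replicates of 199 permutations at n = 80; F-test size with 1,000 null
replicates at n = 180; block-importance recovery over 50 simulated cohorts
of 150 participants; the 2-component cross-validation scenario at n = 72
with 6 signal and 30 noise variables — small enough that extra components
visibly overfit, which is what makes the component choice identifiable.
Ties and degenerate inputs: all-zero count rows are rejected by
`relative_abundance()` and excluded from the LDA; constant analytes abort
the PCA with a named error; constant variables in correlation circles
yield NA with a warning; singleton PERMANOVA groups and sub-minimum strata
are refused or excluded with messages.

## Known limitations

* The LDA is variational; posterior uncertainty in π̂ is not propagated
  into downstream association tests.
* The alignment diagnostics are heuristics: on data whose true
  subcommunities genuinely overlap (profile cosine near the 0.8
  redundancy ceiling) the spurious-topic flags lose their separation.
* DiSTATIS on semimetric dissimilarities relies on eigenvalue truncation;
  strongly non-Euclidean inputs deserve a dedicated correction.
* The heterogeneity F test assumes the binomial mean-variance form up to a
  dispersion factor; strongly clustered outcomes (repeated outcomes per
  participant) would need mixed models, which the package does not fit.
* The MB-PLS-DA decision rule is argmax over predicted response scores;
  probability calibration of those scores is not attempted.
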