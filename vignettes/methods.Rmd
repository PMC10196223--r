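---
title: "Models and methods behind priogen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind priogen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`priogen` chains six analysis stages — diversity metrics, landscape
genetics, demographic inference, niche modelling, ancestry forecasting
and prioritization — into one reproducible pipeline for
microsatellite-genotyped tree populations along an environmental
gradient. This vignette records the models, the tunable parameters and
the design decisions, so that a user knows exactly what each number
means and what the passing test suite does and does not demonstrate.

## The synthetic world

Real genotype panels of this kind are rarely public, so the package
treats its generator as a first-class module. `simulate_world()`
produces:

* **Genotypes.** A forward Wright–Fisher stepping-stone chain:
  `n_pops` diploid demes (default 21) exchange migrants with their
  neighbours at `migration_rate` (default 0.05 per generation, split
  between the two neighbours), for `generations` (default 150)
  generations. Individuals are carried jointly across loci, so finite
  parentage generates real inter-locus linkage disequilibrium — the
  signal the LD-based N~e~ estimator needs; per-locus resampling would
  silently produce none. Mutation is stepwise on a 2-bp repeat lattice
  at `mutation_rate` (default 5.47e-5 per copy per generation, the
  microsatellite rate the motivating analysis uses), with a geometric
  multistep tail (`p_multistep = 0.12`, mean jump 2.8 repeats) shared
  with the two-phase-model coalescent null, so the simulator and the
  null hypothesis use one mutation engine. Demes are founded from a
  common pool whose alleles form a compact ladder of adjacent repeat
  states: a founding pool scattered across the lattice would start
  every population in a bottleneck-like state (low M-ratio) and break
  the demographic calibrations. Deme effective sizes decline west to
  east (`diversity_gradient`, default 0.8, meaning the easternmost deme
  is 20 % the size of the westernmost, default 250): drift then
  produces the west→east decline in allelic richness and private
  alleles that the analysis is designed to detect. Sample sizes default
  to 30 individuals per population; the generator emits complete data
  unless `missing_rate` is set (readers must tolerate missing codes, so
  the knob exists).
* **Climate.** Smooth deterministic fields on a 0.05° lon/lat grid
  spanning 41–48° E, 40.9–42.7° N (the toy footprint mirrors the
  motivating region; cell areas use the equirectangular
  cosine-latitude approximation with 111.32 km/° lon and 110.57 km/°
  lat). The warm- and cold-quarter precipitation layers (bio18, bio19)
  decline strictly monotonically west→east; `climaticMoistureIndex` is
  an exact linear function of `aridityIndexThornthwaite`, so the stack
  always contains one perfectly collinear pair for the VIF filter to
  find. The future stack is `current + shift` (default: +3.1 °C annual
  mean temperature, −95 mm bio18, −190 mm bio19, a drying/warming
  scenario) plus optional cellwise noise.
* **Ancestry.** Population-level Q matrices follow a softmax whose
  cluster-k predictor is w~k~ · (effect · z) with w~k~ equally spaced
  on [−1, 1] and z the standardized climate covariates; the default
  planted effect is bio19. Zero effect gives uniform membership 1/K,
  and the modal cluster is a monotone step function of the driving
  covariate — both used as generator checks.
* **Occurrences.** 88 points sampled (squared-weighted) from a "true"
  suitability surface, a logistic in standardized bio19 and bio18.

What the generator does **not** emulate: genuine spatial
autocorrelation beyond the one-dimensional chain, null alleles and
genotyping error, non-equilibrium colonization history, and realistic
topographic rasters (the DEM is a smooth sinusoidal field). Passing
parameter-recovery tests on this world therefore shows the estimators
are implemented correctly and behave as theory predicts at these sample
sizes — not that any particular real dataset meets their assumptions.

## Diversity and differentiation

Allelic richness is rarefied hypergeometrically: the expected number of
distinct alleles among `g` gene copies drawn without replacement,
`sum(1 - choose(n - n_a, g)/choose(n, g))`. The default `g` is the
smallest per-population sample over populations and loci (after
removing incomplete genotypes), the largest size every population
supports; requests beyond it raise an error naming the limiting locus.
Private alleles are counted over the full dataset, not per subregion.

Pairwise F~ST~ is the Weir–Cockerham (1984) estimator: per-locus,
per-allele variance components a (among populations), b (among
individuals) and c (within individuals), combined as a ratio of sums
across loci and alleles. Negative estimates are preserved — they are
information about sampling noise, not errors. Genotypes missing either
allele are excluded locus-wise; loci with fewer than two gene copies in
either member of a pair are skipped for that pair. The test suite
checks the implementation against an independent three-level ANOVA
(sums-of-squares) formulation.

Slatkin's linearization F/(1−F) clamps negative inputs to 0 and values
at or above 1−10⁻⁶ to (1−ε)/ε with a warning: the downstream
ordinations need finite, non-negative dissimilarities, and the clamp is
part of the contract rather than an error.

## Landscape genetics

The response is the linearized F~ST~ matrix; predictors come in four
standardized blocks: climate (point-sampled at the population sites —
the buffer-mean alternative is not implemented), geographic coordinates,
orography (the first PCNM eigenvector of the pairwise
|TRI~i~ − TRI~j~| dissimilarity of point-sampled terrain-ruggedness
values; absolute difference is the minimal choice where no dissimilarity
is prescribed), and ancestry (the first two centered principal
components of the Q matrix, with the sign fixed so the
largest-|loading| element is positive).

dbRDA delegates to vegan's `capscale`: Gower-centered principal
coordinates, constrained ordination, R² from non-negative eigenvalues
only (a Lingoes correction is deliberately not applied — the dominant
convention for linearized-F~ST~ responses), Ezekiel-adjusted R², and
permutation pseudo-F with p = (#F~perm~ ≥ F~obs~ + 1)/(nperm + 1), so p
is never zero. With conditioning variables the reduced-model residuals
are permuted. Two edge cases are handled explicitly: a perfect fit
(zero residual inertia) returns p = 1/(nperm+1), since no permutation
can beat it; a rank-zero constrained model (e.g. a block aliased by its
conditioning set) returns R² = 0.

Forward selection is greedy on adjusted-R² gain with a marginal
permutation test per entry and the double stopping rule (entry p ≥ α,
default 0.01, or cumulative adjusted R² exceeding the all-candidate
global model's). Ties break lexicographically; exact duplicate columns
are removed up front.

Variance partitioning fits the full model and each block conditioned on
all others. Two decompositions coexist in the output: `confounded` is
the staged-table convention (full explained − pure), which makes every
row close exactly — pure + confounded + unexplained = 1; `shared`
(= R²(block alone) − pure) is the classical varpart overlap, zero for
orthogonal blocks. Reporting both resolves an ambiguity in how such
tables are commonly printed. With `cascade = TRUE`, the least
significant block (pure-effect p ≥ 0.05) is dropped and the reduced
model refitted, repeatedly — the staged model-I/II/III presentation.

## Demography

The LD method computes the Burrows composite disequilibrium Δ̂ for every
allele pair at every locus pair, with the S/(S−1) small-sample factor
and denominators adjusted for Hardy–Weinberg departure (the
NeEstimator convention), squares and averages it weighted by the number
of individuals scored at both loci, and subtracts the random-mating
sampling expectation (1/S + 3.19/S² for S ≥ 30, else
0.0018 + 0.907/S + 4.44/S²). N̂~e~ follows from the drift component via
the standard piecewise quadratic; negative estimates are reported
verbatim (they mean the drift signal is smaller than sampling noise,
i.e. N~e~ is effectively unbounded) and the parametric chi-square
confidence interval can have an infinite upper bound. Alleles at
frequency ≤ 0.02 are excluded by default; diallelic loci contribute a
single allele. Calibration: across 200 Wright–Fisher replicates with
true N~e~ = 50 and S = 50 at 20 loci, the median estimate is ≈ 54.

θ→N~e~ exposes two conventions. The stated relation θ = 4N~e~μ gives
N~e~ = θ/(4μ); published tables in this workflow's lineage are instead
consistent with N~e~ = 4θ/μ rounded to an integer. Both are
implemented (`convention = "stated"` / `"table"`, default `"table"` for
reproduction runs); they differ by exactly a factor of 16 and the
package refuses to silently prefer one beyond that documented default.

The M-ratio is k/(r+1) per locus with r in repeat units; monomorphic
loci give M = 1 and are kept. The equilibrium null is a coalescent
simulation (exponential coalescence times, Poisson mutations at rate
θ/2 per lineage, two-phase mutation with single-step probability 0.88
and geometric multistep mean 2.8 — the recommended defaults, both
configurable). Significance is a one-sided Wilcoxon signed-rank test of
per-locus deficiency, exact for ≤ 25 loci; zero differences are
dropped, and θ defaults to a per-population estimate inverted from
expected heterozygosity under stepwise mutation
(He = 1 − 1/√(1+2θ)) when no external θ is supplied.

A calibration note: the bottleneck-power experiment in the acceptance
suite runs at θ = 10 (N~e~ = 100, μ = 0.025, 500 generations — chosen
so mutation–drift equilibrium is reached at desk scale and verified
against the coalescent null) with a crash to N~e~ = 10 for 10
generations. Extremely severe crashes are a known blind spot of the
M-ratio: when nearly all lineages coalesce inside the bottleneck the
allele-size *range* collapses along with the allele count and M can
even rise; the statistic detects partial allele loss, not total
collapse.

## Niche model

The suitability model is a deliberate simplification of the usual
maximum-entropy software: L1-regularized logistic regression
(`glmnet`) of presence cells against up to 10,000 background cells on
linear, quadratic and pairwise-product features of the standardized
layers, logistic output in [0,1]. Hinge/threshold features and the
original optimizer are out of scope; for smooth synthetic climate
fields the quadratic family is sufficient, and the planted-signal test
(occurrences placed along the precipitation gradient) recovers the true
surface with Spearman ρ > 0.8. The regularization multiplier scales a
fixed base penalty (λ = reg × 10⁻³). Occurrences are deduplicated at
cell level; 20 % are held out by seed for AUC (rank statistic,
presence-versus-background) and TSS (max over thresholds of
sensitivity + specificity − 1).

Area accounting sums cosine-latitude-corrected cell areas over cells at
or above the threshold (0.15 and 0.70 by default); altitudinal
statistics are order statistics of the DEM over the same mask, and an
empty mask is reported as an explicit empty result rather than zeros.
The altitude row of the summary table uses the 15 % mask by default (a
`thr` argument switches it, since published tables are ambiguous on
this point). TRI is the Riley definition: mean absolute elevation
difference to the up-to-eight neighbours, edge cells using the
neighbours that exist.

## Ancestry forecast

The MCMC machinery of ancestry-projection software is replaced by a
deterministic multinomial-logit surrogate with the same inputs
(Q matrix, four bioclimatic covariates — coordinates are deliberately
not included by default, climate-only being the cleaner causal
statement) and the same outputs (per-cell membership maps and hard
cluster maps under future scenarios). The fit minimizes cross-entropy
against the fractional memberships with an L2 penalty (λ = 10⁻³) for
identifiability, by BFGS with analytic gradient from a zero start —
refits are bit-identical, which a randomly initialized optimizer would
not be. K is taken from the input Q; no model selection is performed.
Projections are masked to the suitable range (≥ 0.15 by default);
multi-model ensembles average membership probabilities cellwise before
the argmax. Cluster persistence reports per-cluster cell counts and
areas, "lost" for clusters with no future cells, and Shannon entropy of
cluster area shares as a homogenization index.

## Prioritization

Reserve selection is greedy complementarity on the population-by-allele
incidence matrix: repeatedly take the population covering the most
uncovered alleles (ties by label), to full coverage or an iteration cap
of 100. Greedy set cover is not optimal in general; on realistic
U-shaped allele-occupancy instances it matches the exhaustive optimum
in ≥ 90 % of cases and is within one population otherwise, which the
acceptance suite verifies.

The conservation index is C_i = A_r × F_c / C_l. F_c is the
area-weighted mean of a fraction-valued forest raster over cells whose
centers fall within a 20-km geodesic circle. The published description
of C_l ("a geometric mean between the bioclimatic variables of the
current and future period") is not a formula; the adopted definition —
the geometric mean of (1 + |Δv|/v~current~) over bio18 and bio19 — is
the minimal reading that equals 1 under no change and increases with
the projected shift, matching the stated intent that larger shifts
lower priority. Categories 1–5 default to unit-width bins anchored at
integers (C_i > 4 → category 1, …, ≤ 1 → category 5): applied to the
21 published index values this rule reproduces the reported category-1
and category-2 memberships exactly, which equal-size rank groups and
natural-breaks classifications do not; the equal-size rule remains
available as `method = "equal_rank"`.

## Numerical and reproducibility choices

All randomness flows from one integer seed; each generator stage
derives its own 31-bit sub-seed from a label hash so stages are
independently reproducible and adding a stage never perturbs another's
stream. The pipeline writes a manifest of output files with md5
checksums and refuses to overwrite a populated directory without
`force = TRUE`; reruns with the same configuration are byte-identical.
Problem sizes in the shipped demonstration configuration (21
populations, 150 generations, 499 permutations, 500 coalescent
simulations per population) keep a full run around half a minute on a
single CPU; the test-suite calibration experiments use 60–200
replicates per property, sizes at which each check is stable across
seeds.

## Known limitations

The stepping-stone world is one-dimensional; isolation-by-resistance
is represented only through the TRI dissimilarity, not a full
circuit-theory resistance surface. The LD-N~e~ chi-square interval
treats comparisons as independent, so it is anti-conservative when loci
share individuals (the jackknife alternative common in this literature
is not implemented). The maxent surrogate's quadratic features cannot
express the sharp response edges hinge features capture, so absolute
suitability values are not comparable with published MaxEnt runs — only
threshold areas and ranks are. The coalescent M-ratio null assumes a
single panmictic population at equilibrium; applying it to strongly
substructured samples overstates bottleneck evidence.
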