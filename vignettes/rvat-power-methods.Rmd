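---
title: "Simulating rare-variant association power under evolutionary genetic architectures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating rare-variant association power under evolutionary genetic architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

rvpower simulates case/control association studies of complex traits whose
genetic architecture is shaped by demography and purifying selection, and
measures the statistical power of rare-variant association tests (RVATs)
under different study designs. This vignette explains the models, the
parameters that matter, the numerical choices, and what the simulations can
and cannot say about real data.

## The simulation model, stage by stage

### Neutral haplotypes under a two-population demography

Genotypes for the study region come from a coalescent simulation (msprime,
through a bundled Python bridge) under a two-deme out-of-Africa history: an
ancestral population of 7,310 diploids expands to 14,474 about 5,920
generations ago; a bottlenecked population of 1,861 splits off 2,040
generations ago and suffers a second founding bottleneck (1,032, growing at
0.307%/generation) 920 generations ago; both demes then grow explosively
from ~205 generations ago (Africa at 1.66%/generation to 424,000; Europe at
1.95%/generation to 512,000), with bidirectional migration throughout
(1.5e-4 during the bottleneck era, 2.5e-5 after). These are the standard
published calibrations of this model; every parameter of
`tennessen_model()` can be overridden. The default mutation rate is
1e-8/bp/generation, and a synthetic variable-rate recombination map
(`chr22_like_map()`, mean 1e-8/bp with hotspots) stands in for a real
chromosome-22 genetic map; a uniform map is the fallback. African samples
are the default study population because the headline analyses concern the
African growth history; the European deme is fully configurable.

### Functional variants under selection

Phenotypic effects are anchored to a pool of *functional* variants with
known selection coefficients, generated by `simulate_fitness_table()`. Each
of many independent loci evolves forward in time under Wright–Fisher
binomial resampling with genic selection (fitnesses 1, 1 − s/2, 1 − s for
the ancestral homozygote, heterozygote and derived homozygote — dominance
is not part of the architecture model, so additive h = 0.5 is assumed). New
mutations arrive as a Poisson process and draw |s| from a gamma
distribution of fitness effects — by default shape 0.184 and mean 0.03, the
classic leptokurtic calibration for human nonsynonymous sites; both
parameters are configurable. The simulation burns in for 10 · 2N
generations at the ancestral size, then runs through the demographic
epochs, and finally projects population frequencies binomially to the
requested number of sampled chromosomes.

Two approximations make this tractable on one CPU:

* **Rescaling** (default factor 100): population sizes are divided by, and
  s, the mutation rate and time are multiplied by, the rescale factor.
  Compound parameters (2Ns, 2Nu) are preserved, but frequency granularity
  is coarsened — the smallest representable population frequency at the
  rescaled present-day African size is ~1.2e-4, and the 205-generation
  growth epoch compresses to two rescaled generations. A rescaled
  population below 50 diploids is refused outright.
* **Per-mutation trajectories** (free recombination between sites): each
  mutation's frequency evolves independently, which ignores interference
  among selected sites. This is the stand-in for a linked forward
  simulator, and is the main structural difference from full-scale linked
  simulations.

Mutations too strongly selected to be representable after rescaling
(rescaled |s| > 1.9, i.e. heterozygote fitness ≤ 0.05) are injected
analytically: at mutation–selection balance a site with selection s
segregates at frequency 2u/s, so the expected number of sampled copies per
locus is n · u · L · E[2/s] over the strong tail; copies enter the pool as
independent singletons, with s drawn proportional to f(s)/s. The singleton
approximation misstates a few percent of this class (true counts would
occasionally be 2–3), which is negligible for every quantity computed here.

Convergence checks (rescale 100 vs 50 vs 25 agree within Monte-Carlo noise)
indicate the estimator is at its rescaling limit; residual differences from
full-scale linked simulations are discussed under Limitations.

### From selection to effect sizes: the rho/tau architecture

A causal variant's phenotypic effect derives from a selection coefficient
through
|z| = s^τ, with sign ±1 equiprobable. With probability ρ the variant's own
s is used; otherwise the s of a uniformly drawn pool variant. τ couples
effect size to selection strength (τ = 1: proportional; τ = 0.5:
diminishing); ρ measures how specifically selection acts through this trait
(ρ = 1: fully coupled; ρ = 0: effects are an exchangeable draw from the
selection distribution). Causal loci are contiguous blocks (default 10 kb)
sampled uniformly without replacement; every panel variant inside a causal
block receives an effect through a pool variant with the **same derived
allele count** (after projecting the pool to the panel's chromosome count).
When no pool variant has exactly that count, the nearest count within
±max(1, 5%) is used, with seeded tie-breaking; matching failure is an
error, not a silent fallback.

Traits are additive: Y = Σ X z + ε, with ε normal and its variance set
from the *realised* sample variance of the genetic score, Var(G)(1 −
h²)/h², so the realised heritability is on target for every replicate.
Case/control status derives from the quantitative trait: the top P% (default
prevalence 25%) are cases. Ties at the threshold break by individual index,
so dichotomisation is deterministic.

### Cumulative genetic variance V_x

The rare-variant share of trait variance is summarised by
V_x = 0.5 Σ_{y ≤ x} E(z²|y) f(y) y (1 − y), evaluated over the variants of
a neutral site-frequency spectrum (f comes from pooled coalescent
replicates; by default 100,000 chromosomes), with
E(z²|y) = ρ E(s^{2τ}|y) + (1 − ρ) E_pool(s^{2τ}). The conditional
expectation is estimated from the projected pool binned by derived count:
one bin per distinct count up to 100 copies, log-spaced bins above. Empty
pool bins contribute zero to the conditional component. The threshold
applies to the derived allele frequency, exactly as in the defining
integral; the MAF-folded reading differs only through derived frequencies
above 0.99, which are negligible here. The 0.5·y(1−y) prefactor differs
from the conventional 2p(1−p) per-site variance by a constant, which
cancels in every normalised quantity.

The reported share `ratio` normalises each architecture component by its
own total variance before mixing, so it is exactly linear in ρ:
ratio(ρ) = ρ·ratio(1) + (1 − ρ)·ratio(0). This is the convention under
which reference values for this model are tabulated (their printed grids
are ρ-linear to machine precision, which is only possible under
per-component normalisation); the raw V_x mixes components before
normalising, as the integral is written.

### Study designs, array data and imputation

Three cohort designs are implemented: `random` (cases in proportion to
prevalence), `fifty_fifty` (equal cases and controls) and `extremes` (the
top and bottom tails of the quantitative trait; prevalence plays no role,
and the rule is purely rank-based even when the tail crosses the
prevalence threshold). All sampling is without replacement and seeded.

Array genotyping is emulated by stratified downsampling of the sequence
panel to a manifest — target MAF-bin proportions plus a mean marker
spacing; the bundled synthetic manifest mimics a dense commercial chip
(common-variant skewed, 1 marker per 2 kb). Imputation is a
haplotype-copying (Li–Stephens) model: each target haplotype is a mosaic of
`n_states` reference haplotypes (default 200, chosen as the
nearest-by-Hamming-distance references at typed sites), with a constant
per-bp switch rate (default 2e-6) and typed-site mismatch rate 1e-3;
forward–backward posteriors give expected dosages at untyped sites, and
typed sites pass through as observed. Because simulated haplotypes are
already phased, no statistical phasing stage is needed; this single model
stands in for the phase-then-impute toolchains used on real data. RVATs
consume the expected dosages directly (not hard calls), rare-variant
membership uses dosage-estimated MAF, and no imputation-quality filter is
applied by default (an r² > 0.3 filter is exposed for users who want to
mimic common post-imputation practice).

### Association tests

All tests are implemented from their source formulas against the
intercept-only logistic null (closed form: every fitted probability equals
the case fraction).

* **Single-variant scan**: 1-df score test per dosage column at MAF ≥ 1%,
  summarised per 10 kb block as the minimum p (`GWAS-min`).
* **SKAT**: Q = (y − μ)' G W² G' (y − μ) with Beta(1, 25)-density MAF
  weights; the null tail comes from the eigenvalues of W G' P₀ G W.
* **SKAT-O**: Q_ρ = (1 − ρ) Q_SKAT + ρ Q_burden over the grid
  ρ ∈ {0, 0.1², …, 0.9², 1}; the minimum p over the grid is corrected by
  the standard one-dimensional integral over the common chi-square
  component (Liu moment-matched per-ρ quantiles; the correction integral is
  evaluated on the survival side so small combined p-values keep relative
  accuracy). Single-point grids reduce exactly to SKAT (ρ = 0) or the
  weighted burden score test (ρ = 1).
* **KBAC**: individuals are grouped by their multi-site rare genotype
  pattern (dosages rounded to hard calls — the pattern construction needs
  discrete genotypes); each non-null pattern is weighted by the
  hypergeometric lower-tail probability of its case count, and the
  weighted case-minus-control frequency difference is tested by one-sided
  adaptive Monte-Carlo permutation (1,000 permutations escalating
  ten-fold, stopping once the 99% CI of the p estimate excludes
  `alpha_stop`; a non-positive `alpha_stop` disables early stopping). A
  two-sided variant is exposed by a flag.

Mixture-of-chi-square tail probabilities use characteristic-function
inversion (the Davies/Imhof integral) by Gauss–Legendre quadrature over
oscillation-scaled segments with an integration-by-parts tail closure,
validated to ~1e-10 against chi-square and exponential-mixture closed
forms; a Kuonen saddlepoint approximation takes over in deep tails
(p below ~1e-6), and Liu moment matching is the last-resort fallback. The
method used is recorded on the returned value.

Blocks tile the region at 10 kb (a trailing partial block is dropped);
rare-variant membership is MAF < 0.01 within the analysis cohort
(configurable); blocks without qualifying variants are recorded as
untestable — they count as misses when causal (a test cannot discover a
block it cannot run on) and are excluded from false-positive denominators
when not.

### Power summaries

Power is the fraction of causal-block trials significant at fixed
thresholds (2.5e-6 for RVATs, 5e-8 for the single-variant scan at full
scale); discovery is judged against these fixed thresholds only — no
false-discovery-rate machinery. Conditional
power stratifies causal trials by a conditioning test's significance
(single-variant scan → RVAT, or imputed → sequence). Sample-size response
is summarised as the OLS slope of power on n. Discovery windows bin blocks
by distance from the nearest causal block and report the full-width
half-maximum: the first distance at which the linearly interpolated
significant fraction falls below half its value at distance zero (the
one-sided crossing; a flag doubles it for the two-sided reading).
Cross-test comparisons use the two-sided Mann–Whitney rank-sum test on
per-architecture power values.

## Problem sizes used by the tests and the acceptance script

The full-scale study (5 Mb, 50,000 individuals, 2,000 forward loci, the
complete architecture × design raster) is encoded as `make_fixture("full")`
and runs in hours. The package's own checks use smaller instances, chosen
so Monte-Carlo error stays well inside the asserted margins:

* Variance-share grid: 200–600 pooled 100 kb forward loci at rescale 100,
  projected to 100,000 chromosomes; neutral SFS from 20–30 pooled 300 kb
  coalescent replicates of 50,000 African individuals.
* Calibration: 2,000 null replicates per test at n = 500 with 10 rare
  variants.
* Design comparison: 600 kb region, 8,000 individuals, cohorts of 1,600,
  10 causal blocks, four (ρ, τ) architectures × three designs × two
  replicates. At this size the full-scale 2.5e-6 threshold leaves
  non-extreme designs at floor power, so reduced-scale analyses evaluate at
  2.5e-5 (RVAT) and 5e-7 (single-variant) — the same 50:1 ratio between
  thresholds; the qualitative assertions (design ordering, V_0.01 trend,
  window ordering, concordance) are unchanged.

## What the generator does and does not emulate

The synthetic data reproduce the features that drive RVAT behaviour —
realistic site-frequency spectra under growth, the selection–frequency
correlation of deleterious variants, frequency-matched effect sizes, LD
from a variable recombination map, array ascertainment and imputation
noise. They do not include: linked selection or interference (the forward
simulator is per-site), sequencing or genotyping error, relatedness or
population structure within the sampled deme, covariates, dominance or
epistasis, gene-length or annotation heterogeneity, and admixture. Passing
tests therefore certify the statistical machinery and the qualitative
design conclusions under this model, not performance on any particular real
cohort.

## Known limitations

* The variance-share grid reproduces the τ = 1 column and τ = 0.5, ρ = 0.5
  of its reference values within ±0.05, but the τ = 0.5, ρ ≥ 0.8 shares
  come out 0.07–0.11 low. The estimate is converged in the rescale factor
  and insensitive to the DFE mean and SFS sample size, so the residual is
  attributed to the per-site independent forward simulator (versus
  full-scale linked simulation) and unprinted details of the original
  pipeline's DFE calibration.
* The haplotype-copying imputation is a single-stage stand-in for
  production phase-and-impute toolchains; its absolute r² levels are
  realistic in pattern (declining with MAF) but not calibrated to any
  specific software.
* KBAC p-values are Monte-Carlo estimates; at the full-scale 2.5e-6
  threshold the permutation cap (default 1e4, escalating to 1e6–1e7 in the
  adaptive scheme) bounds the smallest attainable p, exactly as in
  practical permutation-based software.
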