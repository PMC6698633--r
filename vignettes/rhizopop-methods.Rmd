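---
title: "Models and methods behind rhizopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rhizopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizopop)
```

rhizopop analyses multilocus sequence typing (MLST) data from haploid
bacterial populations — its motivating system is the package of symbiotic
nodulation and nitrogen-fixation genes (*nodA*, *nodC*, *nifA*, *nifH*,
*nolT*) carried by *Mesorhizobium* strains nodulating black locust — and
infers their demographic history with mismatch distributions and
approximate Bayesian computation (ABC) over structured-coalescent
simulations. This vignette explains the models, the conventions, and the
choices made where the design was genuinely open. It states no empirical
result beyond what the package's tests compute.

## Data model and the missing-data policy

A `locus_alignment` is a named set of equal-length sequences over
`{A,C,G,T,N,-}`; an `mlst_dataset` bundles loci sharing a strain universe
with per-strain metadata (site, country, species, clade). Clade labels are
consumed as metadata — the package does not infer population structure
itself — and operations that need them fail loudly when they are absent.

All statistics apply **complete deletion**: any alignment column containing
`N` or `-` in any sequence is removed first, and haplotype identity is
exact string equality on the retained columns. This matches the default of
the classical Arlequin-style workflow this package mirrors. The one
exception is the codon-based selection statistics: deleting single columns
would shift the reading frame, so there whole codons containing a masked
character are excluded instead. The retained-column mask is recorded on
every haplotype table. The gap policy is a genuine open choice — other
packages use pairwise deletion — and is isolated in `retained_columns()`
so a sensitivity analysis only needs to swap that function.

Coordinates are 0-based half-open internally; user-facing tables are
1-based inclusive.

## Diversity and neutrality statistics

For n sequences with S segregating sites and mean pairwise difference
count π (computed on retained columns):

* Watterson's estimator: `theta_w = S / a_{n-1}`, `a_m = sum_{i<=m} 1/i`.
* Tajima's D uses the 1989 variance constants; it is undefined (`NA`) when
  S = 0.
* Fu's Fs is computed exactly from the Ewens sampling formula:
  `S' = P(K >= k_obs | theta = pi, n)` with unsigned Stirling numbers of
  the first kind evaluated in log space (stable to n of several hundred),
  and `Fs = ln(S'/(1-S'))`.
* Significance for both is obtained by neutral coalescent simulation
  conditional on the observed S (mutations dropped on simulated
  genealogies with probability proportional to branch length), the
  convention of the workflow this package reproduces, rather than from a
  beta approximation. The replicate count is an argument
  (`neutrality_test(..., n_reps)`, default 1000).
* `pn_ps_dn_ds()` implements Nei–Gojobori (1986) counting: fractional
  synonymous potential sites per codon averaged over sequences;
  polymorphic sites classified against the consensus codon; pairwise
  synonymous/nonsynonymous differences with pathway averaging (pathways
  through stop codons excluded unless all pathways are). No Jukes–Cantor
  correction is applied because within-population divergence in the target
  data is far below the regime where it matters; the polymorphism counts
  can be reported raw (`normalize = FALSE`) since published tables differ
  in whether they normalize by potential sites.
* Hudson-style F_ST between groups is `1 - H_w/H_b` with `H_w` the average
  of the two within-group mean pairwise differences. Negative estimates
  are reported as computed.

## Linkage and homoplasy

The index of association treats each locus as one allele (collapsed
distinct sequence — the MLST convention of START2/poppr, not per-site
states): for strain pairs, `D_ij` counts loci with different alleles,
and `I_A = V_O/V_E - 1` with sample (n−1) variances, so `I_A = 0` under
free recombination and `k - 1` for k perfectly linked equally informative
loci. The permutation test shuffles allele assignments independently at
each locus (preserving allele frequencies exactly) and reports
`p = (1 + #(perm >= obs)) / (1 + n_perm)`. Clone correction — one
representative (lowest strain id) per multilocus haplotype per group —
is expected before testing, as clonal resampling inflates apparent
linkage; `force = TRUE` overrides.

The homoplasy index compares the observed parsimony length `L_obs` to the
compatibility minimum `L_min = sum(states - 1)` and to the
free-recombination expectation `L_free`, the mean parsimony length of
datasets whose site columns are independently permuted across strains:
`H = (L_obs - L_min) / (L_free - L_min)`, clamped to [0, 1]. Tree search
is a neighbour-joining start refined by SPR hill climbing (phangorn's
Fitch engine) with random-start restarts. Defaults are 3 restarts and 20
column shuffles: the estimator is a Monte-Carlo ratio whose error is
dominated by the shuffle count, and SPR search makes further restarts
nearly redundant (an exhaustive-enumeration oracle on seven-taxon data
confirms the search finds the optimum); both knobs are arguments. When
the shuffled data carry no extra steps the index is reported as not
computable rather than 0/0.

## Minimum spanning networks

`build_msn()` runs Kruskal's algorithm on nucleotide mismatch distances
between haplotypes with **tie retention**: at each weight threshold, every
edge joining components that were disconnected when the threshold was
entered is kept. The result is a network whose strict-tree subset equals a
minimum spanning tree (first-found tie-break on deterministic ordering:
weight, then lexicographic endpoints); the extra edges are flagged
`co_minimal` and always tie the weight of a tree edge they could replace.
Nucleotide (not allele-count) distances are used so edge weights read as
SNP steps between sequence types.

## Mismatch distributions

Spectra are histograms of pairwise difference counts. Three expected forms
are available, with τ in mutational units (τ = 2μt, μ the per-locus total
rate) and θ = 2Nμ on the haploid scale used throughout:

* constant size: `F_j = θ^j / (1+θ)^{j+1}`;
* sudden demographic expansion (θ₀ → θ₁ step at τ): the Li/Rogers
  transient solution, evaluated through Poisson convolution in a
  numerically stable form (its θ₁ → ∞, θ₀ = 0 limit is Poisson(τ); its
  τ → 0 limit is the constant form — both are tested);
* spatial expansion: an infinite-island form with parameters (τ, θ, M):
  two lineages sampled in one deme either coalesce (probability
  1/(1+M)) or scatter at total rate (1+M)/θ; scattered or untouched pairs
  coalesce in the single ancestral deme of size θ beyond τ. The closed
  form integrates Poisson mutation over that coalescence-time mixture
  (an incomplete-gamma term plus a Poisson–geometric convolution). It is
  cross-checked in the tests against an independent Gillespie simulation
  of the same pair process, and reduces to the constant form at M = 0.

Fitting minimizes the sum of squared deviations (SSD) between observed
and expected **relative frequencies** (not counts) by a coarse grid
(τ ∈ 0..50 by default, θ grids anchored on the spectrum mean) followed by
Nelder–Mead on transformed coordinates (τ = x², θ = exp(x)), with
θ₁ capped at 1e5; the constant model uses Brent on log θ. If refinement
fails to beat the best grid point, that grid point is returned with
`converged = FALSE`. Harpending's raggedness is summed with the
convention `x_{d+1} = 0` over `i = 1..d+1` (recorded in the result,
because published programs differ here).

`bootstrap_gof()` is a parametric bootstrap: B data sets simulated from
the coalescent at the fitted parameters (matching n; `n_loci` controls
whether the simulated data pool several independent genealogies, matching
data that are pooled across unlinked loci, or a single clonally linked
concatenation, the default), each refit from scratch with a coarse grid
adapted to its spectrum width. `p_ssd` and `p_rag` are upper-tail
fractions; the τ interval is the 2.5/97.5 percentile range of the
refitted values, widened if needed to bracket the point estimate.
Refitting cold (rather than warm-starting from the parent fit) matters:
warm starts shrink the refit spread and make the intervals anticonservative.

`tau_to_generations(tau, mu_per_site, L)` applies t = τ/(2 μ L); the
sequence length is an explicit argument because published conversions do
not always state the length behind them. `generations_to_years()` defaults
to 30 generations per year, an upper bound for slow-growing soil bacteria
cycling between soil and nodules.

## The structured-coalescent engine

`demographic_scenario()` declares demes (present sizes in gene copies,
exponential growth rates), a time-ordered event list (merges, size,
growth and migration changes; times in generations before present), a
backward migration matrix, per-deme sample counts and per-locus lengths
and mutation rates. The convention is **haploid**: k lineages in a deme
of N gene copies coalesce at rate k(k−1)/(2N) per generation, so a pair
coalesces in N generations on average and θ per locus is 2NμL. This is
stated prominently because rhizobia are haploid and diploid-scaled
software differs by a factor of two.

Simulation (C++ core) draws exact exponential waiting times between
events, with closed-form inversion of the time-inhomogeneous coalescence
hazard inside exponentially growing demes; migration is implemented but
defaults to zero, matching divergence-only models in which sizes stay
constant between instantaneous splits. Mutations are Poisson on branches
with infinite-sites placement (unique positions per locus); sequences are
rendered over a reference of As with derived states drawn uniformly from
the three alternatives — statistics never depend on the rendering. All
randomness flows through R's RNG, so `set.seed()` (or the `seed`
arguments) makes every pipeline stage bit-reproducible. Scenarios whose
sampled demes can never coalesce are rejected before simulation;
`validate_scenario()` reports diagnostics without simulating.

## ABC model choice and validation

Reference tables draw parameters from uniform or log-uniform priors,
simulate, and record a 21-statistic panel: per clade K (multilocus
haplotypes), haplotype diversity, S, mean pairwise differences and
Tajima's D (15 for three clades), plus pairwise F_ST and mean
between-clade differences (3 + 3). The exact published panel for the
motivating study is not public, so this default was chosen to describe
within-clade diversity and between-clade differentiation with the same
total count; it is pluggable (`summary_stats()` and the model's `clades`
field). Undefined entries (D on a monomorphic clade) are imputed as 0 and
flagged — imputation keeps the panel dimension fixed across simulations.

Rejection standardizes all statistics by the pooled mean/SD across models
(the behaviour of the reference ABC toolchain), excludes zero-variance
statistics with a warning, and retains the closest 0.5% by default of the
pooled simulations — pooled rather than per model, so the retained counts
themselves estimate the posterior (reported as `rejection_posterior`, a
cross-check on the GLM route). Model choice fits, per model, a
linear-Gaussian regression of statistics on parameters over the retained
rows (the ABC-GLM of Leuenberger & Wegmann) and evaluates the marginal
density of the observation as the average Gaussian density over retained
rows, in log space with a ridge fallback for singular covariances.
Posteriors are normalized prior-weighted marginals; Bayes factors are
marginal ratios with the conventional ">3 rejects the alternative" rule
left to the caller. The goodness-of-fit p-value is the fraction of
retained simulations whose marginal density is at or below the observed
one; models with p < 0.05 (strict) are flagged for exclusion.

Parameter estimation applies Beaumont-style local-linear regression
adjustment with Epanechnikov weights on the rejection distance,
log-transforming parameters with log-uniform priors, truncating adjusted
draws to the prior support (count reported), and summarising by
kernel-density mode, weighted median, and a 95% highest-density interval
clipped to the support.

Validation follows the standard pseudo-observed-dataset (POD) design:
`validate_model_choice()` simulates PODs from each model's prior,
re-runs rejection + GLM choice per POD, and reports the assignment
matrix, type I error (own PODs not won) and type II error (other models'
PODs captured). `validate_coverage()` computes the posterior quantile of
the true parameter for each POD and tests uniformity by Kolmogorov–
Smirnov; a deliberate multiplicative bias (`shift`) documents the test's
sensitivity. `posterior_predictive()` resamples the adjusted posterior,
simulates, and reports 2.5/97.5 envelopes per statistic.

### Shipped scenarios

Four built-in models relate the clades: `model_09` (stepwise divergence,
clade III ancestral; the two drawn times are sorted so the topology is
always respected), `model_10` (simultaneous trifurcation), `model_14`
(an unsampled ghost deme as the source of clade II; because its published
description is ambiguous about whether the ghost splits from the ancestor
or from clade III, both variants ship as `model_14a` and `model_14b`),
and `model_20` (a two-deme split for subclade dating). Default priors are
wide: divergence times uniform(10³, 10⁶) generations, sizes log-uniform
(10³, 10⁶) gene copies, μ log-uniform(0.5e-8, 2e-8) per site per
generation, shared across models and fully overridable. Sample sizes
default to 82/97/87 and the loci to the five symbiotic lengths.

## The synthetic-data generator

`generate_study_like_dataset()` emulates the study design every stage is
tested against: 286 strains — clades of 82/97/87 plus 20 strains labelled
admixed — in a simultaneous trifurcation 204,300 generations ago with a
100-fold clade II expansion 3,690 generations ago, μ = 1e-8 per site per
generation, five symbiotic loci at their printed lengths plus six
housekeeping loci whose mutation rate carries a 10× multiplier (a
deliberate simplification: real housekeeping genes owe much of their
extra diversity to recombination, which is out of scope, so the
multiplier reproduces only the diversity contrast the tests rely on).
Country labels mimic the study's composition (227 Chinese, 48 German and
11 North American strains, the latter split 2 in clade I and 9 in clade
III); species labels are cosmetic draws from eight abbreviations.
Present-day deme sizes (5e4 / 1.5e5 / 1.6e5 gene copies) are arbitrary
defaults chosen once to land within an order of magnitude of the observed
per-site diversities, and documented as such. The generator returns the
ground-truth parameter record so recovery tests never re-read the
configuration.

A consequence of taking the stated conditions seriously: with μ = 1e-8,
L = 3,308 bp and an expansion 3,690 generations ago, the clade II
expansion has a mutational age of only τ = 2μLt ≈ 0.24, so its mismatch
spectrum is nearly indistinguishable from the best constant-size fit and
SSD-based goodness-of-fit tests have essentially no power there. The
expansion's detectable fingerprint at these conditions is the site
frequency spectrum — Tajima's D is strongly negative in clade II and
near zero in clade III — and that is the contrast the tests assert.

What the generator does **not** emulate: recombination and HGT mosaicism,
STRUCTURE-style admixture (the "admixed" strains are ordinary samples
from the three demes, only labelled differently), selection, and
rate variation among branches. Passing tests therefore demonstrate the
pipeline's internal consistency under a clean divergence-plus-expansion
history, not robustness to those violations on real data.

## Problem sizes in the test-suite and acceptance runs

Scaled designs were chosen once for the validation studies shipped with
the package: τ-recovery uses 100 replicates of n = 50 with B = 200
bootstrap refits; homoplasy calibration uses 100 clonal replicates of
n = 16; ABC end-to-end recovery uses 20,000 simulations per model and 100
PODs; coverage uses 200 PODs on a single-parameter model; the acceptance
script runs 5,000 simulations per model with 1% retention (so each model
retains ~50 of the 150 kept rows) and 60 PODs. These sizes give the
Monte-Carlo error the assertions need; the thresholds themselves
(majority recovery, 85% coverage, KS at α = 0.01) were fixed in advance
of the runs.

## Known limitations

* Loci are simulated as independent genealogies; truly clonal multilocus
  data share one genealogy. Analyses of concatenations treat the
  concatenation as one locus, which is the appropriate clonal limit, but
  intermediate linkage is not modelled.
* No recombination within or between loci, no selection, no rate
  heterogeneity.
* The SSD surface of the three-parameter expansion models is flat along a
  τ/θ ridge for near-Poisson spectra; fits can land on the θ₁ bound with
  θ₀ ≈ 0. The τ estimate is robust to this (it tracks the spectrum mean),
  but θ estimates from mismatch fits should not be over-interpreted.
* ABC marginal densities use a linear-Gaussian approximation on the
  retained set; with very small retained counts (< 50 per model) the GLM
  is replaced by a Gaussian fit to the retained cloud and a warning is
  emitted.
* Posterior-quantile coverage is well calibrated for time parameters,
  whose summary statistics respond linearly with roughly constant noise.
  Effective-size parameters behave worse: their statistics' sampling
  variance grows with the parameter, which the local-linear adjustment
  only partly absorbs, so their posterior quantiles deviate mildly from
  uniformity at high POD counts. Size posteriors should therefore be read
  as approximate — the same caution the POD literature attaches to size
  parameters — while time posteriors carry the package's full coverage
  guarantee.
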