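# rhizopop

Population genetics and demographic inference for bacterial MLST data.

Rhizobia that nodulate black locust carry their symbiosis genes (*nodA*,
*nodC*, *nifA*, *nifH*, *nolT*) on mobile elements that move between
chromosomal backgrounds, so the demographic history of the *genes* — when
their clades diverged, when they expanded, where they came from — must be
inferred from the gene sequences themselves. rhizopop implements that
inference chain for haploid multilocus sequence typing (MLST) data:

* **Diversity and neutrality** — per-locus haplotypes, nucleotide
  diversity π, Watterson's θ_w = S/a_{n−1}, Tajima's D, Fu's
  F_s = ln(S′/(1−S′)) with S′ = P(K ≥ k_obs) from the exact Ewens sampling
  formula, and Nei–Gojobori p_N/p_S and d_N/d_S for coding loci.
* **Linkage and recombination screens** — the index of association
  I_A = V_O/V_E − 1 on clone-corrected multilocus data with permutation
  tests, and a parsimony-based homoplasy index H ∈ [0, 1] (0 = clonal,
  1 = free recombination).
* **Haplotype networks** — minimum spanning networks over multilocus
  haplotypes with tie retention (all co-minimal edges kept), GraphML/TSV
  output.
* **Mismatch-distribution demography** — observed spectra; closed-form
  expectations under constant size, sudden demographic expansion
  (τ, θ₀, θ₁) and spatial expansion (τ, θ, M); least-squares fitting; SSD
  and Harpending's raggedness with parametric-bootstrap p-values and τ
  confidence intervals; conversions t = τ/(2μL) and years = t/(gen/yr).
* **A native structured-coalescent simulator** (C++ core) — multiple
  demes, divergence events, ghost demes, growth, migration,
  infinite-sites mutation, fully seed-reproducible.
* **ABC model choice and estimation** — prior specification, reference
  tables over a 21-statistic panel, Euclidean rejection on pooled
  z-standardized statistics, linear-Gaussian ABC-GLM marginal densities,
  posterior probabilities and Bayes factors (">3" decision rule),
  goodness-of-fit p-values, regression-adjusted parameter posteriors, and
  full validation: type I/II error on pseudo-observed datasets,
  posterior-predictive envelopes, and posterior-quantile coverage with KS
  uniformity tests.
* **A synthetic-data generator** emulating the three-clade, eleven-locus
  study design (286 strains, simultaneous divergence, a 100-fold clade II
  expansion), with the ground truth returned for recovery tests.

## Worked example

```r
library(rhizopop)

# a study-like synthetic dataset: 286 strains, 3 clades, 11 loci
out <- generate_study_like_dataset(seed = 3)
ds  <- out$dataset
sym <- symbiotic_loci()$name

conc <- concatenate(ds, sym)          # 3,308 bp symbiotic concatenation
collapse_haplotypes(conc)
#> <haplotype_table> 155 haplotypes from 286 strains (3308 retained sites)

nucleotide_diversity(conc)$per_site   # symbiotic per-site diversity
#> [1] 0.006882005
tajimas_d(conc)
#> [1] 0.8764123

# linkage on clone-corrected data
cc <- clone_correct(ds)
ia_permutation_test(cc, loci = sym, n_perm = 1000, seed = 1)
#> <ia_result> I_A = 2.173, p = 0.000999 (1000 permutations, clone-corrected)

# clade II mismatch distribution: sudden-expansion fit with bootstrap
cl   <- ds$meta$clade[match(names(conc$seq), ds$meta$strain)]
cII  <- conc; cII$seq <- conc$seq[cl == "CII"]
fit  <- fit_mismatch(observed_mismatch(cII), "demographic_expansion")
fit  <- bootstrap_gof(length(cII$seq), fit, B = 200, seed = 2, n_loci = 5)
fit
#> <mismatch_fit> demographic_expansion: tau = 0.4588, theta0 = 0.02315, theta1 = 0.7169; SSD = 1.899e-05, raggedness = 0.2692
#>   bootstrap: p(SSD) = 0.765, p(raggedness) = 0.555, tau 95% CI [9.48e-12, 1.48]
tau_to_generations(fit$params[["tau"]], mu_per_site = 1e-8, L = conc$length)
#> [1] 6934.357
```

The fitted τ ≈ 0.46 mutational steps converts to an expansion roughly
6,900 generations ago; the generator's truth (3,690) lies inside the
bootstrap interval (0 to ~22,000 generations), and the p-values show the
expansion model is compatible with the spectrum. Model choice between
the shipped divergence scenarios:

```r
models <- builtin_models()[c("model_09", "model_10", "model_14a")]
obs    <- summary_stats(ds, loci = sym)
tabs   <- lapply(models, function(m)
  build_reference_table(m, n_sims = 5000, seed = 3))
rej    <- abc_reject(obs, tabs, retain_frac = 0.01)
glm_model_choice(rej)
#> <model_choice>
#>   model_09: posterior 0.913 (rejection 0.407, 61 retained)
#>   model_10: posterior 0.087 (rejection 0.293, 44 retained)
#>   model_14a: posterior 0.000 (rejection 0.300, 45 retained)
```

On this single synthetic dataset the stepwise model edges out the
trifurcation that generated it — the two are observationally equivalent
when the stepwise model's two split times coincide, and at 5,000
simulations per model the flexible model can absorb that boundary case.
The ghost-deme scenario is firmly rejected. The package's validation
tools quantify exactly this: across 100 pseudo-observed trifurcation
datasets at 20,000 simulations per model (`validate_model_choice()`, run
in the test suite), the trifurcation model wins the majority of the time.

A thin command-line wrapper exposes the same pipeline
(`exec/rhizopop synth|stats|linkage|network|mismatch|simulate|abc`); every
run writes a manifest with the package version, seed and argument hash,
and identical seeds give byte-identical outputs.

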