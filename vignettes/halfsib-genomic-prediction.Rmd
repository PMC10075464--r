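---
title: "Genomic prediction in half-sib hybrid trials: models, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction in half-sib hybrid trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(halfsibGP)
```

## The design and its models

`halfsibGP` targets trials in which a panel of inbred lines (the male pool)
is test-crossed to one shared female line, giving one F1 hybrid per male.
Because the parents are homozygous, the hybrid genotype is fully determined:
the allele count at each SNP is the mean of the parental counts, so a cross
of 0 and 2 gives 1 and code 1 appears exactly where the parents disagree.

**Phenotype adjustment.** Replicated records from a randomized complete
block design are reduced to one value per genotype under the two-way
fixed-effects model value = genotype + block + error, with a sum-to-zero
constraint on blocks. The reported BLUE is the genotype coefficient on the
observation scale — for a balanced trial, the genotype's raw mean across
blocks. Shifting one block by a constant *c* moves every BLUE by *c/n_blocks*
(the average block effect); adjusted comparisons are invariant, which is
what blocking is for.

**Heterosis.** Per hybrid, Hp = 2(F1 − MP)/|P1 − P2| with MP the mid-parent
value. Classes: Hp > 1 high-parent heterosis, 0 ≤ Hp ≤ 1 mid-parent, −1 ≤
Hp < 0 low-parent, Hp < −1 hybrid inferiority. Hp = 0 (an F1 exactly at the
mid-parent) is grouped with the non-negative class — the class intervals
otherwise leave it unassigned. Equal parents make Hp undefined; such hybrids
are flagged and excluded from class proportions rather than failing the run.

**Relationship matrices.** `grm_vanraden()` is W Wᵀ / (2 Σ p(1−p)) with W
column-centered allele counts; `grm_yang()` standardizes per marker and uses
the inbreeding-corrected diagonal; `epistatic_kernel()` is the Hadamard
square of an additive GRM (additive-by-additive epistasis). By the package's
defaults the VanRaden kernel drives prediction and the Yang kernel drives the
GWAS background, following the respective conventions.

**GWAS.** The scan is the single-fit ("EMMAX-style") mixed linear model: the
variance components of intercept + ancestry PCs + polygenic(A) + residual
are estimated once by REML, then every marker gets a generalized
least-squares effect and Wald p-value with the covariance frozen. The exact
per-marker update scheme of the originally used tool is internal to it;
calibration properties (type-I error at the thresholds actually swept) are
what the tests pin down. Thresholds are raw p-values by design — the
threshold grid is itself a tuning axis of the MAS study, so no
multiple-testing correction is applied.

**Predictors.** Mid-parental value (no training, hence a single accuracy);
two-step MAS (OLS of the BLUE on all TA-SNPs jointly, minimum-norm when rank
deficient — this deliberately reproduces the accuracy collapse at liberal
thresholds instead of erroring); kernel BLUP with any number of kernels
(GBLUP, EGBLUP, TA-random-partition) by AI-REML with EM fallback
(tolerance 1e-6, 200 iterations; single-kernel fits use an exact 1-D
eigen-profile which is faster and stable at small n); or Gibbs sampling with
each kernel rewritten as regression on its scaled eigenvectors. BayesB
(point mass + scaled-t slab, fixed inclusion probability π = 0.05, slab df
4) and BayesR (normal mixture with relative variances 0, 1e-4, 1e-3, 1e-2
of a genetic variance scalar updated each sweep; Dirichlet-updated
proportions) run as C++ single-site Gibbs samplers. The default schedule is
30,000 sweeps / 5,000 burn-in / thin 5; tests use shorter seeded chains and
verify chain agreement rather than sampler identity.

**Covariates.** The mid-parental covariate scenario adds the hybrid's
mid-parent BLUE as a fixed regressor for training and test hybrids alike.
TA-SNPs can instead enter as fixed effects, represented by their principal
components explaining ≥ 95% of TA-SNP variance (the "effective number"),
with the remaining markers forming the random kernel — TA-SNPs are excluded
from that kernel to avoid double counting, a documented interpretation the
fitter exposes.

## Genomic heritability and kernel scale

`genomic_heritability()` is the plain ratio σa²/(σa² + σe²). The ratio is
only as interpretable as the kernel's scale: for fully inbred {0,2} panels
the VanRaden GRM has mean diagonal near 2, so the raw ratio understates the
realized-variance heritability by construction. `estimate_genomic_h2()`
therefore normalizes the kernel to unit mean diagonal before REML — a
standard move that leaves all BLUP predictions untouched and puts σa² on the
scale of the realized genetic variance. With that convention the estimator
recovers a simulated single-replicate h² = 0.8 within ±0.05 (10 seeds,
n = 402, m = 2000).

## Cross-validation scenarios

The 401-hybrid population is split evenly into five folds (sizes 81, 80,
80, 80, 80). Per test fold: S1 trains on the parents of the reference
(non-test) hybrids; S2 on the reference hybrids; S3 adds their parents; S4
adds all lines; S5 adds the parents of the test hybrids. The shared female
is counted once in every parent set (the source design never states this;
it is switch-free here but logged). Accuracy is one Pearson correlation per
repeat over the combined five test folds; accuracies are compared on the
Fisher-z scale with Welch t-tests (the source says only "t-test") and
two-way ANOVA with interaction. Training-set subsampling thins the
reference hybrids to a rate grid {5, 10, 20, 40, 60, 80, 100}% — the union
of the two grids the source text mentions — with S1 using the parents of
the sampled hybrids. Per-repeat seeds derive from the master seed so
scenarios share fold splits within a repeat, enabling paired comparisons;
rate 100% reproduces the plain run bit-for-bit.

## What the synthetic generator emulates — and what it does not

`simulate_parents()` draws homozygous lines with per-marker MAF in a chosen
band and first-order chain LD: each allele copies its left neighbour with
probability `ld_decay`, else is drawn fresh. This gives `ld_prune()`
something real to prune and makes genomic kernels identifiable, but it is
deliberately minimal: there are no recombination maps, no family or
subpopulation structure, and no selection history. Trait architectures are
additive by default, with optional dominance (expressed in heterozygotes
only, hence only in hybrids — in the single-female design the dominance
profile is collinear with the male additive profile, so it is absorbed, not
separable, exactly as the design implies) and additive-by-additive pairs.
Residual variance is solved empirically from the realized genetic variance
so the single-replicate line heritability equals `target_h2` under any LD;
negative phenotypes are allowed. Blocks are RCBD with three replicates by
default; the baseline trait value is 2 (a mesocotyl-like cm scale).

A green synthetic test therefore establishes internal correctness and the
qualitative behaviour of the estimators in a clean world; it does not
establish that real panels (with structure, ascertainment and
genotype-by-environment effects) will show the same accuracy levels.

Two findings from this clean world are worth recording:

1. **REML identifiability.** With an i.i.d. zero-LD panel the hybrid-block
   kernel of unrelated males is nearly isotropic, and REML on ~100 hybrids
   frequently hits the σa² = 0 boundary (the standard error of a
   GREML heritability on unrelated samples at that size is ≈ 0.4),
   collapsing predictions to a constant. The acceptance worlds therefore
   use the design's full size (402 lines) and `ld_decay = 0.6`.
2. **Why hybrids beat their parents as a training set only with
   dominance.** Under pure additivity the shared female contributes a
   constant half-genotype: the hybrids' extra relatedness to test hybrids
   has no predictive variance (a constant kernel block is annihilated by
   the GLS intercept), while line phenotypes carry the same male-marker
   information at twice the amplitude and higher heritability — so S1
   outperforms S2, and the corresponding additive acceptance assertion is
   left red by design. With dominance present (degree ≈ 1), hybrid
   phenotypes gain a component only hybrid training sets can learn, and S2
   decisively overtakes S1 (a green property test demonstrates this). This
   matches the mechanism the source study itself offers for its real-data
   ordering.

## Numerical choices and degenerate inputs

- REML: AI steps with step-halving backtracking and EM fallback, component
  floor at 1e-9 of var(y), convergence at 1e-6 log-likelihood change or
  1e-8 relative parameter change; boundary fits are clamped to zero.
- Kernels are checked positive semidefinite by Cholesky with a 1e-8 jitter;
  failures error rather than silently deform the model.
- Constant responses yield a flagged degenerate fit, not a crash; constant
  predictions yield a flagged undefined accuracy; |r| = 1 yields an
  infinite Fisher z with a warning.
- Mode imputation ties go to the lower code; LD-prune conflicts keep the
  higher-MAF marker, ties the lower position; both rules are deterministic
  so runs are bit-reproducible.
- Monomorphic markers: excluded with a warning from the Yang GRM, flagged
  with p = 1 in the GWAS, and rejected (zero denominator) by the VanRaden
  GRM when the whole panel is monomorphic.

## Known limitations

Dominance and additive effects cannot be separated in this design and no
attempt is made; there is no VCF support, no haplotype imputation, no
spatial field models, and no optimal training-set selection. The Bayesian
samplers aim at the canonical algorithms, not at numerical identity with
any named implementation. Reproduction of the source study's headline
numbers requires its supplementary tables, which have no public download
endpoint; `reproduce_published_analysis()` performs that computation when
the user supplies them.
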