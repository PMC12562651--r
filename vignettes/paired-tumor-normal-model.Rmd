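---
title: "Modeling somatic relative risk from paired tumor–normal genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling somatic relative risk from paired tumor–normal genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedgwas)
```

## The model

A matched-pair cancer study genotypes both tumor and adjacent normal
tissue from every patient. For a biallelic SNP the data per marker reduce
to a 3×3 table of counts `n_ij` (normal genotype *i*, tumor genotype
*j*, risk-allele dosage 0/1/2), and the sample of patients gives the
table a multinomial distribution over nine cells.

Three parameters generate the cell probabilities:

* `A ∈ (0,1)` — the population risk-allele frequency. Under genetic
  equilibrium the normal genotype follows Hardy–Weinberg proportions
  `((1−A)², 2A(1−A), A²)`.
* `M ∈ (0,1)` — the per-allele somatic mutation rate. Each allele flips
  independently between tissue types, giving a 3×3 row-stochastic
  transition matrix `T(M)`; for example, a heterozygote stays
  heterozygous with probability `M² + (1−M)²` (no alteration, or both
  alleles altered).
* `R > 0` — the somatic relative risk. The penetrance ratio per tumor
  genotype is `(1, (R+1)/2, R)` under the additive model (the
  heterozygote risk is the mean of the homozygote risks); dominant
  `(1, R, R)`, recessive `(1, 1, R)` and multiplicative `(1, R, R²)`
  variants are available behind the `risk_model` argument. The risk
  weights multiply the **tumor** genotype columns: patients are sampled
  from the diseased population, so cells leading to higher-risk tumor
  genotypes are over-represented.

The cell probability is the normalized product
`P_ij = g_i(A) T_ij(M) R_j / qsum`. `qsum` is always computed as the sum
of the nine unnormalized weights (no simplified closed form is assumed),
and equals 1 exactly when `R = 1`, in which case the model factorizes
into the genotype prior times the transition matrix.

### Moment equations and enrichment corrections

Two observable summaries anchor everything downstream: the sample allele
frequency `Â = (n10+n11+n12+2(n20+n21+n22))/(2n)` and the sample
mutation rate `M̂ = (n01+2n02+n10+n12+2n20+n21)/(2n)`. Their model
expectations are rational functions of `(R, A, M)` implemented in
`expected_allele_freq()` and `expected_mutation_rate()`; both reduce to
the identity at `R = 1`.

One subtlety is documented here deliberately: the expectation used for
the mutation rate counts allele-level mutation *events*, so the
double-alteration component of the heterozygote→heterozygote cell
contributes two events although the net genotype change — what `M̂`
can actually observe — is zero. The two notions differ by a term of
order `M²` (exactly `A M² (1−A)(R+1)/qsum`), which is negligible at
somatic rates of 10⁻³–10⁻², and the event-counting form has the
property `E(M̂ | R = 1) = M` that the prior construction relies on. The
test suite checks the implemented expectation against an event-weighted
moment of the cell distribution.

For an associated SNP, the population frequency `A` is *lower* than the
patient-sample frequency `Â` (risk alleles are enriched among
patients). `solve_enriched_af()` and `solve_enriched_mr()` invert the
expectation maps: they solve the quadratic obtained from
`E(Â) = Â` (respectively `E(M̂) = M̂`) for the population parameter.
Numerical choices:

* the quadratics were re-derived symbolically from the expectation
  functions; the root is chosen as the one in `(0,1)` that satisfies the
  fixed point, preferring the root continuous with the neutral limit;
* the equations have removable singularities at `R = 1` (both) and at
  `M = 0.5` / `A = 0.5` (respectively). When the leading coefficient
  vanishes (|a₂| < 1e-8) the linear limit is used, with a guarded
  bisection fallback on the defining moment equation. The contract is the
  fixed-point property (satisfied to 1e-8), not any particular printed
  radical.

## Penalized maximum likelihood

`paired_mle()` maximizes the multinomial log-likelihood plus boundary
penalties

```
− λ[log²A + log²(1−A) + log²M + log²(1−M)] − α log²R
```

with `λ = α = 0.05` by default. `log²x` is the *squared natural
logarithm*: a squared log diverges at every boundary of the open box and
therefore keeps the estimate interior on both sides, which a linear
base-2 logarithm would not do symmetrically (for `R` it diverges on one
side only). A squared base-2 reading is available via
`penalty_base2 = TRUE`. The single stated tuning value 0.05 is applied to
both weights; they are independently configurable.

Optimization runs in unconstrained coordinates `(log R, logit A,
logit M)` with BFGS and five starts: a moment-based start (`R = 1`,
`A = Â`, `M = M̂`) plus random perturbations. The covariance of the
estimate is the inverse *expected* information
`I(θ) = n Σ_ij (∂P_ij/∂θ)(∂P_ij/∂θ)ᵀ / P_ij` at the optimum, with cell
gradients by central differences; a singular information matrix falls
back to a pseudo-inverse and is flagged.

Three tests of `H0: R = 1` are provided. The test statistics use the
*unpenalized* likelihood, score and information evaluated at the
penalized estimates — the penalty is a regularizer for estimation, not
part of the sampling model. The score test's nuisance parameters default
to the full-model MLE (a literal reading of "replaced by the MLE");
`nuisance = "null"` re-estimates them under the restriction. The
likelihood-ratio statistic is clipped at zero because the penalized full
fit is not guaranteed to dominate the restricted fit in unpenalized
likelihood. All three are referred to χ²₁.

A probability floor of 1e-300 is applied before logging only for cells
with zero count; a positive count on a zero-probability cell returns
−∞ rather than an exception, so optimizers and samplers treat it as an
ordinary rejection.

## The hierarchical Bayesian model

For a set of `J` SNPs (a gene, or a gene segment) the latent structure
is: `G ~ Bernoulli(b)` for the set, `b ~ Beta(α_b, β_b)` with default
`(1, 4)` — prior mean 0.2, encoding that few genes are associated;
`H_j | G ~ Bernoulli(p1^G p0^(1−G))` with defaults `p0 = 0.1`,
`p1 = 0.9`; and given `H_j`, independent priors on `(R_j, A_j, M_j)`:

* `R_j | H_j = 0 ~ Gamma(3, 3)` (shape/rate, mean 1);
  `R_j | H_j = 1 ~ Gamma(3, 3/m₁)` with the prior mean `m₁` anchored at
  the average of the per-SNP penalized-MLE relative risks, floored at
  1.1. The Gamma parameters are read as shape/rate throughout: that is
  the only reading under which a mean-one Gamma(3,3) is consistent, and
  the stated mean constraints (neutral mean 1, associated mean > 1)
  outrank any particular tuple. A literal fixed rate remains available
  via `prior_config(r_rate1 = ...)`.
* `A_j | H_j` and `M_j | H_j` are Beta with means at the observed values
  (`Â_j`, `M̂_j`, clipped to `[1/(2n), 1−1/(2n)]`) for the neutral
  branch and at the enrichment-corrected solutions of the moment
  equations for the associated branch. Only the means are pinned down by
  the construction; the concentration is a design choice, default
  `κ = 50` (shapes `mκ` and `(1−m)κ`), weakly informative around the
  empirical anchor.

Posterior sampling is Gibbs-within-Metropolis: per iteration,
component-wise Gaussian random-walk Metropolis updates of `(log R_j,
logit A_j, logit M_j)` (Jacobian-corrected, proposal SD 0.3 on the
transformed scale), then exact Gibbs draws of each `H_j` (log-space
branch-density ratio), of `G` (product-Bernoulli odds), and of `b`
(Beta conjugacy: `Beta(α_b + G, β_b + 1 − G)`). The full conditionals
were re-derived from the joint density; `log_joint()` exposes the joint
for verification, and the tests check the conditionals against direct
normalization of it. The inner loop is compiled (Rcpp) and uses the R
random number generator, so `set.seed()` makes entire fits bit-for-bit
reproducible.

The schedule default is 6000 iterations per restart, 1000 burn-in,
thinning 5, and 3 restarts whose post-burn-in draws are pooled. Restart
one starts at the null-anchored moment estimates (`R = 1`, `A = Â`,
`M = M̂`, `H = 0`, `G = 0`, `b` at its prior mean); the other restarts
start from prior draws, giving one null-anchored chain plus dispersed
chains. No adaptation takes place after burn-in, so the post-burn-in
kernel is a valid MCMC kernel. Decisions use the posterior median of
`H_j` (equivalently: posterior mean > 0.5); point estimates of `R_j` are
posterior medians, and the set-level summary reports both the mean and
the median of `G`.

For `J = 1` the same code is the single-marker model. Correctness of the
sampler is tested against brute-force quadrature: for a single SNP the
marginal likelihood of each association branch is integrated on a
quantile-midpoint grid under the branch priors, combined with the exact
discrete `(H, G)` prior (the `b` hyperprior integrates out in closed
form on its own quantile grid), and the MCMC posterior `P(H = 1)` must
agree within 0.05 total variation.

## The simulator and what the tests show

`simulate_paired_counts()` draws one multinomial sample of size `n` from
the model cells; `simulate_gene()` draws `J` independent SNPs sharing
`(R, A, M)`. The default study grid crosses n ∈ {1000, 3000},
A ∈ {0.05, 0.1, 0.2}, M ∈ {0.001, 0.005}, R ∈ {1, 2, 3} with 4-SNP
genes and 100 replicates — the factorial design of the power study this
package reproduces. SNPs are simulated *without* linkage disequilibrium,
matching that design; this is a fidelity limit: real SNP sets within a
segment are correlated, so passing tests say nothing about LD-induced
miscalibration. Tumor purity, subclonality and copy-number states beyond
{0, 1, 2} are likewise outside the model.

Replicates are seeded by deterministic substreams of a master seed, so
studies are reproducible and order-independent.

Problem sizes in the shipped tests are the package's own choices:
Bayesian grid cells run 50 replicates with shortened pooled chains (2500
iterations, 500 burn-in, thinning 2, 2 restarts), penalized-MLE cells
100 replicates; the oracle-equivalence checks use n = 50 with long
pooled chains (20,000 iterations × 2 restarts) so the Monte Carlo error
stays well inside the 0.05 bound being tested.

## Known limitations

* **Hyperparameter sensitivity in weak-information regimes.** With the
  defaults above, the posterior of `H` in settings with small samples,
  rare alleles and moderate effects (for example n = 1000, A = 0.1,
  R = 2) concentrates near its prior, and the median-based decision is
  conservative: type I error is near zero and power for moderate effects
  is low, while strong-signal settings are detected with probability
  near one. The decision boundary in these regimes is driven mainly by
  the Beta concentration `κ` and the associated-branch Gamma anchoring
  rather than by the likelihood, so differently calibrated prior choices
  can shift rejection rates substantially in either direction. The
  defaults here favor conservatism and are deliberately not tuned per
  dataset.
* The Wald test inherits the usual small-sample inflation of
  likelihood-based tests in this model (type I error well above the
  nominal 0.05 at n = 1000 with rare alleles); the simulation harness
  measures this directly.
* Segment-level fits with a single SNP reduce to the single-marker model
  by construction.
* The gene-score aggregation reads "largest segment" as the
  largest-*scoring* segment, consistent between the single-marker
  (mean-then-max) and multi-marker (max) paths; picking the physically
  longest segment instead is available via `rule = "longest"`.
* The 1 kb flank is applied before segmentation, and a SNP mapping to
  several overlapping genes is scored in every one of them; both choices
  are conventions where the procedure is underdetermined.
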