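# pairedgwas

Association testing for **paired tumor–normal genotype data**.

In a matched-pair cancer design every patient contributes two genotypes at
each SNP: a germline (normal-tissue) genotype and a tumor genotype. The
unit of analysis is the 3×3 cross-tabulation of these genotypes,
`n_ij` = number of patients with normal genotype *i* and tumor genotype
*j* (risk-allele dosage 0/1/2). Standard case–control GWAS machinery does
not apply because the "cases" and "controls" are the same people.
`pairedgwas` implements a model-based framework for this design:

- **A 9-cell multinomial model.** The probability of the paired genotype
  (*i*, *j*) in the patient population is

  `P_ij ∝ g_i(A) · T_ij(M) · R_j`

  where `g(A) = ((1−A)², 2A(1−A), A²)` is the Hardy–Weinberg genotype
  prior at risk-allele frequency *A*; `T(M)` is the somatic transition
  matrix under independent per-allele alteration at rate *M* (e.g., row 0
  is `((1−M)², 2M(1−M), M²)`); and `R = (1, (R+1)/2, R)` is the additive
  genotype relative-risk vector acting on the tumor genotype. The
  normalization constant `qsum` makes the nine cells sum to one, and
  equals 1 exactly when `R = 1`.
- **Penalized maximum likelihood** for `(R, A, M)` per SNP, with squared-log
  boundary penalties (ridge coefficient 0.05 by default), and Wald, score
  and likelihood-ratio tests of `H0: R = 1`, each asymptotically χ²₁.
- **A hierarchical Bayesian model** for SNP sets (genes or ≤32 kb gene
  segments): latent per-SNP association indicators `H_j`, a set-level
  indicator `G` with `P(H_j = 1 | G) = p1^G p0^(1−G)`, and a Beta
  hyperprior on the set-level probability `b`. Spike/slab-style Gamma and
  Beta priors on `(R_j, A_j, M_j)` are anchored at the observed allele
  frequency and mutation rate (neutral branch) or their
  enrichment-corrected values (associated branch). Inference is
  Gibbs-within-Metropolis MCMC with a compiled inner loop; single-marker
  analysis is the `J = 1` special case.
- **A simulator and study harness** reproducing the factorial power /
  type I error design (n ∈ {1000, 3000}, A ∈ {0.05, 0.1, 0.2},
  M ∈ {0.001, 0.005}, R ∈ {1, 2, 3}, 4-SNP genes).
- **Genome-scale plumbing**: Hardy–Weinberg and allele-frequency QC,
  refFlat-based SNP→gene mapping with 1 kb flanks, balanced segmentation
  of long genes into ≤32,000 bp tiles, and segment→gene score
  aggregation.

All user-facing functions are data-frame-first and return tibbles;
fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a 4-SNP gene for 3000 patients with a strong somatic effect
(R = 3, A = 0.2, M = 0.005), then analyze it both ways:

```r
library(pairedgwas)
set.seed(2026)
gene <- simulate_gene(n_snps = 4, n = 3000, R = 3, A = 0.2, M = 0.005)

fit_mle_snps(gene, tests = "wald")
#>   snp_id R_hat A_hat   M_hat  se_R stat_wald     p_wald
#> 1 snp1    3.10 0.192 0.00453 0.489      18.5 0.0000170
#> 2 snp2    3.35 0.196 0.00321 0.504      21.7 0.00000311
#> 3 snp3    2.94 0.201 0.00419 0.477      16.6 0.0000464
#> 4 snp4    2.45 0.216 0.00580 0.437      10.9 0.000942

fit <- fit_bayes(gene)
fit
#> Hierarchical Bayesian SNP-set fit ( 4 SNPs, 3000 pooled draws )
#>   P(G = 1 | data) = 0.996   E(b | data) = 0.329
#>   snp_id H_mean H_median R_median A_median M_median
#> 1 snp1    0.996        1     3.19    0.190  0.00436
#> 2 snp2    0.998        1     3.36    0.196  0.00311
#> 3 snp3    0.996        1     2.93    0.202  0.00411
#> 4 snp4    0.979        1     2.52    0.212  0.00566
```

Every SNP's penalized-MLE relative risk `R_hat` lands near the simulated
value 3 with a small Wald p-value, and the Bayesian model flags all four
SNPs (`H_median = 1`, posterior `P(H_j = 1)` ≈ 0.98–1.00) and the gene
itself (`P(G = 1 | data) = 0.996`). Each SNP's posterior median relative
risk (`R_median`) again recovers the simulated effect.

A thin command-line wrapper is installed with the package
(`inst/scripts/pairedgwas`) exposing `simulate`, `fit-mle`, `bayes` and
`benchmark` subcommands over the same functions.

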