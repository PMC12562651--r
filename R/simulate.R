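# Simulation of paired tumor-normal genotype data and the power /
# type I error study harness.

#' Simulate one paired genotype table
#'
#' A single multinomial draw of size `n` over the nine cells of
#' [paired_probabilities()].
#'
#' @param n Number of patient pairs.
#' @inheritParams paired_probabilities
#' @return Named integer vector of the nine counts in canonical order.
#' @export
#' @examples
#' set.seed(1)
#' simulate_paired_counts(n = 1000, R = 3, A = 0.2, M = 0.005)
simulate_paired_counts <- function(n, R, A, M, risk_model = "additive") {
  stopifnot(n >= 1)
  P <- as.numeric(t(paired_probabilities(R, A, M, risk_model)))
  stats::setNames(as.integer(stats::rmultinom(1, n, P)), COUNT_COLS)
}

#' Simulate a gene of independent SNPs
#'
#' Draws `n_snps` independent paired genotype tables sharing the same
#' `(R, A, M)`. SNPs are simulated without linkage disequilibrium, matching
#' the generative design of the simulation study.
#'
#' @param n_snps Number of SNPs on the gene.
#' @inheritParams simulate_paired_counts
#' @param gene_id Identifier stored in the `gene_id` column.
#' @return Tibble with one row per SNP: `gene_id`, `snp_id`, and the nine
#'   count columns.
#' @export
simulate_gene <- function(n_snps = 4, n = 3000, R = 1, A = 0.2, M = 0.005,
                          risk_model = "additive", gene_id = "gene1") {
  rows <- purrr::map(seq_len(n_snps), function(j) {
    cts <- simulate_paired_counts(n, R, A, M, risk_model)
    tibble::tibble(gene_id = gene_id, snp_id = paste0("snp", j),
                   !!!as.list(cts))
  })
  dplyr::bind_rows(rows)
}

#' Default simulation grid of the power study
#'
#' Crossed settings: sample sizes 1000 and 3000; allele frequencies 0.05,
#' 0.1, 0.2; mutation rates 0.001 and 0.005; relative risks 1, 2, 3; genes
#' of 4 SNPs; 100 replicates per setting.
#'
#' @param n,A,M,R,n_snps,reps Vectors of setting values to cross.
#' @return Tibble of settings, one row per combination.
#' @export
simulation_grid <- function(n = c(1000, 3000), A = c(0.05, 0.1, 0.2),
                            M = c(0.001, 0.005), R = c(1, 2, 3),
                            n_snps = 4, reps = 100) {
  tidyr::expand_grid(n = n, A = A, M = M, R = R, n_snps = n_snps, reps = reps)
}

# Deterministic 31-bit substream seed for (setting, replicate).
replicate_seed <- function(master_seed, setting_index, rep_index) {
  as.integer((as.numeric(master_seed) * 48271 + setting_index * 104729 +
                rep_index * 7919) %% 2147483647L) + 1L
}

#' Run the simulation study
#'
#' For every setting of `grid` and every replicate, simulates a gene of
#' independent SNPs and applies the requested methods: the penalized-MLE
#' Wald test (per SNP, reject when `p < alpha`), the single-marker
#' Bayesian model (per SNP, `J = 1`), and the multi-marker Bayesian model
#' (all SNPs jointly); Bayesian decisions are the posterior median of the
#' SNP association indicator. Replicates are seeded from `seed` via
#' deterministic substreams.
#'
#' @param grid Settings tibble as from [simulation_grid()].
#' @param methods Character subset of
#'   `c("mle", "bayes_single", "bayes_multi")`.
#' @param alpha Nominal level of the likelihood-based test.
#' @param seed Master seed.
#' @param mcmc [mcmc_config()] for the Bayesian fits.
#' @param verbose Print progress per setting.
#' @return Tibble with one row per (setting, replicate, SNP, method):
#'   setting columns, `rep`, `snp`, `method`, `reject` (logical) and
#'   `R_hat`, plus a `failed` flag for replicates a method could not fit.
#' @export
run_simulation_study <- function(grid, methods = c("mle", "bayes_single",
                                                   "bayes_multi"),
                                 alpha = 0.05, seed = 1,
                                 mcmc = mcmc_config(), verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- vector("list", nrow(grid))
  for (s in seq_len(nrow(grid))) {
    g <- grid[s, ]
    if (verbose) {
      message(sprintf("setting %d/%d: n=%d A=%.2f M=%.3f R=%g",
                      s, nrow(grid), g$n, g$A, g$M, g$R))
    }
    rows <- vector("list", g$reps)
    for (r in seq_len(g$reps)) {
      set.seed(replicate_seed(seed, s, r))
      gene <- simulate_gene(g$n_snps, g$n, g$R, g$A, g$M)
      rows[[r]] <- evaluate_methods_once(gene, methods, alpha, mcmc)
      rows[[r]]$rep <- r
    }
    res <- dplyr::bind_rows(rows)
    res$n <- g$n; res$A <- g$A; res$M <- g$M; res$R <- g$R
    out[[s]] <- res
  }
  dplyr::bind_rows(out) |>
    dplyr::select("n", "A", "M", "R", "rep", "snp", "method", "reject",
                  "R_hat", "failed")
}

evaluate_methods_once <- function(gene, methods, alpha, mcmc) {
  J <- nrow(gene)
  res <- list()
  if ("mle" %in% methods) {
    fit <- tryCatch(fit_mle_snps(gene, tests = "wald"), error = function(e) NULL)
    res$mle <- if (is.null(fit)) {
      tibble::tibble(snp = gene$snp_id, method = "mle", reject = NA,
                     R_hat = NA_real_, failed = TRUE)
    } else {
      tibble::tibble(snp = gene$snp_id, method = "mle",
                     reject = fit$p_wald < alpha, R_hat = fit$R_hat,
                     failed = FALSE)
    }
  }
  if ("bayes_multi" %in% methods) {
    fit <- tryCatch(fit_bayes(gene, mcmc = mcmc), error = function(e) NULL)
    res$bm <- if (is.null(fit)) {
      tibble::tibble(snp = gene$snp_id, method = "bayes_multi", reject = NA,
                     R_hat = NA_real_, failed = TRUE)
    } else {
      tibble::tibble(snp = fit$snp$snp_id, method = "bayes_multi",
                     reject = fit$snp$H_median == 1, R_hat = fit$snp$R_median,
                     failed = FALSE)
    }
  }
  if ("bayes_single" %in% methods) {
    rows <- purrr::map(seq_len(J), function(j) {
      fit <- tryCatch(fit_bayes(gene[j, ], mcmc = mcmc),
                      error = function(e) NULL)
      if (is.null(fit)) {
        tibble::tibble(snp = gene$snp_id[j], method = "bayes_single",
                       reject = NA, R_hat = NA_real_, failed = TRUE)
      } else {
        tibble::tibble(snp = gene$snp_id[j], method = "bayes_single",
                       reject = fit$snp$H_median == 1,
                       R_hat = fit$snp$R_median, failed = FALSE)
      }
    })
    res$bs <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(res)
}

#' Summarize a simulation study into rejection rates and MSE
#'
#' @param results Output of [run_simulation_study()].
#' @return Tibble per (setting, SNP, method): `rejection_rate` (type I
#'   error when `R = 1`, power otherwise), `mse_R` of the relative-risk
#'   estimate, and counts of replicates and failures.
#' @export
summarize_simulation_study <- function(results) {
  results |>
    dplyr::group_by(.data$n, .data$A, .data$M, .data$R, .data$snp,
                    .data$method) |>
    dplyr::summarise(
      rejection_rate = mean(.data$reject[!.data$failed]),
      mse_R = mean((.data$R_hat[!.data$failed] - .data$R)^2),
      reps = dplyr::n(),
      failures = sum(.data$failed),
      .groups = "drop"
    )
}
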