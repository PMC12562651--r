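# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a penalized MLE fit
#'
#' @param x A [paired_mle()] object.
#' @param ... Unused.
#' @return One-row-per-parameter tibble with `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.paired_mle <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  tibble::tibble(term = c("R", "A", "M"),
                 estimate = c(x$R, x$A, x$M),
                 std.error = se)
}

#' Model-level summary of a penalized MLE fit
#'
#' @inheritParams tidy.paired_mle
#' @return One-row tibble with `n`, `loglik`, `penalized_loglik`,
#'   `converged`, `n_starts_used`.
#' @export
glance.paired_mle <- function(x, ...) {
  tibble::tibble(n = x$n, loglik = x$loglik,
                 penalized_loglik = x$penalized_loglik,
                 converged = x$converged, n_starts_used = x$n_starts_used)
}

#' Tidy a hierarchical Bayesian SNP-set fit
#'
#' @param x A [fit_bayes()] object.
#' @param ... Unused.
#' @return Per-SNP posterior summary tibble (`snp_id`, `H_mean`,
#'   `H_median`, `R_median`, `A_median`, `M_median`).
#' @export
tidy.paired_bayes <- function(x, ...) x$snp

#' Set-level summary of a hierarchical Bayesian fit
#'
#' @inheritParams tidy.paired_bayes
#' @return One-row tibble with the posterior mean and median of the
#'   set-level indicator `G`, the posterior mean of `b`, the number of
#'   SNPs and pooled draws.
#' @export
glance.paired_bayes <- function(x, ...) {
  dplyr::mutate(x$set, n_snps = nrow(x$snp), n_draws = nrow(x$draws$R))
}
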