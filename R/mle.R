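# Penalized maximum-likelihood estimation of (R, A, M) and the three
# frequentist tests of H0: R = 1.

#' Penalized log-likelihood of a paired genotype table
#'
#' The multinomial log-likelihood plus boundary penalties
#' `- lambda [log^2 A + log^2(1-A) + log^2 M + log^2(1-M)] - alpha log^2 R`,
#' where `log^2 x` is the squared natural logarithm (default) or squared
#' base-2 logarithm when `penalty_base2 = TRUE`. Every penalty term diverges
#' as its parameter approaches a boundary of the open box, keeping the
#' optimizer interior.
#'
#' @inheritParams paired_loglik
#' @param lambda Penalty weight on the `A` and `M` boundary terms.
#' @param alpha Penalty weight on the `R` boundary term.
#' @param penalty_base2 If `TRUE`, use squared base-2 logarithms in the
#'   penalty instead of squared natural logarithms.
#' @return Scalar penalized log-likelihood.
#' @export
penalized_loglik <- function(R, A, M, counts, lambda = 0.05, alpha = 0.05,
                             risk_model = "additive", penalty_base2 = FALSE) {
  stopifnot(lambda >= 0, alpha >= 0)
  lg <- if (penalty_base2) log2 else log
  paired_loglik(R, A, M, counts, risk_model) -
    lambda * (lg(A)^2 + lg(1 - A)^2 + lg(M)^2 + lg(1 - M)^2) -
    alpha * lg(R)^2
}

theta_to_phi <- function(R, A, M) c(log(R), stats::qlogis(A), stats::qlogis(M))
phi_to_theta <- function(phi) {
  list(R = exp(phi[1]), A = stats::plogis(phi[2]), M = stats::plogis(phi[3]))
}

#' Expected Fisher information of the paired genotype model
#'
#' `I(theta) = n * sum_ij (1/P_ij) (dP_ij/dtheta)(dP_ij/dtheta)^T` over the
#' nine cells, `theta = (R, A, M)`, with cell-probability gradients by
#' central finite differences.
#'
#' @inheritParams paired_probabilities
#' @param n Sample size (number of patient pairs).
#' @return 3x3 matrix with dimnames `R`, `A`, `M`.
#' @export
expected_information <- function(R, A, M, n, risk_model = "additive") {
  check_param_domain(R, A, M)
  stopifnot(n > 0)
  theta <- c(R = R, A = A, M = M)
  P <- as.numeric(paired_probabilities(R, A, M, risk_model))
  grad <- matrix(0, 9, 3)
  for (k in 1:3) {
    h <- 1e-6 * max(abs(theta[k]), 1e-3)
    up <- theta; up[k] <- up[k] + h
    dn <- theta; dn[k] <- dn[k] - h
    # keep perturbed A, M inside (0,1)
    up[2:3] <- pmin(up[2:3], 1 - 1e-12); dn[2:3] <- pmax(dn[2:3], 1e-12)
    Pu <- as.numeric(paired_probabilities(up[1], up[2], up[3], risk_model))
    Pd <- as.numeric(paired_probabilities(dn[1], dn[2], dn[3], risk_model))
    grad[, k] <- (Pu - Pd) / (up[k] - dn[k])
  }
  keep <- P > 1e-300
  info <- n * crossprod(grad[keep, , drop = FALSE] / sqrt(P[keep]))
  dimnames(info) <- list(c("R", "A", "M"), c("R", "A", "M"))
  info
}

#' Penalized MLE of (R, A, M) for one paired genotype table
#'
#' Maximizes [penalized_loglik()] over the open parameter box via an
#' unconstrained reparameterization `(log R, logit A, logit M)` and BFGS,
#' with multiple starts: a moment-based start (`R = 1`, `A` and `M` at
#' their observed values) plus random perturbations. The covariance of the
#' estimate is the inverse expected information (unpenalized sampling
#' model) at the optimum.
#'
#' @inheritParams penalized_loglik
#' @param n_starts Number of optimizer starts.
#' @return Object of class `paired_mle`: a list with elements `R`, `A`,
#'   `M`, `loglik` (unpenalized, at the optimum), `penalized_loglik`,
#'   `vcov`, `se_R`, `converged`, `n_starts_used`, `n`, and the call
#'   configuration.
#' @export
#' @examples
#' counts <- simulate_paired_counts(n = 2000, R = 2, A = 0.2, M = 0.005)
#' fit <- paired_mle(counts)
#' tidy(fit)
paired_mle <- function(counts, lambda = 0.05, alpha = 0.05, n_starts = 5,
                       risk_model = "additive", penalty_base2 = FALSE) {
  n <- as_paired_counts(counts)
  N <- sum(n)
  stopifnot(N > 0)
  clip <- function(x) pmin(pmax(x, 1 / (2 * N)), 1 - 1 / (2 * N))
  a_hat <- clip(observed_allele_freq(n))
  m_hat <- clip(observed_mutation_rate(n))

  negobj <- function(phi) {
    th <- phi_to_theta(phi)
    if (!is.finite(th$R) || th$A <= 0 || th$A >= 1 || th$M <= 0 || th$M >= 1) {
      return(.Machine$double.xmax)
    }
    v <- penalized_loglik(th$R, th$A, th$M, n, lambda, alpha, risk_model,
                          penalty_base2)
    if (!is.finite(v)) .Machine$double.xmax else -v
  }

  starts <- list(theta_to_phi(1, a_hat, m_hat))
  if (n_starts > 1) {
    for (k in seq_len(n_starts - 1)) {
      starts[[k + 1]] <- starts[[1]] + stats::rnorm(3, 0, 0.5)
    }
  }
  best <- NULL
  conv <- FALSE
  used <- 0L
  for (s in starts) {
    used <- used + 1L
    opt <- tryCatch(
      stats::optim(s, negobj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
    conv <- conv || (opt$convergence == 0)
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  th <- phi_to_theta(best$par)

  vcov <- matrix(NA_real_, 3, 3, dimnames = list(c("R", "A", "M"),
                                                 c("R", "A", "M")))
  info <- expected_information(th$R, th$A, th$M, N, risk_model)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  singular <- is.null(vc)
  if (singular) {
    ev <- eigen(info, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    vc <- ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
    dimnames(vc) <- dimnames(vcov)
  }
  vcov[] <- vc

  structure(list(
    R = th$R, A = th$A, M = th$M,
    loglik = paired_loglik(th$R, th$A, th$M, n, risk_model),
    penalized_loglik = -best$value,
    vcov = vcov, se_R = sqrt(max(vcov["R", "R"], 0)),
    converged = conv, singular_information = singular,
    n_starts_used = used, n = N, counts = n,
    lambda = lambda, alpha = alpha, risk_model = risk_model,
    penalty_base2 = penalty_base2
  ), class = "paired_mle")
}

#' @export
print.paired_mle <- function(x, ...) {
  cat("Paired tumor-normal penalized MLE (n =", x$n, ")\n")
  cat(sprintf("  R = %.4f (SE %.4f)   A = %.4f   M = %.5f\n",
              x$R, x$se_R, x$A, x$M))
  cat(sprintf("  log-likelihood %.3f   converged: %s\n",
              x$loglik, x$converged))
  invisible(x)
}

chisq1_p <- function(stat) stats::pchisq(stat, df = 1, lower.tail = FALSE)

#' Wald test of H0: R = R0
#'
#' `W = (R_hat - R0)^2 / var(R_hat)`, with the variance from the inverse
#' expected information at the penalized MLE; `W` is asymptotically
#' chi-squared with one degree of freedom under the null.
#'
#' @param fit A [paired_mle()] fit.
#' @param R0 Null relative risk (default 1, no association).
#' @return One-row tibble with `test`, `statistic`, `p_value`, `df`.
#' @export
wald_test <- function(fit, R0 = 1) {
  stopifnot(inherits(fit, "paired_mle"))
  v <- fit$vcov["R", "R"]
  if (!is.finite(v) || v <= 0) stop("non-positive variance of R estimate",
                                    call. = FALSE)
  W <- (fit$R - R0)^2 / v
  tibble::tibble(test = "wald", statistic = W, p_value = chisq1_p(W), df = 1L)
}

#' Score test of H0: R = R0
#'
#' The score `u(R0)` is the derivative in `R` of the unpenalized
#' log-likelihood at `R = R0` with `A` and `M` held at their estimates;
#' the statistic is `u(R0)^2 / I_R(R0)` with `I_R` the `(R, R)` entry of
#' the expected information at the same point.
#'
#' @inheritParams wald_test
#' @param nuisance `"full"` evaluates `A`, `M` at the joint penalized MLE;
#'   `"null"` re-estimates them with `R` fixed at `R0`.
#' @return One-row tibble with `test`, `statistic`, `p_value`, `df`.
#' @export
score_test <- function(fit, R0 = 1, nuisance = c("full", "null")) {
  stopifnot(inherits(fit, "paired_mle"))
  nuisance <- match.arg(nuisance)
  if (nuisance == "null") {
    nf <- paired_mle_fixed_R(fit$counts, R0, fit$lambda, fit$risk_model,
                             fit$penalty_base2)
    A <- nf$A; M <- nf$M
  } else {
    A <- fit$A; M <- fit$M
  }
  h <- 1e-6 * max(R0, 1e-3)
  u <- (paired_loglik(R0 + h, A, M, fit$counts, fit$risk_model) -
        paired_loglik(R0 - h, A, M, fit$counts, fit$risk_model)) / (2 * h)
  IR <- expected_information(R0, A, M, fit$n, fit$risk_model)["R", "R"]
  if (!is.finite(IR) || IR <= 0) stop("non-positive Fisher information",
                                      call. = FALSE)
  S <- u^2 / IR
  tibble::tibble(test = "score", statistic = S, p_value = chisq1_p(S), df = 1L)
}

# Restricted penalized fit with R fixed; optimizes (A, M) only.
paired_mle_fixed_R <- function(counts, R0, lambda, risk_model, penalty_base2) {
  n <- as_paired_counts(counts)
  N <- sum(n)
  clip <- function(x) pmin(pmax(x, 1 / (2 * N)), 1 - 1 / (2 * N))
  start <- c(stats::qlogis(clip(observed_allele_freq(n))),
             stats::qlogis(clip(observed_mutation_rate(n))))
  negobj <- function(phi) {
    A <- stats::plogis(phi[1]); M <- stats::plogis(phi[2])
    if (A <= 0 || A >= 1 || M <= 0 || M >= 1) return(.Machine$double.xmax)
    v <- penalized_loglik(R0, A, M, n, lambda, alpha = 0, risk_model,
                          penalty_base2)
    if (!is.finite(v)) .Machine$double.xmax else -v
  }
  opt <- stats::optim(start, negobj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  list(A = stats::plogis(opt$par[1]), M = stats::plogis(opt$par[2]))
}

#' Likelihood-ratio test of H0: R = R0
#'
#' `LR = 2 [l(theta_hat) - l(theta_hat_0)]` comparing the unpenalized
#' log-likelihood at the full penalized MLE against the restricted fit with
#' `R` fixed at `R0` (`A`, `M` re-optimized); clipped at zero.
#'
#' @inheritParams wald_test
#' @return One-row tibble with `test`, `statistic`, `p_value`, `df`.
#' @export
lr_test <- function(fit, R0 = 1) {
  stopifnot(inherits(fit, "paired_mle"))
  nf <- paired_mle_fixed_R(fit$counts, R0, fit$lambda, fit$risk_model,
                           fit$penalty_base2)
  l0 <- paired_loglik(R0, nf$A, nf$M, fit$counts, fit$risk_model)
  LR <- max(0, 2 * (fit$loglik - l0))
  tibble::tibble(test = "lr", statistic = LR, p_value = chisq1_p(LR), df = 1L)
}

#' Fit the penalized MLE to every SNP of a counts tibble
#'
#' Data-frame-first surface over [paired_mle()] and the association tests.
#' The input carries one SNP per row with the nine count columns
#' `n00 ... n22` (see [count_cols()]); all other columns are preserved.
#'
#' @param data Tibble with one row per SNP and the nine count columns.
#' @inheritParams paired_mle
#' @param tests Character subset of `c("wald", "score", "lr")` (any of
#'   them, or `"none"`).
#' @param R0 Null relative risk for the tests.
#' @return The input tibble with columns `R_hat`, `A_hat`, `M_hat`,
#'   `se_R`, `loglik`, `converged`, and `stat_*` / `p_*` per requested
#'   test, plus a `fit` list-column of `paired_mle` objects.
#' @export
#' @examples
#' sims <- simulate_gene(n_snps = 2, n = 1000, R = 2, A = 0.2, M = 0.005)
#' fit_mle_snps(sims, tests = "wald")
fit_mle_snps <- function(data, lambda = 0.05, alpha = 0.05,
                         tests = c("wald", "score", "lr"), R0 = 1,
                         n_starts = 5, risk_model = "additive") {
  stopifnot(is.data.frame(data), all(COUNT_COLS %in% names(data)))
  if (identical(tests, "none")) tests <- character(0)
  tests <- intersect(tests, c("wald", "score", "lr"))
  fits <- purrr::pmap(data[COUNT_COLS], function(...) {
    paired_mle(c(...), lambda = lambda, alpha = alpha, n_starts = n_starts,
               risk_model = risk_model)
  })
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    R_hat = purrr::map_dbl(fits, "R"),
    A_hat = purrr::map_dbl(fits, "A"),
    M_hat = purrr::map_dbl(fits, "M"),
    se_R = purrr::map_dbl(fits, "se_R"),
    loglik = purrr::map_dbl(fits, "loglik"),
    converged = purrr::map_lgl(fits, "converged")
  )
  for (tt in tests) {
    fn <- switch(tt, wald = wald_test, score = score_test, lr = lr_test)
    res <- purrr::map(fits, function(f) {
      tryCatch(fn(f, R0 = R0),
               error = function(e) tibble::tibble(statistic = NA_real_,
                                                  p_value = NA_real_))
    })
    out[[paste0("stat_", tt)]] <- purrr::map_dbl(res, "statistic")
    out[[paste0("p_", tt)]] <- purrr::map_dbl(res, "p_value")
  }
  out$fit <- fits
  out
}
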