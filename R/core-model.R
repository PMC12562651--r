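#' @useDynLib pairedgwas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data :=
#' @keywords internal
"_PACKAGE"

# Canonical column order of the 9-cell paired genotype table: row = normal
# genotype (0/1/2), column = tumor genotype (0/1/2), flattened row-major.
COUNT_COLS <- c("n00", "n01", "n02", "n10", "n11", "n12", "n20", "n21", "n22")

#' Column names of the 9-cell paired genotype table
#'
#' The paired tumor-normal design summarizes each SNP by a 3x3 table of
#' counts `n_ij`: the number of patients whose normal-tissue genotype is `i`
#' and tumor-tissue genotype is `j` (minor/risk allele dosage, 0/1/2).
#' Throughout the package these tables travel as nine columns of a tibble,
#' in the fixed order `n00, n01, n02, n10, n11, n12, n20, n21, n22`.
#'
#' @return Character vector of the nine column names.
#' @export
#' @examples
#' count_cols()
count_cols <- function() COUNT_COLS

#' Coerce a paired genotype table to the canonical 9-vector
#'
#' Accepts a 3x3 matrix (rows = normal genotype, columns = tumor genotype),
#' a length-9 vector in canonical order, or a one-row data frame carrying the
#' `n00 ... n22` columns.
#'
#' @param x Counts in any of the accepted forms.
#' @return Named numeric vector of length 9 in canonical order.
#' @export
as_paired_counts <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, all(COUNT_COLS %in% names(x)))
    x <- as.numeric(x[1, COUNT_COLS])
  } else if (is.matrix(x)) {
    stopifnot(identical(dim(x), c(3L, 3L)))
    x <- as.numeric(t(x))
  } else {
    x <- as.numeric(x)
  }
  if (length(x) != 9L) stop("paired counts must have 9 cells", call. = FALSE)
  if (any(x < 0) || any(x != round(x))) {
    stop("paired counts must be non-negative integers", call. = FALSE)
  }
  stats::setNames(x, COUNT_COLS)
}

check_param_domain <- function(R, A, M) {
  if (!is.finite(R) || R <= 0) stop("R must be in (0, Inf)", call. = FALSE)
  if (!is.finite(A) || A <= 0 || A >= 1) stop("A must be in (0, 1)", call. = FALSE)
  if (!is.finite(M) || M <= 0 || M >= 1) stop("M must be in (0, 1)", call. = FALSE)
  invisible(TRUE)
}

#' Genotype probabilities under Hardy-Weinberg equilibrium
#'
#' @param A Risk allele frequency in (0, 1).
#' @return Numeric vector `(P(g=0), P(g=1), P(g=2)) = ((1-A)^2, 2A(1-A), A^2)`.
#' @export
#' @examples
#' genotype_prior(0.2)
genotype_prior <- function(A) {
  if (!is.finite(A) || A <= 0 || A >= 1) stop("A must be in (0, 1)", call. = FALSE)
  c((1 - A)^2, 2 * A * (1 - A), A^2)
}

#' Somatic genotype transition matrix
#'
#' Row-stochastic 3x3 matrix `T[i+1, j+1] = P(tumor genotype j | normal
#' genotype i)` under independent per-allele alteration with rate `M`.
#'
#' @param M Per-allele somatic mutation rate in (0, 1).
#' @return 3x3 numeric matrix; each row sums to 1.
#' @export
mutation_transition <- function(M) {
  if (!is.finite(M) || M <= 0 || M >= 1) stop("M must be in (0, 1)", call. = FALSE)
  matrix(c(
    (1 - M)^2, 2 * M * (1 - M), M^2,
    M * (1 - M), M^2 + (1 - M)^2, M * (1 - M),
    M^2, 2 * M * (1 - M), (1 - M)^2
  ), nrow = 3, byrow = TRUE)
}

#' Genotype relative-risk vector
#'
#' Maps the scalar relative risk `R` to per-genotype risks `(R0, R1, R2)`.
#' The additive model (default) sets the heterozygote risk to the mean of
#' the homozygote risks: `(1, (R+1)/2, R)`. Dominant, recessive and
#' multiplicative alternatives use the conventional vectors `(1, R, R)`,
#' `(1, 1, R)` and `(1, R, R^2)`.
#'
#' @param R Relative risk, `R > 0`.
#' @param risk_model One of `"additive"`, `"dominant"`, `"recessive"`,
#'   `"multiplicative"`.
#' @return Numeric vector `(R0, R1, R2)`.
#' @export
relative_risk_vector <- function(R, risk_model = c("additive", "dominant",
                                                   "recessive", "multiplicative")) {
  if (!is.finite(R) || R <= 0) stop("R must be in (0, Inf)", call. = FALSE)
  switch(match.arg(risk_model),
    additive = c(1, (R + 1) / 2, R),
    dominant = c(1, R, R),
    recessive = c(1, 1, R),
    multiplicative = c(1, R, R^2)
  )
}

#' Cell probabilities of the paired tumor-normal genotype model
#'
#' The probability of observing normal genotype `i` and tumor genotype `j`
#' in a patient sample is proportional to
#' `genotype_prior(A)[i] * mutation_transition(M)[i, j] * relative_risk_vector(R)[j]`,
#' normalized by the constant `qsum` so the nine cells sum to one. The risk
#' vector acts on the tumor genotype (columns).
#'
#' @inheritParams relative_risk_vector
#' @param A Risk allele frequency in (0, 1).
#' @param M Somatic mutation rate in (0, 1).
#' @return 3x3 matrix of cell probabilities with attribute `"qsum"`.
#' @export
#' @examples
#' P <- paired_probabilities(R = 2, A = 0.2, M = 0.005)
#' sum(P)          # 1
#' attr(P, "qsum") # normalization constant
paired_probabilities <- function(R, A, M, risk_model = "additive") {
  check_param_domain(R, A, M)
  w <- genotype_prior(A) * mutation_transition(M) *
    rep(relative_risk_vector(R, risk_model), each = 3)
  qsum <- sum(w)
  structure(w / qsum, qsum = qsum)
}

#' Multinomial log-likelihood of a paired genotype table
#'
#' `sum_ij n_ij * log P_ij`. Cells with zero count contribute zero even if
#' the cell probability underflows; a positive count on a zero-probability
#' cell yields `-Inf`.
#'
#' @inheritParams paired_probabilities
#' @param counts Paired genotype counts (see [as_paired_counts()]).
#' @return Scalar log-likelihood.
#' @export
paired_loglik <- function(R, A, M, counts, risk_model = "additive") {
  n <- as_paired_counts(counts)
  P <- as.numeric(t(paired_probabilities(R, A, M, risk_model)))
  pos <- n > 0
  if (!any(pos)) return(0)
  if (any(P[pos] == 0)) return(-Inf)
  sum(n[pos] * log(pmax(P[pos], 1e-300)))
}

#' Observed allele frequency of a paired genotype table
#'
#' Risk-allele dosage of the normal-tissue genotype averaged over `2n`
#' chromosomes: `(n10+n11+n12 + 2(n20+n21+n22)) / (2n)`.
#'
#' @inheritParams paired_loglik
#' @return Scalar in `[0, 1]`.
#' @export
observed_allele_freq <- function(counts) {
  n <- as_paired_counts(counts)
  N <- sum(n)
  if (N == 0) stop("allele frequency undefined for an empty table", call. = FALSE)
  (sum(n[c("n10", "n11", "n12")]) + 2 * sum(n[c("n20", "n21", "n22")])) / (2 * N)
}

#' Observed somatic mutation rate of a paired genotype table
#'
#' Net allele changes between normal and tumor genotypes per chromosome:
#' `(n01 + 2 n02 + n10 + n12 + 2 n20 + n21) / (2n)`.
#'
#' @inheritParams paired_loglik
#' @return Scalar in `[0, 1]`.
#' @export
observed_mutation_rate <- function(counts) {
  n <- as_paired_counts(counts)
  N <- sum(n)
  if (N == 0) stop("mutation rate undefined for an empty table", call. = FALSE)
  (n[["n01"]] + 2 * n[["n02"]] + n[["n10"]] + n[["n12"]] +
    2 * n[["n20"]] + n[["n21"]]) / (2 * N)
}

#' Expected sample allele frequency in the patient population
#'
#' Closed-form expectation of [observed_allele_freq()] under the paired
#' genotype model with additive risk. Equals `A` when `R = 1`; for `R > 1`
#' the risk allele is enriched among patients, so the expectation exceeds
#' the population frequency.
#'
#' @inheritParams paired_probabilities
#' @return Scalar expectation.
#' @export
expected_allele_freq <- function(R, A, M) {
  check_param_domain(R, A, M)
  qsum <- R * A - M - A + R * M + 2 * A * M - 2 * R * A * M + 1
  A * (R - A + R * A + 2 * A * M - 2 * R * A * M + 1) / (2 * qsum)
}

#' Expected sample mutation rate in the patient population
#'
#' Closed-form expectation of the per-chromosome somatic mutation-event
#' rate under the paired genotype model with additive risk; equals `M`
#' when `R = 1`. This counts allele-level mutation events, so the
#' double-alteration component of the heterozygote-to-heterozygote cell
#' contributes two events although the net genotype change is zero; it
#' differs from the expectation of [observed_mutation_rate()] by a term
#' of order `M^2`, negligible at realistic somatic rates.
#'
#' @inheritParams paired_probabilities
#' @return Scalar expectation.
#' @export
expected_mutation_rate <- function(R, A, M) {
  check_param_domain(R, A, M)
  qsum <- R * A - M - A + R * M + 2 * A * M - 2 * R * A * M + 1
  M * (R - M + R * M + 2 * A * M - 2 * R * A * M + 1) / (2 * qsum)
}

# Solve a quadratic a2 x^2 + a1 x + a0 = 0 and return the root in (0,1)
# satisfying |target(x) - obs| < tol, preferring the one continuous with the
# neutral limit. Falls back to uniroot on the moment equation.
solve_enrichment_root <- function(obs, a2, a1, a0, moment_fn, limit_value,
                                  tol = 1e-8) {
  if (abs(a2) < 1e-10) {
    # removable singularity (R ~ 1 or the symmetric-parameter degeneracy):
    # the quadratic collapses to a linear equation
    if (abs(a1) > 1e-12) {
      x <- -a0 / a1
      if (x > 0 && x < 1 && abs(moment_fn(x) - obs) < 1e-6) return(x)
    }
    return(solve_enrichment_bisect(obs, moment_fn, limit_value))
  }
  disc <- a1^2 - 4 * a2 * a0
  if (disc < 0) return(solve_enrichment_bisect(obs, moment_fn, limit_value))
  roots <- (-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2)
  ok <- roots > 0 & roots < 1
  ok[ok] <- vapply(roots[ok], function(x) abs(moment_fn(x) - obs) < tol,
                   logical(1))
  if (!any(ok)) return(solve_enrichment_bisect(obs, moment_fn, limit_value))
  cand <- roots[ok]
  cand[which.min(abs(cand - limit_value))]
}

solve_enrichment_bisect <- function(obs, moment_fn, limit_value) {
  eps <- 1e-12
  f <- function(x) moment_fn(x) - obs
  lo <- eps; hi <- 1 - eps
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) {
    # monotone moment map with no interior sign change: neutral limit
    return(limit_value)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Population allele frequency implied by an enriched sample frequency
#'
#' Inverts the expectation map: finds the population frequency `A` such
#' that [expected_allele_freq()]`(R, A, M)` equals the observed sample
#' frequency `af_hat`, given the relative risk and mutation rate. Used to
#' anchor the prior mean of `A` for an associated SNP. At `R = 1` the map
#' is the identity and `af_hat` is returned.
#'
#' @param af_hat Observed sample allele frequency in (0, 1).
#' @param R Relative risk.
#' @param M Somatic mutation rate.
#' @return Scalar `A` in (0, 1) with
#'   `expected_allele_freq(R, A, M) == af_hat` (to 1e-8).
#' @export
solve_enriched_af <- function(af_hat, R, M) {
  stopifnot(af_hat > 0, af_hat < 1, R > 0, M > 0, M < 1)
  # quadratic in A from expected_allele_freq(R, A, M) = af_hat
  a2 <- -(2 * M - 1) * (R - 1)
  a1 <- 4 * af_hat * M * R - 4 * af_hat * M - 2 * af_hat * R + 2 * af_hat + R + 1
  a0 <- -2 * af_hat * (M * R - M + 1)
  solve_enrichment_root(af_hat, a2, a1, a0,
                        function(A) expected_allele_freq(R, A, M), af_hat)
}

#' Population mutation rate implied by an enriched sample rate
#'
#' Inverts [expected_mutation_rate()] in `M` given `R` and `A`; anchors the
#' prior mean of `M` for an associated SNP. At `R = 1` returns `mr_hat`.
#'
#' @param mr_hat Observed sample mutation rate in (0, 1).
#' @param R Relative risk.
#' @param A Risk allele frequency.
#' @return Scalar `M` in (0, 1) with
#'   `expected_mutation_rate(R, A, M) == mr_hat` (to 1e-8).
#' @export
solve_enriched_mr <- function(mr_hat, R, A) {
  stopifnot(mr_hat > 0, mr_hat < 1, R > 0, A > 0, A < 1)
  a2 <- -(2 * A - 1) * (R - 1)
  a1 <- 4 * A * mr_hat * R - 4 * A * mr_hat - 2 * mr_hat * R + 2 * mr_hat + R + 1
  a0 <- -2 * mr_hat * (A * R - A + 1)
  solve_enrichment_root(mr_hat, a2, a1, a0,
                        function(M) expected_mutation_rate(R, A, M), mr_hat)
}
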