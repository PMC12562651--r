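# The paired-genotype probability model and its moment equations.

test_that("genotype prior follows Hardy-Weinberg proportions", {
  expect_equal(genotype_prior(0.5), c(0.25, 0.5, 0.25))
  expect_equal(genotype_prior(0.2), c(0.64, 0.32, 0.04))
  expect_equal(sum(genotype_prior(0.137)), 1)
  expect_equal(genotype_prior(1e-9), c(1, 0, 0), tolerance = 1e-6)
  expect_error(genotype_prior(0), "0, 1")
  expect_error(genotype_prior(1.2), "0, 1")
})

test_that("mutation transition matrix is row-stochastic with the stated rows", {
  T5 <- mutation_transition(0.5)
  expect_equal(T5[1, ], c(0.25, 0.5, 0.25))
  expect_equal(T5[2, ], c(0.25, 0.5, 0.25))
  for (M in c(0.001, 0.05, 0.3, 0.9)) {
    expect_equal(rowSums(mutation_transition(M)), rep(1, 3))
  }
  expect_equal(mutation_transition(1e-12), diag(3), tolerance = 1e-9)
  expect_error(mutation_transition(0))
})

test_that("relative-risk vectors match the genetic risk models", {
  expect_equal(relative_risk_vector(1), c(1, 1, 1))
  expect_equal(relative_risk_vector(3), c(1, 2, 3))
  expect_equal(relative_risk_vector(2), c(1, 1.5, 2))
  expect_equal(relative_risk_vector(2, "dominant"), c(1, 2, 2))
  expect_equal(relative_risk_vector(2, "recessive"), c(1, 1, 2))
  expect_equal(relative_risk_vector(2, "multiplicative"), c(1, 2, 4))
  expect_error(relative_risk_vector(-1))
})

test_that("cell probabilities normalize, and qsum = 1 exactly under the null", {
  set.seed(101)
  for (i in 1:100) {
    p <- random_params(1)
    P <- paired_probabilities(p$R, p$A, p$M)
    expect_equal(sum(P), 1, tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1))
    P0 <- paired_probabilities(1, p$A, p$M)
    expect_equal(attr(P0, "qsum"), 1, tolerance = 1e-12)
    # null model factorizes into HWE prior x transition
    expect_equal(unclass(P0)[, ],
                 genotype_prior(p$A) * mutation_transition(p$M),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("cell probabilities equal the closed-form 9-cell display", {
  closed_form <- function(R, A, M) {
    r1 <- (R + 1) / 2
    w <- c((1 - A)^2 * (1 - M)^2,       2 * (1 - A)^2 * M * (1 - M) * r1,
           (1 - A)^2 * M^2 * R,
           2 * A * (1 - A) * M * (1 - M), 2 * A * (1 - A) * (M^2 + (1 - M)^2) * r1,
           2 * A * (1 - A) * M * (1 - M) * R,
           A^2 * M^2,                    2 * A^2 * M * (1 - M) * r1,
           A^2 * (1 - M)^2 * R)
    w / sum(w)
  }
  set.seed(7)
  for (i in 1:25) {
    p <- random_params(1)
    expect_equal(as.numeric(t(paired_probabilities(p$R, p$A, p$M))),
                 closed_form(p$R, p$A, p$M), tolerance = 1e-13)
  }
})

test_that("degenerate no-mutation limit concentrates on the diagonal", {
  P <- matrix(as.numeric(paired_probabilities(3, 0.5, 1e-12)), 3, 3,
              byrow = TRUE)
  expect_equal(diag(P), c(0.125, 0.5, 0.375), tolerance = 1e-9)
  expect_equal(attr(paired_probabilities(3, 0.5, 1e-12), "qsum"), 2,
               tolerance = 1e-9)
})

test_that("log-likelihood evaluates counts against cell probabilities", {
  zero <- stats::setNames(rep(0, 9), count_cols())
  expect_equal(paired_loglik(2, 0.3, 0.1, zero), 0)
  one00 <- zero; one00["n00"] <- 1
  expect_equal(paired_loglik(1, 0.5, 0.5, one00), log(0.0625))
  # grid scan: expected counts at the true parameters maximize the loglik
  truth <- list(R = 2, A = 0.3, M = 0.05)
  P <- as.numeric(t(paired_probabilities(truth$R, truth$A, truth$M)))
  cts <- stats::setNames(round(1e5 * P), count_cols())
  grid <- expand.grid(R = c(0.5, 1, 2, 3), A = c(0.1, 0.3, 0.5),
                      M = c(0.01, 0.05, 0.2))
  ll <- mapply(function(R, A, M) paired_loglik(R, A, M, cts),
               grid$R, grid$A, grid$M)
  best <- grid[which.max(ll), ]
  expect_equal(as.numeric(best), c(2, 0.3, 0.05))
})

test_that("observed allele frequency and mutation rate match hand counts", {
  x <- stats::setNames(rep(0, 9), count_cols())
  x[c("n10", "n11", "n12")] <- 10
  x[c("n20", "n21", "n22")] <- 5
  expect_equal(observed_allele_freq(x), 2 / 3)
  row0 <- stats::setNames(c(5, 3, 2, 0, 0, 0, 0, 0, 0), count_cols())
  expect_equal(observed_allele_freq(row0), 0)
  row2 <- stats::setNames(c(0, 0, 0, 0, 0, 0, 5, 3, 2), count_cols())
  expect_equal(observed_allele_freq(row2), 1)
  diag_only <- stats::setNames(c(5, 0, 0, 0, 7, 0, 0, 0, 3), count_cols())
  expect_equal(observed_mutation_rate(diag_only), 0)
  expect_error(observed_allele_freq(rep(0, 9)), "empty")
})

test_that("expected allele frequency equals its moment and is neutral at R = 1", {
  set.seed(11)
  for (i in 1:100) {
    p <- random_params(1)
    expect_equal(expected_allele_freq(1, p$A, p$M), p$A, tolerance = 1e-12)
    Pm <- matrix(as.numeric(paired_probabilities(p$R, p$A, p$M)), 3, 3)
    moment <- sum((0:2) / 2 * rowSums(Pm))
    expect_equal(expected_allele_freq(p$R, p$A, p$M), moment,
                 tolerance = 1e-10)
  }
})

test_that("expected mutation rate equals the event-weighted moment and is neutral at R = 1", {
  # per-cell expected allele-level mutation events: off-diagonal cells carry
  # their net change; the heterozygote->heterozygote cell mixes 0 events
  # (no alteration) and 2 events (both alleles flipped)
  event_moment <- function(R, A, M) {
    W <- genotype_prior(A) * mutation_transition(M) *
      rep(relative_risk_vector(R), each = 3)
    e <- matrix(c(0, 1, 2, 1, 2 * M^2 / (M^2 + (1 - M)^2), 1, 2, 1, 0),
                3, 3, byrow = TRUE)
    sum(W * e) / (2 * sum(W))
  }
  set.seed(12)
  for (i in 1:100) {
    p <- random_params(1)
    expect_equal(expected_mutation_rate(1, p$A, p$M), p$M, tolerance = 1e-12)
    expect_equal(expected_mutation_rate(p$R, p$A, p$M),
                 event_moment(p$R, p$A, p$M), tolerance = 1e-10)
  }
})

test_that("enrichment solvers satisfy their fixed points and match bisection", {
  set.seed(13)
  for (i in 1:50) {
    af <- runif(1, 0.05, 0.9); R <- exp(runif(1, log(0.5), log(4)))
    M <- runif(1, 0.002, 0.45)
    A <- solve_enriched_af(af, R, M)
    expect_lt(abs(expected_allele_freq(R, A, M) - af), 1e-8)
    ref <- bisect01(function(x) expected_allele_freq(R, x, M), af)
    if (!is.na(ref)) expect_equal(A, ref, tolerance = 1e-6)
    mr <- runif(1, 0.002, 0.3)
    Ms <- solve_enriched_mr(mr, R, A)
    expect_lt(abs(expected_mutation_rate(R, A, Ms) - mr), 1e-8)
  }
})

test_that("enrichment solvers handle neutral and degenerate limits", {
  expect_equal(solve_enriched_af(0.2, 1, 0.005), 0.2)
  expect_equal(solve_enriched_mr(0.005, 1, 0.2), 0.005)
  # removable singularities: M = 0.5 for the frequency map, A = 0.5 for the
  # rate map; results must still satisfy the fixed point
  A5 <- solve_enriched_af(0.3, 2, 0.5)
  expect_lt(abs(expected_allele_freq(2, A5, 0.5) - 0.3), 1e-8)
  M5 <- solve_enriched_mr(0.01, 2, 0.5)
  expect_lt(abs(expected_mutation_rate(2, 0.5, M5) - 0.01), 1e-8)
  # enrichment direction: with R > 1 and M < 0.5 the population frequency
  # lies below the patient-sample frequency
  expect_lt(solve_enriched_af(0.2, 3, 0.005), 0.2)
})

test_that("paired counts coercion validates and round-trips shapes", {
  v <- as_paired_counts(c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  expect_named(v, count_cols())
  m <- matrix(1:9, 3, 3, byrow = TRUE)
  expect_equal(as.numeric(as_paired_counts(m)), as.numeric(1:9))
  df <- tibble::as_tibble(as.list(v))
  expect_equal(as_paired_counts(df), v)
  expect_error(as_paired_counts(1:8), "9 cells")
  expect_error(as_paired_counts(c(-1, 1:8)), "non-negative")
})
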