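# ggplot2 displays for fitted objects and simulation studies.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Posterior summaries of a Bayesian SNP-set fit
#'
#' Trace-free display: per-SNP posterior association probabilities and the
#' posterior density of each SNP's relative risk.
#'
#' @param object A [fit_bayes()] object.
#' @param type `"association"` (per-SNP posterior `P(H = 1)`) or
#'   `"relative_risk"` (posterior densities of `R_j`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.paired_bayes <- function(object, type = c("association",
                                                   "relative_risk"), ...) {
  type <- match.arg(type)
  if (type == "association") {
    ggplot2::ggplot(object$snp,
                    ggplot2::aes(x = .data$snp_id, y = .data$H_mean)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
      ggplot2::ylim(0, 1) +
      ggplot2::labs(x = NULL, y = "posterior P(H = 1)",
                    title = sprintf("Set-level P(G = 1) = %.2f",
                                    object$set$G_mean)) +
      ggplot2::theme_minimal()
  } else {
    d <- object$draws$R
    long <- tibble::tibble(
      snp_id = rep(object$snp$snp_id, each = nrow(d)),
      R = as.numeric(d)
    )
    ggplot2::ggplot(long, ggplot2::aes(x = .data$R, colour = .data$snp_id)) +
      ggplot2::geom_density() +
      ggplot2::geom_vline(xintercept = 1, linetype = 2) +
      ggplot2::labs(x = "relative risk R", y = "posterior density",
                    colour = NULL) +
      ggplot2::theme_minimal()
  }
}

#' Power / type I error display of a simulation study
#'
#' @param summary Output of [summarize_simulation_study()].
#' @return A ggplot object: rejection rate against relative risk, faceted
#'   by sample size and allele frequency, coloured by method.
#' @export
plot_power_curves <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$R, y = .data$rejection_rate,
                               colour = .data$method,
                               group = interaction(.data$method, .data$snp))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 3) +
    ggplot2::facet_grid(n ~ A, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "relative risk R", y = "rejection rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
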