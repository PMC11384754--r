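# ggplot2 displays for the main result types.

#' Plot per-allele usage frequencies
#'
#' Points per participant, grouped by allele, with median and interquartile
#' box, on either the mRNA (UMI) or unique-HCDR3 frequency scale.
#'
#' @param usages An `allele_usage` tibble (combined, S4953-collapsed).
#' @param value `"umi_frequency"` or `"hcdr3_frequency"`.
#' @param alleles Alleles to display.
#' @return A ggplot object.
#' @export
plot_allele_usage <- function(usages,
                              value = c("umi_frequency", "hcdr3_frequency"),
                              alleles = c("*02", "*04", "*05", "*06")) {
  value <- match.arg(value)
  u <- dplyr::filter(tibble::as_tibble(usages), .data$allele %in% alleles)
  ggplot2::ggplot(u, ggplot2::aes(x = .data$allele, y = .data[[value]],
                                  colour = .data$allele)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5,
                          colour = "grey40") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.1f%%", 100 * x)) +
    ggplot2::labs(x = "IGHV1-2 allele",
                  y = if (value == "umi_frequency")
                    "mRNA (UMI) frequency" else "unique-HCDR3 frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot QAICc model ranking across timepoints
#'
#' @param ranking Ranking tibble from [model_all_timepoints()].
#' @return A ggplot object.
#' @export
plot_model_ranking <- function(ranking) {
  r <- dplyr::mutate(tibble::as_tibble(ranking),
                     timepoint = paste0(.data$compartment, " wk",
                                        .data$week))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$timepoint,
                                  y = .data$delta_QAICc,
                                  colour = .data$model,
                                  group = .data$model)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = NULL, y = expression(Delta * "QAICc"),
                  colour = "model") +
    ggplot2::theme_minimal()
}

#' Plot genotype mean estimates with confidence intervals
#'
#' @param genotype_means Tibble with columns `genotype`, `estimate`,
#'   `conf.low`, `conf.high` (see [genotype_mean()]).
#' @return A ggplot object.
#' @export
plot_genotype_means <- function(genotype_means) {
  g <- tibble::as_tibble(genotype_means)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$genotype, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high),
                             shape = 5) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.3f%%", 100 * x)) +
    ggplot2::labs(x = "IGHV1-2 genotype",
                  y = "estimated VRC01-class frequency") +
    ggplot2::theme_minimal()
}

#' Plot affinities per group
#'
#' Log10-scaled K_D points per group with median and interquartile bars.
#'
#' @param records Affinity table (`group`, `kd_molar`, optional
#'   `censored`).
#' @return A ggplot object.
#' @export
plot_affinities <- function(records) {
  rec <- tibble::as_tibble(records)
  if (!"censored" %in% names(rec)) rec$censored <- FALSE
  ggplot2::ggplot(dplyr::filter(rec, !.data$censored),
                  ggplot2::aes(x = .data$group, y = .data$kd_molar)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.4,
                          linewidth = 0.4) +
    ggplot2::scale_y_log10(labels = function(x) sprintf("%.3g", x)) +
    ggplot2::labs(x = NULL, y = expression(K[D] ~ "(M)")) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot qp_fit
#' @importFrom ggplot2 autoplot
autoplot.qp_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::labs(x = NULL, y = "per-cell response frequency") +
    ggplot2::theme_minimal()
}
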