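#' Plot crosstalk scores by direction
#'
#' Bar chart of the similarity, suppression and novel-interaction scores for
#' the up, down and direction-blind DEG sets.
#'
#' @param object A `crosstalk_scores` tibble from [crosstalk_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crosstalk_scores
#' @export
autoplot.crosstalk_scores <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("direction", "similarity", "suppression",
                                  "novel_interaction")],
    cols = c("similarity", "suppression", "novel_interaction"),
    names_to = "metric", values_to = "score")
  long$direction <- factor(long$direction, levels = c("up", "down", "all"))
  long$metric <- factor(long$metric,
                        levels = c("similarity", "suppression",
                                   "novel_interaction"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$direction, y = .data$score,
                               fill = .data$direction)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::labs(x = NULL, y = "score") +
    ggplot2::theme_minimal()
}

#' Plot Venn region counts
#'
#' Bar chart of the disjoint region counts of a Venn partition. (A faithful
#' area-proportional Venn diagram is deliberately not attempted; the counts
#' themselves are the quantity of interest.)
#'
#' @param object A `venn_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot venn_partition
#' @export
autoplot.venn_partition <- function(object, ...) {
  dat <- tibble::as_tibble(object[, c("region", "count")])
  dat$region <- factor(dat$region, levels = dat$region)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$region, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = "Venn region", y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Scatter plot of mRNA versus protein fold-changes
#'
#' Quadrant-coloured scatter of the paired log2 fold-changes from
#' [omic_fc_concordance()], with the Spearman correlation in the subtitle.
#'
#' @param object An `omic_concordance` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot omic_concordance
#' @export
autoplot.omic_concordance <- function(object, ...) {
  ggplot2::ggplot(object$per_gene,
                  ggplot2::aes(x = .data$mrna_log2fc,
                               y = .data$protein_log2fc,
                               colour = .data$quadrant)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "mRNA log2 fold-change",
                  y = "protein log2 fold-change",
                  subtitle = sprintf("Spearman rho = %.3f (n = %d)",
                                     object$spearman_rho, object$n_common)) +
    ggplot2::theme_minimal()
}
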