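# ggplot2 views of the result objects.

#' @importFrom ggplot2 ggplot aes geom_tile geom_boxplot geom_col labs
#'   scale_fill_gradient2 scale_fill_viridis_c theme_minimal facet_grid
NULL

#' Heatmap of real-versus-scrambled scores
#'
#' Models by threshold positions, colored by the RZ score on the 0-100
#' scale, diverging around the median.
#'
#' @param object `rz_screen` tibble from [run_rz_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rz_screen <- function(object, ...) {
  d <- mutate(as_tibble(object), rz100 = 100 * .data$rz)
  ggplot(d, aes(x = factor(.data$threshold_position),
                y = stats::reorder(.data$pattern, .data$model_id),
                fill = .data$rz100)) +
    geom_tile() +
    scale_fill_gradient2(midpoint = stats::median(d$rz100, na.rm = TRUE),
                         low = "firebrick", mid = "white", high = "steelblue",
                         name = "RZ x 100") +
    labs(x = "threshold position", y = "model") +
    theme_minimal()
}

#' Heatmap of pairwise interdependency p-values
#'
#' One tile per (position pair, nucleotide pair) hypothesis, colored by the
#' two-tailed Monte Carlo p-value on a -log10 scale.
#'
#' @param object `interdep_test` tibble from [pair_dependence_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.interdep_test <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(pair = paste0(.data$pos_i, "-", .data$pos_j),
           nts = paste0(.data$nt_i, .data$nt_j))
  ggplot(d, aes(x = .data$nts, y = .data$pair,
                fill = -log10(.data$p_two_tailed))) +
    geom_tile() +
    scale_fill_viridis_c(name = "-log10 p") +
    labs(x = "nucleotide pair (first position, second position)",
         y = "position pair") +
    theme_minimal()
}

#' Boxplot of leave-parts-out mean true hit ratios
#'
#' One box per model over the trials, in model-id order.
#'
#' @param object `lpo_result` from [leave_parts_out()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lpo_result <- function(object, ...) {
  d <- filter(object$trials, !is.na(.data$mean_true_hit_ratio))
  ggplot(d, aes(x = factor(.data$model_id), y = .data$mean_true_hit_ratio)) +
    geom_boxplot(outlier.size = 0.5) +
    labs(x = "model", y = "mean true hit ratio") +
    theme_minimal()
}
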