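#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_boxplot geom_line
#'   geom_hline labs facet_wrap stat_summary position_jitter theme_minimal
#' @export
ggplot2::autoplot

#' Plot pattern typicality by condition
#'
#' Subject-mean distance from the held-out centroid per condition and ROI:
#' small dots are subjects, large dots the group mean. Shorter distance =
#' higher typicality = greater convergence.
#'
#' @param object A `typicality_tbl` from [compute_typicality()].
#' @param trials Trial table supplying the `condition` column.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.typicality_tbl <- function(object, trials, ...) {
  df <- dplyr::left_join(object,
                         trials[, c("trial_id", "condition")], by = "trial_id") |>
    dplyr::group_by(.data$subject_id, .data$roi, .data$condition) |>
    dplyr::summarise(distance = mean(.data$distance), .groups = "drop")
  ggplot(df, aes(x = .data$condition, y = .data$distance,
                 colour = .data$condition)) +
    geom_point(position = position_jitter(width = 0.08), alpha = 0.6, size = 1) +
    stat_summary(fun = mean, geom = "point", size = 4) +
    facet_wrap(~roi, scales = "free_y") +
    labs(x = NULL, y = "distance from centroid (1 - r)",
         title = "Pattern typicality by condition") +
    theme_minimal()
}

#' Plot a group-level convergence-coupling map
#'
#' Per-voxel group t-values of the null-adjusted correlation, with the
#' family-wise error threshold voxels highlighted.
#'
#' @param object A `brain_map` from [group_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.brain_map <- function(object, ...) {
  ggplot(object, aes(x = .data$voxel, y = .data$t,
                     colour = .data$significant)) +
    geom_point(size = 0.7) +
    geom_hline(yintercept = 0, linetype = 2) +
    labs(x = "voxel", y = "group t (adjusted r vs 0)",
         title = sprintf("Convergence-coupling map (%s FWE %.2g)",
                         attr(object, "fwe"), attr(object, "alpha"))) +
    theme_minimal()
}

#' Plot per-subject recall rates by condition
#'
#' @param trials Trial table with `recalled`.
#' @return A ggplot object.
#' @export
plot_recall <- function(trials) {
  df <- trials |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::summarise(rate = mean(.data$recalled), .groups = "drop")
  ggplot(df, aes(x = .data$condition, y = .data$rate, colour = .data$condition)) +
    geom_boxplot(outlier.shape = NA, colour = "grey40") +
    geom_point(position = position_jitter(width = 0.08), alpha = 0.7) +
    labs(x = NULL, y = "recall rate", title = "Recall by curiosity condition") +
    theme_minimal()
}
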