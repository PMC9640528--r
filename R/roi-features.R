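#' Mean activation across an ROI's voxels
#'
#' Arithmetic mean over voxels per trial — the univariate summary used
#' alongside the multivariate typicality, computed from the same z-valued
#' (or beta-valued) trial estimates.
#'
#' @param estimates Trials-by-voxels numeric matrix (>= 1 voxel).
#' @return Per-trial numeric vector, names taken from the rownames.
#' @export
#' @examples
#' roi_mean(matrix(1:6, 2, 3))
roi_mean <- function(estimates) {
  estimates <- as.matrix(estimates)
  if (ncol(estimates) < 1) {
    stopf("empty ROI: no voxels", class = "typicality_validation_error")
  }
  rowMeans(estimates)
}

#' Univariate ROI summaries for a cohort pattern set
#'
#' Applies [roi_mean()] to every subject/ROI cell of a pattern set and
#' returns a tidy table keyed like the typicality table.
#'
#' @param patterns A tibble with `subject_id`, `roi` and a `patterns`
#'   list-column (rownames = `trial_id`).
#' @param trials Trial table (for `run` / `trial_in_run` keys).
#' @return Tibble: `subject_id`, `run`, `trial_in_run`, `trial_id`, `roi`,
#'   `roi_mean_z`.
#' @export
compute_roi_means <- function(patterns, trials) {
  res <- purrr::pmap(
    list(patterns$subject_id, patterns$roi, patterns$patterns),
    function(subject_id, roi, mat) {
      tr <- trials[match(rownames(mat), trials$trial_id), ]
      new_tbl(subject_id = subject_id, run = tr$run,
              trial_in_run = tr$trial_in_run, trial_id = tr$trial_id,
              roi = roi, roi_mean_z = roi_mean(mat))
    })
  dplyr::bind_rows(res)
}

#' Assemble the trial-level modeling table
#'
#' Joins the univariate ROI means, the multivariate typicality scores and
#' the behavioural trial table into one wide row per trial: condition,
#' outcome, one `mean_<roi>` column per ROI and one `dist_<roi>` column per
#' scored ROI. The join is checked for completeness — orphan trial ids on
#' either side are an error, named in the message.
#'
#' @param univariate Output of [compute_roi_means()].
#' @param typicality Output of [compute_typicality()] (optionally with
#'   `z_distance` / `outlier_flag`).
#' @param trials Trial table with `recalled`.
#' @return Tibble with one row per trial, ready for the inference module.
#' @export
join_features <- function(univariate, typicality, trials) {
  orphan <- function(a, b) setdiff(unique(a), unique(b))
  o1 <- orphan(univariate$trial_id, trials$trial_id)
  o2 <- orphan(typicality$trial_id, trials$trial_id)
  if (length(o1) || length(o2)) {
    stopf("trial ids absent from the trial table: %s",
          paste(head(unique(c(o1, o2)), 10), collapse = ", "),
          class = "typicality_join_error")
  }
  uni_wide <- tidyr::pivot_wider(
    univariate[, c("trial_id", "roi", "roi_mean_z")],
    names_from = "roi", values_from = "roi_mean_z", names_prefix = "mean_")
  typ_cols <- intersect(c("trial_id", "roi", "distance", "outlier_flag"),
                        names(typicality))
  typ_wide <- tidyr::pivot_wider(
    typicality[, typ_cols], names_from = "roi",
    values_from = dplyr::any_of(c("distance", "outlier_flag")),
    names_glue = "{.value}_{roi}")
  names(typ_wide) <- sub("^distance_", "dist_", names(typ_wide))
  names(typ_wide) <- sub("^outlier_flag_", "outlier_", names(typ_wide))
  out <- trials |>
    dplyr::inner_join(uni_wide, by = "trial_id") |>
    dplyr::left_join(typ_wide, by = "trial_id")
  n_missing <- sum(!complete.cases(out[, setdiff(names(out), names(trials))]))
  if (n_missing > 0) {
    inform(sprintf("modeling table: %d trial(s) with missing features", n_missing))
  }
  out
}
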