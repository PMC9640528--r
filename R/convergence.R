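#' Correlation distance between two voxel patterns
#'
#' `1 - Pearson's r`, the distance metric of the convergence analysis:
#' 0 for perfectly correlated patterns, 2 for perfectly anticorrelated,
#' invariant to per-pattern additive shifts and positive rescaling.
#'
#' @param x,y Numeric vectors of equal length (>= 3), each non-constant.
#' @return A single number in `[0, 2]`.
#' @export
#' @examples
#' correlation_distance(c(1, 2, 3), c(1, 2, 4))
correlation_distance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stopf("patterns must have equal length >= 3", class = "typicality_validation_error")
  }
  xd <- unit_center(x, "x"); yd <- unit_center(y, "y")
  d <- 1 - sum(xd * yd)
  min(max(d, 0), 2)
}

#' Estimate the prototypical-state centroid of a pattern set
#'
#' The centroid is the point with the shortest summed correlation distance
#' to the trial patterns — the prototypical state. Two estimators:
#'
#' * `"kmeans_mean"` (default): the mean of row-standardized patterns, the
#'   closed-form k = 1 k-means solution under correlation geometry; fully
#'   deterministic (no stochastic initialization).
#' * `"medoid"`: the trial pattern minimizing summed correlation distance
#'   to all patterns.
#'
#' The two disagree on pathological geometries (e.g. two antipodal pattern
#' clusters, where the mean collapses toward orthogonality while the medoid
#' stays inside one cluster); the option exists for exactly that reason.
#'
#' @param patterns Trials-by-voxels numeric matrix (>= 2 rows, every row
#'   non-constant).
#' @param method `"kmeans_mean"` or `"medoid"`.
#' @return Numeric voxel vector with attributes `method` and
#'   `summed_distance` (summed correlation distance to all rows).
#' @export
compute_centroid <- function(patterns, method = c("kmeans_mean", "medoid")) {
  method <- match.arg(method)
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 2) {
    stopf("need >= 2 trials to estimate a centroid", class = "typicality_validation_error")
  }
  std <- standardize_rows(patterns)
  centroid <- switch(method,
    kmeans_mean = colMeans(std),
    medoid = {
      # pairwise correlation distances via the standardized rows
      r <- tcrossprod(std) / (ncol(std) - 1L)
      patterns[which.min(rowSums(1 - r)), ]
    }
  )
  if (var(centroid) == 0) {
    stopf("centroid is constant; degenerate pattern set",
          class = "typicality_degenerate_error")
  }
  cu <- unit_center(centroid, "centroid")
  summed <- sum(1 - (std %*% cu) / sqrt(ncol(std) - 1L))
  structure(centroid, method = method, summed_distance = summed)
}

# distances from every row of `patterns` to a single centroid vector
distances_to_centroid <- function(patterns, centroid) {
  std <- standardize_rows(as.matrix(patterns))
  cu <- unit_center(as.numeric(centroid), "centroid")
  d <- as.numeric(1 - (std %*% cu) / sqrt(ncol(std) - 1L))
  pmin(pmax(d, 0), 2)
}

#' Leave-one-run-out pattern typicality
#'
#' The convergence statistic: for each run r, a centroid is estimated from
#' the trials of all other runs and every trial of run r is scored by its
#' correlation distance to that held-out-fold centroid. Each trial is scored
#' exactly once, and never contributes to the centroid it is measured
#' against, so typicality is independent of the centroid-defining samples
#' and unconfounded by within-run temporal correlation. Shorter distance =
#' higher typicality = greater convergence.
#'
#' @param patterns Trials-by-voxels matrix.
#' @param run_labels Per-trial run index (length `nrow(patterns)`).
#' @param method Centroid estimator, see [compute_centroid()].
#' @return A list with `distance` (per-trial numeric, input order) and
#'   `centroids` (tibble: `run`, `centroid` list-column, `n_source_trials`,
#'   `method`).
#' @export
loro_typicality <- function(patterns, run_labels, method = c("kmeans_mean", "medoid")) {
  method <- match.arg(method)
  patterns <- as.matrix(patterns)
  if (length(run_labels) != nrow(patterns)) {
    stopf("run_labels length %d != %d trials", length(run_labels), nrow(patterns),
          class = "typicality_validation_error")
  }
  runs <- sort(unique(run_labels))
  if (length(runs) < 2) {
    stopf("need >= 2 distinct runs for leave-one-run-out scoring",
          class = "typicality_validation_error")
  }
  distance <- numeric(nrow(patterns))
  cents <- purrr::map(runs, function(r) {
    train <- run_labels != r
    if (sum(train) < 2) {
      stopf("fewer than 2 training trials when leaving out run %s", r,
            class = "typicality_validation_error")
    }
    centroid <- compute_centroid(patterns[train, , drop = FALSE], method)
    distance[run_labels == r] <<-
      distances_to_centroid(patterns[run_labels == r, , drop = FALSE], centroid)
    new_tbl(run = r, centroid = list(as.numeric(centroid)),
            n_source_trials = sum(train), method = method)
  })
  list(distance = distance, centroids = dplyr::bind_rows(cents))
}

#' Compute pattern typicality across a cohort
#'
#' Tidy driver for [loro_typicality()]: scores every subject and ROI of a
#' pattern set (either [generate_patterns()] output or the estimate set from
#' [fit_trial_glm()]) and joins the scores back to the trial keys.
#'
#' @param patterns A tibble with columns `subject_id`, `roi` and a
#'   `patterns` list-column of trials-by-voxels matrices whose rownames are
#'   `trial_id`s.
#' @param trials Trial table carrying `trial_id`, `run`, `trial_in_run`.
#' @param rois ROIs to score (default: all in `patterns`).
#' @param method Centroid estimator.
#' @return An object of class `typicality_tbl`: tibble with `subject_id`,
#'   `run`, `trial_in_run`, `trial_id`, `roi`, `distance`; the per-fold
#'   centroids are attached as attribute `"centroids"`.
#' @export
compute_typicality <- function(patterns, trials, rois = NULL,
                               method = c("kmeans_mean", "medoid")) {
  method <- match.arg(method)
  keep <- if (is.null(rois)) unique(patterns$roi) else rois
  cells <- patterns[patterns$roi %in% keep, , drop = FALSE]
  if (nrow(cells) == 0) stopf("no matching ROIs in `patterns`")
  res <- purrr::pmap(
    list(cells$subject_id, cells$roi, cells$patterns),
    function(subject_id, roi, mat) {
      tr <- trials[match(rownames(mat), trials$trial_id), ]
      if (anyNA(tr$run)) {
        stopf("pattern rows of %s/%s missing from the trial table", subject_id, roi,
              class = "typicality_validation_error")
      }
      lt <- loro_typicality(mat, tr$run, method)
      list(
        scores = new_tbl(subject_id = subject_id, run = tr$run,
                         trial_in_run = tr$trial_in_run, trial_id = tr$trial_id,
                         roi = roi, distance = lt$distance),
        centroids = dplyr::mutate(lt$centroids, subject_id = subject_id,
                                  roi = roi, .before = 1)
      )
    })
  out <- dplyr::bind_rows(purrr::map(res, "scores"))
  attr(out, "centroids") <- dplyr::bind_rows(purrr::map(res, "centroids"))
  class(out) <- c("typicality_tbl", class(out))
  out
}

#' Standardize typicality within subject
#'
#' Adds `z_distance`, the distance z-scored across trials within each
#' subject (and ROI). The raw distances are retained: inference runs on the
#' raw typicality score; the standardized variant serves outlier flagging
#' and visualization.
#'
#' @param table A `typicality_tbl` (or any tibble with `subject_id`, `roi`,
#'   `distance`).
#' @return The table with a `z_distance` column.
#' @export
zscore_within_subject <- function(table) {
  grouped <- dplyr::group_by(table, .data$subject_id, .data$roi)
  n <- dplyr::summarise(grouped, n = dplyr::n(), s = sd(.data$distance),
                        .groups = "drop")
  if (any(n$n < 2)) {
    stopf("subject/ROI cells with < 2 trials cannot be standardized",
          class = "typicality_validation_error")
  }
  if (any(n$s == 0)) {
    stopf("zero within-subject distance variance for %s",
          paste(unique(n$subject_id[n$s == 0]), collapse = ", "),
          class = "typicality_degenerate_error")
  }
  out <- dplyr::mutate(grouped,
                       z_distance = (.data$distance - mean(.data$distance)) / sd(.data$distance))
  out <- dplyr::ungroup(out)
  class(out) <- unique(c("typicality_tbl", class(out)))
  out
}

#' Flag outlying typicality values
#'
#' Marks trials whose within-subject standardized distance exceeds the
#' threshold (default 3 SD). Downstream model helpers accept an
#' include/exclude switch; the flagged fraction is reported via a message.
#'
#' @param table A `typicality_tbl` with `z_distance` (see
#'   [zscore_within_subject()]).
#' @param threshold_sd Absolute z threshold; `Inf` flags nothing.
#' @param quiet Suppress the flagged-fraction message.
#' @return The table with a logical `outlier_flag` column.
#' @export
flag_outliers <- function(table, threshold_sd = 3, quiet = FALSE) {
  if (!"z_distance" %in% names(table)) {
    stopf("`z_distance` missing; run zscore_within_subject() first")
  }
  table$outlier_flag <- abs(table$z_distance) > threshold_sd
  if (!quiet) {
    inform(sprintf("flagged %d / %d trials (%.2f%%) beyond %.3g SD",
                   sum(table$outlier_flag), nrow(table),
                   100 * mean(table$outlier_flag), threshold_sd))
  }
  table
}
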