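#' Write and read BIDS-style event tables
#'
#' Events are written one file per cohort as tab-separated text in the BIDS
#' events dialect — `onset`, `duration`, `trial_type` (the condition), plus
#' `run`, `subject_id`, `trial_id` and `interval` so the table round-trips
#' losslessly. Onsets are seconds from run start.
#'
#' @param events Event tibble from [events_from_trials()].
#' @param path Output path (`.tsv`).
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  out <- new_tbl(onset = events$onset_s, duration = events$duration_s,
                 trial_type = events$condition, run = events$run,
                 subject_id = events$subject_id, trial_id = events$trial_id,
                 interval = events$interval)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("onset", "duration")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "),
          class = "typicality_io_error")
  }
  bad <- which(!(raw$duration > 0) | raw$onset < 0 | is.na(raw$onset))
  if (length(bad)) {
    stopf("%s: malformed event row(s) at line(s) %s (negative onset or non-positive duration)",
          path, paste(bad + 1L, collapse = ", "), class = "typicality_io_error")
  }
  new_tbl(subject_id = raw$subject_id, run = raw$run, trial_id = raw$trial_id,
          interval = raw$interval, onset_s = raw$onset,
          duration_s = raw$duration, condition = raw$trial_type)
}

#' Write and read trial tables as CSV
#'
#' @param trials Trial table tibble.
#' @param path File path (`.csv`).
#' @return `path` invisibly; `read_trial_table()` returns the tibble.
#' @export
write_trial_table <- function(trials, path) {
  readr::write_csv(trials, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a NIfTI volume or binary ROI mask
#'
#' Thin wrappers over RNifti for real-data mode: `read_nifti_matrix()`
#' flattens a 4D BOLD volume to a timepoints-by-voxels matrix (voxel order
#' = column-major over the volume grid); `read_nifti_mask()` returns the
#' linear voxel indices of a binary mask.
#'
#' @param path NIfTI file path.
#' @return A matrix (with attribute `"dim3"`) or an integer index vector.
#' @export
read_nifti_matrix <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stopf("RNifti is required to read NIfTI volumes", class = "typicality_io_error")
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) {
    stopf("%s: expected a 4D volume, got %d dims", path, length(d),
          class = "typicality_io_error")
  }
  m <- t(matrix(as.numeric(img), prod(d[1:3]), d[4]))
  attr(m, "dim3") <- d[1:3]
  m
}

#' @rdname read_nifti_matrix
#' @export
read_nifti_mask <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stopf("RNifti is required to read NIfTI masks", class = "typicality_io_error")
  }
  img <- RNifti::readNifti(path)
  which(as.numeric(img) != 0)
}
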