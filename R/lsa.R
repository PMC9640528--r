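#' Canonical double-gamma haemodynamic response function
#'
#' The FEAT/SPM-convention difference of gamma densities: response peak at
#' 6 s, undershoot peak at 16 s, undershoot ratio 1/6, no derivatives.
#'
#' @param t Time in seconds (vector).
#' @param peak,undershoot Gamma shape parameters (seconds to peak).
#' @param ratio Undershoot amplitude ratio.
#' @return HRF values at `t`.
#' @export
#' @examples
#' curve(hrf_double_gamma(x), 0, 30)
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h[t < 0] <- 0
  h
}

# convolve event boxcars with the HRF, sampled at the TR. A boxcar
# convolution is the difference of the HRF's running integral at the two
# interval edges, so each column is evaluated exactly (up to the fine-grid
# quadrature of the integral) in O(n_timepoints).
convolve_events <- function(onsets, durations, n_timepoints, tr_s, hrf_params) {
  dt <- 0.05
  t_grid <- seq(0, 34, by = dt)
  h <- do.call(hrf_double_gamma, c(list(t = t_grid), hrf_params))
  hcum <- c(0, cumsum((h[-1] + h[-length(h)]) / 2) * dt)  # trapezoid integral
  hrf_span <- max(t_grid)
  interp <- function(x) {
    # running integral of the HRF evaluated at arbitrary lags
    y <- numeric(length(x))
    y[x >= hrf_span] <- hcum[length(hcum)]
    mid <- x > 0 & x < hrf_span
    if (any(mid)) {
      i <- pmin(findInterval(x[mid], t_grid), length(t_grid) - 1L)
      w <- (x[mid] - t_grid[i]) / dt
      y[mid] <- (1 - w) * hcum[i] + w * hcum[i + 1L]
    }
    y
  }
  t_vol <- (seq_len(n_timepoints) - 1L) * tr_s
  cols <- matrix(0, n_timepoints, length(onsets))
  for (j in seq_along(onsets)) {
    cols[, j] <- interp(t_vol - onsets[j]) -
      interp(t_vol - onsets[j] - durations[j])
  }
  cols
}

#' Build a least-squares-all (LSA) trial-level design matrix
#'
#' One regressor per (trial, interval) event: the event boxcar convolved
#' with the canonical double-gamma HRF and sampled at the TR. Nuisance
#' columns, an intercept and an optional linear drift are appended. With the
#' study design of 144 trials and two modelled intervals this yields 288
#' task regressors per subject.
#'
#' @param events Event tibble with columns `onset_s`, `duration_s`,
#'   `trial_id`, `interval` (see [events_from_trials()]). Must belong to a
#'   single run.
#' @param n_timepoints Number of volumes in the run.
#' @param tr_s Repetition time (seconds).
#' @param nuisance Optional numeric matrix (`n_timepoints` rows) of nuisance
#'   regressors (e.g. motion); included but not reported.
#' @param add_intercept Include a constant column (default `TRUE`).
#' @param add_drift Include a linear drift column (default `FALSE`).
#' @param hrf_params Named list passed to [hrf_double_gamma()].
#' @param check_rank Error on a rank-deficient design, naming the collinear
#'   columns (default `TRUE`).
#' @return An object of class `lsa_design`: list with `matrix` (time by
#'   regressors), `column_labels` (tibble: `name`, `trial_id`, `interval`,
#'   `type`), `hrf_params` and `dof` (timepoints minus matrix rank).
#' @export
build_lsa_design <- function(events, n_timepoints, tr_s, nuisance = NULL,
                             add_intercept = TRUE, add_drift = FALSE,
                             hrf_params = list(), check_rank = TRUE) {
  n_timepoints <- check_count(n_timepoints, "n_timepoints")
  tr_s <- check_number(tr_s, "tr_s", min = 1e-9)
  bad <- which(!(events$duration_s > 0))
  if (length(bad)) {
    stopf("event(s) %s have non-positive duration",
          paste(bad, collapse = ", "), class = "typicality_validation_error")
  }
  if (any(events$onset_s < 0)) {
    stopf("negative event onsets", class = "typicality_validation_error")
  }
  run_len <- n_timepoints * tr_s
  if (max(events$onset_s + events$duration_s) > run_len) {
    stopf("events extend past the run (last offset %.1f s > run length %.1f s)",
          max(events$onset_s + events$duration_s), run_len,
          class = "typicality_validation_error")
  }
  events <- events[order(events$onset_s, events$interval), ]

  task <- convolve_events(events$onset_s, events$duration_s, n_timepoints,
                          tr_s, hrf_params)
  labels <- new_tbl(
    name = paste(events$trial_id, events$interval, sep = ":"),
    trial_id = events$trial_id, interval = events$interval, type = "task"
  )
  X <- task
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_timepoints) {
      stopf("nuisance matrix has %d rows; expected %d", nrow(nuisance),
            n_timepoints, class = "typicality_validation_error")
    }
    k <- ncol(nuisance)
    X <- cbind(X, nuisance)
    labels <- dplyr::bind_rows(labels, new_tbl(
      name = paste0("nuisance", seq_len(k)), trial_id = NA_character_,
      interval = NA_character_, type = "nuisance"))
  }
  if (add_drift) {
    X <- cbind(X, seq_len(n_timepoints) - (n_timepoints + 1) / 2)
    labels <- dplyr::bind_rows(labels, new_tbl(
      name = "drift", trial_id = NA_character_, interval = NA_character_,
      type = "drift"))
  }
  if (add_intercept) {
    X <- cbind(X, 1)
    labels <- dplyr::bind_rows(labels, new_tbl(
      name = "intercept", trial_id = NA_character_, interval = NA_character_,
      type = "intercept"))
  }
  colnames(X) <- labels$name
  qrX <- qr(X)
  if (check_rank && qrX$rank < ncol(X)) {
    dropped <- labels$name[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stopf("design is rank deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "), class = "typicality_rank_error")
  }
  structure(list(matrix = X, column_labels = labels,
                 hrf_params = hrf_params, dof = n_timepoints - qrX$rank),
            class = "lsa_design")
}

#' Fit the LSA model to a run of BOLD data
#'
#' Ordinary least squares per voxel against the full design; t-values use
#' the voxel's pooled residual variance and the design's residual degrees of
#' freedom; z-values come from [t_to_z()].
#'
#' @param bold Numeric matrix, timepoints by voxels.
#' @param design An [build_lsa_design()] object.
#' @return An object of class `trial_estimates`: list with `beta`, `t_value`
#'   and `z_value` (task-trials by voxels, rows labelled `trial_id:interval`),
#'   `labels` (task rows of the design's column labels), and `dof`.
#' @export
fit_lsa <- function(bold, design) {
  stopifnot(inherits(design, "lsa_design"))
  bold <- as.matrix(bold)
  X <- design$matrix
  if (nrow(bold) != nrow(X)) {
    stopf("bold has %d timepoints; design has %d rows", nrow(bold), nrow(X),
          class = "typicality_validation_error")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- design$column_labels$name[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stopf("singular normal equations; collinear column(s): %s",
          paste(dropped, collapse = ", "), class = "typicality_rank_error")
  }
  beta <- qr.coef(qrX, bold)
  res <- bold - X %*% beta
  dof <- design$dof
  sigma2 <- colSums(res^2) / dof
  xtx_inv_diag <- diag(chol2inv(qr.R(qrX)))[order(qrX$pivot)]
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  tval <- beta / se
  task <- design$column_labels$type == "task"
  zval <- t_to_z(tval[task, , drop = FALSE], dof)
  structure(list(beta = beta[task, , drop = FALSE],
                 t_value = tval[task, , drop = FALSE],
                 z_value = zval,
                 labels = design$column_labels[task, ],
                 dof = dof),
            class = "trial_estimates")
}

#' Convert t-values to z-values via two-sided p
#'
#' `z = sign(t) * qnorm(1 - p/2)` with `p` the two-sided Student-t tail
#' probability at `dof` degrees of freedom. Computed in log space so large
#' |t| never underflows to an infinite z prematurely.
#'
#' @param t Numeric vector or matrix of t-values.
#' @param dof Degrees of freedom (scalar).
#' @return z-values with the shape of `t`.
#' @export
#' @examples
#' t_to_z(2, 10)
t_to_z <- function(t, dof) {
  dof <- check_number(dof, "dof", min = 1)
  log_tail <- pt(abs(t), df = dof, lower.tail = FALSE, log.p = TRUE)
  z <- sign(t) * qnorm(log_tail, lower.tail = FALSE, log.p = TRUE)
  if (is.matrix(t)) dimnames(z) <- dimnames(t)
  z
}

#' Restrict trial estimates to an ROI
#'
#' Subsets the voxel columns of a [fit_lsa()] result to a mask, preserving
#' the mask's order and attaching the ROI label as provenance.
#'
#' @param estimates A `trial_estimates` object.
#' @param mask Integer voxel indices (or logical vector over voxels).
#' @param roi Character ROI label to attach.
#' @return A `trial_estimates` object restricted to the mask.
#' @export
extract_roi <- function(estimates, mask, roi = NULL) {
  stopifnot(inherits(estimates, "trial_estimates"))
  nv <- ncol(estimates$beta)
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0) {
    stopf("empty ROI mask", class = "typicality_validation_error")
  }
  if (min(mask) < 1 || max(mask) > nv) {
    stopf("mask indices outside 1..%d", nv, class = "typicality_validation_error")
  }
  out <- estimates
  for (f in c("beta", "t_value", "z_value")) {
    out[[f]] <- estimates[[f]][, mask, drop = FALSE]
  }
  out$roi <- roi
  out
}

#' Fit the trial GLM across a synthetic BOLD cohort
#'
#' Runs [build_lsa_design()] + [fit_lsa()] per subject, run and ROI on a
#' [generate_bold()] object, then concatenates the per-run estimates into
#' one trials-by-voxels matrix per subject, ROI and interval. Models are fit
#' per run and estimates concatenated across runs.
#'
#' @param bold A `synthetic_bold` object.
#' @param interval Which event interval to return (`"question"` or
#'   `"answer"`).
#' @param value Which statistic to return per trial and voxel: `"beta"`
#'   (default; the planted-amplitude scale) or `"z"`.
#' @param nuisance Optional function `(subject_id, run, n_timepoints) ->
#'   matrix` supplying per-run nuisance regressors.
#' @return A tibble with one row per (subject, ROI): `subject_id`, `roi`,
#'   `patterns` (list-column of trials-by-voxels matrices, rows named by
#'   `trial_id`), `dof` (list of per-run dof).
#' @export
fit_trial_glm <- function(bold, interval = c("question", "answer"),
                          value = c("beta", "z"), nuisance = NULL) {
  stopifnot(inherits(bold, "synthetic_bold"))
  interval <- match.arg(interval)
  value <- match.arg(value)
  field <- if (value == "beta") "beta" else "z_value"
  series <- bold$series
  tr_s <- bold$tr_seconds
  events_all <- bold$events
  cells <- dplyr::distinct(series, .data$subject_id, .data$roi)
  out <- purrr::pmap(cells, function(subject_id, roi) {
    rows <- series[series$subject_id == subject_id & series$roi == roi, ]
    rows <- rows[order(rows$run), ]
    per_run <- purrr::pmap(
      list(rows$run, rows$bold, rows$n_timepoints),
      function(run, y, n_tp) {
        ev <- events_all[events_all$subject_id == subject_id &
                           events_all$run == run, ]
        nuis <- if (is.null(nuisance)) NULL else nuisance(subject_id, run, n_tp)
        des <- build_lsa_design(ev, n_tp, tr_s, nuisance = nuis)
        est <- fit_lsa(y, des)
        keep <- est$labels$interval == interval
        m <- est[[field]][keep, , drop = FALSE]
        rownames(m) <- est$labels$trial_id[keep]
        list(m = m, dof = est$dof)
      })
    list(patterns = do.call(rbind, purrr::map(per_run, "m")),
         dof = purrr::map_int(per_run, "dof"))
  })
  cells$patterns <- purrr::map(out, "patterns")
  cells$dof <- purrr::map(out, "dof")
  cells
}
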