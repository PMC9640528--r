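#' Generate the trial table for a synthetic cohort
#'
#' Lays out every trial of the cohort: per subject and run, the two curiosity
#' conditions in randomized order, question onsets, anticipation delays drawn
#' from the allowed set, and answer onsets. Two hidden ground-truth columns
#' are attached per trial: `latent_modulator`, a standard-normal scalar
#' standing in for anticipatory midbrain (VTA) drive, and
#' `latent_eccentricity`, the planted correlation distance of the trial's
#' upcoming activation pattern from the prototypical state,
#'
#'   `max(0, base + shift * [condition == high] + slope * modulator + noise)`
#'
#' so that a high-vs-low fixed effect on measured distance recovers `shift`
#' and a modulator slope recovers `slope`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per trial: `subject_id`, `run`,
#'   `trial_in_run`, `trial_id`, `condition`, `curiosity_rating`,
#'   `onset_question_s`, `delay_s`, `onset_answer_s`, `latent_modulator`,
#'   `latent_eccentricity`.
#' @export
#' @examples
#' trials <- generate_trial_table(cohort_spec(n_subjects = 2, seed = 7))
#' nrow(trials) # 2 subjects x 6 runs x 24 trials
generate_trial_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(child_seed(spec$seed, "trial_table"))
  n_per_run <- spec$trials_per_condition_per_run * length(spec$conditions)
  high <- spec$conditions[1]

  grid <- tidyr::expand_grid(
    subject_id = sprintf("S%02d", seq_len(spec$n_subjects)),
    run = seq_len(spec$n_runs)
  )
  rows <- purrr::pmap(grid, function(subject_id, run) {
    condition <- sample(rep(spec$conditions, spec$trials_per_condition_per_run))
    delay <- sample(spec$anticipation_delays_s, n_per_run, replace = TRUE)
    iti <- runif(n_per_run, spec$iti_range_s[1], spec$iti_range_s[2])
    # onset accumulation: question ... (delay) ... answer ... iti ... next question
    trial_len <- delay + spec$answer_duration_s + iti
    onset_q <- c(0, cumsum(trial_len))[seq_len(n_per_run)]
    new_tbl(
      subject_id = subject_id, run = run,
      trial_in_run = seq_len(n_per_run),
      condition = condition,
      curiosity_rating = ifelse(condition == high, runif(n_per_run, 60, 100),
                                runif(n_per_run, 0, 40)),
      onset_question_s = onset_q,
      delay_s = delay,
      onset_answer_s = onset_q + delay,
      latent_modulator = rnorm(n_per_run)
    )
  })
  trials <- dplyr::bind_rows(rows)
  trials$trial_id <- sprintf("%s_r%d_t%02d", trials$subject_id, trials$run,
                             trials$trial_in_run)
  trials$latent_eccentricity <- pmax(
    0,
    spec$eccentricity_base +
      spec$eccentricity_condition_shift * (trials$condition == high) +
      spec$modulator_typicality_slope * trials$latent_modulator +
      rnorm(nrow(trials), 0, spec$eccentricity_noise_sd)
  )
  dplyr::relocate(trials, "trial_id", .after = "trial_in_run")
}

#' Simulate trial-level memory outcomes
#'
#' Draws a binary recall outcome per trial from a logistic model on the
#' hidden ground truth: condition-specific intercept plus the planted
#' typicality and modulator slopes. With both slopes at zero the marginal
#' recall rate per condition equals the inverse-logit of its intercept
#' (defaults: 0.63 high, 0.40 low).
#'
#' @param trials A trial table from [generate_trial_table()].
#' @param spec The [cohort_spec()] that produced it.
#' @return `trials` with a `recalled` column in `{0, 1}`.
#' @export
generate_memory_outcomes <- function(trials, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!all(c("latent_modulator", "latent_eccentricity") %in% names(trials))) {
    stopf("latent columns missing; run generate_trial_table() first")
  }
  set.seed(child_seed(spec$seed, "memory"))
  eta <- unname(spec$memory_intercept_by_condition[trials$condition]) +
    spec$memory_typicality_slope * trials$latent_eccentricity +
    spec$memory_modulator_slope * trials$latent_modulator
  trials$recalled <- rbinom(nrow(trials), 1L, plogis(eta))
  trials
}

#' Generate multivoxel activation patterns with planted typicality
#'
#' For every subject and ROI a fixed random prototype vector is drawn; each
#' trial's pattern is placed at exactly its latent eccentricity (in
#' correlation-distance units) from that prototype, displaced along a
#' trial-unique random direction orthogonal to the prototype, and then
#' perturbed by i.i.d. Gaussian voxel noise. The ROI named
#' `spec$modulator_roi` is generated differently: the latent modulator is
#' added as a spatially uniform amplitude, so its ROI mean observes the
#' modulator (a VTA-like univariate signal).
#'
#' With `pattern_noise_sd = 0` the correlation distance of each trial from
#' the (standardized) prototype equals `latent_eccentricity` exactly, making
#' distance-from-centroid an identifiable ground truth.
#'
#' @param trials Trial table.
#' @param spec The generating [cohort_spec()].
#' @return An object of class `synthetic_patterns`: a tibble with one row
#'   per (subject, ROI) and list-columns `prototype` (voxel vector),
#'   `patterns` (trials-by-voxels matrix, rows named by `trial_id`) and
#'   `amplitude` (per-trial BOLD amplitude, default 1).
#' @export
generate_patterns <- function(trials, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(child_seed(spec$seed, "patterns"))
  rois <- names(spec$n_voxels_by_roi)
  bad <- rois[spec$n_voxels_by_roi < 3 & rois != spec$modulator_roi]
  if (length(bad)) {
    stopf("ROI(s) %s have < 3 voxels", paste(bad, collapse = ", "),
          class = "typicality_config_error")
  }

  out <- tidyr::expand_grid(subject_id = unique(trials$subject_id), roi = rois)
  gen_one <- function(subject_id, roi) {
    v <- spec$n_voxels_by_roi[[roi]]
    tr <- trials[trials$subject_id == subject_id, ]
    n <- nrow(tr)
    if (roi == spec$modulator_roi) {
      # centered prototype: the ROI mean observes the modulator plus
      # measurement noise only, with no subject-level amplitude offset
      proto <- rnorm(v) * spec$prototype_scale
      proto <- proto - mean(proto)
      pat <- matrix(proto, n, v, byrow = TRUE) +
        tr$latent_modulator +
        rnorm(n * v, 0, spec$pattern_noise_sd)
    } else {
      proto <- unit_center(rnorm(v)) * spec$prototype_scale
      phat <- proto / sqrt(sum(proto^2))
      e <- pmin(pmax(tr$latent_eccentricity, 0), 2)
      cc <- 1 - e
      ss <- sqrt(pmax(0, 1 - cc^2))
      # trial-unique unit directions orthogonal to the constant vector and
      # the prototype, so correlation distance from the prototype is exact
      U <- matrix(rnorm(n * v), n, v)
      U <- U - rowMeans(U)
      U <- U - tcrossprod(U %*% phat, phat)
      U <- U / sqrt(rowSums(U^2))
      pat <- spec$prototype_scale * (tcrossprod(cc, phat) + ss * U)
      if (spec$pattern_noise_sd > 0) {
        pat <- pat + rnorm(n * v, 0, spec$pattern_noise_sd)
      }
    }
    rownames(pat) <- tr$trial_id
    list(prototype = proto, patterns = pat, amplitude = rep(1, n))
  }
  cells <- purrr::pmap(out, gen_one)
  out$prototype <- purrr::map(cells, "prototype")
  out$patterns <- purrr::map(cells, "patterns")
  out$amplitude <- purrr::map(cells, "amplitude")
  structure(out, class = c("synthetic_patterns", class(out)))
}

#' Build an event table from a trial table
#'
#' Expands each trial into its question and answer events. The question
#' epoch is configurable: `"anticipation"` spans question onset to answer
#' onset (the default the convergence analysis targets), `"stim"` covers
#' only the question presentation, `"impulse"` is a brief 0.1 s event.
#'
#' @param trials Trial table.
#' @param spec A [cohort_spec()].
#' @param question_epoch One of `"anticipation"`, `"stim"`, `"impulse"`.
#' @return A tibble with `subject_id`, `run`, `trial_id`, `interval`,
#'   `onset_s`, `duration_s`, `condition`.
#' @export
events_from_trials <- function(trials, spec,
                               question_epoch = c("anticipation", "stim", "impulse")) {
  question_epoch <- match.arg(question_epoch)
  qdur <- switch(question_epoch,
                 anticipation = trials$delay_s,
                 stim = rep(spec$question_duration_s, nrow(trials)),
                 impulse = rep(0.1, nrow(trials)))
  dplyr::bind_rows(
    new_tbl(subject_id = trials$subject_id, run = trials$run,
            trial_id = trials$trial_id, interval = "question",
            onset_s = trials$onset_question_s, duration_s = qdur,
            condition = trials$condition),
    new_tbl(subject_id = trials$subject_id, run = trials$run,
            trial_id = trials$trial_id, interval = "answer",
            onset_s = trials$onset_answer_s,
            duration_s = spec$answer_duration_s,
            condition = trials$condition)
  ) |>
    dplyr::arrange(.data$subject_id, .data$run, .data$onset_s, .data$interval)
}

#' Generate BOLD time series from planted patterns
#'
#' Per subject, run and ROI, the series is the sum over trials and intervals
#' of the HRF-convolved event boxcar scaled, voxel by voxel, by that trial's
#' pattern value times its amplitude, plus Gaussian noise. Run length covers
#' the last event offset plus 20 s. Because the generator uses the same
#' design construction as [build_lsa_design()], a noiseless series is an
#' exact linear combination of the GLM's task regressors and the LSA fit
#' recovers the planted trial patterns to numerical precision.
#'
#' @param trials Trial table.
#' @param patterns A `synthetic_patterns` object.
#' @param spec The generating [cohort_spec()].
#' @param question_epoch Passed to [events_from_trials()].
#' @return An object of class `synthetic_bold`: list with `series` (tibble:
#'   `subject_id`, `run`, `roi`, `bold` list-column of time-by-voxel
#'   matrices, `n_timepoints`), `events` (event tibble), and `tr_seconds`.
#' @export
generate_bold <- function(trials, patterns, spec,
                          question_epoch = c("anticipation", "stim", "impulse")) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(patterns, "synthetic_patterns"))
  question_epoch <- match.arg(question_epoch)
  set.seed(child_seed(spec$seed, "bold"))
  events <- events_from_trials(trials, spec, question_epoch)

  runs <- dplyr::distinct(trials, .data$subject_id, .data$run)
  sim_run <- function(subject_id, run) {
    ev <- events[events$subject_id == subject_id & events$run == run, ]
    n_tp <- ceiling((max(ev$onset_s + ev$duration_s) + 20) / spec$tr_seconds)
    des <- build_lsa_design(ev, n_timepoints = n_tp, tr_s = spec$tr_seconds,
                            add_intercept = FALSE, check_rank = FALSE)
    task <- des$matrix
    labs <- des$column_labels
    per_roi <- lapply(rois_tbl$roi[rois_tbl$subject_id == subject_id], function(roi) {
      cell <- patterns[patterns$subject_id == subject_id & patterns$roi == roi, ]
      pat <- cell$patterns[[1]]
      amp <- cell$amplitude[[1]]
      idx <- match(labs$trial_id, rownames(pat))   # one pattern row per regressor
      B <- pat[idx, , drop = FALSE] * amp[idx]
      y <- task %*% B
      if (spec$bold_noise_sd > 0) {
        y <- y + rnorm(length(y), 0, spec$bold_noise_sd)
      }
      y
    })
    new_tbl(subject_id = subject_id, run = run,
            roi = rois_tbl$roi[rois_tbl$subject_id == subject_id],
            bold = per_roi, n_timepoints = n_tp)
  }
  rois_tbl <- dplyr::distinct(patterns[, c("subject_id", "roi")])
  series <- dplyr::bind_rows(purrr::pmap(runs, sim_run))
  structure(list(series = series, events = events, tr_seconds = spec$tr_seconds,
                 question_epoch = question_epoch),
            class = "synthetic_bold")
}

#' Simulate a whole cohort in one call
#'
#' Convenience driver for the generator: trial table, memory outcomes and
#' patterns (and, in BOLD mode, run-wise time series).
#'
#' @param spec A [cohort_spec()].
#' @param mode `"pattern"` (default) to stop at activation patterns,
#'   `"bold"` to also synthesize time series.
#' @return A list with `trials`, `patterns`, and (BOLD mode) `bold`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_subjects = 2, n_voxels_by_roi = c(HPC = 40, VTA = 10)))
#' names(coh)
simulate_cohort <- function(spec, mode = c("pattern", "bold")) {
  mode <- match.arg(mode)
  trials <- generate_trial_table(spec)
  trials <- generate_memory_outcomes(trials, spec)
  patterns <- generate_patterns(trials, spec)
  out <- list(trials = trials, patterns = patterns, spec = spec)
  if (mode == "bold") {
    out$bold <- generate_bold(trials, patterns, spec)
  }
  out
}

#' Simulate a voxel grid with an optional region coupled to a trial series
#'
#' Builds a trials-by-voxels matrix of standard-normal noise in which a
#' chosen subset of voxels is correlated (population correlation `rho`) with
#' a supplied per-trial series. Used to validate the permutation-null
#' voxelwise map: under `rho = 0` every voxel is null; a planted region
#' should survive family-wise error control.
#'
#' @param reference Per-trial numeric series (e.g. pattern typicality).
#' @param n_voxels Number of voxels in the grid.
#' @param coupled Integer indices of voxels coupled to `reference`.
#' @param rho Population correlation of coupled voxels with `reference`.
#' @param seed Integer seed.
#' @return A trials-by-voxels numeric matrix.
#' @export
simulate_coupled_grid <- function(reference, n_voxels, coupled = integer(0),
                                  rho = 0.5, seed = 1L) {
  n <- length(reference)
  if (n < 4) stopf("need at least 4 trials")
  if (length(coupled) && (min(coupled) < 1 || max(coupled) > n_voxels)) {
    stopf("coupled indices outside 1..%d", n_voxels)
  }
  check_number(rho, "rho", min = -1, max = 1)
  set.seed(child_seed(seed, "grid"))
  g <- matrix(rnorm(n * n_voxels), n, n_voxels)
  if (length(coupled)) {
    z <- as.numeric(scale(reference))
    g[, coupled] <- rho * z + sqrt(1 - rho^2) * g[, coupled]
  }
  g
}
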