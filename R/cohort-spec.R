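#' Specify a synthetic cohort
#'
#' Builds the full parameter set for the synthetic-cohort generator. The
#' defaults reproduce the design of the curiosity/anticipation study the
#' package targets: 23 subjects, 6 runs, 12 high- plus 12 low-curiosity
#' trials per run, a 4 s question followed by a 9 s or 13 s anticipation
#' delay and a 1 s answer, TR of 2 s, and memory intercepts calibrated so
#' that (at zero slopes) expected recall is 0.63 under high and 0.40 under
#' low curiosity.
#'
#' Planted effects are expressed in the units the analysis estimates them
#' in: `eccentricity_condition_shift` is the high-minus-low shift in
#' correlation-distance units (negative = high-curiosity trials closer to
#' the prototype), `modulator_typicality_slope` is the change in distance
#' per unit of the latent modulatory (VTA-like) scalar, and the two memory
#' slopes are log-odds per distance unit and per modulator unit.
#'
#' @param n_subjects,n_runs,trials_per_condition_per_run Design counts.
#' @param conditions Condition labels; the first is the "high" condition the
#'   shift applies to.
#' @param n_voxels_by_roi Named integer vector of voxels per ROI. The ROI
#'   named by `modulator_roi` carries the latent modulator as an additive
#'   amplitude (its ROI mean observes the modulator); all other ROIs carry
#'   the planted eccentricity geometry.
#' @param modulator_roi Name of the ROI whose univariate mean observes the
#'   latent modulator (default `"VTA"`).
#' @param tr_seconds Repetition time in seconds.
#' @param question_duration_s,answer_duration_s Stimulus durations (s).
#' @param anticipation_delays_s Possible question-to-answer delays (s).
#' @param iti_range_s Length-2 range of the uniform inter-trial interval (s).
#' @param prototype_scale Multiplier applied to the (unit-norm) prototype.
#' @param eccentricity_base Baseline correlation distance from the prototype.
#' @param eccentricity_condition_shift Planted high-vs-low shift (distance).
#' @param eccentricity_noise_sd Trial-level sd of the eccentricity noise.
#' @param modulator_typicality_slope Planted modulator-to-distance slope.
#' @param memory_intercept_by_condition Named log-odds intercepts.
#' @param memory_typicality_slope Log-odds of recall per distance unit.
#' @param memory_modulator_slope Log-odds of recall per modulator unit.
#' @param pattern_noise_sd Per-voxel sd of i.i.d. pattern noise added on top
#'   of the unit-norm planted signal.
#' @param bold_noise_sd Per-sample sd of Gaussian noise in generated BOLD.
#' @param seed Integer seed; identical spec + seed gives an identical cohort.
#' @return An object of class `cohort_spec` (a named list).
#' @seealso [generate_trial_table()], [generate_patterns()], [generate_bold()]
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 4, seed = 1)
#' spec$n_subjects
cohort_spec <- function(n_subjects = 23,
                        n_runs = 6,
                        trials_per_condition_per_run = 12,
                        conditions = c("high", "low"),
                        n_voxels_by_roi = c(HPC = 300, VTA = 50),
                        modulator_roi = "VTA",
                        tr_seconds = 2,
                        question_duration_s = 4,
                        anticipation_delays_s = c(9, 13),
                        answer_duration_s = 1,
                        iti_range_s = c(1, 20),
                        prototype_scale = 1,
                        eccentricity_base = 0.5,
                        eccentricity_condition_shift = -0.02,
                        eccentricity_noise_sd = 0.15,
                        modulator_typicality_slope = -0.05,
                        memory_intercept_by_condition = c(high = qlogis(0.63),
                                                          low  = qlogis(0.40)),
                        memory_typicality_slope = -0.6,
                        memory_modulator_slope = 0.1,
                        pattern_noise_sd = 0.02,
                        bold_noise_sd = 0.5,
                        seed = 1L) {
  spec <- list(
    n_subjects = check_count(n_subjects, "n_subjects"),
    n_runs = check_count(n_runs, "n_runs"),
    trials_per_condition_per_run =
      check_count(trials_per_condition_per_run, "trials_per_condition_per_run"),
    conditions = as.character(conditions),
    n_voxels_by_roi = n_voxels_by_roi,
    modulator_roi = modulator_roi,
    tr_seconds = check_number(tr_seconds, "tr_seconds", min = 1e-6),
    question_duration_s = check_number(question_duration_s, "question_duration_s", min = 0),
    anticipation_delays_s = as.numeric(anticipation_delays_s),
    answer_duration_s = check_number(answer_duration_s, "answer_duration_s", min = 0),
    iti_range_s = as.numeric(iti_range_s),
    prototype_scale = check_number(prototype_scale, "prototype_scale", min = 1e-12),
    eccentricity_base = check_number(eccentricity_base, "eccentricity_base", min = 0),
    eccentricity_condition_shift =
      check_number(eccentricity_condition_shift, "eccentricity_condition_shift"),
    eccentricity_noise_sd = check_number(eccentricity_noise_sd, "eccentricity_noise_sd", min = 0),
    modulator_typicality_slope =
      check_number(modulator_typicality_slope, "modulator_typicality_slope"),
    memory_intercept_by_condition = memory_intercept_by_condition,
    memory_typicality_slope = check_number(memory_typicality_slope, "memory_typicality_slope"),
    memory_modulator_slope = check_number(memory_modulator_slope, "memory_modulator_slope"),
    pattern_noise_sd = check_number(pattern_noise_sd, "pattern_noise_sd", min = 0),
    bold_noise_sd = check_number(bold_noise_sd, "bold_noise_sd", min = 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  validate_cohort_spec(structure(spec, class = "cohort_spec"))
}

validate_cohort_spec <- function(spec) {
  if (length(spec$conditions) < 1L || anyDuplicated(spec$conditions)) {
    stopf("`conditions` must be distinct labels", class = "typicality_config_error")
  }
  if (is.null(names(spec$n_voxels_by_roi)) || any(names(spec$n_voxels_by_roi) == "")) {
    stopf("`n_voxels_by_roi` must be a named vector", class = "typicality_config_error")
  }
  spec$n_voxels_by_roi <-
    vapply(seq_along(spec$n_voxels_by_roi), function(i) {
      check_count(spec$n_voxels_by_roi[[i]], names(spec$n_voxels_by_roi)[i], min = 1L)
    }, integer(1), USE.NAMES = FALSE) |>
    setNames(names(spec$n_voxels_by_roi))
  non_mod <- setdiff(names(spec$n_voxels_by_roi), spec$modulator_roi)
  if (any(spec$n_voxels_by_roi[non_mod] < 3L)) {
    stopf("pattern ROIs need >= 3 voxels for correlation distance (got %s)",
          paste(spec$n_voxels_by_roi[non_mod], collapse = ", "),
          class = "typicality_config_error")
  }
  if (length(spec$anticipation_delays_s) < 1L || any(spec$anticipation_delays_s <= 0)) {
    stopf("`anticipation_delays_s` must be positive durations", class = "typicality_config_error")
  }
  if (length(spec$iti_range_s) != 2L || any(spec$iti_range_s < 0) ||
      spec$iti_range_s[1] > spec$iti_range_s[2]) {
    stopf("`iti_range_s` must be a nondecreasing nonnegative pair", class = "typicality_config_error")
  }
  miss <- setdiff(spec$conditions, names(spec$memory_intercept_by_condition))
  if (length(miss)) {
    stopf("`memory_intercept_by_condition` missing condition(s): %s",
          paste(miss, collapse = ", "), class = "typicality_config_error")
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  %d subjects x %d runs x %d trials/condition/run (%s)\n",
              x$n_subjects, x$n_runs, x$trials_per_condition_per_run,
              paste(x$conditions, collapse = "/")))
  cat(sprintf("  ROIs: %s\n",
              paste(sprintf("%s[%d]", names(x$n_voxels_by_roi), x$n_voxels_by_roi),
                    collapse = ", ")))
  cat(sprintf("  planted: condition shift %+.3f, modulator slope %+.3f, memory slopes (%+.2f, %+.2f)\n",
              x$eccentricity_condition_shift, x$modulator_typicality_slope,
              x$memory_typicality_slope, x$memory_modulator_slope))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
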