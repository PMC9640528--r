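test_that("trial table has the study's design structure", {
  spec <- cohort_spec(seed = 4)
  trials <- generate_trial_table(spec)
  expect_equal(nrow(trials), 23 * 6 * 24)
  counts <- dplyr::count(trials, subject_id, run, condition)
  expect_true(all(counts$n == 12))                       # counterbalanced
  expect_true(all(trials$delay_s %in% c(9, 13)))
  expect_equal(trials$onset_answer_s, trials$onset_question_s + trials$delay_s)
  ord <- trials |>
    dplyr::group_by(subject_id, run) |>
    dplyr::summarise(inc = all(diff(onset_question_s) > 0), .groups = "drop")
  expect_true(all(ord$inc))
})

test_that("degenerate generator settings give constant eccentricity", {
  spec <- tiny_spec(eccentricity_noise_sd = 0, eccentricity_condition_shift = 0,
                    modulator_typicality_slope = 0)
  trials <- generate_trial_table(spec)
  expect_true(all(trials$latent_eccentricity == spec$eccentricity_base))
})

test_that("identical spec and seed reproduce the cohort byte-for-byte", {
  spec <- tiny_spec(seed = 99)
  t1 <- generate_memory_outcomes(generate_trial_table(spec), spec)
  t2 <- generate_memory_outcomes(generate_trial_table(spec), spec)
  f1 <- tempfile(); f2 <- tempfile()
  write_trial_table(t1, f1); write_trial_table(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  p1 <- generate_patterns(t1, spec); p2 <- generate_patterns(t2, spec)
  expect_identical(p1$patterns, p2$patterns)
})

test_that("non-positive design counts are a configuration error", {
  expect_error(cohort_spec(n_subjects = 0), class = "typicality_config_error")
  expect_error(cohort_spec(trials_per_condition_per_run = -1),
               class = "typicality_config_error")
  expect_error(cohort_spec(n_voxels_by_roi = c(HPC = 2, VTA = 5)),
               class = "typicality_config_error")
})

test_that("memory intercepts calibrate marginal recall rates at zero slopes", {
  spec <- cohort_spec(memory_typicality_slope = 0, memory_modulator_slope = 0,
                      seed = 21)
  trials <- generate_memory_outcomes(generate_trial_table(spec), spec)
  rates <- trials |>
    dplyr::group_by(condition) |>
    dplyr::summarise(rate = mean(recalled), n = dplyr::n())
  # realized rate within the binomial 99% CI of the intercept-implied p
  for (cond in c("high", "low")) {
    p0 <- plogis(spec$memory_intercept_by_condition[[cond]])
    row <- rates[rates$condition == cond, ]
    half <- 2.576 * sqrt(p0 * (1 - p0) / row$n)
    expect_lt(abs(row$rate - p0), half)
  }
  expect_equal(plogis(spec$memory_intercept_by_condition[["high"]]), 0.63)
  expect_equal(plogis(spec$memory_intercept_by_condition[["low"]]), 0.40)
})

test_that("a hugely negative typicality slope saturates recall to zero", {
  spec <- tiny_spec(memory_typicality_slope = -1e6, memory_modulator_slope = 0)
  trials <- generate_memory_outcomes(generate_trial_table(spec), spec)
  expect_true(all(trials$recalled[trials$latent_eccentricity > 0] == 0))
})

test_that("logistic fit on the generator's own latents recovers the planted slope", {
  spec <- cohort_spec(memory_typicality_slope = -0.6, memory_modulator_slope = 0,
                      seed = 7)
  trials <- generate_memory_outcomes(generate_trial_table(spec), spec)
  fit <- glm(recalled ~ latent_eccentricity + condition, binomial, data = trials)
  est <- unname(coef(fit)[2]); se <- sqrt(diag(vcov(fit)))[2]
  expect_lt(abs(est - (-0.6)), 3 * se)
})

test_that("noise-free patterns sit exactly at their planted eccentricity", {
  spec <- tiny_spec(pattern_noise_sd = 0)
  trials <- generate_trial_table(spec)
  pats <- generate_patterns(trials, spec)
  cell <- pats[pats$subject_id == "S01" & pats$roi == "HPC", ]
  mat <- cell$patterns[[1]]
  proto <- cell$prototype[[1]]
  e <- trials$latent_eccentricity[match(rownames(mat), trials$trial_id)]
  d <- apply(mat, 1, function(r) 1 - cor(r, proto))
  expect_equal(unname(d), unname(e), tolerance = 1e-10)
})

test_that("zero eccentricity and zero noise collapse every trial onto the prototype", {
  spec <- tiny_spec(pattern_noise_sd = 0, eccentricity_base = 0,
                    eccentricity_condition_shift = 0,
                    modulator_typicality_slope = 0, eccentricity_noise_sd = 0)
  trials <- generate_trial_table(spec)
  pats <- generate_patterns(trials, spec)
  mat <- pats$patterns[[which(pats$roi == "HPC")[1]]]
  proto <- pats$prototype[[which(pats$roi == "HPC")[1]]]
  expect_true(all(abs(sweep(mat, 2, proto)) < 1e-12))
  # all pairwise correlation distances are 0
  expect_true(all(abs(1 - cor(t(mat))) < 1e-12))
})

test_that("mean distance from prototype is ordered by planted eccentricity", {
  spec <- tiny_spec(pattern_noise_sd = 0, eccentricity_noise_sd = 0,
                    eccentricity_base = 0.2, eccentricity_condition_shift = 0.3,
                    modulator_typicality_slope = 0)
  trials <- generate_trial_table(spec)     # high condition planted at 0.5, low 0.2
  pats <- generate_patterns(trials, spec)
  cell <- pats[pats$subject_id == "S01" & pats$roi == "HPC", ]
  d <- apply(cell$patterns[[1]], 1, function(r) 1 - cor(r, cell$prototype[[1]]))
  cond <- trials$condition[match(rownames(cell$patterns[[1]]), trials$trial_id)]
  expect_lt(mean(d[cond == "low"]), mean(d[cond == "high"]))
})

test_that("pattern matrices have one row per trial at the documented sizes", {
  spec <- cohort_spec(n_voxels_by_roi = c(HPC = 300, VTA = 50), seed = 2)
  trials <- generate_trial_table(spec)
  pats <- generate_patterns(trials, spec)
  hpc <- do.call(rbind, pats$patterns[pats$roi == "HPC"])
  expect_equal(dim(hpc), c(3312, 300))
})

test_that("the modulator ROI's mean observes the latent modulator", {
  spec <- tiny_spec(seed = 12)
  trials <- generate_trial_table(spec)
  pats <- generate_patterns(trials, spec)
  uni <- compute_roi_means(pats, trials)
  m <- dplyr::left_join(uni[uni$roi == "VTA", ], trials, by = "trial_id")
  expect_gt(cor(m$roi_mean_z, m$latent_modulator), 0.9)
})

test_that("planted monotonicity: measured distance tracks latent eccentricity", {
  for (s in 1:3) {
    spec <- tiny_spec(pattern_noise_sd = 0,
                      n_voxels_by_roi = c(HPC = 150, VTA = 8), seed = s)
    coh <- simulate_cohort(spec)
    # distance from the prototype is exactly monotone in the latent
    for (subj in c("S01", "S02")) {
      cell <- coh$patterns[coh$patterns$subject_id == subj &
                             coh$patterns$roi == "HPC", ]
      d <- apply(cell$patterns[[1]], 1, function(r) 1 - cor(r, cell$prototype[[1]]))
      e <- coh$trials$latent_eccentricity[match(rownames(cell$patterns[[1]]),
                                                coh$trials$trial_id)]
      expect_equal(cor(d, e, method = "spearman"), 1)
    }
    # distance from the held-out-fold centroid preserves it up to fold jitter
    typ <- compute_typicality(coh$patterns, coh$trials, rois = "HPC")
    e <- coh$trials$latent_eccentricity[match(typ$trial_id, coh$trials$trial_id)]
    rho <- typ |>
      dplyr::mutate(e = e) |>
      dplyr::group_by(subject_id) |>
      dplyr::summarise(r = cor(distance, e, method = "spearman"))
    expect_true(all(rho$r > 0.95))
  }
})
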