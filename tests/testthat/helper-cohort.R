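# small cohort specs used across test files; sizes chosen for test speed,
# effects kept at package defaults unless a test plants its own

tiny_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_subjects = 3, n_runs = 4, trials_per_condition_per_run = 6,
         n_voxels_by_roi = c(HPC = 40, VTA = 8), seed = seed),
    list(...))
  do.call(cohort_spec, args)
}

null_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(eccentricity_condition_shift = 0, modulator_typicality_slope = 0,
         memory_typicality_slope = 0, memory_modulator_slope = 0, seed = seed),
    list(...))
  do.call(cohort_spec, args)
}

# modeling table for a cohort at the given spec (pattern-level mode)
modeling_table_for <- function(spec, roi = "HPC") {
  coh <- simulate_cohort(spec)
  typ <- compute_typicality(coh$patterns, coh$trials, rois = roi)
  join_features(compute_roi_means(coh$patterns, coh$trials), typ, coh$trials)
}

# naive reference implementation of leave-one-run-out typicality:
# explicit loops, its own centroid and correlation code (kmeans_mean only)
brute_force_loro <- function(patterns, runs) {
  std <- t(apply(patterns, 1, function(r) (r - mean(r)) / sd(r)))
  out <- numeric(nrow(patterns))
  for (r in unique(runs)) {
    centroid <- colMeans(std[runs != r, , drop = FALSE])
    for (i in which(runs == r)) {
      out[i] <- 1 - cor(patterns[i, ], centroid)
    }
  }
  out
}
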