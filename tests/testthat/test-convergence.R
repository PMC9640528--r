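test_that("correlation distance has the metric's basic geometry", {
  x <- c(1, 2, 3, 5)
  expect_equal(correlation_distance(x, x), 0)
  expect_equal(correlation_distance(x, -x), 2)
  expect_equal(correlation_distance(x, 2 * x + 7), 0)   # affine invariance
  # hand-computed Pearson r for the 3-vectors (1,2,3), (1,2,4): r = 27/sqrt(756)
  expect_equal(correlation_distance(c(1, 2, 3), c(1, 2, 4)),
               1 - 27 / sqrt(756), tolerance = 1e-12)
  expect_equal(1 - 27 / sqrt(756), 0.018019494, tolerance = 1e-7)
  expect_error(correlation_distance(rep(1, 4), x),
               class = "typicality_degenerate_error")
  expect_error(correlation_distance(1:3, 1:4), class = "typicality_validation_error")
})

test_that("both centroid estimators collapse onto a repeated pattern", {
  m <- matrix(rep(c(1, 4, 2, 6, 3), 5), 5, 5, byrow = TRUE)
  for (method in c("kmeans_mean", "medoid")) {
    cen <- compute_centroid(m, method)
    expect_equal(correlation_distance(as.numeric(cen), m[1, ]), 0, tolerance = 1e-12)
    expect_equal(attr(cen, "summed_distance"), 0, tolerance = 1e-12)
  }
  expect_error(compute_centroid(m[1, , drop = FALSE]),
               class = "typicality_validation_error")
})

test_that("the medoid equals an exhaustive search over candidate rows", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(rnorm(20 * 15), 20, 15)
    med <- compute_centroid(m, "medoid")
    sums <- vapply(seq_len(nrow(m)), function(i) {
      sum(vapply(seq_len(nrow(m)),
                 function(j) 1 - cor(m[i, ], m[j, ]), numeric(1)))
    }, numeric(1))
    expect_equal(as.numeric(med), m[which.min(sums), ])
  }
})

test_that("antipodal clusters: medoid stays in a cluster, mean goes orthogonal", {
  set.seed(3)
  v <- rnorm(30)
  m <- rbind(matrix(rep(v, 10), 10, byrow = TRUE) + rnorm(300, 0, 0.05),
             matrix(rep(-v, 10), 10, byrow = TRUE) + rnorm(300, 0, 0.05))
  med <- compute_centroid(m, "medoid")
  km <- compute_centroid(m, "kmeans_mean")
  expect_gt(abs(cor(as.numeric(med), v)), 0.95)        # inside one cluster
  expect_lt(abs(cor(as.numeric(km), v)), 0.5)          # collapsed toward orthogonal
})

test_that("leave-one-run-out scoring is exact against a naive reimplementation", {
  set.seed(5)
  m <- matrix(rnorm(48 * 25), 48, 25)
  runs <- rep(1:4, each = 12)
  got <- loro_typicality(m, runs)
  expect_equal(got$distance, brute_force_loro(m, runs), tolerance = 1e-12)
  expect_equal(nrow(got$centroids), 4)
  expect_true(all(got$centroids$n_source_trials == 36))
})

test_that("identical patterns across runs score zero everywhere", {
  m <- matrix(rep(c(3, 1, 4, 1, 5), 12), 12, 5, byrow = TRUE)
  got <- loro_typicality(m, rep(1:3, each = 4))
  expect_equal(got$distance, rep(0, 12), tolerance = 1e-12)
})

test_that("fold independence: a fold's centroid ignores its own run", {
  set.seed(9)
  m <- matrix(rnorm(36 * 10), 36, 10)
  runs <- rep(1:3, each = 12)
  c_before <- loro_typicality(m, runs)$centroids
  m2 <- m
  m2[runs == 3, ] <- m2[runs == 3, ] + rnorm(120)     # perturb only run 3
  c_after <- loro_typicality(m2, runs)$centroids
  expect_identical(c_before$centroid[[3]], c_after$centroid[[3]])
  expect_false(identical(c_before$centroid[[1]], c_after$centroid[[1]]))
})

test_that("a trial's distance is invariant to positive rescaling of its pattern", {
  set.seed(13)
  m <- matrix(rnorm(24 * 12), 24, 12)
  runs <- rep(1:2, each = 12)
  d0 <- loro_typicality(m, runs)$distance
  m[5, ] <- 10 * m[5, ]
  expect_equal(loro_typicality(m, runs)$distance[5], d0[5], tolerance = 1e-12)
  expect_true(all(d0 >= 0 & d0 <= 2))
})

test_that("degenerate leave-one-run-out inputs are rejected", {
  m <- matrix(rnorm(40), 4, 10)
  expect_error(loro_typicality(m, rep(1, 4)), class = "typicality_validation_error")
  expect_error(loro_typicality(m, 1:3), class = "typicality_validation_error")
})

test_that("within-subject standardization matches direct group-by arithmetic", {
  tbl <- tibble::tibble(
    subject_id = rep(c("a", "b"), each = 2), roi = "HPC",
    trial_id = paste0("t", 1:4), distance = c(0.1, 0.3, 0.5, 0.9))
  z <- zscore_within_subject(tbl)
  expect_equal(z$z_distance[1:2], c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # oracle recomputation per subject
  for (s in c("a", "b")) {
    d <- tbl$distance[tbl$subject_id == s]
    expect_equal(z$z_distance[z$subject_id == s], (d - mean(d)) / sd(d),
                 tolerance = 1e-12)
  }
  # monotone transform: rank order preserved
  set.seed(2)
  tbl2 <- tibble::tibble(subject_id = "a", roi = "HPC",
                         trial_id = paste0("t", 1:20), distance = runif(20))
  z2 <- zscore_within_subject(tbl2)
  expect_equal(order(z2$z_distance), order(tbl2$distance))
  expect_error(zscore_within_subject(
    tibble::tibble(subject_id = "a", roi = "HPC", trial_id = c("1", "2"),
                   distance = c(0.2, 0.2))),
    class = "typicality_degenerate_error")
})

test_that("outlier flagging thresholds the standardized distance", {
  set.seed(4)
  tbl <- tibble::tibble(subject_id = "a", roi = "HPC",
                        trial_id = paste0("t", 1:40),
                        distance = c(rnorm(39, 0.5, 0.02), 0.5))
  tbl$distance[40] <- 0.5 + 10 * sd(tbl$distance[1:39])
  z <- flag_outliers(zscore_within_subject(tbl), 3, quiet = TRUE)
  expect_equal(which(z$outlier_flag), 40L)
  z_inf <- flag_outliers(zscore_within_subject(tbl), Inf, quiet = TRUE)
  expect_false(any(z_inf$outlier_flag))
})

test_that("excluding flagged outliers barely moves the planted condition effect", {
  spec <- tiny_spec(n_subjects = 6, eccentricity_condition_shift = -0.05, seed = 31)
  m <- modeling_table_for(spec)
  typ <- tibble::tibble(subject_id = m$subject_id, roi = "HPC",
                        trial_id = m$trial_id, distance = m$dist_HPC)
  fl <- flag_outliers(zscore_within_subject(typ), 3, quiet = TRUE)
  keep <- !fl$outlier_flag[match(m$trial_id, fl$trial_id)]
  b_all <- tidy(fit_condition_effect(m, "dist_HPC", random_slope = "never"))$estimate[2]
  b_kept <- tidy(fit_condition_effect(m[keep, ], "dist_HPC",
                                      random_slope = "never"))$estimate[2]
  expect_lt(abs(b_all - b_kept) / abs(b_all), 0.10)
})

test_that("greater planted typicality under high curiosity shows up in the distances", {
  wins <- vapply(1:20, function(s) {
    spec <- cohort_spec(n_subjects = 10, n_voxels_by_roi = c(HPC = 40, VTA = 8),
                        seed = 100 + s)
    coh <- simulate_cohort(spec)
    typ <- compute_typicality(coh$patterns, coh$trials, rois = "HPC")
    cond <- coh$trials$condition[match(typ$trial_id, coh$trials$trial_id)]
    mean(typ$distance[cond == "high"]) < mean(typ$distance[cond == "low"])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
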