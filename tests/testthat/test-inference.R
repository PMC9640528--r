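trials_from_rates <- function(rates, n_trials = 10) {
  # rates: tibble(subject_id, condition, rate); builds exact recall sequences
  purrr::pmap(rates, function(subject_id, condition, rate) {
    k <- round(rate * n_trials)
    tibble::tibble(subject_id = subject_id, condition = condition,
                   recalled = c(rep(1L, k), rep(0L, n_trials - k)))
  }) |> dplyr::bind_rows()
}

test_that("identical recall rates across conditions give a null contrast", {
  rates <- tidyr::expand_grid(subject_id = c("a", "b", "c"),
                              condition = c("high", "low")) |>
    dplyr::mutate(rate = c(0.4, 0.4, 0.6, 0.6, 0.2, 0.2))
  rc <- recall_contrast(trials_from_rates(rates))
  expect_equal(rc$statistic, 0)
  expect_equal(rc$cohens_d, 0)
})

test_that("the paired t matches hand arithmetic on two subjects", {
  rates <- tibble::tibble(subject_id = c("a", "a", "b", "b"),
                          condition = c("high", "low", "high", "low"),
                          rate = c(0.6, 0.4, 0.7, 0.4))
  rc <- recall_contrast(trials_from_rates(rates))
  # diffs (0.2, 0.3): mean 0.25, sd 0.0707, t = 0.25 / (0.0707/sqrt(2)) = 5
  expect_equal(rc$estimate, 0.25)
  expect_equal(rc$statistic, 5, tolerance = 1e-10)
  expect_equal(rc$df, 1)
})

test_that("subjects missing a condition are excluded with a warning", {
  rates <- tibble::tibble(subject_id = c("a", "a", "b", "b", "c"),
                          condition = c("high", "low", "high", "low", "high"),
                          rate = c(0.6, 0.4, 0.7, 0.4, 0.9))
  expect_warning(rc <- recall_contrast(trials_from_rates(rates)),
                 regexp = "excluding")
  expect_equal(rc$n_subjects, 2L)
})

test_that("a constant response yields a null condition effect", {
  d <- tidyr::expand_grid(subject_id = c("a", "b", "c"), i = 1:10) |>
    dplyr::mutate(condition = rep(c("high", "low"), 15), y = 1.7)
  fit <- fit_condition_effect(d, "y")
  row <- tidy(fit)[2, ]
  expect_equal(row$estimate, 0)
  expect_equal(row$p_value, 1)
})

test_that("mixed-model condition effects match a two-stage paired estimator", {
  for (s in 1:5) {
    spec <- tiny_spec(n_subjects = 8, seed = 40 + s)
    m <- modeling_table_for(spec)
    fit <- fit_condition_effect(m, "dist_HPC", random_slope = "never")
    b <- tidy(fit)[2, ]
    two_stage <- m |>
      dplyr::group_by(subject_id, condition) |>
      dplyr::summarise(d = mean(dist_HPC), .groups = "drop") |>
      tidyr::pivot_wider(names_from = condition, values_from = d) |>
      dplyr::mutate(diff = high - low)
    expect_lt(abs(b$estimate - mean(two_stage$diff)), b$se)
  }
})

test_that("memory model estimates are on the log-odds scale with joint predictors", {
  spec <- tiny_spec(n_subjects = 8, seed = 50)
  m <- modeling_table_for(spec)
  fit <- fit_memory_model(m, c("dist_HPC", "mean_VTA"), random_slope = "never")
  td <- tidy(fit)
  expect_setequal(td$term, c("(Intercept)", "dist_HPC", "mean_VTA"))
  # against a plain logistic fit: random-intercept estimates should be close
  ref <- coef(glm(recalled ~ dist_HPC + mean_VTA, binomial, data = m))
  expect_equal(td$estimate[td$term == "dist_HPC"], unname(ref["dist_HPC"]),
               tolerance = 0.25)
  expect_error(fit_memory_model(dplyr::mutate(m, recalled = 1L), "dist_HPC"),
               class = "typicality_validation_error")
})

test_that("complete separation is reported with the offending predictor", {
  set.seed(6)
  d <- tibble::tibble(subject_id = rep(c("a", "b", "c", "d"), each = 30),
                      x = rnorm(120))
  d$recalled <- as.integer(d$x > 0)
  expect_error(suppressWarnings(
    fit_memory_model(d, "x", random_slope = "never")),
    class = "typicality_separation_error")
})

test_that("likelihood-ratio comparison follows its definition", {
  spec <- tiny_spec(n_subjects = 6, seed = 60)
  m <- modeling_table_for(spec)
  f0 <- fit_memory_model(m, "mean_VTA", random_slope = "never")
  f1 <- fit_memory_model(m, c("mean_VTA", "dist_HPC"), random_slope = "never")
  cmp <- lrt_select(f0, f1)
  expect_equal(cmp$chi2,
               2 * (as.numeric(logLik(f1$model)) - as.numeric(logLik(f0$model))),
               tolerance = 1e-8)
  expect_equal(cmp$df_diff, 1L)
  # identical models: chi2 0, p 1
  same <- lrt_select(f0, f0)
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)
  # row mismatch is an error
  f0b <- fit_memory_model(m[-(1:5), ], "mean_VTA", random_slope = "never")
  expect_error(lrt_select(f0b, f1), class = "typicality_validation_error")
})

test_that("planted random-slope heterogeneity is detected by the LRT policy", {
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n_subj <- 16; n_per <- 40
    d <- tibble::tibble(
      subject_id = rep(sprintf("s%02d", 1:n_subj), each = n_per),
      x = rnorm(n_subj * n_per),
      b_s = rep(rnorm(n_subj, 1, 0.8), each = n_per))
    d$y <- d$b_s * d$x + rnorm(nrow(d), 0, 1)
    fit <- fit_lmm(d, "y", "x", focal = "x", random_slope = "lrt")
    fit$slope_used
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("mediation is deterministic under a fixed seed", {
  spec <- tiny_spec(seed = 70)
  m <- modeling_table_for(spec)
  m1 <- mediate(m, "mean_VTA", "dist_HPC", n_boot = 1, seed = 5)
  m2 <- mediate(m, "mean_VTA", "dist_HPC", n_boot = 1, seed = 5)
  expect_identical(m1$estimates, m2$estimates)
  expect_identical(m1$boot, m2$boot)
  expect_error(mediate(m, "mean_VTA", "dist_HPC", n_boot = 10),
               regexp = "seed")
})

test_that("a pure-pipeline effect is decomposed as (almost) complete mediation", {
  set.seed(8)
  n_subj <- 20; n_per <- 100
  d <- tibble::tibble(subject_id = rep(sprintf("s%02d", 1:n_subj), each = n_per),
                      t = rnorm(n_subj * n_per))
  d$m <- 0.8 * d$t + rnorm(nrow(d), 0, 0.5)
  d$recalled <- rbinom(nrow(d), 1, plogis(1.0 * d$m))       # no direct path
  md <- mediate(d, "t", "m", n_boot = 400, seed = 3)
  est <- md$estimates
  expect_gt(est$prop_mediated, 0.8)
  expect_lt(est$prop_mediated, 1.2)
  expect_gt(est$ci_indirect_low, 0)
})

test_that("between-subject correlation handles exact and planted couplings", {
  x <- c(1, 3, 2, 5, 4, 7)
  expect_equal(subject_correlation(x, x)$r, 1)
  expect_equal(subject_correlation(x, -x)$r, -1)
  expect_error(subject_correlation(x, rep(1, 6)),
               class = "typicality_degenerate_error")
  # sampling distribution of r at n = 23, true coupling -0.6
  set.seed(9)
  rs <- replicate(100, {
    a <- rnorm(23); b <- -0.6 * a + sqrt(1 - 0.36) * rnorm(23)
    subject_correlation(a, b)$r
  })
  expect_gt(mean(rs), -0.75)
  expect_lt(mean(rs), -0.45)
})
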