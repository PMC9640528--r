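#' Assemble a pipeline configuration
#'
#' A single serializable document controlling the end-to-end workflow:
#' cohort generator settings, GLM options, convergence options, model
#' recipes, permutation-map options and the top-level seed. Every
#' stochastic stage derives its own seed deterministically from the
#' top-level seed via [child_seed()], so adding a stage never perturbs the
#' others. Round-trips through YAML unchanged via [write_config()] /
#' [read_config()].
#'
#' @param cohort A [cohort_spec()].
#' @param mode `"pattern"` (typicality computed on generated patterns) or
#'   `"bold"` (BOLD synthesis + trial GLM first).
#' @param glm List: `question_epoch` (see [events_from_trials()]) and
#'   `value_type` (`"beta"` or `"z"`; trial estimates fed to convergence).
#' @param convergence List: `method`, `target_roi` (the ROI whose
#'   typicality enters the linking models), `outlier_threshold_sd`,
#'   `exclude_outliers`.
#' @param models List: `mediation_n_boot` (bootstrap replicates),
#'   `random_slope` policy.
#' @param permmap List: `enabled`, `n_perm`, `alpha_percentile`, `fwe`.
#' @param seed Top-level integer seed (overrides `cohort$seed`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            mode = c("pattern", "bold"),
                            glm = list(),
                            convergence = list(),
                            models = list(),
                            permmap = list(),
                            seed = 1L) {
  mode <- match.arg(mode)
  defaults <- function(user, def) utils::modifyList(def, user)
  cfg <- list(
    cohort = cohort,
    mode = mode,
    glm = defaults(glm, list(question_epoch = "anticipation", value_type = "beta")),
    convergence = defaults(convergence, list(
      method = "kmeans_mean", target_roi = "HPC",
      outlier_threshold_sd = 3, exclude_outliers = FALSE)),
    models = defaults(models, list(mediation_n_boot = 1000,
                                   random_slope = "lrt")),
    permmap = defaults(permmap, list(enabled = FALSE, n_perm = 500,
                                     alpha_percentile = 0.95,
                                     fwe = "bonferroni")),
    seed = check_count(seed, "seed", min = 0L)
  )
  cfg$cohort$seed <- cfg$seed
  cfg$cohort <- validate_cohort_spec(cfg$cohort)
  validate_pipeline_config(structure(cfg, class = "pipeline_config"))
}

validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!inherits(config$cohort, "cohort_spec")) {
    stopf("config$cohort must be a cohort_spec", class = "typicality_config_error")
  }
  rois <- names(config$cohort$n_voxels_by_roi)
  if (!config$convergence$target_roi %in% setdiff(rois, config$cohort$modulator_roi)) {
    stopf("target_roi `%s` is not a pattern ROI of the cohort (%s)",
          config$convergence$target_roi,
          paste(setdiff(rois, config$cohort$modulator_roi), collapse = ", "),
          class = "typicality_config_error")
  }
  if (!config$glm$value_type %in% c("beta", "z")) {
    stopf("glm$value_type must be 'beta' or 'z'", class = "typicality_config_error")
  }
  config
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` the
#'   reconstructed `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- unclass(config)
  plain$cohort <- lapply(unclass(plain$cohort), function(x) {
    if (!is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  coh <- raw$cohort
  for (f in c("n_voxels_by_roi", "memory_intercept_by_condition")) {
    coh[[f]] <- unlist(coh[[f]])
  }
  for (f in c("conditions", "anticipation_delays_s", "iti_range_s")) {
    coh[[f]] <- unlist(coh[[f]])
  }
  cohort <- do.call(cohort_spec, coh)
  pipeline_config(cohort = cohort, mode = raw$mode, glm = raw$glm,
                  convergence = raw$convergence, models = raw$models,
                  permmap = raw$permmap, seed = raw$seed)
}

term_row <- function(fit, pattern) {
  row <- fit$terms[grepl(pattern, fit$terms$term), , drop = FALSE]
  if (nrow(row) == 0) return(NULL)
  as.list(row[1, ])
}

#' Run the full convergence-state workflow
#'
#' Executes the stages in dependency order — simulate, (BOLD + trial GLM),
#' convergence scoring, univariate summaries, linking models, optional
#' permutation map — and writes every table, a `results.json` with all
#' fitted quantities, the effective configuration, and a `manifest.json`
#' recording parameters, seeds, package version and an MD5 checksum per
#' output file. Reruns with an identical configuration are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if absent).
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  config <- validate_pipeline_config(config)
  if (missing(outdir) || !nzchar(outdir)) {
    stopf("`outdir` is required", class = "typicality_config_error")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  spec <- config$cohort
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage `%s` failed: %s", name, conditionMessage(e),
            class = "typicality_stage_error")
    })
  }

  # -- simulate ------------------------------------------------------------
  say("stage simulate: %d subjects, %d runs, mode=%s", spec$n_subjects,
      spec$n_runs, config$mode)
  sim <- stage("simulate", {
    trials <- generate_memory_outcomes(generate_trial_table(spec), spec)
    patterns <- generate_patterns(trials, spec)
    list(trials = trials, patterns = patterns)
  })
  trials <- sim$trials
  write_trial_table(trials, file.path(outdir, "trial_table.csv"))
  events <- events_from_trials(trials, spec, config$glm$question_epoch)
  write_events_tsv(events, file.path(outdir, "events.tsv"))

  # -- glm (bold mode) -----------------------------------------------------
  pattern_set <- sim$patterns
  if (config$mode == "bold") {
    say("stage glm: synthesizing BOLD and fitting the trial LSA model")
    pattern_set <- stage("glm", {
      bold <- generate_bold(trials, sim$patterns, spec, config$glm$question_epoch)
      fit_trial_glm(bold, interval = "question", value = config$glm$value_type)
    })
  }

  # -- converge ------------------------------------------------------------
  say("stage converge: leave-one-run-out typicality (%s centroid)",
      config$convergence$method)
  pattern_rois <- setdiff(names(spec$n_voxels_by_roi), spec$modulator_roi)
  typ_raw <- stage("converge", {
    compute_typicality(pattern_set, trials, rois = pattern_rois,
                       method = config$convergence$method)
  })
  typ <- typ_raw |>
    zscore_within_subject() |>
    flag_outliers(config$convergence$outlier_threshold_sd, quiet = quiet)
  readr::write_csv(typ, file.path(outdir, "typicality.csv"), progress = FALSE)
  cents <- attr(typ_raw, "centroids")
  cent_long <- cents |>
    dplyr::mutate(centroid = purrr::map(.data$centroid, function(v) {
      new_tbl(voxel = seq_along(v), value = v)
    })) |>
    tidyr::unnest("centroid")
  readr::write_csv(cent_long, file.path(outdir, "centroids.csv"),
                   progress = FALSE)

  # -- univariate + join ---------------------------------------------------
  say("stage univariate: ROI means and modeling table")
  modeling <- stage("univariate", {
    uni <- compute_roi_means(pattern_set, trials)
    join_features(uni, typ, trials)
  })
  readr::write_csv(modeling, file.path(outdir, "modeling_table.csv"),
                   progress = FALSE)

  # -- models --------------------------------------------------------------
  say("stage model: behavioural contrast and linking models")
  troi <- config$convergence$target_roi
  dist_col <- paste0("dist_", troi)
  mod_col <- paste0("mean_", spec$modulator_roi)
  rs <- config$models$random_slope
  if (isTRUE(config$convergence$exclude_outliers)) {
    model_data <- modeling[!modeling[[paste0("outlier_", troi)]], ]
  } else {
    model_data <- modeling
  }
  results <- stage("model", {
    behav <- recall_contrast(trials, conditions = spec$conditions[1:2])
    cond_fit <- fit_condition_effect(model_data, dist_col, random_slope = rs)
    modu_fit <- fit_lmm(model_data, dist_col, mod_col, focal = mod_col,
                        random_slope = rs)
    mem_fit <- fit_memory_model(model_data,
                                predictors = c(dist_col, mod_col),
                                random_slope = rs)
    m_treat <- fit_memory_model(model_data, predictors = mod_col,
                                random_slope = "never")
    m_med <- fit_memory_model(model_data, predictors = dist_col,
                              random_slope = "never")
    med <- mediate(model_data, treatment = mod_col, mediator = dist_col,
                   n_boot = config$models$mediation_n_boot,
                   seed = child_seed(config$seed, "mediation"))
    subj <- model_data |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(m = mean(.data[[mod_col]]), d = mean(.data[[dist_col]]),
                       .groups = "drop")
    list(
      recall = as.list(behav),
      condition_typicality = term_row(cond_fit, "^condition"),
      modulator_typicality = term_row(modu_fit, mod_col),
      memory_typicality = term_row(mem_fit, dist_col),
      memory_modulator = term_row(mem_fit, mod_col),
      lrt_add_typicality = as.list(lrt_select(m_treat, mem_fit)),
      lrt_add_modulator = as.list(lrt_select(m_med, mem_fit)),
      mediation = as.list(med$estimates),
      subject_correlation = as.list(subject_correlation(subj$m, subj$d)),
      random_slope_used = list(condition = cond_fit$slope_used,
                               modulator = modu_fit$slope_used,
                               memory = mem_fit$slope_used)
    )
  })

  # -- permmap (optional) --------------------------------------------------
  if (isTRUE(config$permmap$enabled)) {
    say("stage permmap: permutation-null voxelwise map on the %s grid", troi)
    pm <- stage("permmap", {
      cells <- pattern_set[pattern_set$roi == troi, ]
      typ_s <- split(model_data[[dist_col]], model_data$subject_id)
      cov_s <- split(model_data[[mod_col]], model_data$subject_id)
      vox_s <- setNames(cells$patterns, cells$subject_id)
      ord <- split(model_data$trial_id, model_data$subject_id)
      vox_s <- purrr::imap(vox_s, function(m, s) m[match(ord[[s]], rownames(m)), ])
      convergence_map(typ_s, vox_s, cov_s, n_perm = config$permmap$n_perm,
                      alpha_percentile = config$permmap$alpha_percentile,
                      seed = child_seed(config$seed, "permmap"),
                      fwe = config$permmap$fwe)
    })
    readr::write_csv(pm$map, file.path(outdir, "permmap.csv"), progress = FALSE)
    results$permmap <- list(
      n_significant = sum(pm$map$significant, na.rm = TRUE),
      frac_adjusted_positive = mean(pm$adjusted > 0),
      n_perm = pm$n_perm
    )
  }

  jsonlite::write_json(results, file.path(outdir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_config(config, file.path(outdir, "config.yaml"))

  # -- manifest ------------------------------------------------------------
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package = "typicality",
    version = as.character(utils::packageVersion("typicality")),
    seed = config$seed,
    mode = config$mode,
    stage_seeds = list(
      trial_table = child_seed(config$seed, "trial_table"),
      memory = child_seed(config$seed, "memory"),
      patterns = child_seed(config$seed, "patterns"),
      bold = child_seed(config$seed, "bold"),
      mediation = child_seed(config$seed, "mediation"),
      permmap = child_seed(config$seed, "permmap")
    ),
    checksums = as.list(setNames(
      unname(tools::md5sum(file.path(outdir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(trials = trials, patterns = pattern_set, typicality = typ,
                 modeling = modeling, results = results,
                 manifest = manifest))
}
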