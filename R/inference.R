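#' Paired behavioural recall contrast
#'
#' Computes per-subject recall rates per condition and compares conditions
#' with a two-tailed paired t-test, with Cohen's d (mean difference over the
#' SD of the paired differences) and a 95% CI. Subjects missing either
#' condition are excluded with a warning.
#'
#' @param trials Trial table with `subject_id`, `condition`, `recalled`.
#' @param conditions Length-2 character: the contrast is
#'   `conditions[1] - conditions[2]` (default high minus low).
#' @return Object of class `recall_contrast` (a one-row tibble): per-
#'   condition mean rates, `estimate` (mean difference), `statistic` (t),
#'   `df`, `p_value`, `cohens_d`, `conf_low`, `conf_high`, `n_subjects`.
#' @export
recall_contrast <- function(trials, conditions = c("high", "low")) {
  rates <- trials |>
    dplyr::filter(.data$condition %in% conditions) |>
    dplyr::group_by(.data$subject_id, .data$condition) |>
    dplyr::summarise(rate = mean(.data$recalled), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "rate")
  complete <- complete.cases(rates[, conditions])
  if (any(!complete)) {
    warn(sprintf("excluding %d subject(s) missing a condition", sum(!complete)))
    rates <- rates[complete, ]
  }
  if (nrow(rates) < 2) {
    stopf("need >= 2 subjects with both conditions",
          class = "typicality_validation_error")
  }
  diffs <- rates[[conditions[1]]] - rates[[conditions[2]]]
  if (sd(diffs) == 0) {
    ht <- list(statistic = c(t = 0), parameter = c(df = length(diffs) - 1),
               p.value = 1, conf.int = c(mean(diffs), mean(diffs)))
  } else {
    ht <- t.test(diffs)
  }
  out <- new_tbl(
    mean_rate_1 = mean(rates[[conditions[1]]]),
    mean_rate_2 = mean(rates[[conditions[2]]]),
    estimate = mean(diffs),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    cohens_d = if (sd(diffs) == 0) 0 else mean(diffs) / sd(diffs),
    conf_low = ht$conf.int[1], conf_high = ht$conf.int[2],
    n_subjects = nrow(rates)
  )
  names(out)[1:2] <- paste0("rate_", conditions)
  structure(out, class = c("recall_contrast", class(out)))
}

# ---------------------------------------------------------------------------
# linear mixed models on trial-level responses

relevel_condition <- function(x, reference = "low") {
  lv <- unique(as.character(x))
  if (reference %in% lv) {
    factor(x, levels = c(reference, setdiff(sort(lv), reference)))
  } else {
    factor(x)
  }
}

fit_with_slope_policy <- function(data, fixed_rhs, response, focal, subject,
                                  random_slope, fitter, ...) {
  f0 <- as.formula(sprintf("%s ~ %s + (1 | %s)", response, fixed_rhs, subject))
  fit0 <- fitter(f0, data, ...)
  slope_used <- FALSE
  comparison <- NULL
  if (!is.null(focal) && random_slope != "never") {
    f1 <- as.formula(sprintf("%s ~ %s + (1 + %s | %s)", response, fixed_rhs,
                             focal, subject))
    fit1 <- tryCatch(fitter(f1, data, ...), error = function(e) NULL)
    if (is.null(fit1)) {
      if (random_slope == "always") {
        stopf("random-slope model failed to fit", class = "typicality_fit_error")
      }
    } else if (random_slope == "always") {
      fit0 <- fit1; slope_used <- TRUE
    } else {
      comparison <- lrt_select(fit0, fit1)
      if (comparison$preferred == "with") {
        fit0 <- fit1; slope_used <- TRUE
      }
    }
  }
  list(model = fit0, slope_used = slope_used, comparison = comparison)
}

lmm_terms <- function(model) {
  sm <- coef(summary(model))
  has_df <- "df" %in% colnames(sm)
  df <- if (has_df) sm[, "df"] else rep(Inf, nrow(sm))
  est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  stat <- est / se
  p <- if (has_df) sm[, ncol(sm)] else 2 * pnorm(-abs(stat))
  q <- qt(0.975, pmax(df, 1))
  new_tbl(term = rownames(sm), estimate = unname(est), se = unname(se),
          df = unname(df), statistic = unname(stat), p_value = unname(p),
          conf_low = unname(est - q * se), conf_high = unname(est + q * se))
}

new_typicality_fit <- function(model, terms, slope_used, comparison, formula_chr) {
  structure(list(model = model, terms = terms, slope_used = slope_used,
                 comparison = comparison, formula = formula_chr),
            class = "typicality_fit")
}

#' Fit a linear mixed model for a trial-level response
#'
#' Subject-random-intercept linear mixed model (REML, Satterthwaite degrees
#' of freedom) for any trial-level response against an arbitrary fixed-
#' effect recipe — the workhorse behind the condition-effect, modulator and
#' time-on-task analyses. A random slope for the focal predictor is
#' attempted and retained when a likelihood-ratio test favours it
#' (`random_slope = "lrt"`, the default policy).
#'
#' @param data Modeling table (one row per trial).
#' @param response Response column name.
#' @param fixed_rhs Right-hand-side recipe, e.g. `"condition"` or
#'   `"mean_VTA"` or `"run * trial_in_run"`.
#' @param focal Column the random slope applies to (default: first term of
#'   `fixed_rhs` if it names a column).
#' @param subject Grouping column (default `"subject_id"`).
#' @param random_slope `"lrt"`, `"never"` or `"always"`.
#' @return Object of class `typicality_fit`: the fitted model, a `terms`
#'   tibble (estimate, SE, Satterthwaite df, p, 95% CI), the slope policy
#'   outcome and any model comparison.
#' @export
fit_lmm <- function(data, response, fixed_rhs, focal = NULL,
                    subject = "subject_id",
                    random_slope = c("lrt", "never", "always")) {
  random_slope <- match.arg(random_slope)
  if (sd(data[[response]]) == 0) {
    # degenerate response: no information about any predictor
    mm <- stats::model.matrix(as.formula(paste("~", fixed_rhs)), data)
    terms <- new_tbl(term = colnames(mm),
                     estimate = c(data[[response]][1], rep(0, ncol(mm) - 1L)),
                     se = NA_real_, df = NA_real_, statistic = NA_real_,
                     p_value = c(NA_real_, rep(1, ncol(mm) - 1L)),
                     conf_low = NA_real_, conf_high = NA_real_)
    return(new_typicality_fit(NULL, terms, FALSE, NULL,
                              sprintf("%s ~ %s [constant response]",
                                      response, fixed_rhs)))
  }
  if (is.null(focal)) {
    first <- all.vars(as.formula(paste("~", fixed_rhs)))[1]
    if (!is.na(first) && first %in% names(data)) focal <- first
  }
  fitter <- function(f, d) {
    suppressMessages(lmerTest::lmer(f, data = d, REML = TRUE))
  }
  res <- fit_with_slope_policy(data, fixed_rhs, response, focal, subject,
                               random_slope, fitter)
  new_typicality_fit(res$model, lmm_terms(res$model), res$slope_used,
                     res$comparison,
                     paste(deparse(stats::formula(res$model)), collapse = ""))
}

#' Condition effect on a trial-level response
#'
#' The curiosity-state analysis: a linear mixed model of the response
#' (e.g. pattern typicality, or a univariate ROI mean) on condition with
#' subjects as random intercepts (random slope by the LRT policy). The
#' condition factor is coded with `"low"` as reference, so the reported
#' coefficient is the high-minus-low shift; a negative estimate on distance
#' means greater typicality under high curiosity.
#'
#' @inheritParams fit_lmm
#' @param condition Condition column name.
#' @param reference Reference level (default `"low"`).
#' @return A `typicality_fit`; the condition row of `$terms` carries the
#'   effect of interest.
#' @export
fit_condition_effect <- function(data, response, condition = "condition",
                                 subject = "subject_id", reference = "low",
                                 random_slope = c("lrt", "never", "always")) {
  random_slope <- match.arg(random_slope)
  data[[condition]] <- relevel_condition(data[[condition]], reference)
  fit <- fit_lmm(data, response, condition, focal = condition,
                 subject = subject, random_slope = random_slope)
  fit$condition_term <- grep(paste0("^", condition), fit$terms$term, value = TRUE)[1]
  fit
}

#' Mixed-effects logistic subsequent-memory model
#'
#' Predicts the binary recall outcome from trial-level brain measures, all
#' predictors entered jointly so each coefficient reflects uniquely
#' accounted variance, with subjects as random intercepts. Coefficients are
#' on the log-odds scale with Wald tests. An optional interaction of every
#' predictor with a condition column reproduces the moderation analysis; a
#' random slope for `focal` follows the LRT policy.
#'
#' @param data Modeling table.
#' @param predictors Character vector of predictor columns (entered jointly).
#' @param outcome Binary outcome column (default `"recalled"`).
#' @param subject Grouping column.
#' @param focal Predictor eligible for a random slope (default: first).
#' @param interaction_with Optional column name: adds `predictor * column`
#'   interactions for every predictor.
#' @param random_slope `"lrt"`, `"never"` or `"always"`.
#' @param exclude Optional logical vector/column name of trials to drop
#'   (e.g. an outlier flag).
#' @return A `typicality_fit`; `$terms` holds one row per fixed effect.
#' @export
fit_memory_model <- function(data, predictors, outcome = "recalled",
                             subject = "subject_id", focal = predictors[1],
                             interaction_with = NULL,
                             random_slope = c("lrt", "never", "always"),
                             exclude = NULL) {
  random_slope <- match.arg(random_slope)
  if (!is.null(exclude)) {
    keep <- if (is.character(exclude)) !isTRUE_vec(data[[exclude]]) else !isTRUE_vec(exclude)
    data <- data[keep, , drop = FALSE]
  }
  y <- data[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2) {
    stopf("outcome `%s` is degenerate (single class)", outcome,
          class = "typicality_validation_error")
  }
  for (p in predictors) {
    x <- data[[p]]
    if (!is.numeric(x)) next
    if (max(x[y == 0]) < min(x[y == 1]) || max(x[y == 1]) < min(x[y == 0])) {
      stopf("complete separation of `%s` by predictor `%s`", outcome, p,
            class = "typicality_separation_error")
    }
  }
  rhs <- if (is.null(interaction_with)) {
    paste(predictors, collapse = " + ")
  } else {
    paste(sprintf("%s * %s", predictors, interaction_with), collapse = " + ")
  }
  fitter <- function(f, d) {
    suppressMessages(lme4::glmer(f, data = d, family = stats::binomial,
                                 control = lme4::glmerControl(calc.derivs = FALSE)))
  }
  res <- fit_with_slope_policy(data, rhs, outcome, focal, subject,
                               random_slope, fitter)
  terms <- lmm_terms(res$model)
  sep <- terms$term[terms$se > 50 | abs(terms$estimate) > 20]
  sep <- setdiff(sep, "(Intercept)")
  if (length(sep)) {
    stopf("apparent complete separation for predictor(s): %s",
          paste(sep, collapse = ", "), class = "typicality_separation_error")
  }
  new_typicality_fit(res$model, terms, res$slope_used, res$comparison,
                     paste(deparse(stats::formula(res$model)), collapse = ""))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Likelihood-ratio comparison of nested mixed models
#'
#' `chi^2 = 2 * (logLik(with) - logLik(without))` with the parameter-count
#' difference as degrees of freedom; linear mixed models are refit by
#' maximum likelihood first. `preferred` is `"with"` when p < 0.05.
#'
#' @param model_without,model_with Nested `merMod` fits (or
#'   `typicality_fit` objects) on the same rows.
#' @return Object of class `model_comparison` (one-row tibble): `chi2`,
#'   `df_diff`, `p_value`, `preferred`.
#' @export
lrt_select <- function(model_without, model_with) {
  m0 <- if (inherits(model_without, "typicality_fit")) model_without$model else model_without
  m1 <- if (inherits(model_with, "typicality_fit")) model_with$model else model_with
  if (stats::nobs(m0) != stats::nobs(m1)) {
    stopf("models fit to different numbers of rows (%d vs %d)",
          stats::nobs(m0), stats::nobs(m1), class = "typicality_validation_error")
  }
  to_ml <- function(m) {
    if (inherits(m, "lmerMod") && lme4::isREML(m)) {
      suppressMessages(lme4::refitML(m))
    } else m
  }
  m0 <- to_ml(m0); m1 <- to_ml(m1)
  df0 <- attr(logLik(m0), "df"); df1 <- attr(logLik(m1), "df")
  if (df1 < df0) {
    stopf("`model_with` has fewer parameters than `model_without`; not nested as given",
          class = "typicality_validation_error")
  }
  chi2 <- max(0, 2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0))))
  df_diff <- df1 - df0
  p <- if (df_diff == 0) 1 else stats::pchisq(chi2, df_diff, lower.tail = FALSE)
  structure(new_tbl(chi2 = chi2, df_diff = df_diff, p_value = p,
                    preferred = if (p < 0.05) "with" else "without"),
            class = c("model_comparison", class(new_tbl())))
}

# ---------------------------------------------------------------------------
# mediation

mediation_paths <- function(treat, med, out) {
  Xa <- cbind(1, treat)
  a <- .lm.fit(Xa, med)$coefficients[2]
  Xb <- cbind(1, treat, med)
  fit <- suppressWarnings(
    stats::glm.fit(Xb, out, family = stats::binomial())
  )
  cf <- fit$coefficients
  c(a = unname(a), b = unname(cf[3]), direct = unname(cf[2]))
}

#' Subject-level bootstrap mediation
#'
#' Decomposes the effect of a trial-level treatment (e.g. VTA activation)
#' on a binary outcome (recall) into a direct path and an indirect path
#' through a mediator (e.g. hippocampal typicality). Paths are the product-
#' of-coefficients on the linear-predictor scale: `a` from a linear model
#' `mediator ~ treatment`, `b` and the direct effect from a logistic model
#' `outcome ~ treatment + mediator`; `indirect = a * b`,
#' `total = direct + indirect` (an approximation on the log-odds scale),
#' `prop_mediated = indirect / total`. Uncertainty comes from a
#' nonparametric bootstrap resampling whole subjects with replacement —
#' the resampling unit carries the within-subject dependence — with
#' percentile intervals; fully reproducible given `seed`.
#'
#' @param data Modeling table.
#' @param treatment,mediator Numeric trial-level columns.
#' @param outcome Binary outcome column (default `"recalled"`).
#' @param subject Grouping column.
#' @param n_boot Bootstrap replicates (>= 1000 recommended; default 5000).
#' @param seed Integer seed (required).
#' @return Object of class `mediation_boot`: list with `estimates` (one-row
#'   tibble: `indirect`, `direct`, `total`, `prop_mediated`, percentile CIs,
#'   `p_indirect`), `boot` (replicate draws), `n_boot`, `seed`.
#' @export
mediate <- function(data, treatment, mediator, outcome = "recalled",
                    subject = "subject_id", n_boot = 5000, seed) {
  if (missing(seed)) stopf("`seed` is required for reproducible mediation")
  n_boot <- check_count(n_boot, "n_boot")
  treat <- data[[treatment]]; med <- data[[mediator]]; out <- data[[outcome]]
  point <- mediation_paths(treat, med, out)
  rows_by_subj <- split(seq_len(nrow(data)), data[[subject]])
  n_subj <- length(rows_by_subj)
  set.seed(child_seed(seed, "mediate"))
  boot <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, c("a", "b", "direct")))
  for (i in seq_len(n_boot)) {
    idx <- unlist(rows_by_subj[sample.int(n_subj, n_subj, replace = TRUE)],
                  use.names = FALSE)
    boot[i, ] <- mediation_paths(treat[idx], med[idx], out[idx])
  }
  b_ind <- boot[, "a"] * boot[, "b"]
  b_tot <- b_ind + boot[, "direct"]
  b_prop <- b_ind / b_tot
  ind <- point[["a"]] * point[["b"]]
  tot <- ind + point[["direct"]]
  ci <- function(x) unname(quantile(x, c(0.025, 0.975), na.rm = TRUE))
  ci_ind <- ci(b_ind); ci_prop <- ci(b_prop); ci_tot <- ci(b_tot)
  if (ci_tot[1] <= 0 && ci_tot[2] >= 0) {
    warn("total effect CI covers 0; prop_mediated is unstable")
  }
  p_ind <- min(1, 2 * min(mean(b_ind <= 0), mean(b_ind >= 0)))
  p_ind <- max(p_ind, 1 / (n_boot + 1))
  est <- new_tbl(indirect = ind, direct = point[["direct"]], total = tot,
                 prop_mediated = ind / tot,
                 ci_indirect_low = ci_ind[1], ci_indirect_high = ci_ind[2],
                 ci_prop_low = ci_prop[1], ci_prop_high = ci_prop[2],
                 p_indirect = p_ind)
  structure(list(estimates = est, boot = boot, n_boot = n_boot, seed = seed),
            class = "mediation_boot")
}

#' Between-subject Pearson correlation
#'
#' Individual-differences analysis: Pearson correlation of two per-subject
#' summaries with a Fisher-z 95% CI and two-sided p.
#'
#' @param x,y Per-subject numeric vectors (n >= 3, non-constant).
#' @return Object of class `subject_correlation` (one-row tibble): `r`,
#'   `conf_low`, `conf_high`, `p_value`, `n`.
#' @export
subject_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stopf("need paired vectors of length >= 3", class = "typicality_validation_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stopf("zero variance input", class = "typicality_degenerate_error")
  }
  ht <- cor.test(x, y, method = "pearson")
  r <- unname(ht$estimate)
  ci <- if (abs(r) == 1 || length(x) < 4) c(r, r) else as.numeric(ht$conf.int)
  structure(new_tbl(r = r, conf_low = ci[1], conf_high = ci[2],
                    p_value = ht$p.value, n = length(x)),
            class = c("subject_correlation", class(new_tbl())))
}
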