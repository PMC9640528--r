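#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy fixed effects of a mixed-model fit
#'
#' @param x A `typicality_fit` from [fit_lmm()], [fit_condition_effect()]
#'   or [fit_memory_model()].
#' @param ... Unused.
#' @return Tibble of fixed-effect terms (estimate, se, df, statistic,
#'   p_value, 95% CI).
#' @export
tidy.typicality_fit <- function(x, ...) x$terms

#' @rdname tidy.typicality_fit
#' @export
glance.typicality_fit <- function(x, ...) {
  new_tbl(nobs = stats::nobs(x$model),
          logLik = as.numeric(logLik(x$model)),
          AIC = stats::AIC(x$model),
          random_slope = x$slope_used,
          formula = x$formula)
}

#' @export
print.typicality_fit <- function(x, ...) {
  cat("<typicality_fit> ", x$formula, "\n", sep = "")
  if (x$slope_used) cat("  (random slope retained by LRT)\n")
  print(x$terms)
  invisible(x)
}

#' Tidy a bootstrap mediation result
#'
#' @param x A `mediation_boot` from [mediate()].
#' @param ... Unused.
#' @return One row per effect (`indirect`, `direct`, `total`,
#'   `prop_mediated`) with bootstrap percentile CIs where defined.
#' @export
tidy.mediation_boot <- function(x, ...) {
  e <- x$estimates
  new_tbl(
    effect = c("indirect", "direct", "total", "prop_mediated"),
    estimate = c(e$indirect, e$direct, e$total, e$prop_mediated),
    conf_low = c(e$ci_indirect_low, NA, NA, e$ci_prop_low),
    conf_high = c(e$ci_indirect_high, NA, NA, e$ci_prop_high),
    p_value = c(e$p_indirect, NA, NA, NA)
  )
}

#' @rdname tidy.mediation_boot
#' @export
glance.mediation_boot <- function(x, ...) {
  new_tbl(n_boot = x$n_boot, seed = x$seed)
}

#' @export
print.mediation_boot <- function(x, ...) {
  cat(sprintf("<mediation_boot> %d subject-bootstrap replicates (seed %d)\n",
              x$n_boot, x$seed))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.recall_contrast <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.recall_contrast <- function(x, ...) {
  new_tbl(n_subjects = x$n_subjects, df = x$df)
}

#' @export
tidy.model_comparison <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
tidy.subject_correlation <- function(x, ...) tibble::as_tibble(unclass(x))
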