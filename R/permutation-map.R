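#' Residualize a trial series against a covariate
#'
#' Least-squares residuals of `y` on `covariate` plus an intercept: mean
#' zero and orthogonal to the covariate. With `covariate = NULL` the series
#' is simply centered.
#'
#' @param y Per-trial numeric vector.
#' @param covariate Per-trial numeric vector (non-constant), or `NULL`.
#' @return Residual vector, same length as `y`.
#' @export
residualize <- function(y, covariate = NULL) {
  if (is.null(covariate)) return(y - mean(y))
  if (sd(covariate) == 0) {
    stopf("constant covariate", class = "typicality_degenerate_error")
  }
  unname(resid(lm(y ~ covariate)))
}

# residualize every column of a matrix against (1, covariate) via projection
residualize_cols <- function(M, covariate = NULL) {
  X <- if (is.null(covariate)) matrix(1, nrow(M), 1) else cbind(1, covariate)
  M - X %*% qr.coef(qr(X), M)
}

#' Voxelwise correlation with a trial series
#'
#' Pearson correlation between a per-trial series (typically hippocampal
#' pattern typicality) and each voxel's univariate activation, after
#' residualizing both against a covariate (typically VTA activation) — a
#' vectorized partial correlation per voxel.
#'
#' @param typicality Per-trial numeric vector (>= 4 trials).
#' @param voxels Trials-by-voxels numeric matrix.
#' @param covariate Optional per-trial covariate to control for.
#' @return Per-voxel correlation vector; zero-variance voxels are `NA` (a
#'   message reports how many).
#' @export
voxelwise_r <- function(typicality, voxels, covariate = NULL) {
  voxels <- as.matrix(voxels)
  n <- length(typicality)
  if (n < 4) stopf("need >= 4 trials", class = "typicality_validation_error")
  if (nrow(voxels) != n) {
    stopf("voxels has %d rows; expected %d", nrow(voxels), n,
          class = "typicality_validation_error")
  }
  ty <- residualize(typicality, covariate)
  vx <- residualize_cols(voxels, covariate)
  ss <- sqrt(colSums(vx^2))
  bad <- ss == 0
  if (any(bad)) {
    inform(sprintf("%d zero-variance voxel(s); r recorded as NA", sum(bad)))
    ss[bad] <- NA_real_
  }
  unname(as.numeric(crossprod(vx, ty)) / (ss * sqrt(sum(ty^2))))
}

#' Permutation-null adjustment of a voxelwise correlation map
#'
#' For each voxel, a null distribution of the correlation is built from
#' `n_perm` permutations of the typicality series' trial order (the same
#' permutations shared across voxels), with the covariate residualization
#' re-applied inside every permutation so the null matches the observed
#' statistic. The null quantile at `alpha_percentile` (default the 95th
#' percentile) is subtracted from the observed r, so only correlations
#' exceeding that percentile of their own null remain positive.
#'
#' @inheritParams voxelwise_r
#' @param n_perm Number of permutations (>= 100; must resolve the requested
#'   percentile, i.e. `n_perm * (1 - alpha_percentile) >= 1`).
#' @param alpha_percentile Null quantile to subtract (default 0.95).
#' @param seed Integer seed for the permutation draws.
#' @return A tibble with per-voxel `r_obs`, `null_q` and
#'   `adjusted_r = r_obs - null_q`.
#' @export
null_adjust <- function(typicality, voxels, covariate = NULL, n_perm = 500,
                        alpha_percentile = 0.95, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", min = 100L)
  check_number(alpha_percentile, "alpha_percentile", min = 0.5, max = 1)
  if (n_perm * (1 - alpha_percentile) < 1) {
    stopf("n_perm = %d cannot resolve the %.3f percentile", n_perm,
          alpha_percentile, class = "typicality_config_error")
  }
  voxels <- as.matrix(voxels)
  r_obs <- voxelwise_r(typicality, voxels, covariate)
  n <- length(typicality)
  set.seed(child_seed(seed, "null_adjust"))
  P <- vapply(seq_len(n_perm), function(i) typicality[sample.int(n)],
              numeric(n))
  Pr <- residualize_cols(P, covariate)
  Pr <- sweep(Pr, 2, sqrt(colSums(Pr^2)), "/")
  vx <- residualize_cols(voxels, covariate)
  ss <- sqrt(colSums(vx^2))
  ss[ss == 0] <- NA_real_
  vx <- sweep(vx, 2, ss, "/")
  null_r <- crossprod(Pr, vx)                 # n_perm x voxels
  null_q <- apply(null_r, 2, quantile, probs = alpha_percentile, names = FALSE)
  new_tbl(voxel = seq_along(r_obs), r_obs = r_obs, null_q = null_q,
          adjusted_r = r_obs - null_q)
}

#' Group-level test of null-adjusted correlation maps
#'
#' One-sample t-test per voxel of the subjects' adjusted correlations
#' against zero. The test is right-tailed: after the null-percentile
#' subtraction the adjusted correlation is negative in expectation under
#' the null, and only voxels whose observed correlation beats their own
#' null carry evidence. Family-wise error is controlled over the tested
#' voxel set:
#' Bonferroni by default, or a max-statistic sign-flip permutation test.
#' Voxels with zero between-subject variance (t undefined) are excluded
#' with a message.
#'
#' @param adjusted Subjects-by-voxels matrix of adjusted correlations.
#' @param alpha Family-wise error level (default 0.05).
#' @param fwe `"bonferroni"` or `"maxT"` (sign-flip max-statistic).
#' @param n_flip Sign-flip draws for `fwe = "maxT"`.
#' @param seed Seed for the sign flips.
#' @return Object of class `brain_map`: tibble with per-voxel
#'   `mean_adjusted_r`, `t`, `p`, `p_fwe`, `significant`; attributes record
#'   the FWE method, alpha and excluded voxels.
#' @export
group_test <- function(adjusted, alpha = 0.05, fwe = c("bonferroni", "maxT"),
                       n_flip = 1000, seed = 1L) {
  fwe <- match.arg(fwe)
  adjusted <- as.matrix(adjusted)
  n_subj <- nrow(adjusted)
  if (n_subj < 3) {
    stopf("need >= 3 subjects", class = "typicality_validation_error")
  }
  mu <- colMeans(adjusted)
  s <- apply(adjusted, 2, sd)
  degenerate <- which(s == 0)
  if (length(degenerate)) {
    inform(sprintf("excluding %d voxel(s) with zero between-subject variance",
                   length(degenerate)))
    s[degenerate] <- NA_real_
  }
  tval <- mu / (s / sqrt(n_subj))
  # right-tailed: the null-adjusted correlation is negative in expectation
  # (the 95th-percentile subtraction), so only positive exceedance is evidence
  p <- pt(tval, n_subj - 1, lower.tail = FALSE)
  n_tested <- sum(!is.na(tval))
  p_fwe <- switch(fwe,
    bonferroni = pmin(1, p * n_tested),
    maxT = {
      set.seed(child_seed(seed, "group_maxT"))
      maxs <- replicate(n_flip, {
        flips <- sample(c(-1, 1), n_subj, replace = TRUE)
        f <- flips * adjusted
        tf <- colMeans(f) / (apply(f, 2, sd) / sqrt(n_subj))
        max(tf, na.rm = TRUE)
      })
      vapply(tval, function(t0) {
        if (is.na(t0)) NA_real_ else (1 + sum(maxs >= t0)) / (n_flip + 1)
      }, numeric(1))
    })
  out <- new_tbl(voxel = seq_along(tval), mean_adjusted_r = mu, t = tval,
                 p = p, p_fwe = p_fwe,
                 significant = !is.na(p_fwe) & p_fwe <= alpha)
  structure(out, fwe = fwe, alpha = alpha, n_subjects = n_subj,
            excluded_voxels = degenerate,
            class = c("brain_map", class(out)))
}

#' Whole-map convergence-coupling analysis across subjects
#'
#' End-to-end driver: per subject, computes the covariate-controlled
#' voxelwise correlation of typicality with each voxel, applies the
#' permutation-null 95th-percentile subtraction, then runs the group-level
#' one-sample test with FWE control.
#'
#' @param typicality_by_subject Named list of per-trial typicality vectors.
#' @param voxels_by_subject Named list of trials-by-voxels matrices.
#' @param covariate_by_subject Optional named list of per-trial covariates.
#' @param n_perm,alpha_percentile,seed Passed to [null_adjust()]; each
#'   subject's permutations use a subject-specific child seed.
#' @param alpha,fwe Passed to [group_test()].
#' @return A list with `map` (the [group_test()] result), `adjusted`
#'   (subjects-by-voxels matrix) and the parameters used.
#' @export
convergence_map <- function(typicality_by_subject, voxels_by_subject,
                            covariate_by_subject = NULL, n_perm = 500,
                            alpha_percentile = 0.95, seed = 1L, alpha = 0.05,
                            fwe = c("bonferroni", "maxT")) {
  fwe <- match.arg(fwe)
  subjects <- names(typicality_by_subject)
  adj <- t(vapply(subjects, function(s) {
    cov_s <- if (is.null(covariate_by_subject)) NULL else covariate_by_subject[[s]]
    null_adjust(typicality_by_subject[[s]], voxels_by_subject[[s]], cov_s,
                n_perm = n_perm, alpha_percentile = alpha_percentile,
                seed = child_seed(seed, paste0("subject_", s)))$adjusted_r
  }, numeric(ncol(voxels_by_subject[[1]]))))
  map <- group_test(adj, alpha = alpha, fwe = fwe, seed = seed)
  list(map = map, adjusted = adj, n_perm = n_perm,
       alpha_percentile = alpha_percentile, alpha = alpha, fwe = fwe,
       seed = seed)
}
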