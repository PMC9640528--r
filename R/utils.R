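#' @importFrom rlang abort warn inform .data %||%
#' @importFrom stats coef cor lm median plogis pnorm pt qlogis qnorm qt quantile
#'   rbinom rnorm runif sd setNames t.test var vcov anova as.formula logLik
#'   complete.cases cor.test df.residual resid
#' @importFrom utils head
NULL

# single module-level check helper; keeps error classes greppable
stopf <- function(fmt, ..., class = "typicality_error") {
  abort(sprintf(fmt, ...), class = class)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    stopf("`%s` must be a single integer >= %d (got %s)", name, min,
          paste(format(x), collapse = ", "), class = "typicality_config_error")
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x > max) {
    stopf("`%s` must be a single number in [%s, %s]", name, format(min), format(max),
          class = "typicality_config_error")
  }
  as.numeric(x)
}

#' Derive a stage-specific child seed from a top-level seed
#'
#' Stage seeds are a stable arithmetic hash of the top-level seed and the
#' stage name, so that adding or reordering pipeline stages never perturbs
#' the random stream of the others. The result is always in `[0, 2^31 - 2]`.
#'
#' @param seed Integer top-level seed.
#' @param stage Character stage label, e.g. `"simulate"`.
#' @return A single integer seed.
#' @export
#' @examples
#' child_seed(1, "simulate")
child_seed <- function(seed, stage) {
  seed <- check_count(seed, "seed", min = 0L)
  m <- 2147483629 # prime < 2^31; all arithmetic exact in doubles
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer((h * 48271 + as.numeric(seed) * 69621 + 1) %% m)
}

# correlation-geometry helpers ------------------------------------------------

# center to mean zero and scale to unit L2 norm; errors on zero variance
unit_center <- function(x, what = "vector") {
  x <- x - mean(x)
  n <- sqrt(sum(x^2))
  if (n == 0) {
    stopf("%s has zero variance; correlation geometry undefined", what,
          class = "typicality_degenerate_error")
  }
  x / n
}

# rows standardized to mean 0, sd 1 (the representation k-means sees under
# correlation distance)
standardize_rows <- function(mat) {
  mu <- rowMeans(mat)
  cx <- mat - mu
  s <- sqrt(rowSums(cx^2) / (ncol(mat) - 1L))
  if (any(s == 0)) {
    stopf("pattern rows %s have zero variance",
          paste(which(s == 0), collapse = ", "),
          class = "typicality_degenerate_error")
  }
  cx / s
}

new_tbl <- function(...) tibble::tibble(...)
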