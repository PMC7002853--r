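#' Per-group sufficient statistics
#'
#' Every effect-size estimator in this package consumes only the mean, the
#' unbiased (n-1 denominator) variance and the sample size of each group, so
#' raw-data and summary-parameter entry points share a single code path built
#' on `sample_summary` objects.
#'
#' @param mean Sample (or population) mean, in the units of the measurement.
#' @param var Unbiased variance, in squared units; must be non-negative.
#' @param n Sample size; a positive integer.
#'
#' @return An object of class `"sample_summary"`: a list with elements
#'   `mean`, `var` and `n`.
#' @seealso [summarize_sample()] to build one from raw data.
#' @export
#' @examples
#' sample_summary(mean = 1, var = 2, n = 5)
sample_summary <- function(mean, var, n) {
  stopifnot(
    is.numeric(mean), length(mean) == 1L, is.finite(mean),
    is.numeric(var), length(var) == 1L, is.finite(var),
    is.numeric(n), length(n) == 1L, is.finite(n)
  )
  if (var < 0) stop("variance must be non-negative")
  if (n < 1 || n != round(n)) stop("n must be a positive integer")
  structure(list(mean = mean, var = var, n = as.integer(n)),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("sample summary: mean = %g, var = %g, n = %d\n",
              x$mean, x$var, x$n))
  invisible(x)
}

#' Summarize a raw sample
#'
#' Computes the mean and the unbiased variance with a two-pass algorithm
#' (mean first, then centered sum of squares), which keeps ~15 significant
#' digits even for poorly centred data.
#'
#' @param values Numeric vector of at least two finite observations.
#' @return A [sample_summary()] object.
#' @export
#' @examples
#' summarize_sample(c(0, 1, 2, 3, 4)) # mean 2, var 2.5
summarize_sample <- function(values) {
  if (!is.numeric(values)) stop("values must be numeric")
  if (length(values) < 2L) stop("insufficient sample: need at least 2 values")
  if (any(!is.finite(values))) stop("non-finite values are not allowed")
  m <- sum(values) / length(values)
  ss <- sum((values - m)^2)
  sample_summary(m, ss / (length(values) - 1L), length(values))
}

#' Pooled standard deviation of two groups
#'
#' The square root of the degrees-of-freedom-weighted average of the two
#' unbiased variances, `sqrt((s1^2 (n1-1) + s2^2 (n2-1)) / (n1+n2-2))`.
#' This is the denominator of Cohen's g and Hedges' d and presumes equal
#' population variances.
#'
#' @param g1,g2 [sample_summary()] objects.
#' @return The pooled standard deviation (scalar).
#' @export
pooled_sd <- function(g1, g2) {
  stopifnot(inherits(g1, "sample_summary"), inherits(g2, "sample_summary"))
  m <- g1$n + g2$n - 2L
  if (m <= 0) stop("pooled SD undefined: n1 + n2 - 2 must be positive")
  sqrt((g1$var * (g1$n - 1L) + g2$var * (g2$n - 1L)) / m)
}

#' Welch's t statistic from group summaries
#'
#' `(mean1 - mean2) / sqrt(s1^2/n1 + s2^2/n2)`; the unpooled two-sample t
#' that does not assume equal variances.
#'
#' @param g1,g2 [sample_summary()] objects with `n >= 2`.
#' @return Welch's t (scalar).
#' @export
welch_t <- function(g1, g2) {
  stopifnot(inherits(g1, "sample_summary"), inherits(g2, "sample_summary"))
  if (g1$n < 2L || g2$n < 2L) stop("welch_t requires n >= 2 in both groups")
  se2 <- g1$var / g1$n + g2$var / g2$n
  if (se2 <= 0) stop("degenerate samples: both variances are zero")
  (g1$mean - g2$mean) / sqrt(se2)
}

#' Welch-Satterthwaite degrees of freedom
#'
#' The moment-matched approximate df of the unpooled variance combination,
#' `(s1^2/n1 + s2^2/n2)^2 / (s1^4/(n1^2 (n1-1)) + s2^4/(n2^2 (n2-1)))`.
#' Kept as a real number throughout: the bias-correction coefficient and the
#' noncentral-t confidence interval are evaluated at this fractional df, and
#' truncating it changes the results.
#'
#' @param g1,g2 [sample_summary()] objects with `n >= 2`.
#' @return The fractional df (scalar), between `min(n1, n2) - 1` and
#'   `n1 + n2 - 2`.
#' @export
welch_df <- function(g1, g2) {
  stopifnot(inherits(g1, "sample_summary"), inherits(g2, "sample_summary"))
  if (g1$n < 2L || g2$n < 2L) stop("welch_df requires n >= 2 in both groups")
  a1 <- g1$var / g1$n
  a2 <- g2$var / g2$n
  if (a1 + a2 <= 0) stop("degenerate samples: both variances are zero")
  (a1 + a2)^2 / (a1^2 / (g1$n - 1L) + a2^2 / (g2$n - 1L))
}

#' Two-group design with derived quantities
#'
#' Bundles the two group summaries with the quantities shared by all
#' two-sample estimators: the effective sample size
#' `n_tilde = n1 n2 / (n1 + n2)`, the sample-size ratio `r = n1/n2`, the
#' pooled SD, and the Welch-Satterthwaite df.
#'
#' @param g1,g2 [sample_summary()] objects with `n >= 2`.
#' @return An object of class `"two_sample_design"`.
#' @export
two_sample_design <- function(g1, g2) {
  structure(list(
    group1 = g1,
    group2 = g2,
    n_tilde = g1$n * g2$n / (g1$n + g2$n),
    r_ratio = g1$n / g2$n,
    s_pooled = pooled_sd(g1, g2),
    f_welch = welch_df(g1, g2)
  ), class = "two_sample_design")
}

#' @export
print.two_sample_design <- function(x, ...) {
  cat(sprintf(
    "two-sample design: n = (%d, %d), n~ = %g, pooled SD = %g, Welch df = %g\n",
    x$group1$n, x$group2$n, x$n_tilde, x$s_pooled, x$f_welch))
  invisible(x)
}
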