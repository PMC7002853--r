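# High-level effect-size interface: point estimate + variance + CI bundled
# into an "es_estimate" object, from raw data or from summary parameters.

es_estimate <- function(value, variance, ci, df, family, corrected, alpha) {
  structure(list(
    value = value, variance = variance,
    ci_lower = ci[1], ci_upper = ci[2],
    df = df, family = family, corrected = corrected, alpha = alpha
  ), class = "es_estimate")
}

es_label <- function(x) {
  switch(x$family,
    d = if (x$corrected) "Hedges' d" else "Cohen's g",
    e = if (x$corrected) "Unbiased e" else "Biased e",
    c = if (x$corrected) "Unbiased c" else "Biased c",
    stop("unknown family"))
}

#' @export
print.es_estimate <- function(x, digits = 15, ...) {
  fmt <- function(v) format(v, digits = digits)
  cat(sprintf("%s: %s\n", es_label(x), fmt(x$value)))
  cat(sprintf("variance: %s\n", fmt(x$variance)))
  cat(sprintf("%g%% CI: [ %s , %s ]\n", 100 * (1 - x$alpha),
              fmt(x$ci_lower), fmt(x$ci_upper)))
  invisible(x)
}

#' Flatten an effect-size estimate to the four-number vector form
#'
#' @param x An `"es_estimate"` as returned by [es_d()], [es_e()] or
#'   [es_c()].
#' @return `c(estimate, variance, ci_lower, ci_upper)`.
#' @export
es_vector <- function(x) {
  stopifnot(inherits(x, "es_estimate"))
  c(x$value, x$variance, x$ci_lower, x$ci_upper)
}

es_two_sample <- function(g1, g2, family, alpha, unbiased, tol) {
  design <- two_sample_design(g1, g2)
  config <- ncp_search_config(alpha = alpha, tol = tol)
  if (family == "d") {
    df <- g1$n + g2$n - 2L
    est <- hedges_g(design)
    t_obs <- est * sqrt(design$n_tilde)
    variance <- if (unbiased) var_d(design) else
      var_biased_two_sample(design, "d")
  } else {
    df <- design$f_welch
    est <- e_biased(design)
    t_obs <- welch_t(g1, g2)
    variance <- if (unbiased) var_e(design) else
      var_biased_two_sample(design, "e")
  }
  value <- if (unbiased) est * correction_j(df) else est
  ci <- ci_two_sample(t_obs, df, design$n_tilde, corrected = unbiased,
                      config = config)
  es_estimate(value, variance, ci, df, family, unbiased, alpha)
}

#' Hedges' d with variance and exact confidence interval
#'
#' Computes the pooled-SD standardized mean difference of `group1` minus
#' `group2`, its sampling variance, and the noncentral-t confidence
#' interval.  With `unbiased = FALSE` the uncorrected Cohen's g, its
#' variance and its uncorrected interval are reported instead.
#'
#' @param group1,group2 Numeric vectors (at least two finite values each).
#' @param alpha Two-sided type-I error rate of the CI (default 0.05).
#' @param unbiased Apply the small-sample correction `J`?  Default `TRUE`.
#' @param tol Noncentral-parameter search tolerance.
#' @return An `"es_estimate"` object; see [es_vector()] for the flat form.
#' @export
#' @examples
#' es_d(c(0, 1, 2, 3, 4), c(0, 0, 1, 2, 2))
es_d <- function(group1, group2, alpha = 0.05, unbiased = TRUE, tol = 1e-8) {
  es_two_sample(summarize_sample(group1), summarize_sample(group2),
                "d", alpha, unbiased, tol)
}

#' Welch-based effect size e with variance and exact confidence interval
#'
#' The heteroscedastic standardized mean difference of `group1` minus
#' `group2`: no equal-variance assumption, bias correction at the
#' fractional Welch-Satterthwaite df.
#'
#' @inheritParams es_d
#' @return An `"es_estimate"` object.
#' @export
#' @examples
#' es_e(c(0, 1, 2, 3, 4), c(0, 0, 1, 2, 2))
es_e <- function(group1, group2, alpha = 0.05, unbiased = TRUE, tol = 1e-8) {
  es_two_sample(summarize_sample(group1), summarize_sample(group2),
                "e", alpha, unbiased, tol)
}

#' One-sample effect size against a known constant
#'
#' Standardized difference between the mean of `data` and the constant `C`,
#' with variance and noncentral-t confidence interval under the `n - 1`
#' scaling convention of the one-sample t.
#'
#' @param data Numeric vector (at least two finite values).
#' @param constant The known constant C.
#' @inheritParams es_d
#' @return An `"es_estimate"` object.
#' @export
#' @examples
#' es_c(c(0, 0, 1, 2, 2), 2, alpha = 0.01, unbiased = FALSE)
es_c <- function(data, constant, alpha = 0.05, unbiased = TRUE, tol = 1e-8) {
  sample <- summarize_sample(data)
  config <- ncp_search_config(alpha = alpha, tol = tol)
  value <- if (unbiased) c_unbiased(sample, constant) else
    c_biased(sample, constant)
  variance <- var_c(sample, constant, corrected = unbiased)
  ci <- ci_one_sample(sample, constant, corrected = unbiased, config = config)
  es_estimate(value, variance, ci, sample$n - 1L, "c", unbiased, alpha)
}

#' Effect sizes from summary parameters
#'
#' Parameter-based entry points: identical numerics to [es_d()], [es_e()]
#' and [es_c()], but starting from per-group means, unbiased variances and
#' sample sizes instead of raw data.  Useful when only summary statistics
#' are reported.
#'
#' @param mean1,mean2 Group means.
#' @param var1,var2 Group unbiased variances.
#' @param n1,n2 Group sample sizes.
#' @inheritParams es_d
#' @return An `"es_estimate"` object.
#' @export
#' @examples
#' es_para_d(1, 0, 2, 1, 5, 10)
es_para_d <- function(mean1, mean2, var1, var2, n1, n2,
                      alpha = 0.05, unbiased = TRUE, tol = 1e-8) {
  es_two_sample(sample_summary(mean1, var1, n1),
                sample_summary(mean2, var2, n2),
                "d", alpha, unbiased, tol)
}

#' @rdname es_para_d
#' @export
es_para_e <- function(mean1, mean2, var1, var2, n1, n2,
                      alpha = 0.05, unbiased = TRUE, tol = 1e-8) {
  es_two_sample(sample_summary(mean1, var1, n1),
                sample_summary(mean2, var2, n2),
                "e", alpha, unbiased, tol)
}

#' @rdname es_para_d
#' @param constant The known constant C (one-sample family).
#' @export
es_para_c <- function(mean1, var1, n1, constant,
                      alpha = 0.05, unbiased = TRUE, tol = 1e-8) {
  sample <- sample_summary(mean1, var1, n1)
  config <- ncp_search_config(alpha = alpha, tol = tol)
  value <- if (unbiased) c_unbiased(sample, constant) else
    c_biased(sample, constant)
  variance <- var_c(sample, constant, corrected = unbiased)
  ci <- ci_one_sample(sample, constant, corrected = unbiased, config = config)
  es_estimate(value, variance, ci, sample$n - 1L, "c", unbiased, alpha)
}
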