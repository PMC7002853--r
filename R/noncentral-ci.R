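# Exact effect-size confidence intervals by inverting the noncentral
# parameter of the noncentral t distribution.
#
# The CDF of the noncentral t at a fixed quantile is strictly decreasing in
# the noncentral parameter, so each interval endpoint is the unique root of
# CDF(t_obs; df, ncp) = p.  We bracket the root by geometric expansion from
# [t_obs - 1, t_obs + 1] and bisect; everything is vectorized over
# replicates so the Monte Carlo harness can solve tens of thousands of
# roots in a handful of stats::pt() calls.

#' Search policy for the noncentral-parameter root find
#'
#' @param alpha Two-sided type-I error rate of the interval, in (0, 1).
#' @param tol Absolute tolerance on the noncentral parameter.
#' @param max_expand Maximum number of bracket doublings on each side.
#' @return An object of class `"ncp_search_config"`.
#' @export
ncp_search_config <- function(alpha = 0.05, tol = 1e-8, max_expand = 60L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.numeric(tol), length(tol) == 1L, tol > 0,
            is.numeric(max_expand), length(max_expand) == 1L, max_expand >= 1)
  structure(list(alpha = alpha, tol = tol, max_expand = as.integer(max_expand)),
            class = "ncp_search_config")
}

#' Invert the noncentral-t CDF for its noncentral parameter
#'
#' Finds the `ncp` such that `pt(t_obs, df, ncp) == target_prob`, to within
#' `config$tol`.  All three numeric arguments are vectorized (recycled to a
#' common length), and `df` may be fractional.
#'
#' @param t_obs Observed t statistic(s).
#' @param df Degrees of freedom, `> 0`, possibly fractional.
#' @param target_prob Target cumulative probability, strictly in (0, 1).
#' @param config An [ncp_search_config()].
#' @return The noncentral parameter(s), same length as the recycled inputs.
#' @export
#' @examples
#' find_ncp(0, 10, 0.5)               # 0 by symmetry
#' find_ncp(-2, 4, 0.995)             # about -5.078
find_ncp <- function(t_obs, df, target_prob, config = ncp_search_config()) {
  n <- max(length(t_obs), length(df), length(target_prob))
  t_obs <- rep_len(as.numeric(t_obs), n)
  df <- rep_len(as.numeric(df), n)
  p <- rep_len(as.numeric(target_prob), n)
  if (any(!is.finite(t_obs))) stop("t_obs must be finite")
  if (any(df <= 0)) stop("df must be positive")
  if (any(p <= 0 | p >= 1)) stop("target_prob must be strictly inside (0, 1)")

  cdf <- function(ncp) suppressWarnings(stats::pt(t_obs, df, ncp))

  # CDF is decreasing in ncp: need cdf(lo) >= p >= cdf(hi)
  lo <- t_obs - 1
  hi <- t_obs + 1
  step <- rep(1, n)
  for (k in seq_len(config$max_expand)) {
    bad <- cdf(lo) < p
    if (!any(bad)) break
    lo[bad] <- lo[bad] - step[bad]
    step[bad] <- 2 * step[bad]
  }
  if (any(cdf(lo) < p)) stop("ncp bracket not found (lower side)")
  step <- rep(1, n)
  for (k in seq_len(config$max_expand)) {
    bad <- cdf(hi) > p
    if (!any(bad)) break
    hi[bad] <- hi[bad] + step[bad]
    step[bad] <- 2 * step[bad]
  }
  if (any(cdf(hi) > p)) stop("ncp bracket not found (upper side)")

  iter <- 0L
  while (max(hi - lo) > config$tol && iter < 200L) {
    mid <- (lo + hi) / 2
    up <- cdf(mid) >= p
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
    iter <- iter + 1L
  }
  (lo + hi) / 2
}

#' Noncentral-t confidence interval for a two-sample effect size
#'
#' Scales the inverted noncentral parameters back to the effect-size scale:
#' the interval is `[ncp_L, ncp_H] / sqrt(n_tilde)`, multiplied elementwise
#' by `J(df)` when `corrected`.  `ncp_L` solves
#' `CDF(t_obs) = 1 - alpha/2`, `ncp_H` solves `CDF(t_obs) = alpha/2`.
#'
#' The pivot `t_obs` is `g * sqrt(n_tilde)` (the pooled-variance t) for the
#' d family with `df = n1 + n2 - 2`, or Welch's t for the e family with
#' `df = f_welch`.
#'
#' @param t_obs The pivotal t statistic.
#' @param df Its degrees of freedom (fractional allowed).
#' @param scale_n The effective sample size `n_tilde` dividing the t scale.
#' @param corrected Multiply both endpoints by `J(df)`?
#' @param config An [ncp_search_config()] (carries `alpha` and `tol`).
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
ci_two_sample <- function(t_obs, df, scale_n, corrected = TRUE,
                          config = ncp_search_config()) {
  stopifnot(is.numeric(scale_n), scale_n > 0)
  a <- config$alpha
  lims <- find_ncp(t_obs, df, c(1 - a / 2, a / 2), config) / sqrt(scale_n)
  if (corrected) lims <- lims * correction_j(df)
  lims
}

#' Noncentral-t confidence interval for the one-sample effect size
#'
#' Uses the one-sample pivot `t = c_biased * sqrt(n - 1)` with `df = n - 1`
#' (the `n - 1` scaling convention matching [var_c()]); the interval is
#' `[ncp_L, ncp_H] / sqrt(n - 1)`, times `J(n - 1)` when `corrected`.
#'
#' @param sample A [sample_summary()] with `n >= 2` and positive variance.
#' @param constant The known constant C.
#' @param corrected Multiply the endpoints by `J(n - 1)`?
#' @param config An [ncp_search_config()].
#' @return Length-2 numeric `c(lower, upper)`.
#' @export
ci_one_sample <- function(sample, constant, corrected = TRUE,
                          config = ncp_search_config()) {
  stopifnot(inherits(sample, "sample_summary"))
  nu <- sample$n - 1L
  t_obs <- c_biased(sample, constant) * sqrt(nu)
  a <- config$alpha
  lims <- find_ncp(t_obs, nu, c(1 - a / 2, a / 2), config) / sqrt(nu)
  if (corrected) lims <- lims * correction_j(nu)
  lims
}
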