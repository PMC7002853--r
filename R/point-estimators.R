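# Point estimators and their population parameters.
#
# Naming convention: *_param functions are population quantities (take means
# and SDs), everything else is a statistic computed from sample summaries.

#' Cohen's g: biased pooled-SD standardized mean difference
#'
#' `(mean1 - mean2) / s_pooled`.  Assumes equal population variances; the
#' biased precursor of Hedges' d.
#'
#' @param design A [two_sample_design()].
#' @return The effect size (scalar).
#' @export
hedges_g <- function(design) {
  stopifnot(inherits(design, "two_sample_design"))
  if (design$s_pooled <= 0) stop("zero pooled SD: effect size undefined")
  (design$group1$mean - design$group2$mean) / design$s_pooled
}

#' Hedges' d: unbiased pooled-SD standardized mean difference
#'
#' `J(n1 + n2 - 2) * g`, with [correction_j()] the exact gamma-ratio
#' correction.
#'
#' @inheritParams hedges_g
#' @return The effect size (scalar).
#' @export
hedges_d <- function(design) {
  m <- design$group1$n + design$group2$n - 2L
  correction_j(m) * hedges_g(design)
}

#' Glass' Delta: mean difference over the control group's SD
#'
#' The control group must be designated explicitly; no heuristic ordering is
#' attempted.
#'
#' @param experimental,control [sample_summary()] objects; `control` needs
#'   `n >= 2` and a positive variance.
#' @return The effect size (scalar).
#' @export
glass_delta <- function(experimental, control) {
  stopifnot(inherits(experimental, "sample_summary"),
            inherits(control, "sample_summary"))
  if (control$n < 2L) stop("control group needs n >= 2")
  if (control$var <= 0) stop("zero control-group SD: effect size undefined")
  (experimental$mean - control$mean) / sqrt(control$var)
}

#' Bonett's delta-hat: mean difference over the unweighted average variance
#'
#' `(mean1 - mean2) / sqrt((s1^2 + s2^2)/2)`; coincides with Cohen's g when
#' `n1 = n2`.  Its population parameter is undefined, which is the main
#' argument for the Welch-based effect size instead.
#'
#' @param g1,g2 [sample_summary()] objects.
#' @return The effect size (scalar).
#' @export
bonett_delta_hat <- function(g1, g2) {
  stopifnot(inherits(g1, "sample_summary"), inherits(g2, "sample_summary"))
  s2 <- (g1$var + g2$var) / 2
  if (s2 <= 0) stop("both variances zero: effect size undefined")
  (g1$mean - g2$mean) / sqrt(s2)
}

#' Biased Welch-based effect size
#'
#' `t_w / sqrt(n_tilde)` with `t_w` Welch's t and
#' `n_tilde = n1 n2/(n1 + n2)`.  Estimates the heteroscedastic parameter
#' [epsilon_param()] with `r = n1/n2`, without assuming equal variances.
#'
#' @inheritParams hedges_g
#' @return The effect size (scalar).
#' @export
e_biased <- function(design) {
  stopifnot(inherits(design, "two_sample_design"))
  welch_t(design$group1, design$group2) / sqrt(design$n_tilde)
}

#' Unbiased Welch-based effect size
#'
#' `e = e_biased * J(f)` with `f` the fractional Welch-Satterthwaite df.
#'
#' @inheritParams hedges_g
#' @return The effect size (scalar).
#' @export
e_unbiased <- function(design) {
  if (design$f_welch <= 1) stop("Welch df too small for correction")
  e_biased(design) * correction_j(design$f_welch)
}

#' Biased one-sample effect size against a known constant
#'
#' `(mean - C) / s`, with `s` the unbiased sample SD.
#'
#' @param sample A [sample_summary()] with `n >= 2` and positive variance.
#' @param constant The known constant C.
#' @return The effect size (scalar).
#' @export
c_biased <- function(sample, constant) {
  stopifnot(inherits(sample, "sample_summary"),
            is.numeric(constant), length(constant) == 1L, is.finite(constant))
  if (sample$n < 2L) stop("one-sample effect size needs n >= 2")
  if (sample$var <= 0) stop("zero sample SD: effect size undefined")
  (sample$mean - constant) / sqrt(sample$var)
}

#' Unbiased one-sample effect size against a known constant
#'
#' `c = c_biased * J(n - 1)`; the unbiased estimator of [gamma_param()].
#'
#' @inheritParams c_biased
#' @return The effect size (scalar).
#' @export
c_unbiased <- function(sample, constant) {
  if (sample$n < 3L) stop("unbiased one-sample effect size needs n >= 3")
  c_biased(sample, constant) * correction_j(sample$n - 1L)
}

#' One-sample effect size of the constant relative to the mean
#'
#' `c' = (C - mean) J(n-1) / s`, i.e. exactly `-c_unbiased`; convenient when
#' the constant, not the variable, is the quantity of interest.
#'
#' @inheritParams c_biased
#' @return The effect size (scalar).
#' @export
c_prime <- function(sample, constant) {
  -c_unbiased(sample, constant)
}

#' Homoscedastic effect-size parameter delta
#'
#' `(mu1 - mu2) / sigma` for two normal populations sharing the SD `sigma`.
#'
#' @param mu1,mu2 Population means.
#' @param sigma Common population SD, `> 0`.
#' @return The parameter value.
#' @export
delta_param <- function(mu1, mu2, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  (mu1 - mu2) / sigma
}

#' Heteroscedastic effect-size parameter epsilon_r
#'
#' `(mu1 - mu2) / sqrt((sigma1^2 + r sigma2^2) / (r + 1))`, the parameter
#' estimated by the Welch-based effect size; `r` is the sample-size ratio
#' `n1/n2`.  Collapses to [delta_param()] when `sigma1 = sigma2`.
#'
#' @param mu1,mu2 Population means.
#' @param sigma1,sigma2 Population SDs, not both zero.
#' @param r Sample-size ratio `n1/n2`, `> 0`.
#' @return The parameter value.
#' @export
epsilon_param <- function(mu1, mu2, sigma1, sigma2, r) {
  if (any(r <= 0)) stop("r must be positive")
  if (any(sigma1 < 0) || any(sigma2 < 0)) stop("SDs must be non-negative")
  denom2 <- (sigma1^2 + r * sigma2^2) / (r + 1)
  if (any(denom2 <= 0)) stop("degenerate denominator: both SDs are zero")
  (mu1 - mu2) / sqrt(denom2)
}

#' One-sample effect-size parameter gamma
#'
#' `(mu - C) / sigma1` for a normal population and a known constant C.
#'
#' @param mu Population mean.
#' @param constant The known constant C.
#' @param sigma1 Population SD, `> 0`.
#' @return The parameter value.
#' @export
gamma_param <- function(mu, constant, sigma1) {
  if (any(sigma1 <= 0)) stop("sigma must be positive")
  (mu - constant) / sigma1
}

#' The parameter a pooled-SD estimator drifts to under unequal variances
#'
#' `(mu1 - mu2) / sqrt((q sigma1^2 + sigma2^2) / (1 + q))` with
#' `q = (n1-1)/(n2-1)`.  When the population variances differ, Cohen's g no
#' longer estimates [delta_param()]; it is (biasedly) aimed at this
#' `q`-weighted parameter instead, which is why pooled-SD effect sizes
#' become sample-size dependent under heteroscedasticity.
#'
#' @param mu1,mu2 Population means.
#' @param sigma1,sigma2 Population SDs, not both zero.
#' @param q Degrees-of-freedom ratio `(n1-1)/(n2-1)`, `> 0`.
#' @return The parameter value.
#' @export
delta_q_param <- function(mu1, mu2, sigma1, sigma2, q) {
  if (any(q <= 0)) stop("q must be positive")
  if (any(sigma1 < 0) || any(sigma2 < 0)) stop("SDs must be non-negative")
  denom2 <- (q * sigma1^2 + sigma2^2) / (1 + q)
  if (any(denom2 <= 0)) stop("degenerate denominator: both SDs are zero")
  (mu1 - mu2) / sqrt(denom2)
}
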