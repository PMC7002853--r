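# Sampling variances via noncentral-t second moments.
#
# Plug-in convention, used throughout: every unknown parameter slot in a
# variance formula receives the BIASED point estimate (g, e_biased or
# c_biased), never the corrected one.  For the corrected estimator with df
# nu, scale k and parameter theta the variance is
#     nu/(nu-2) * J(nu)^2 * (1/k + theta^2) - theta^2,
# and for the uncorrected statistic (mean parameter theta/J(nu)) it is
#     nu/(nu-2) * (1/k + theta^2) - theta^2 / J(nu)^2.

#' Sampling variance of Hedges' d
#'
#' The `m = n1 + n2 - 2` noncentral-t second-moment form
#' `m/(m-2) J(m)^2 (1/n_tilde + g^2) - g^2`, with the biased estimate g
#' plugged into the parameter slot.
#'
#' @param design A [two_sample_design()] with `n1 + n2 - 2 > 2`.
#' @return The estimated sampling variance (scalar).
#' @export
var_d <- function(design) {
  stopifnot(inherits(design, "two_sample_design"))
  m <- design$group1$n + design$group2$n - 2L
  if (m <= 2) stop("variance undefined: needs n1 + n2 - 2 > 2")
  g <- hedges_g(design)
  m / (m - 2) * correction_j(m)^2 * (1 / design$n_tilde + g^2) - g^2
}

#' Sampling variance of the unbiased Welch-based effect size
#'
#' `f/(f-2) J(f)^2 (1/n_tilde + e_biased^2) - e_biased^2` at the fractional
#' Welch-Satterthwaite df `f`.
#'
#' @param design A [two_sample_design()] with `f_welch > 2`.
#' @return The estimated sampling variance (scalar).
#' @export
var_e <- function(design) {
  stopifnot(inherits(design, "two_sample_design"))
  f <- design$f_welch
  if (f <= 2) stop("variance undefined: Welch df must exceed 2")
  eb <- e_biased(design)
  f / (f - 2) * correction_j(f)^2 * (1 / design$n_tilde + eb^2) - eb^2
}

#' Sampling variance of the one-sample effect size
#'
#' Corrected branch:
#' `(n-1)/(n-3) J(n-1)^2 (1/(n-1) + c_biased^2) - c_biased^2`.
#' Biased branch (variance of the uncorrected statistic):
#' `(1 + (n-1) c_biased^2)/(n-3) - c_biased^2 / J(n-1)^2`.
#'
#' Both use the `nu = n - 1` scaling convention of the one-sample t written
#' as `t = (mean - C)/sqrt(s^2/(n-1))`, and both plug the biased estimate
#' into the parameter slot.
#'
#' @param sample A [sample_summary()] with `n > 3`.
#' @param constant The known constant C.
#' @param corrected If `TRUE` (default) the variance of the unbiased
#'   estimator; otherwise that of the biased statistic.
#' @return The estimated sampling variance (scalar).
#' @export
var_c <- function(sample, constant, corrected = TRUE) {
  stopifnot(inherits(sample, "sample_summary"))
  n <- sample$n
  if (n <= 3) stop("variance undefined: needs n > 3")
  cb <- c_biased(sample, constant)
  nu <- n - 1L
  j <- correction_j(nu)
  if (corrected) {
    nu / (nu - 2) * j^2 * (1 / nu + cb^2) - cb^2
  } else {
    (1 + nu * cb^2) / (nu - 2) - cb^2 / j^2
  }
}

#' Sampling variance of a biased two-sample effect size
#'
#' For the uncorrected statistics g (family `"d"`, df `n1 + n2 - 2`) and
#' e_biased (family `"e"`, df `f_welch`):
#' `df/(df-2) (1/n_tilde + est^2) - est^2 / J(df)^2`.
#'
#' @param design A [two_sample_design()].
#' @param family `"d"` for the pooled-SD statistic, `"e"` for the
#'   Welch-based one.
#' @return The estimated sampling variance (scalar).
#' @export
var_biased_two_sample <- function(design, family = c("d", "e")) {
  stopifnot(inherits(design, "two_sample_design"))
  family <- match.arg(family)
  if (family == "d") {
    df <- design$group1$n + design$group2$n - 2L
    est <- hedges_g(design)
  } else {
    df <- design$f_welch
    est <- e_biased(design)
  }
  if (df <= 2) stop("variance undefined: df must exceed 2")
  df / (df - 2) * (1 / design$n_tilde + est^2) - est^2 / correction_j(df)^2
}
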