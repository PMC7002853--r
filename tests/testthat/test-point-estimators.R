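worked <- design_from(data1, data2)
para <- two_sample_design(sample_summary(1, 2, 5), sample_summary(0, 1, 10))

test_that("two-sample point estimators reproduce the worked examples", {
  expect_equal(hedges_g(worked), 1 / sqrt(1.75))
  expect_equal(hedges_d(worked), 0.682379579593354, tolerance = 1e-14)
  expect_equal(hedges_d(para), 0.82286529714397, tolerance = 1e-14)
  expect_equal(hedges_g(para), 1 / sqrt(17 / 13))

  expect_equal(e_biased(worked), (1 / sqrt(0.7)) / sqrt(2.5))
  expect_equal(e_biased(worked), hedges_g(worked)) # n1 = n2
  expect_equal(e_biased(para), sqrt(2) / sqrt(10 / 3))
  expect_equal(e_unbiased(worked), 0.668264936033828, tolerance = 1e-14)
  expect_equal(e_unbiased(para), 0.674259756444758, tolerance = 1e-14)

  expect_equal(bonett_delta_hat(summarize_sample(data1),
                                summarize_sample(data2)), 1 / sqrt(1.75))
  expect_equal(bonett_delta_hat(sample_summary(1, 2, 5),
                                sample_summary(0, 1, 10)), 1 / sqrt(1.5))

  same <- design_from(data2, data2)
  expect_equal(hedges_d(same), 0)
  expect_equal(e_unbiased(same), 0)
})

test_that("Glass' Delta divides by the designated control SD", {
  e <- summarize_sample(data1)
  ctrl <- summarize_sample(data2)
  expect_equal(glass_delta(e, ctrl), 1) # control SD = 1
  expect_equal(glass_delta(ctrl, ctrl), 0)
  expect_equal(glass_delta(sample_summary(1, 1, 5), sample_summary(0, 4, 5)),
               0.5)
  expect_error(glass_delta(e, sample_summary(0, 0, 5)), "zero control")
})

test_that("one-sample estimators and their sign-flipped twin", {
  s <- summarize_sample(data2)
  expect_equal(c_biased(s, 2), -1)
  expect_equal(c_biased(summarize_sample(data1), 0), 2 / sqrt(2.5))
  expect_equal(c_biased(s, 1), 0)
  expect_equal(c_unbiased(s, 2), -correction_j(4))
  expect_equal(c_unbiased(s, 2), -1 * 2 / sqrt(2 * pi)) # J(4) = 2/sqrt(2*pi)
  expect_equal(c_prime(s, 2), -c_unbiased(s, 2))
  expect_error(c_biased(sample_summary(1, 0, 5), 0), "zero sample SD")
})

test_that("population parameters match their definitions", {
  expect_equal(delta_param(1, 0, 1), 1)
  expect_equal(delta_param(1, 0, 2), 0.5)
  expect_equal(delta_param(3, 3, 0.7), 0)
  expect_error(delta_param(1, 0, 0), "positive")

  expect_equal(epsilon_param(1, 0, 1, 4, r = 1), 1 / sqrt(8.5))
  expect_equal(round(epsilon_param(1, 0, 1, 4, r = 1), 3), 0.343)
  expect_equal(epsilon_param(1, 0, 1, 4, r = 0.5), 1 / sqrt(6))
  # equal SDs collapse to delta regardless of r
  for (r in c(0.2, 1, 3)) {
    expect_equal(epsilon_param(2, 0, 1.5, 1.5, r), delta_param(2, 0, 1.5))
  }

  expect_equal(gamma_param(1, 2, 1), -1)
  expect_equal(gamma_param(3, 1, 2), 1)
  expect_equal(gamma_param(5, 5, 2), 0)

  expect_equal(delta_q_param(1, 0, 1, 1, q = 7), delta_param(1, 0, 1))
  expect_equal(delta_q_param(1, 0, 1, 4, q = 1), epsilon_param(1, 0, 1, 4, 1))
  expect_equal(delta_q_param(1, 0, 2, 1, q = 1), 1 / sqrt(2.5))
})

test_that("estimators agree when n1 = n2 and flip sign when groups swap", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(3:25, 1)
    x <- rnorm(n, 0, runif(1, 0.3, 3))
    y <- rnorm(n, 1, runif(1, 0.3, 3))
    d <- design_from(x, y)
    # equal-n degeneracy: e_biased = g = Bonett's delta-hat
    expect_equal(e_biased(d), hedges_g(d))
    expect_equal(bonett_delta_hat(d$group1, d$group2), hedges_g(d))
    # antisymmetry under group swap
    rev <- design_from(y, x)
    expect_equal(hedges_g(rev), -hedges_g(d))
    expect_equal(hedges_d(rev), -hedges_d(d))
    expect_equal(e_biased(rev), -e_biased(d))
    expect_equal(e_unbiased(rev), -e_unbiased(d))
    expect_equal(bonett_delta_hat(rev$group1, rev$group2),
                 -bonett_delta_hat(d$group1, d$group2))
  }
})

test_that("all effect sizes are invariant to a common rescaling", {
  set.seed(51)
  for (i in 1:20) {
    gr <- random_groups()
    k <- runif(1, 0.1, 50)
    d <- design_from(gr$x, gr$y)
    dk <- design_from(k * gr$x, k * gr$y)
    expect_equal(hedges_d(dk), hedges_d(d))
    expect_equal(e_unbiased(dk), e_unbiased(d))
    expect_equal(bonett_delta_hat(dk$group1, dk$group2),
                 bonett_delta_hat(d$group1, d$group2))
    expect_equal(glass_delta(dk$group1, dk$group2),
                 glass_delta(d$group1, d$group2))
    const <- runif(1, -2, 2)
    expect_equal(c_unbiased(summarize_sample(k * gr$x), k * const),
                 c_unbiased(summarize_sample(gr$x), const))
  }
})

test_that("corrected estimates are shrunk relative to biased ones", {
  set.seed(61)
  for (i in 1:20) {
    gr <- random_groups()
    d <- design_from(gr$x, gr$y)
    expect_lt(abs(e_unbiased(d)), abs(e_biased(d)))
    s <- summarize_sample(gr$x)
    expect_lt(abs(c_unbiased(s, 0.5)), abs(c_biased(s, 0.5)))
  }
})
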