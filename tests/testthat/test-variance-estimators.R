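worked <- design_from(data1, data2)
para <- two_sample_design(sample_summary(1, 2, 5), sample_summary(0, 1, 10))

test_that("var_d and var_e reproduce the worked-example variances", {
  expect_equal(var_d(worked), 0.484026380702367, tolerance = 1e-12)
  expect_equal(var_d(para), 0.349443397657368, tolerance = 1e-12)
  expect_equal(var_e(worked), 0.506830833214916, tolerance = 1e-12)
  expect_equal(var_e(para), 0.41613476136966, tolerance = 1e-12)
})

test_that("the parameter slot takes the biased estimate, not the corrected", {
  # plugging d^2 instead of g^2 gives a visibly different number (~0.4656),
  # so the reproduction above pins down the plug-in convention
  g <- hedges_g(worked)
  d <- hedges_d(worked)
  j <- correction_j(8)
  wrong <- 8 / 6 * j^2 * (1 / 2.5 + d^2) - d^2
  expect_gt(abs(wrong - 0.484026380702367), 1e-3)
  right <- 8 / 6 * j^2 * (1 / 2.5 + g^2) - g^2
  expect_equal(right, 0.484026380702367, tolerance = 1e-12)
})

test_that("var_c matches both branches on the worked one-sample example", {
  s <- summarize_sample(data2)
  expect_equal(var_c(s, 2, corrected = FALSE), 0.9292037, tolerance = 1e-7)
  # the nu = n-1 convention is what reproduces the printed value:
  # 2.5 - pi/2, whereas a nu = n convention gives ~0.829
  expect_equal(var_c(s, 2, corrected = FALSE), 2.5 - pi / 2, tolerance = 1e-14)
  expect_equal(var_c(s, 2, corrected = TRUE),
               2 * correction_j(4)^2 * 1.25 - 1, tolerance = 1e-14)
  # at zero effect the corrected variance reduces to its first term
  s0 <- sample_summary(0, 1, 8)
  expect_equal(var_c(s0, 0, corrected = TRUE),
               (7 / 5) * correction_j(7)^2 / 7)
  expect_error(var_c(summarize_sample(c(0, 1, 2)), 0), "needs n > 3")
})

test_that("var_biased_two_sample follows the uncorrected second-moment form", {
  # at zero effect: df/(df-2)/n_tilde
  d0 <- two_sample_design(sample_summary(0, 1, 6), sample_summary(0, 1, 6))
  expect_equal(var_biased_two_sample(d0, "d"), (10 / 8) / 3)
  g <- hedges_g(worked)
  expect_equal(var_biased_two_sample(worked, "d"),
               (4 / 3) * (0.4 + g^2) - g^2 / correction_j(8)^2)
  expect_equal(var_biased_two_sample(worked, "d"), 0.594, tolerance = 1e-4)
})

test_that("variances are positive over random designs", {
  set.seed(71)
  for (i in 1:40) {
    gr <- random_groups()
    d <- design_from(gr$x, gr$y)
    expect_gt(var_d(d), 0)
    if (d$f_welch > 2) expect_gt(var_e(d), 0)
    expect_gt(var_biased_two_sample(d, "d"), 0)
    if (d$f_welch > 2) expect_gt(var_biased_two_sample(d, "e"), 0)
    if (length(gr$x) > 3) expect_gt(var_c(summarize_sample(gr$x), 0), 0)
  }
})

test_that("var estimators agree with a Monte Carlo oracle", {
  # empirical variance of g over many replicates vs the formula evaluated
  # at the population values (parameter in place of the plug-in estimate)
  set.seed(81)
  n1 <- 10L; n2 <- 10L; reps <- 40000L
  y1 <- matrix(rnorm(n1 * reps, 1, 1), n1)
  y2 <- matrix(rnorm(n2 * reps, 0, 1), n2)
  v1 <- apply(y1, 2, var); v2 <- apply(y2, 2, var)
  g <- (colMeans(y1) - colMeans(y2)) / sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) /
                                              (n1 + n2 - 2))
  m <- n1 + n2 - 2
  nt <- n1 * n2 / (n1 + n2)
  theo <- m / (m - 2) * (1 / nt + 1^2) - 1 / correction_j(m)^2
  expect_equal(var(g), theo, tolerance = 0.05)
})
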