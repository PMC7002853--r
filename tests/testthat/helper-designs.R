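# Shared fixtures: the two worked samples and a generator of random
# two-group designs for property tests.

data1 <- c(0, 1, 2, 3, 4)
data2 <- c(0, 0, 1, 2, 2)

# Random normal two-group data with varied n and SDs.
random_groups <- function() {
  n1 <- sample(4:30, 1)
  n2 <- sample(4:30, 1)
  list(x = rnorm(n1, mean = runif(1, -2, 2), sd = runif(1, 0.2, 4)),
       y = rnorm(n2, mean = runif(1, -2, 2), sd = runif(1, 0.2, 4)))
}

design_from <- function(x, y) {
  two_sample_design(summarize_sample(x), summarize_sample(y))
}
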