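pine <- scaling_params("pine")
aspen <- scaling_params("aspen")

pine_tree <- function(L = 10, ...) tree_spec(pine, L = L, ...)

## noisy power-law sample with known truth, for fitter tests
power_law_sample <- function(n, B, E, cv, d_range = c(1, 100), seed = 1) {
  set.seed(seed)
  d <- exp(runif(n, log(d_range[1]), log(d_range[2])))
  y <- B * d^E * exp(rnorm(n, 0, sqrt(log(1 + cv^2))))
  data.frame(d_over_bark = d, y = y)
}
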