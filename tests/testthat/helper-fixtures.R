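# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

zero_noise_truth <- function(...) {
  default_ground_truth(cv = 0, subject_sd = 0, baseline_sd = 0, ...)
}

# Zero-noise study and its reduction: the noiseless stated world.
zero_noise_data <- function() {
  memo("zn_data", function() {
    simulate_study(zero_noise_truth(), study_design(), seed = 101)
  })
}

zero_noise_md <- function() {
  memo("zn_md", function() reduce_to_model_dataset(zero_noise_data()))
}

# Noisy study at the default noise model.
noisy_data <- function() {
  memo("noisy_data", function() {
    simulate_study(default_ground_truth(), study_design(), seed = 202)
  })
}

# Small input-curve fixture over an hour.
toy_inputs <- function(glc = 100, pro = 50) {
  input_curves(c(0, 30, 60, 120), rep(glc, 4), rep(pro, 4))
}

toy_rates <- function(value = 0.01) {
  as_rate_params(stats::setNames(rep(value, 11), postflux:::rate_names()))
}

# Type-7 quantile written out by hand: the brute-force oracle used against
# the filter's quantile calls.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- min(lo + 1, n)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
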