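# Shared fixtures: tiny frames and simulations built in code.

# report every expectation even when full-scale checks fail
options(testthat.progress.max_fails = 1000)

tiny_frame <- function(n = 12, q = 3, K = 2, seed = 42, binary = TRUE) {
  set.seed(seed)
  X <- matrix(rnorm(n * q), n, q)
  eta <- sample(seq_len(K), n, replace = TRUE)
  eta[seq_len(K)] <- seq_len(K)  # every arm non-empty
  Y_f <- if (binary) rbinom(n, 1, 0.5) else rnorm(n)
  treatment_frame(X, eta, Y_f, K = K,
                  outcome_type = if (binary) "binary" else "continuous")
}

small_binary_sim <- function(n = 400, seed = 7) {
  simulate_binary(binary_sim_spec(n = n, seed = seed, eval_subset = min(n, 100)))
}

fast_config <- function(total = 200L, seed = 3L, ...) {
  gan_config(total_batches = total, seed = seed, trace_every = max(1L, total %/% 4L), ...)
}
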