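# shared fixtures: backends, scaled-down model settings, random sentences

stub16 <- function(seed = 42) make_hash_backend(16, seed)

# benchmark-dimension stub (matches the production embedding dimensionality)
stub300 <- function(seed = 42) make_hash_backend(300, seed)

# scaled-down truncations keep the full suite fast; contracts that probe the
# defaults construct hdp_params() explicitly
fast_hdp <- function(seed = 42) hdp_params(T = 50, K = 10, iterations = 50, seed = seed)

fast_cfg <- function(seed = 42, ...) metric_config(hdp = fast_hdp(seed), ...)

# deterministic pseudo-sentences: n tokens of 3-6 lowercase letters
random_sentence <- function(n_tokens, seed) {
  set.seed(seed)
  paste(vapply(seq_len(n_tokens), function(i) {
    paste(sample(letters, sample(3:6, 1), replace = TRUE), collapse = "")
  }, ""), collapse = " ")
}
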