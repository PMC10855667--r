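# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed conditions so callers can distinguish failure modes
embedhdp_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "embedhdp_error"), call = call))
}

err_invalid_input <- function(msg) embedhdp_error(msg, "embedhdp_invalid_input")
err_config <- function(msg) embedhdp_error(msg, "embedhdp_config_error")
err_degenerate <- function(msg) embedhdp_error(msg, "embedhdp_degenerate_document")
err_dictionary <- function(msg) embedhdp_error(msg, "embedhdp_dictionary_mismatch")

# run code under a temporary RNG state; the caller's stream is untouched
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# deterministic 31-bit string hash (polynomial rolling hash over UTF-8 bytes);
# products stay below 2^53 so the arithmetic is exact in doubles
str_hash <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 16777213L
  as.integer(h)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) err_degenerate("cosine undefined for a zero vector")
  sum(a * b) / (na * nb)
}
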