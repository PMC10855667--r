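# independent oracle: explicit two-key sort (value desc, index asc), then cap
brute_quantize <- function(v, L, scale, mode = "clip") {
  w <- if (mode == "clip") pmax(v, 0) else abs(v)
  ord <- order(-w, seq_along(w))
  keep <- ord[seq_len(min(L, length(w)))]
  keep <- sort(keep[w[keep] > 0])
  list(term_id = keep - 1L, weight = scale * w[keep])
}

test_that("quantize_vector matches the worked examples", {
  q <- quantize_vector(c(0.02, -0.5, 0.01), quantize_config(L = 2))
  expect_equal(q$term_id, c(0L, 2L))
  expect_equal(q$weight, c(2.0, 1.0))
  # all-zero vector gives an empty document
  expect_length(quantize_vector(rep(0, 5))$term_id, 0)
  # one-hot
  v <- rep(0, 8); v[6] <- 0.07
  q1 <- quantize_vector(v)
  expect_equal(q1$term_id, 5L)
  expect_equal(q1$weight, 7.0)
  # absolute mode keeps negative magnitude
  qa <- quantize_vector(c(-0.5, 0.1), quantize_config(L = 1, negative_handling = "absolute"))
  expect_equal(qa$term_id, 0L)
  expect_equal(qa$weight, 50)
})

test_that("quantize_vector matches the brute-force oracle on 1000 random vectors", {
  set.seed(99)
  for (i in 1:1000) {
    d <- sample(3:40, 1)
    v <- round(rnorm(d), 3)  # rounding forces frequent exact ties
    L <- sample(1:12, 1)
    q <- quantize_vector(v, quantize_config(L = L))
    o <- brute_quantize(v, L, 100)
    expect_identical(q$term_id, o$term_id)
    expect_equal(q$weight, o$weight)
  }
})

test_that("increasing L preserves the entries selected at smaller L", {
  set.seed(5)
  for (i in 1:50) {
    v <- rnorm(20)
    prev <- quantize_vector(v, quantize_config(L = 3))
    for (L in 4:8) {
      cur <- quantize_vector(v, quantize_config(L = L))
      expect_true(all(prev$term_id %in% cur$term_id))
      prev <- cur
    }
  }
})

test_that("all emitted weights are strictly positive", {
  set.seed(8)
  be <- stub16()
  for (i in 1:25) {
    q <- quantize_vector(rnorm(16), quantize_config())
    expect_true(all(q$weight > 0))
  }
  b <- sentence_bow(c("alpha", "beta"), be)
  expect_true(all(b$weight > 0))
})

test_that("sentence_bow is additive over repeated tokens", {
  be <- stub16()
  single <- sentence_bow("wound", be)
  double <- sentence_bow(c("wound", "wound"), be)
  expect_identical(double$term_id, single$term_id)
  expect_equal(double$weight, 2 * single$weight)
  # single-token sentence equals the raw quantization
  q <- quantize_vector(embed_token(be, "wound"), quantize_config())
  expect_identical(single$term_id, q$term_id)
  expect_equal(single$weight, q$weight)
})

test_that("sentence_bow merges several tokens by summed term weight", {
  be <- stub16()
  cfg <- quantize_config(L = 3)
  toks <- c("fe", "ab", "zq")
  merged <- sentence_bow(toks, be, cfg)
  # brute-force merge of the three per-token quantizations
  acc <- list()
  for (tok in toks) {
    q <- quantize_vector(embed_token(be, tok), cfg)
    for (i in seq_along(q$term_id)) {
      k <- as.character(q$term_id[i])
      acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) + q$weight[i]
    }
  }
  ids <- sort(as.integer(names(acc)))
  expect_identical(merged$term_id, ids)
  expect_equal(merged$weight, unname(unlist(acc[as.character(ids)])))
})

test_that("pair corpus dictionary is the union of document terms", {
  be <- stub16()
  s1 <- tokenize("fever reported tonight")
  s2 <- tokenize("fever gone today")
  pc <- build_pair_corpus(s1, s2, be)
  used <- sort(unique(c(pc$corpus[[1]]$term_id, pc$corpus[[2]]$term_id)))
  expect_identical(used, seq_len(pc$dictionary$n_terms) - 1L)
  # identical sentences produce identical documents
  pc2 <- build_pair_corpus(s1, s1, be)
  expect_identical(pc2$corpus[[1]], pc2$corpus[[2]])
})

test_that("a lexicon augments the dictionary beyond the pair's own terms", {
  be <- make_hash_backend(300, 42)
  s1 <- tokenize("aa bb")
  s2 <- tokenize("aa cc")
  plain <- build_pair_corpus(s1, s2, be)
  aug <- build_pair_corpus(s1, s2, be, lexicon = c("rehabilitation", "infection"))
  expect_gte(aug$dictionary$n_terms, plain$dictionary$n_terms)
  # documents still only use their own terms
  used <- unique(c(aug$corpus[[1]]$term_id, aug$corpus[[2]]$term_id))
  expect_true(all(used < aug$dictionary$n_terms))
})

test_that("lexicon files are parsed with comments stripped", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "病院", "", "リハビリテーション  ", "fever # trailing"), path)
  expect_equal(read_lexicon(path), c("病院", "リハビリテーション", "fever"))
})
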