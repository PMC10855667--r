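# brute-force LCS: enumerate all subsequences of the shorter side
brute_lcs <- function(a, b) {
  best <- 0L
  n <- length(a)
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sub <- a[idx]
    # is sub a subsequence of b?
    j <- 1L
    for (x in b) {
      if (j <= length(sub) && identical(x, sub[j])) j <- j + 1L
    }
    if (j > length(sub)) best <- max(best, length(sub))
  }
  best
}

test_that("modified precision clips repeated n-grams", {
  expect_equal(modified_precision(c("the", "the", "the"), c("the", "cat"), 1), 1 / 3)
  expect_equal(modified_precision(c("a", "b"), c("a", "b"), 1), 1)
  expect_equal(modified_precision(c("a", "b"), c("a", "b"), 2), 1)
  expect_equal(modified_precision(c("a", "b"), c("c", "d"), 1), 0)
  # candidate shorter than n: 0 by convention
  expect_equal(modified_precision(c("a", "b"), c("a", "b"), 3), 0)
  expect_error(modified_precision(c("a"), c("a"), 0), class = "embedhdp_invalid_input")
})

test_that("bleu matches closed forms for identity and brevity", {
  s <- c("p", "q", "r", "s", "t")
  expect_equal(bleu(s, s), 1)
  # perfect overlap at n = 1..2 but half-length candidate: BP = exp(1 - 4/2)
  expect_equal(bleu(c("a", "b"), c("a", "b", "a", "b"), max_n = 2), exp(-1),
               tolerance = 1e-12)
  # longer candidate than reference: no brevity penalty applied
  expect_equal(bleu(c("a", "b", "c"), c("a", "b", "c"), max_n = 3), 1)
  expect_error(bleu(character(0), s), class = "embedhdp_invalid_input")
})

test_that("bleu with smoothing is monotone-bounded in [0, 1]", {
  set.seed(17)
  for (i in 1:20) {
    a <- strsplit(random_sentence(sample(2:10, 1), i), " ")[[1]]
    b <- strsplit(random_sentence(sample(2:10, 1), 50 + i), " ")[[1]]
    v <- bleu(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("rouge_n matches hand counts", {
  r <- rouge_n(c("a", "b", "c"), c("a", "c"), 1)
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 1)
  expect_equal(r$f, 0.8)
  ident <- rouge_n(c("x", "y"), c("x", "y"), 2)
  expect_equal(c(ident$precision, ident$recall, ident$f), c(1, 1, 1))
  disj <- rouge_n(c("a", "b"), c("c", "d"), 1)
  expect_equal(c(disj$precision, disj$recall, disj$f), c(0, 0, 0))
})

test_that("rouge_l matches hand DP and the F identity holds", {
  r <- rouge_l(c("a", "b", "c"), c("a", "c"))
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 1)
  expect_equal(r$f, 0.8)
  ident <- rouge_l(c("a", "b"), c("a", "b"))
  expect_equal(ident$f, 1)
  disj <- rouge_l(c("a", "b"), c("c", "d"))
  expect_equal(disj$f, 0)
})

test_that("LCS dynamic programme equals brute-force enumeration", {
  set.seed(9)
  pool <- lapply(1:8, function(i) {
    strsplit(random_sentence(sample(2:8, 1), 300 + i), " ")[[1]]
  })
  # add overlapping constructions so the LCS is non-trivial
  pool <- c(pool, list(c("a", "b", "c", "d"), c("a", "c", "d", "e"),
                       c("b", "b", "a", "c")))
  for (i in seq_along(pool)) {
    for (j in seq_along(pool)) {
      a <- pool[[i]]; b <- pool[[j]]
      dp <- rouge_l(a, b)$recall * length(b)  # recover lcs length
      expect_equal(dp, brute_lcs(a, b))
    }
  }
})

test_that("every precision_recall_f satisfies the F-measure identity", {
  set.seed(13)
  for (i in 1:25) {
    a <- strsplit(random_sentence(sample(2:8, 1), 400 + i), " ")[[1]]
    b <- strsplit(random_sentence(sample(2:8, 1), 500 + i), " ")[[1]]
    for (r in list(rouge_n(a, b, 1), rouge_n(a, b, 2), rouge_l(a, b))) {
      expected <- if (r$precision + r$recall > 0)
        2 * r$precision * r$recall / (r$precision + r$recall) else 0
      expect_equal(r$f, expected, tolerance = 1e-12)
    }
  }
})

test_that("bow_cosine matches hand values and ignores order", {
  expect_equal(bow_cosine(c("a", "b"), c("b", "c")), 0.5, tolerance = 1e-12)
  expect_equal(bow_cosine(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(bow_cosine(c("a", "b", "c"), c("c", "b", "a")), 1)
  expect_error(bow_cosine(character(0), "a"), class = "embedhdp_invalid_input")
})

test_that("the external-scorer adapter validates its output", {
  sc <- make_external_scorer(function(s1, s2) 0.5, name = "stub-bert")
  p <- pair_record("a", "b")
  expect_equal(sc(p, metric_config(), NULL), 0.5)
  bad <- make_external_scorer(function(s1, s2) NA_real_)
  expect_error(bad(p, metric_config(), NULL), class = "embedhdp_invalid_input")
})
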