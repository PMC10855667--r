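#' Comparator metrics
#'
#' From-scratch sentence-level implementations of the standard surface
#' metrics the topic-model score is benchmarked against: BLEU (clipped
#' n-gram precision with brevity penalty), ROUGE-N and ROUGE-L
#' (precision/recall/F over n-gram overlap and longest common subsequence),
#' and plain bag-of-words cosine. All operate on token vectors so they share
#' the tokenizer configuration with the main metric.
#'
#' @name comparator-metrics
NULL

as_tokens <- function(x, arg = "sentence") {
  toks <- if (inherits(x, "tokenized_sentence")) x$tokens else x
  if (!is.character(toks) || length(toks) == 0L || any(!nzchar(toks)))
    err_invalid_input(sprintf("%s must contain at least one non-empty token", arg))
  toks
}

ngrams_of <- function(tokens, n) {
  if (length(tokens) < n) return(character(0))
  starts <- seq_len(length(tokens) - n + 1L)
  # unit-separator join keeps ("ab","c") and ("a","bc") distinct n-grams
  vapply(starts, function(i) paste(tokens[i:(i + n - 1L)], collapse = "\u001f"), "")
}

clipped_overlap <- function(cand_grams, ref_grams) {
  if (length(cand_grams) == 0L || length(ref_grams) == 0L) return(0)
  ct <- table(cand_grams)
  rt <- table(ref_grams)
  shared <- intersect(names(ct), names(rt))
  sum(pmin(ct[shared], rt[shared]))
}

#' Modified (clipped) n-gram precision
#'
#' Each candidate n-gram is credited at most as many times as it occurs in
#' the reference. A candidate shorter than `n` tokens has precision 0 by
#' convention.
#'
#' @param cand,ref Token vectors (or [tokenize()]d sentences).
#' @param n N-gram order, integer >= 1.
#' @return Precision in `[0, 1]`.
#' @examples
#' modified_precision(c("the", "the", "the"), c("the", "cat"), 1)  # 1/3
#' @export
modified_precision <- function(cand, ref, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    err_invalid_input("`n` must be an integer >= 1")
  cand <- as_tokens(cand, "cand"); ref <- as_tokens(ref, "ref")
  cg <- ngrams_of(cand, n)
  if (length(cg) == 0L) return(0)
  clipped_overlap(cg, ngrams_of(ref, n)) / length(cg)
}

#' Sentence-level BLEU
#'
#' Geometric mean of modified precisions for orders `1..max_n`, times the
#' brevity penalty `BP = 1` if the candidate is longer than the reference,
#' else `exp(1 - r/c)`. Zero precisions — unavoidable for short care-record
#' sentences at higher orders — are floored at `epsilon` before the
#' geometric mean (floor smoothing), which keeps the score defined while
#' still heavily penalizing missing higher-order overlap.
#'
#' @param cand,ref Token vectors (or [tokenize()]d sentences).
#' @param max_n Highest n-gram order (default 4).
#' @param epsilon Smoothing floor for zero precisions (default 1e-9).
#' @return BLEU in `[0, 1]`.
#' @export
bleu <- function(cand, ref, max_n = 4L, epsilon = 1e-9) {
  cand <- as_tokens(cand, "cand"); ref <- as_tokens(ref, "ref")
  if (max_n < 1) err_invalid_input("`max_n` must be >= 1")
  prec <- vapply(seq_len(max_n), function(n) modified_precision(cand, ref, n), 0)
  prec <- pmax(prec, epsilon)
  bp <- if (length(cand) > length(ref)) 1 else exp(1 - length(ref) / length(cand))
  min(max(bp * exp(mean(log(prec))), 0), 1)
}

prf <- function(p, r, beta = 1) {
  f <- if (p + r > 0) (1 + beta^2) * p * r / (beta^2 * p + r) else 0
  structure(list(precision = p, recall = r, f = f, beta = beta),
            class = "precision_recall_f")
}

#' @export
print.precision_recall_f <- function(x, ...) {
  cat(sprintf("<P/R/F> P = %.4f, R = %.4f, F%s = %.4f\n",
              x$precision, x$recall,
              if (x$beta == 1) "1" else sprintf("(beta=%g)", x$beta), x$f))
  invisible(x)
}

#' ROUGE-N
#'
#' Clipped n-gram overlap: recall is overlap over reference n-gram count,
#' precision over candidate n-gram count, F the harmonic mean (`beta = 1`).
#'
#' @inheritParams modified_precision
#' @param beta F-measure beta (default 1).
#' @return A `precision_recall_f`.
#' @examples
#' rouge_n(c("a", "b", "c"), c("a", "c"), 1)  # P = 2/3, R = 1, F = 0.8
#' @export
rouge_n <- function(cand, ref, n, beta = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n))
    err_invalid_input("`n` must be an integer >= 1")
  cand <- as_tokens(cand, "cand"); ref <- as_tokens(ref, "ref")
  cg <- ngrams_of(cand, n); rg <- ngrams_of(ref, n)
  ov <- clipped_overlap(cg, rg)
  p <- if (length(cg)) ov / length(cg) else 0
  r <- if (length(rg)) ov / length(rg) else 0
  prf(p, r, beta)
}

# longest common subsequence length, O(|a||b|) dynamic programme
lcs_length <- function(a, b) {
  la <- length(a); lb <- length(b)
  prev <- integer(lb + 1L)
  for (i in seq_len(la)) {
    cur <- integer(lb + 1L)
    for (j in seq_len(lb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[lb + 1L]
}

#' ROUGE-L
#'
#' Longest-common-subsequence overlap: with LCS length `l`,
#' `P = l / |cand|`, `R = l / |ref|`, F the harmonic mean.
#'
#' @inheritParams rouge_n
#' @return A `precision_recall_f`.
#' @export
rouge_l <- function(cand, ref, beta = 1) {
  cand <- as_tokens(cand, "cand"); ref <- as_tokens(ref, "ref")
  l <- lcs_length(cand, ref)
  prf(l / length(cand), l / length(ref), beta)
}

#' Bag-of-words cosine similarity
#'
#' Cosine of the two term-frequency vectors over the union vocabulary.
#' Order-insensitive by construction: permuting a sentence leaves the score
#' unchanged.
#'
#' @param s1,s2 Token vectors (or [tokenize()]d sentences).
#' @return Similarity in `[0, 1]`.
#' @examples
#' bow_cosine(c("a", "b"), c("b", "c"))  # 0.5
#' @export
bow_cosine <- function(s1, s2) {
  a <- as_tokens(s1, "s1"); b <- as_tokens(s2, "s2")
  vocab <- unique(c(a, b))
  va <- tabulate(match(a, vocab), length(vocab))
  vb <- tabulate(match(b, vocab), length(vocab))
  min(max(cosine_sim(va, vb), 0), 1)
}

#' BERTScore adapter
#'
#' Contextual-embedding metrics require a pretrained model this package does
#' not ship; they participate in the benchmark panel through an adapter: any
#' function `(suggestion, ground_truth) -> numeric(1)` can be wrapped and
#' slotted into [run_benchmark()] like a built-in metric.
#'
#' @param fn Function of two character scalars returning one finite numeric.
#' @param name Metric name used in reports (default `"bertscore"`).
#' @return A scorer closure with signature `(pair, cfg, backend)`.
#' @export
make_external_scorer <- function(fn, name = "bertscore") {
  if (!is.function(fn)) err_config("`fn` must be a function")
  force(name)
  scorer <- function(pair, cfg, backend) {
    v <- fn(pair$suggestion, pair$ground_truth)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      err_invalid_input(sprintf("external scorer '%s' returned a non-finite value", name))
    v
  }
  attr(scorer, "metric_name") <- name
  scorer
}
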