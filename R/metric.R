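#' A suggestion / ground-truth sentence pair
#'
#' The unit of evaluation: a generated sentence suggestion, the sentence the
#' caregiver actually recorded, and optionally the per-rater human
#' similarity scores attached to the pair.
#'
#' @param suggestion,ground_truth Non-empty strings.
#' @param human_scores Optional numeric vector of finite rater scores.
#' @param id Identifier string.
#' @return A `pair_record`.
#' @export
pair_record <- function(suggestion, ground_truth, human_scores = NULL,
                        id = "") {
  if (!is.character(suggestion) || length(suggestion) != 1L ||
      !is.character(ground_truth) || length(ground_truth) != 1L)
    err_invalid_input("suggestion and ground_truth must be single strings")
  if (!is.null(human_scores)) {
    human_scores <- as.numeric(human_scores)
    if (length(human_scores) == 0L || any(!is.finite(human_scores)))
      err_invalid_input("human_scores must be finite when supplied")
  }
  structure(list(suggestion = suggestion, ground_truth = ground_truth,
                 human_scores = human_scores, id = as.character(id)),
            class = "pair_record")
}

#' Metric configuration
#'
#' Bundles every knob of the scoring pipeline: tokenizer mode and particle
#' handling, quantization, HDP hyperparameters, the sentence-length cap used
#' by [length_filter()] (default 13 tokens — the metric degrades on longer
#' sentences, so pairs with a longer side are excluded from evaluation), and
#' an optional domain lexicon that augments each pair's dictionary.
#'
#' @param quantize A [quantize_config()].
#' @param hdp An [hdp_params()].
#' @param tokenizer_mode `"whitespace"` or `"morphological"`.
#' @param attach_particles Merge bare particles into host words?
#' @param particles Particle list for the tokenizer.
#' @param segmenter Optional morphological analyzer adapter.
#' @param max_len Length-filter cap (tokens), >= 1.
#' @param lexicon Optional character vector of domain terms, or a file path
#'   understood by [read_lexicon()].
#' @return A `metric_config`.
#' @export
metric_config <- function(quantize = quantize_config(),
                          hdp = hdp_params(),
                          tokenizer_mode = c("whitespace", "morphological"),
                          attach_particles = TRUE,
                          particles = japanese_particles(),
                          segmenter = NULL,
                          max_len = 13L,
                          lexicon = NULL) {
  tokenizer_mode <- match.arg(tokenizer_mode)
  if (!is.numeric(max_len) || length(max_len) != 1L || max_len < 1)
    err_config("`max_len` must be >= 1")
  if (is.character(lexicon) && length(lexicon) == 1L && file.exists(lexicon))
    lexicon <- read_lexicon(lexicon)
  structure(list(quantize = quantize, hdp = hdp,
                 tokenizer_mode = tokenizer_mode,
                 attach_particles = attach_particles,
                 particles = particles, segmenter = segmenter,
                 max_len = as.integer(max_len), lexicon = lexicon),
            class = "metric_config")
}

config_digest <- function(cfg, backend = NULL) {
  flat <- c(cfg$tokenizer_mode, cfg$attach_particles, cfg$particles,
            cfg$max_len, cfg$lexicon,
            unlist(cfg$quantize), unlist(cfg$hdp),
            if (!is.null(backend)) backend$name)
  sprintf("%08x", str_hash(paste(flat, collapse = "")))
}

cfg_tokenize <- function(cfg, text) {
  tokenize(text, mode = cfg$tokenizer_mode,
           attach_particles = cfg$attach_particles,
           particles = cfg$particles, segmenter = cfg$segmenter)
}

#' Cosine similarity of two topic distributions
#'
#' Both arguments are non-negative unit-sum vectors of equal length, so the
#' value lies in `[0, 1]`; it is symmetric in its arguments.
#'
#' @param t1,t2 Topic-proportion vectors of equal length, neither all-zero.
#' @return Similarity in `[0, 1]`.
#' @examples
#' cosine_of_distributions(c(0.5, 0.5), c(1, 0))  # 1/sqrt(2)
#' @export
cosine_of_distributions <- function(t1, t2) {
  t1 <- as.numeric(t1); t2 <- as.numeric(t2)
  if (length(t1) != length(t2))
    err_invalid_input("topic distributions have different lengths")
  if (any(t1 < 0) || any(t2 < 0))
    err_invalid_input("topic distributions must be non-negative")
  min(max(cosine_sim(t1, t2), 0), 1)
}

#' EmbedHDP similarity score
#'
#' The full pipeline: tokenize both sentences, embed and quantize every
#' token into pseudo-bag-of-words documents, build the two-document corpus
#' and its dictionary (optionally lexicon-augmented), fit a fresh HDP on
#' exactly that corpus, infer both topic distributions, and return their
#' cosine. The model is refitted per pair — the corpus *is* the pair — so
#' scores are deterministic given the configuration, backend and seed.
#'
#' @param pair A [pair_record()].
#' @param cfg A [metric_config()].
#' @param backend An `embedding_backend`.
#' @return A `metric_score`: list with `value` in `[0, 1]`, `metric_name`,
#'   and `config_digest`.
#' @export
embedhdp_score <- function(pair, cfg = metric_config(), backend) {
  if (!inherits(pair, "pair_record"))
    err_invalid_input("`pair` must be a pair_record")
  s1 <- cfg_tokenize(cfg, pair$suggestion)
  s2 <- cfg_tokenize(cfg, pair$ground_truth)
  pc <- build_pair_corpus(s1, s2, backend, cfg$quantize, lexicon = cfg$lexicon)
  model <- fit_hdp(pc$dictionary, pc$corpus, cfg$hdp)
  t1 <- topic_distribution(model, pc$corpus[[1L]])
  t2 <- topic_distribution(model, pc$corpus[[2L]])
  structure(list(value = cosine_of_distributions(t1, t2),
                 metric_name = "embedhdp",
                 config_digest = config_digest(cfg, backend),
                 id = pair$id),
            class = "metric_score")
}

#' @export
print.metric_score <- function(x, ...) {
  cat(sprintf("<metric_score> %s = %.6f [config %s]\n",
              x$metric_name, x$value, x$config_digest))
  invisible(x)
}

#' Filter sentence pairs by length
#'
#' Partitions pairs into those where both sides have at most `cfg$max_len`
#' tokens (kept) and those where either side exceeds it (removed; both
#' sentences of such a pair are eliminated together). Order is preserved
#' within each part and the two parts partition the input exactly.
#'
#' @param pairs List of [pair_record()]s.
#' @param cfg A [metric_config()]; its tokenizer settings define what a
#'   "word" is and `max_len` the cap.
#' @return List with `kept` and `removed` (both lists of pair records) and
#'   integer counts `n_kept`, `n_removed`.
#' @export
length_filter <- function(pairs, cfg = metric_config()) {
  if (inherits(pairs, "pair_record")) pairs <- list(pairs)
  over <- vapply(pairs, function(p) {
    count_words(p$suggestion, cfg$tokenizer_mode, cfg$attach_particles,
                cfg$particles, cfg$segmenter) > cfg$max_len ||
      count_words(p$ground_truth, cfg$tokenizer_mode, cfg$attach_particles,
                  cfg$particles, cfg$segmenter) > cfg$max_len
  }, logical(1))
  list(kept = pairs[!over], removed = pairs[over],
       n_kept = sum(!over), n_removed = sum(over))
}
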