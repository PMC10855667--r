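#' Synthetic dataset parameters
#'
#' Controls the generator that emulates a caregiver-scored sentence-pair
#' dataset: pairs with a controllable latent overlap `theta`, lengths that
#' span the 13-token filter boundary, occasional domain-lexicon terms, and
#' noisy multi-rater scores on `[0, 1]`.
#'
#' Defaults mirror the study conditions the package is designed around:
#' 390 pairs scored by 3 raters, roughly 18% of pairs built to exceed the
#' 13-token cap (the share removed by the filter in the reference dataset,
#' 70 of 390), in-filter lengths of 4–13 tokens with over-limit pairs at
#' 14–20.
#'
#' @param n_pairs Number of pairs, >= 1.
#' @param vocab_size Size of the base vocabulary (split 60/40 into a
#'   ground-truth pool and a disjoint distractor pool so `theta = 0` means
#'   exactly zero shared tokens).
#' @param lexicon_terms Character vector of pseudo-clinical terms injected
#'   with probability `lexicon_prob` per sentence.
#' @param lexicon_prob Per-sentence lexicon injection probability.
#' @param length_range Integer `(min, max)` token counts for in-filter pairs.
#' @param over_length_range Token counts used for over-limit pairs.
#' @param frac_over_limit Share of pairs built to exceed 13 tokens.
#' @param rater_sd Gaussian rater noise SD on the `[0, 1]` score scale.
#' @param n_raters Raters per pair (default 3).
#' @param seed Master seed.
#' @return A `synth_params`.
#' @export
synth_params <- function(n_pairs = 390L, vocab_size = 200L,
                         lexicon_terms = default_lexicon_terms(),
                         lexicon_prob = 0.2,
                         length_range = c(4L, 13L),
                         over_length_range = c(14L, 20L),
                         frac_over_limit = 70 / 390,
                         rater_sd = 0.1, n_raters = 3L, seed = 1L) {
  if (n_pairs < 1) err_config("`n_pairs` must be >= 1")
  if (length(length_range) != 2L || length_range[1] < 1 ||
      length_range[2] < length_range[1])
    err_config("`length_range` must be (min, max) with 1 <= min <= max")
  if (frac_over_limit < 0 || frac_over_limit > 1)
    err_config("`frac_over_limit` must lie in [0, 1]")
  if (rater_sd < 0) err_config("`rater_sd` must be >= 0")
  if (n_raters < 1) err_config("`n_raters` must be >= 1")
  structure(list(n_pairs = as.integer(n_pairs),
                 vocab_size = as.integer(vocab_size),
                 lexicon_terms = lexicon_terms,
                 lexicon_prob = lexicon_prob,
                 length_range = as.integer(length_range),
                 over_length_range = as.integer(over_length_range),
                 frac_over_limit = frac_over_limit,
                 rater_sd = rater_sd, n_raters = as.integer(n_raters),
                 seed = as.integer(seed)),
            class = "synth_params")
}

# pseudo-clinical tokens standing in for a domain lexicon
default_lexicon_terms <- function() {
  c("fever", "nausea", "intake", "bp", "pulse", "lotion",
    "rehab", "anxiety", "infection", "hospital")
}

# deterministic pseudo-word pools; letter strings of length 3-6
synth_vocab <- function(params) {
  with_seed(params$seed + 104729L, {
    words <- unique(vapply(seq_len(params$vocab_size * 2L), function(i) {
      paste(sample(letters, sample(3:6, 1L), replace = TRUE), collapse = "")
    }, ""))
    words <- setdiff(words, params$lexicon_terms)[seq_len(params$vocab_size)]
    n_gt <- max(1L, floor(0.6 * params$vocab_size))
    list(gt_pool = words[seq_len(n_gt)],
         distractor_pool = words[(n_gt + 1L):params$vocab_size])
  })
}

#' Generate one synthetic sentence pair
#'
#' The ground truth draws `len` tokens from the ground-truth pool (with an
#' occasional lexicon term); the suggestion copies `ceiling(theta * len)`
#' ground-truth tokens in order — the kept positions are the first entries of
#' a per-pair random permutation, so higher `theta` keeps a superset of the
#' positions kept at lower `theta` — and replaces the rest with tokens from
#' the disjoint distractor pool. Each of `n_raters` scores is
#' `theta + Normal(0, rater_sd)` clamped to `[0, 1]`. Fully deterministic
#' given `(theta, params, seed)`.
#'
#' @param theta Latent overlap in `[0, 1]`.
#' @param params A [synth_params()].
#' @param seed Seed for this pair (defaults to `params$seed`).
#' @param over_limit Build the pair longer than 13 tokens on both sides?
#' @return List with `pair` (a [pair_record()]) and `theta`.
#' @export
generate_pair <- function(theta, params = synth_params(), seed = params$seed,
                          over_limit = FALSE) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 0 || theta > 1)
    err_invalid_input("`theta` must lie in [0, 1]")
  pools <- synth_vocab(params)
  with_seed(seed, {
    rng <- params$length_range
    if (over_limit) rng <- params$over_length_range
    len <- sample(rng[1]:rng[2], 1L)
    gt <- sample(pools$gt_pool, len, replace = TRUE)
    if (stats::runif(1) < params$lexicon_prob && length(params$lexicon_terms))
      gt[sample(len, 1L)] <- sample(params$lexicon_terms, 1L)
    keep_order <- sample(len)            # nested keep sets across theta
    n_keep <- ceiling(theta * len)
    keep <- sort(keep_order[seq_len(n_keep)])
    sug <- sample(pools$distractor_pool, len, replace = TRUE)
    sug[keep] <- gt[keep]
    scores <- pmin(pmax(theta + stats::rnorm(params$n_raters, 0, params$rater_sd), 0), 1)
    list(pair = pair_record(paste(sug, collapse = " "),
                            paste(gt, collapse = " "),
                            human_scores = scores),
         theta = theta)
  })
}

#' Generate a synthetic benchmark dataset
#'
#' Draws `theta` uniformly on `[0, 1]` for each pair and builds exactly
#' `round(frac_over_limit * n_pairs)` pairs whose sentences exceed 13
#' tokens (positions chosen at random), so the length-filter outcome is
#' known by construction. Whitespace tokenization applies: sentences are
#' space-joined token lists.
#'
#' @param params A [synth_params()].
#' @return A `synth_dataset`: list with `dataset` (same shape as
#'   [load_dataset()] output), `latent_theta`, `over_limit` (logical vector,
#'   the generator's own labels), and `params`.
#' @export
generate_dataset <- function(params = synth_params()) {
  n <- params$n_pairs
  meta <- with_seed(params$seed, {
    n_over <- round(params$frac_over_limit * n)
    list(theta = stats::runif(n),
         over = seq_len(n) %in% sample(n, n_over),
         seeds = sample.int(2147483646L, n))
  })
  records <- vector("list", n)
  for (i in seq_len(n)) {
    gp <- generate_pair(meta$theta[[i]], params, seed = meta$seeds[[i]],
                        over_limit = meta$over[[i]])
    gp$pair$id <- as.character(i)
    records[[i]] <- gp$pair
  }
  structure(list(dataset = structure(list(records = records,
                                          source = "synthetic", n = n),
                                     class = "dataset"),
                 latent_theta = meta$theta,
                 over_limit = meta$over,
                 params = params),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("<synth_dataset> ", x$dataset$n, " pair(s), ",
      sum(x$over_limit), " over the length limit, seed ", x$params$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write a dataset to benchmark CSV
#'
#' Emits the schema [load_dataset()] reads: `id`, `suggestion`,
#' `ground_truth`, `human_1..k`.
#'
#' @param ds A `dataset` or `synth_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  if (inherits(ds, "synth_dataset")) ds <- ds$dataset
  recs <- ds$records
  k <- max(vapply(recs, function(p) length(p$human_scores %||% numeric(0)), 0L))
  rows <- lapply(recs, function(p) {
    hs <- rep(NA_real_, k)
    if (!is.null(p$human_scores)) hs[seq_along(p$human_scores)] <- p$human_scores
    c(id = p$id, suggestion = p$suggestion, ground_truth = p$ground_truth,
      stats::setNames(as.character(hs), paste0("human_", seq_len(k))))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
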