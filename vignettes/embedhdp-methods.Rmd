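---
title: "EmbedHDP: topic-model scoring of care-record sentence suggestions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EmbedHDP: topic-model scoring of care-record sentence suggestions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embedhdp)
```

## The problem

Care-record applications can suggest a sentence to complete a caregiver's
free-text note. Whether a suggestion is *good* is a question about
informational similarity with the sentence the caregiver actually wrote (the
ground truth), and care-record Japanese makes that hard to judge with surface
metrics: sentences are short, often subject-less, grammatically non-standard,
and dense in clinical terms. Surface-overlap metrics (BLEU, ROUGE, bag-of-words
cosine) under-credit paraphrases such as 看護師/ナース (*nurse*), while generic
contextual-embedding metrics are not tuned to the domain.

EmbedHDP scores a suggestion/ground-truth pair by comparing what the two
sentences are *about*:

1. **Tokenize** both sentences, keeping Japanese particles attached to their
   host words (は, を, の, ... carry role information that would otherwise be
   lost as isolated one-character tokens).
2. **Embed** every token with a subword-capable embedding, so rare clinical
   terms still receive usable vectors.
3. **Quantize** each token vector into a pseudo-bag-of-words: the 10 largest
   non-negative components survive, each emitted as a (dimension index,
   100 × component) pair. Dimension indices act as pseudo-terms; the scaled
   components act as counts.
4. **Fit a hierarchical Dirichlet process** (HDP) topic model on the
   two-document corpus formed by the pair, with a dictionary covering the
   union of their pseudo-terms (optionally augmented by a domain lexicon).
5. **Score** the pair as the cosine of the two inferred topic distributions.
   Both distributions are non-negative and sum to one, so the score lies in
   [0, 1].

The HDP is chosen over a fixed-K topic model because the number of topics a
sentence pair needs is not knowable in advance; the HDP infers it.

## Why quantization looks the way it does

An HDP consumes (term id, count) documents, not dense vectors. Three design
points make the conversion sound:

* **Pseudo-terms are embedding dimensions.** The only reading under which
  "select the highest-frequency elements" and "multiply by 100" jointly make
  sense is that large embedding components play the role of frequent terms.
  Two sentences that excite the same embedding directions then share
  pseudo-terms, which is exactly the semantic-overlap signal wanted.
* **Negatives are clipped by default** (`negative_handling = "clip"`).
  Scaling alone cannot make a negative component positive, and a topic model
  cannot accept negative counts; clipping is the minimal intervention. An
  `"absolute"` mode is available for embeddings whose sign carries little
  meaning.
* **Weights stay fractional.** Rounding the ×100-scaled components to
  integers would destroy precisely the small components the scaling step
  exists to preserve; the inference accepts fractional counts without
  modification.

Ties between equal components break toward the lower dimension index, making
quantization fully deterministic.

## The inference engine

The fitting algorithm is batch mean-field variational inference for the
stick-breaking representation of the HDP, with a global truncation `T = 150`
and a per-document truncation `K = 15`. Truncations are properties of the
approximation, not of the model — for a two-document corpus whose dictionary
rarely exceeds a few dozen pseudo-terms they are never binding.
Concentrations default to `gamma = alpha = 1`; topic–term smoothing
`eta = 0.01` is deliberately small so topics can specialize sharply on the
few pseudo-terms of a single pair.

Per document, coordinate ascent alternates three updates: term-to-table
responsibilities (`zeta`), table-to-topic assignments (`phi`), and the
document stick proportions. Globally, each EM pass re-estimates topic–term
weights and the corpus-level sticks from the accumulated statistics.
`iterations` (default 100) caps the EM passes; fitting stops early once the
topic–term parameters are stationary (relative change below 1e-6).

Three numerical choices matter and were made deliberately:

* **Topic–term weights are term-anchored at initialization.** Every
  dictionary term starts with one preferred topic (cycling through topics
  when the dictionary outgrows the truncation), in the spirit of anchor-word
  initializations for topic models. For a pair corpus this is what makes the
  score graded rather than binary: a pseudo-term shared by both sentences is
  pulled toward the *same global topic* in both documents, so the two topic
  distributions overlap in proportion to the weight the sentences share.
  Without anchoring, coordinate ascent frequently settles in local optima
  where each document claims private topics even for shared terms, and
  moderately similar pairs score near 0.
* **Responsibilities are initialized randomly, not uniformly.** A uniform
  initialization is a symmetric fixed point of the mean-field updates: every
  table receives identical statistics, all terms collapse onto one topic, and
  every pair — however dissimilar — scores 1. The initialization noise is
  drawn from an RNG seeded by the document's own content (term ids and
  weights), so identical documents are initialized identically and the
  identity score of 1 is exact, while the caller's RNG stream is never
  touched.
* **Document responsibilities warm-start across EM passes.** Re-initializing
  them every pass wastes the local optimum found so far; carrying them
  forward converges to materially better optima (on synthetic data the
  correlation with the latent overlap roughly doubles).

Because every source of randomness is a function of `(corpus, params, seed)`,
refitting reproduces the model bit for bit, and the score is exactly
symmetric in the order of the two sentences (the batch updates treat
documents exchangeably).

A consequence worth knowing: for a *pair* corpus, the fitted topics tend to
be sharply specialized (near one topic per pseudo-term), so the score behaves
like a soft, topic-space version of weighted profile overlap — graded in
between the exact limits score(s, s) = 1 and score(disjoint) ≈ 0.

## Tokenization

The analyzer interface is pluggable: any function producing a surface-token
stream can be passed as `segmenter`. The built-in default splits on
whitespace and on Unicode script boundaries (kanji/hiragana/katakana/
latin/digit) — a coarse, dictionary-free approximation of wakati-style
segmentation that keeps the whole pipeline dependency-free. Input is NFKC
normalized first because care records mix full- and half-width characters.
Particle attachment is a post-pass: a token exactly matching the configured
particle list (は, へ, で, を, の, て, ます, し, あり, ある, する, なる —
user-extensible) merges into its predecessor. Lemmatization and stemming are
deliberately not performed. The 13-token length cap of `length_filter`
counts tokens under the active tokenizer configuration, since that is the
representation every downstream step sees.

## Embedding backends

Production use loads pretrained vectors (`make_vec_backend`, standard
word2vec/fastText text format; out-of-vocabulary tokens fall back to the
hash construction so scoring never fails). All tests and the benchmark run
on `make_hash_backend`: a token's vector is the normalized mean of seeded
pseudo-random unit vectors keyed by its character n-grams (n = 2..4 plus the
whole token), which reproduces the subword property that makes rare clinical
terms embeddable and gives orthographically similar tokens correlated
vectors. Its default dimension for benchmarking is 300, matching the
dimensionality of the production Japanese fastText model: much lower
dimensions (e.g. 16) make the clipped top-10 profiles of unrelated sentences
overlap in almost every dimension and compress the metric's dynamic range.

## The synthetic benchmark

`generate_dataset()` emulates the study conditions the package is designed
around: by default 390 pairs scored by 3 raters, with 70/390 of pairs built
to exceed the 13-token filter (so the filter yields a 320/70 split by
construction), in-filter lengths of 4–13 tokens, over-limit lengths of
14–20, occasional pseudo-clinical lexicon terms (probability 0.2 per
sentence), and rater noise of sd 0.1 on the [0, 1] score scale. Each pair
has a latent overlap `theta`: the suggestion copies `ceiling(theta * len)`
ground-truth tokens in order (nested keep-sets across `theta`, so overlap is
monotone) and fills the rest from a disjoint distractor pool; rater scores
are `theta` plus clamped Gaussian noise.

What passing the synthetic benchmark shows: every metric in the panel
recovers a *lexical* latent overlap under controlled noise, the filter
partitions exactly, and the harness plumbing is correct end to end. What it
does not show: performance on real Japanese care records, where similarity
is partly *semantic* (paraphrase, synonymy) rather than lexical — the
dimension on which the topic-model metric is designed to differ from surface
metrics. That comparison requires the caregiver-scored dataset and a
pretrained embedding model, neither of which ships with the package.

Problem sizes used by the shipped tests and the acceptance script — chosen
as comfortable desk-scale settings — are 200-pair benchmark datasets and a
reduced inference configuration (`T = 50`, `K = 10`, `iterations = 50`) that
probing showed gives the same qualitative behaviour as the defaults on
two-document corpora.

## Comparator metrics

Sentence-level BLEU uses clipped n-gram precisions for n = 1..4, the
standard brevity penalty, and floor smoothing (zero precisions are floored
at 1e-9): short care-record sentences routinely have no 3- or 4-gram
overlap, and an unsmoothed product would be identically zero. ROUGE-N and
ROUGE-L report precision, recall and F (beta = 1; the F-measure identity is
enforced by construction). Bag-of-words cosine operates on term-frequency
vectors over the union vocabulary and is order-insensitive by design.
BERTScore-style metrics join the panel through `make_external_scorer`, an
adapter for any user-supplied `(suggestion, ground_truth) -> score`
function; reimplementing a contextual-embedding metric is out of scope.

`pearson_r` (the benchmark's correlation; Spearman available via `method`)
delegates to `stats::cor` after enforcing the harness contract: at least
three observations and non-zero variance on both sides. A metric that
returns a constant has no defined correlation and is reported as such
rather than as a number; row-level scoring failures are excluded from that
metric's `n_used` and logged, so one bad pair cannot abort a panel.

## Degenerate inputs and failure modes

Empty or whitespace-only sentences are invalid inputs, never zero-token
successes. An all-zero embedding vector quantizes to an empty document;
emptiness is policed where it matters — a document with no pseudo-terms
raises a degenerate-document error from the corpus builder or the model,
with a distinct condition class (`embedhdp_invalid_input`,
`embedhdp_degenerate_document`, `embedhdp_dictionary_mismatch`,
`embedhdp_config_error`) so batch callers can triage. Every score is
stamped with a digest of the full configuration for provenance.

## Known limitations

* Long sentences (14+ tokens) dilute the two-document topic structure; the
  package follows the method's own practice of excluding them via
  `length_filter` rather than attempting to score them well.
* The built-in segmenter is a script-boundary heuristic, not a dictionary
  analyzer; token counts near the 13-token boundary can differ from those of
  a real morphological analyzer, which is why the analyzer is pluggable.
* Scores from pair-fitted topic models are not comparable across different
  configurations or backends — compare only scores sharing a config digest.
* With only two documents, the HDP's topic estimates are intentionally
  coarse; the metric is a ranking signal for benchmarking against human
  judgment, not a calibrated probability.
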