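#' Quantization configuration
#'
#' Controls how a dense embedding vector is quantized into a pseudo-bag-of-
#' words document. `L` caps the number of retained components per vector
#' (default 10 — short care-record sentences make a short fixed BoW length
#' adequate and comparable across sentences), `scale` multiplies retained
#' components (default 100, lifting the typically tiny embedding components
#' to count-like magnitudes so the topic model does not collapse all
#' documents onto one topic), and `negative_handling` says what to do with
#' negative components before selection: `"clip"` zeroes them (default, the
#' minimal change that guarantees positive weights) or `"absolute"` keeps
#' their magnitude.
#'
#' @param L Maximum entries per quantized vector, integer >= 1.
#' @param scale Positive multiplier applied to retained components.
#' @param negative_handling `"clip"` or `"absolute"`.
#' @return A `quantize_config`.
#' @export
quantize_config <- function(L = 10L, scale = 100,
                            negative_handling = c("clip", "absolute")) {
  negative_handling <- match.arg(negative_handling)
  if (!is.numeric(L) || length(L) != 1L || L < 1 || L != floor(L))
    err_config("`L` must be an integer >= 1")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    err_config("`scale` must be > 0")
  structure(list(L = as.integer(L), scale = as.numeric(scale),
                 negative_handling = negative_handling),
            class = "quantize_config")
}

#' Pseudo-bag-of-words document
#'
#' A sparse document whose "terms" are embedding-dimension indices (0-based)
#' and whose "counts" are scaled embedding components: the representation a
#' bag-of-words topic model can consume. Weights are strictly positive and
#' term ids unique.
#'
#' @param term_id Integer vector of 0-based term ids.
#' @param weight Numeric vector of strictly positive weights.
#' @return A `pseudo_bow`.
#' @export
pseudo_bow <- function(term_id = integer(0), weight = numeric(0)) {
  term_id <- as.integer(term_id)
  weight <- as.numeric(weight)
  if (length(term_id) != length(weight))
    err_invalid_input("term_id and weight lengths differ")
  if (anyDuplicated(term_id)) err_invalid_input("duplicate term ids in pseudo_bow")
  if (any(term_id < 0L)) err_invalid_input("term ids must be >= 0")
  if (any(weight <= 0)) err_invalid_input("pseudo_bow weights must be > 0")
  structure(list(term_id = term_id, weight = weight), class = "pseudo_bow")
}

#' @export
print.pseudo_bow <- function(x, ...) {
  cat("<pseudo_bow> ", length(x$term_id), " term(s)\n", sep = "")
  if (length(x$term_id))
    print(data.frame(term_id = x$term_id, weight = x$weight), row.names = FALSE)
  invisible(x)
}

#' Quantize one embedding vector into a pseudo-bag-of-words
#'
#' Negative components are clipped (or replaced by their absolute value),
#' the `L` largest remaining components are selected — ties broken toward
#' the lower dimension index — and each surviving strictly positive
#' component is emitted as `(dimension_index, scale * component)`. An
#' all-zero vector yields an empty document; emptiness is policed by the
#' corpus builder, not here.
#'
#' @param v Finite numeric vector.
#' @param cfg A [quantize_config()].
#' @return A [pseudo_bow()] with at most `cfg$L` entries.
#' @examples
#' quantize_vector(c(0.02, -0.5, 0.01), quantize_config(L = 2))
#' @export
quantize_vector <- function(v, cfg = quantize_config()) {
  if (!is.numeric(v) || any(!is.finite(v)))
    err_invalid_input("`v` must be a finite numeric vector")
  w <- if (cfg$negative_handling == "clip") pmax(v, 0) else abs(v)
  # stable selection of the L largest; ties go to the lower index
  ord <- order(w, decreasing = TRUE)  # radix sort: stable, preserves index order
  keep <- ord[seq_len(min(cfg$L, length(w)))]
  keep <- keep[w[keep] > 0]
  keep <- sort(keep)
  pseudo_bow(term_id = keep - 1L, weight = cfg$scale * w[keep])
}

#' Quantize a whole sentence
#'
#' Each token is embedded and quantized, and the per-token documents are
#' merged by summing weights of shared term ids. A repeated token therefore
#' contributes additively, as in an ordinary bag of words.
#'
#' @param tokens A [tokenize()]d sentence (or plain character vector).
#' @param backend An `embedding_backend`.
#' @param cfg A [quantize_config()].
#' @return A [pseudo_bow()].
#' @export
sentence_bow <- function(tokens, backend, cfg = quantize_config()) {
  toks <- if (inherits(tokens, "tokenized_sentence")) tokens$tokens else tokens
  if (!is.character(toks) || length(toks) == 0L)
    err_invalid_input("`tokens` must contain at least one token")
  acc <- new.env(parent = emptyenv())
  for (tok in toks) {
    q <- quantize_vector(embed_token(backend, tok), cfg)
    for (i in seq_along(q$term_id)) {
      key <- as.character(q$term_id[[i]])
      acc[[key]] <- (acc[[key]] %||% 0) + q$weight[[i]]
    }
  }
  ids <- sort(as.integer(ls(acc)))
  if (length(ids) == 0L)
    err_degenerate("every token quantized to an empty document")
  pseudo_bow(ids, vapply(as.character(ids), function(k) acc[[k]], 0))
}

#' Term dictionary
#'
#' Bijection between pseudo-terms (embedding-dimension indices) and
#' contiguous integer ids from 0, the id space the topic model works in.
#'
#' @param terms Integer vector of distinct pseudo-terms (dimension indices).
#' @return A `term_dictionary` with `term_of` (id -> term, 1-indexed by
#'   id + 1) and `n_terms`.
#' @export
term_dictionary <- function(terms) {
  terms <- as.integer(terms)
  if (anyDuplicated(terms)) err_invalid_input("dictionary terms must be distinct")
  structure(list(term_of = terms, n_terms = length(terms)),
            class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat("<term_dictionary> ", x$n_terms, " term(s)\n", sep = "")
  invisible(x)
}

dict_id_of <- function(dict, terms) {
  idx <- match(as.integer(terms), dict$term_of)
  if (anyNA(idx)) err_dictionary("term not present in dictionary")
  idx - 1L
}

#' Build the two-document pair corpus
#'
#' Quantizes both sentences, forms the dictionary from the union of their
#' pseudo-terms (ascending term order, ids contiguous from 0), and re-expresses
#' each document in dictionary-id space. Document order is
#' `[suggestion, ground_truth]`. When a domain lexicon is supplied, each
#' lexicon token is embedded and quantized and its pseudo-terms are added to
#' the dictionary as well, seeding the model's term space with
#' domain-relevant directions even when the pair itself misses them.
#'
#' @param s1,s2 Tokenized suggestion and ground-truth sentences (or character
#'   vectors of tokens).
#' @param backend An `embedding_backend`.
#' @param cfg A [quantize_config()].
#' @param lexicon Optional character vector of domain terms (see
#'   [read_lexicon()]).
#' @return List with `dictionary` (a [term_dictionary()]) and `corpus`
#'   (list of two [pseudo_bow()] documents in dictionary-id space).
#' @export
build_pair_corpus <- function(s1, s2, backend, cfg = quantize_config(),
                              lexicon = NULL) {
  b1 <- sentence_bow(s1, backend, cfg)
  b2 <- sentence_bow(s2, backend, cfg)
  terms <- sort(unique(c(b1$term_id, b2$term_id)))
  if (!is.null(lexicon) && length(lexicon)) {
    lex_terms <- unlist(lapply(lexicon, function(tok) {
      quantize_vector(embed_token(backend, tok), cfg)$term_id
    }))
    terms <- sort(unique(c(terms, lex_terms)))
  }
  dict <- term_dictionary(terms)
  remap <- function(b) {
    ids <- dict_id_of(dict, b$term_id)
    o <- order(ids)
    pseudo_bow(ids[o], b$weight[o])
  }
  list(dictionary = dict, corpus = list(remap(b1), remap(b2)))
}

#' Read a domain lexicon file
#'
#' One term per line, UTF-8; blank lines and `#` comments are ignored.
#'
#' @param path Path to the lexicon file.
#' @return Character vector of terms.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) err_config(sprintf("lexicon file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- stringi::stri_trim_both(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}
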