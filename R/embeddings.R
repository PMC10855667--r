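#' Embedding backends
#'
#' A backend maps a token to a dense vector of fixed dimension `dim`,
#' deterministically: the same token always yields the identical vector.
#' Two constructors are provided:
#' \itemize{
#'   \item [make_hash_backend()] — a seeded character n-gram backend that
#'     needs no model file; orthographically similar tokens get correlated
#'     vectors, mimicking the subword property that makes rare clinical
#'     terms embeddable.
#'   \item [make_vec_backend()] — loads pretrained vectors from the standard
#'     word2vec/fastText text format (`.vec`), with an n-gram fallback for
#'     out-of-vocabulary tokens so embedding never fails.
#' }
#' Downstream code only ever touches `backend$dim` and [embed_token()], so
#' backends are interchangeable.
#'
#' @name embedding-backends
NULL

#' Embed a single token
#'
#' @param backend An `embedding_backend`.
#' @param token Single non-empty string.
#' @return Numeric vector of length `backend$dim`, all entries finite.
#'   Never fails for out-of-vocabulary tokens.
#' @export
embed_token <- function(backend, token) {
  if (!inherits(backend, "embedding_backend"))
    err_config("`backend` is not an embedding_backend")
  if (!is.character(token) || length(token) != 1L || is.na(token) || !nzchar(token))
    err_invalid_input("`token` must be a single non-empty string")
  v <- backend$embed(token)
  if (length(v) != backend$dim || any(!is.finite(v)))
    err_config(sprintf("backend '%s' returned an invalid vector for token '%s'",
                       backend$name, token))
  v
}

#' Seeded hash-based embedding backend
#'
#' The vector of a token is the L2-normalized mean of pseudo-random unit
#' vectors keyed by the token's character n-grams (n = 2..4 plus the whole
#' token). Each n-gram's unit vector is drawn from an RNG seeded by a hash of
#' the n-gram and the backend seed, so vectors are byte-identical across
#' processes, and tokens sharing n-grams get correlated vectors.
#'
#' @param dim Embedding dimension, integer >= 2.
#' @param seed Integer seed.
#' @return An `embedding_backend`.
#' @examples
#' be <- make_hash_backend(dim = 16, seed = 7)
#' v <- embed_token(be, "nausea")
#' sqrt(sum(v^2))  # 1
#' @export
make_hash_backend <- function(dim, seed = 1L) {
  if (!is.numeric(dim) || length(dim) != 1L || dim < 2 || dim != floor(dim))
    err_config("`dim` must be an integer >= 2")
  dim <- as.integer(dim)
  seed <- as.integer(seed)
  cache <- new.env(parent = emptyenv())

  gram_vec <- function(gram) {
    h <- (str_hash(gram) + seed * 7919L) %% 2147483646L
    with_seed(h, {
      u <- stats::rnorm(dim)
      u / sqrt(sum(u^2))
    })
  }

  embed <- function(token) {
    key <- paste0("t:", token)
    if (!is.null(cache[[key]])) return(cache[[key]])
    grams <- token_ngrams(token)
    m <- rowMeans(vapply(grams, gram_vec, numeric(dim)))
    nrm <- sqrt(sum(m^2))
    v <- if (nrm > 0) m / nrm else gram_vec(token)
    cache[[key]] <- v
    v
  }

  structure(list(name = sprintf("hash-%d-%d", dim, seed),
                 dim = dim, seed = seed, embed = embed),
            class = "embedding_backend")
}

# character n-grams, n = 2..4, plus the whole token
token_ngrams <- function(token) {
  n_ch <- stringi::stri_length(token)
  grams <- token
  for (n in 2:4) {
    if (n_ch >= n) {
      starts <- seq_len(n_ch - n + 1L)
      grams <- c(grams, stringi::stri_sub(token, starts, length = n))
    }
  }
  unique(grams)
}

#' Pretrained word-vector backend (text format)
#'
#' Reads the standard word2vec/fastText text format: an optional
#' `"<n_words> <dim>"` header line, then one `word v1 v2 ... vd` row per
#' line. Vectors are served verbatim for in-vocabulary tokens; out-of-
#' vocabulary tokens fall back to the hash n-gram construction of
#' [make_hash_backend()] in the same dimension, so scoring never fails on
#' unseen clinical terms.
#'
#' @param path Path to a UTF-8 `.vec` file.
#' @param max_words Optional cap on rows read (the full Japanese common-crawl
#'   model is multi-gigabyte; loading a frequency-sorted prefix is standard).
#' @param fallback_seed Seed for the OOV fallback.
#' @return An `embedding_backend`.
#' @export
make_vec_backend <- function(path, max_words = Inf, fallback_seed = 1L) {
  if (!file.exists(path)) err_config(sprintf("vector file not found: %s", path))
  lines <- readLines(path, n = if (is.finite(max_words)) max_words + 1L else -1L,
                     encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) err_config("empty vector file")
  first <- strsplit(lines[[1L]], " ", fixed = TRUE)[[1L]]
  has_header <- length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first)))
  if (has_header) lines <- lines[-1L]
  if (is.finite(max_words) && length(lines) > max_words)
    lines <- lines[seq_len(max_words)]
  parts <- strsplit(lines, " ", fixed = TRUE)
  words <- vapply(parts, `[[`, "", 1L)
  dim <- length(parts[[1L]]) - 1L
  if (dim < 2L) err_config("vector file has dimension < 2")
  tab <- new.env(parent = emptyenv())
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]][-1L]))
    if (length(v) == dim && !anyNA(v)) assign(words[[i]], v, envir = tab)
  }
  oov <- make_hash_backend(dim, fallback_seed)
  embed <- function(token) {
    hit <- get0(token, envir = tab, inherits = FALSE)
    if (!is.null(hit)) hit else oov$embed(token)
  }
  structure(list(name = sprintf("vec:%s", basename(path)),
                 dim = dim, embed = embed),
            class = "embedding_backend")
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat("<embedding_backend> ", x$name, " (dim = ", x$dim, ")\n", sep = "")
  invisible(x)
}
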