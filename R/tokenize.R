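#' Default Japanese particle list
#'
#' Short grammatical markers (particles and light verbs) that are merged into
#' their host word when `attach_particles = TRUE`: \code{wa, e, de, wo, no, te,
#' masu, shi, ari, aru, suru, naru}. The list is user-extensible: pass a
#' modified vector to [tokenize()] or [count_words()].
#'
#' @return Character vector of particle surface forms.
#' @export
japanese_particles <- function() {
  c("は", "へ", "で", "を", "の", "て",
    "ます", "し", "あり", "ある",
    "する", "なる")
}

#' Tokenize a sentence
#'
#' Splits a raw sentence into surface tokens. Input is NFKC-normalized first
#' (mixed-width Japanese input is common in care records). Two modes:
#' \describe{
#'   \item{whitespace}{split on runs of whitespace; joining the tokens with
#'     single spaces reproduces the normalized input.}
#'   \item{morphological}{segment via a pluggable analyzer adapter. If no
#'     `segmenter` is supplied, a built-in heuristic segmenter is used that
#'     splits on whitespace and on script boundaries (kanji / hiragana /
#'     katakana / latin / digit), a coarse stand-in for wakati-style
#'     morphological segmentation.}
#' }
#' With `attach_particles = TRUE`, any emitted token that is exactly a
#' configured particle is merged into the preceding token (or the following
#' token when the sentence starts with one), so no bare particle survives.
#' Lemmatization and stemming are deliberately not performed.
#'
#' @param text Single non-empty string (UTF-8).
#' @param mode `"whitespace"` or `"morphological"`.
#' @param attach_particles Merge bare particle tokens into their host word?
#' @param particles Character vector of particle surface forms
#'   (default [japanese_particles()]).
#' @param segmenter Optional function `character(1) -> character()` used as
#'   the morphological analyzer adapter; must return surface tokens in order.
#' @return A `tokenized_sentence`: list with `tokens` (character vector) and
#'   `n_tokens` (integer).
#' @examples
#' tokenize("report making a corset")$tokens
#' tokenize("りんご を たべます",
#'          mode = "morphological")$tokens  # "ringo wo tabemasu" -> 2 tokens
#' @export
tokenize <- function(text,
                     mode = c("whitespace", "morphological"),
                     attach_particles = TRUE,
                     particles = japanese_particles(),
                     segmenter = NULL) {
  mode <- match.arg(mode)
  if (!is.character(text) || length(text) != 1L || is.na(text))
    err_invalid_input("`text` must be a single string")
  norm <- stringi::stri_trans_nfkc(text)
  norm <- stringi::stri_trim_both(norm)
  if (!nzchar(norm))
    err_invalid_input("cannot tokenize an empty or whitespace-only sentence")

  toks <- if (mode == "whitespace") {
    stringi::stri_split_regex(norm, "\\s+")[[1L]]
  } else {
    seg <- segmenter %||% script_segmenter
    out <- seg(norm)
    if (!is.character(out) || length(out) == 0L || any(!nzchar(out)))
      err_invalid_input("segmenter returned no usable tokens")
    if (attach_particles) out <- merge_particles(out, particles)
    out
  }
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L)
    err_invalid_input("tokenization produced no tokens")
  structure(list(tokens = toks, n_tokens = length(toks)),
            class = "tokenized_sentence")
}

#' Count the tokens of a sentence
#'
#' `count_words(x, ...)` equals `tokenize(x, ...)$n_tokens` under the same
#' configuration; it is the quantity the 13-token length filter inspects.
#'
#' @inheritParams tokenize
#' @return Integer token count (>= 1).
#' @export
count_words <- function(text,
                        mode = c("whitespace", "morphological"),
                        attach_particles = TRUE,
                        particles = japanese_particles(),
                        segmenter = NULL) {
  tokenize(text, mode, attach_particles, particles, segmenter)$n_tokens
}

#' @export
print.tokenized_sentence <- function(x, ...) {
  cat("<tokenized_sentence> ", x$n_tokens, " token(s): ",
      paste(x$tokens, collapse = " | "), "\n", sep = "")
  invisible(x)
}

# Heuristic wakati-style segmenter: split on whitespace, then split each chunk
# wherever the Unicode script class changes. Kanji->hiragana transitions
# approximate stem/okurigana boundaries; it is a coarse heuristic, not a
# dictionary-based analyzer, and exists so the pipeline runs with no external
# morphological analyzer. Any real analyzer can be plugged in via `segmenter`.
script_segmenter <- function(text) {
  chunks <- stringi::stri_split_regex(text, "\\s+")[[1L]]
  chunks <- chunks[nzchar(chunks)]
  unlist(lapply(chunks, function(chunk) {
    chars <- stringi::stri_sub(chunk, seq_len(stringi::stri_length(chunk)), length = 1L)
    cls <- char_script_class(chars)
    breaks <- c(TRUE, cls[-1L] != cls[-length(cls)])
    unname(vapply(split(chars, cumsum(breaks)), paste, "", collapse = ""))
  }), use.names = FALSE)
}

char_script_class <- function(chars) {
  cls <- rep("other", length(chars))
  cls[stringi::stri_detect_regex(chars, "\\p{Han}")] <- "han"
  cls[stringi::stri_detect_regex(chars, "\\p{Hiragana}")] <- "hira"
  # prolonged sound mark belongs with katakana words
  cls[stringi::stri_detect_regex(chars, "[\\p{Katakana}ー]")] <- "kata"
  cls[stringi::stri_detect_regex(chars, "[A-Za-z]")] <- "latin"
  cls[stringi::stri_detect_regex(chars, "[0-9]")] <- "digit"
  cls
}

# Post-pass over analyzer output: a token that is exactly a configured
# particle is glued onto its predecessor; leading particles glue forward.
# Character content is conserved.
merge_particles <- function(tokens, particles) {
  out <- character(0)
  pending <- ""   # leading particles with no host yet
  for (tok in tokens) {
    if (tok %in% particles) {
      if (length(out) == 0L) pending <- paste0(pending, tok)
      else out[length(out)] <- paste0(out[length(out)], tok)
    } else {
      out <- c(out, paste0(pending, tok))
      pending <- ""
    }
  }
  if (nzchar(pending)) out <- c(out, pending)  # sentence was all particles
  out
}
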