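#' Normalize free text into stemmed tokens
#'
#' Applies the preprocessing pipeline used by both classifiers: lowercasing,
#' tokenization on runs of Unicode letters/digits, stop-word removal, and
#' Porter stemming. Token order is preserved so that entry-term phrases can
#' later be matched as contiguous token subsequences.
#'
#' Single-character and purely numeric tokens are kept: the method defines
#' no such filters and silently adding them would change term statistics.
#'
#' @param text a character scalar (may be empty or `NA`).
#' @param stopwords character vector of words to drop. The filter is applied
#'   both before and after stemming (a word such as "canning" stems to the
#'   stop word "can"), which makes the pipeline idempotent on its own
#'   output. Defaults to [default_stopwords()].
#' @return character vector of stemmed tokens in source order (possibly
#'   empty).
#' @examples
#' preprocess_text("Body mass index and waist circumference")
#' @export
preprocess_text <- function(text, stopwords = default_stopwords()) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(character(0))
  text <- tolower(text)
  toks <- regmatches(text, gregexpr("[\\p{L}\\p{N}]+", text, perl = TRUE))[[1L]]
  toks <- toks[!(toks %in% stopwords)]
  if (length(toks) == 0L) return(character(0))
  toks <- porter_stem(toks)
  toks[!(toks %in% stopwords)]
}

#' Tokenize a corpus into title and abstract token streams
#'
#' @param corpus a corpus data frame as returned by [read_corpus()] or
#'   [generate_corpus()].
#' @param stopwords stop-word list passed to [preprocess_text()].
#' @return a list of tokenized documents; each element has `doc_id`,
#'   `title_tokens` and `abstract_tokens`.
#' @export
tokenize_corpus <- function(corpus, stopwords = default_stopwords()) {
  out <- lapply(seq_len(nrow(corpus)), function(i) {
    list(
      doc_id = corpus$doc_id[i],
      title_tokens = preprocess_text(corpus$title[i], stopwords),
      abstract_tokens = preprocess_text(corpus$abstract[i], stopwords)
    )
  })
  names(out) <- corpus$doc_id
  out
}
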