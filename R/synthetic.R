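#' Configuration of the synthetic corpus generator
#'
#' The generator emulates the statistical structure of annotated citation
#' collections: documents made of a short title and a longer abstract,
#' each annotated with several descriptors, where a descriptor's presence
#' shifts the document's word distribution toward its signal terms. The
#' defaults describe the study conditions used throughout the package's
#' end-to-end checks: 2000 documents, 50 labels, a mean of 5 labels per
#' document and a signal strength of 0.8.
#'
#' @param n_docs number of documents.
#' @param n_labels number of descriptors.
#' @param vocab_size vocabulary size (must be at least
#'   `n_labels * signal_terms_per_label`).
#' @param labels_per_doc mean of the (min-1-truncated) Poisson number of
#'   labels per document.
#' @param signal_terms_per_label signal terms planted per label (disjoint
#'   across labels).
#' @param signal_strength probability that a token is drawn from an
#'   assigned label's signal distribution rather than the background.
#' @param title_len,abstract_len token counts of title and abstract.
#' @param entry_terms_per_label entry terms per descriptor (drawn from its
#'   signal terms; the preferred term is a two-token signal phrase).
#' @param background `"zipf"` (rank^-exponent frequency skew, emulating
#'   natural-language word frequencies) or `"uniform"`.
#' @param zipf_exponent exponent of the Zipf-like background (default 1.1).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_docs = 2000, n_labels = 50, vocab_size = 2000,
                             labels_per_doc = 5, signal_terms_per_label = 10,
                             signal_strength = 0.8, title_len = 10,
                             abstract_len = 100, entry_terms_per_label = 3,
                             background = c("zipf", "uniform"),
                             zipf_exponent = 1.1, seed = 1L) {
  background <- match.arg(background)
  cfg <- list(n_docs = as.integer(n_docs), n_labels = as.integer(n_labels),
              vocab_size = as.integer(vocab_size),
              labels_per_doc = labels_per_doc,
              signal_terms_per_label = as.integer(signal_terms_per_label),
              signal_strength = signal_strength,
              title_len = as.integer(title_len),
              abstract_len = as.integer(abstract_len),
              entry_terms_per_label = as.integer(entry_terms_per_label),
              background = background, zipf_exponent = zipf_exponent,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_docs >= 1, n_labels >= 1, vocab_size >= 1,
              labels_per_doc >= 1, signal_terms_per_label >= 1,
              signal_strength >= 0, signal_strength <= 1,
              title_len >= 1, abstract_len >= 1, entry_terms_per_label >= 1)
  })
  if (cfg$vocab_size < cfg$n_labels * cfg$signal_terms_per_label) {
    stop("vocab_size must be at least n_labels * signal_terms_per_label",
         call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic annotated corpus with planted label-term signal
#'
#' Each document samples a label set of truncated-Poisson size, then emits
#' tokens from a mixture: with probability `signal_strength` a token comes
#' from a uniformly chosen assigned label's signal-term distribution,
#' otherwise from the Zipf-skewed background over the whole vocabulary.
#' Tokens are emitted as pre-stemmed synthetic strings (`"t0001"` ...), so
#' the stemmer is a no-op on them. Each label's entry terms are drawn from
#' its signal terms, which makes the title/entry-term features and the
#' term-concept association statistics exercisable end to end.
#'
#' @param config a [generator_config()].
#' @return list with `corpus` (annotated corpus tibble), `thesaurus` (a
#'   `thesaurus` object) and `truth` (tibble: `label`, list-column
#'   `signal_terms`).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  vocab <- sprintf("t%04d", seq_len(config$vocab_size))
  labels <- sprintf("L%03d", seq_len(config$n_labels))
  signal <- split(vocab[seq_len(config$n_labels * config$signal_terms_per_label)],
                  rep(seq_len(config$n_labels),
                      each = config$signal_terms_per_label))
  names(signal) <- labels

  bg_weights <- if (config$background == "zipf") {
    seq_len(config$vocab_size)^(-config$zipf_exponent)
  } else {
    rep(1, config$vocab_size)
  }
  bg_weights <- bg_weights / sum(bg_weights)

  # thesaurus: preferred term is a two-token signal phrase, remaining entry
  # terms single signal tokens
  preferred <- vapply(signal, function(s) {
    paste(s[seq_len(min(2L, length(s)))], collapse = " ")
  }, character(1))
  entries <- lapply(seq_along(labels), function(i) {
    s <- signal[[i]]
    extra <- s[seq_len(min(config$entry_terms_per_label - 1L, length(s)))]
    unique(c(preferred[i], extra))
  })
  thesaurus <- new_thesaurus(labels, unname(preferred), entries)

  emit <- function(doc_labels, n_tokens) {
    is_sig <- stats::runif(n_tokens) < config$signal_strength
    out <- character(n_tokens)
    n_bg <- sum(!is_sig)
    if (n_bg > 0L) {
      out[!is_sig] <- sample(vocab, n_bg, replace = TRUE, prob = bg_weights)
    }
    n_sig <- sum(is_sig)
    if (n_sig > 0L) {
      labs <- doc_labels[sample.int(length(doc_labels), n_sig, replace = TRUE)]
      out[is_sig] <- vapply(labs, function(l) {
        s <- signal[[l]]
        s[sample.int(length(s), 1L)]
      }, character(1))
    }
    out
  }

  docs <- lapply(seq_len(config$n_docs), function(i) {
    n_lab <- min(config$n_labels, max(1L, stats::rpois(1L, config$labels_per_doc)))
    doc_labels <- sort(sample(labels, n_lab))
    list(doc_id = sprintf("d%05d", i),
         title = paste(emit(doc_labels, config$title_len), collapse = " "),
         abstract = paste(emit(doc_labels, config$abstract_len), collapse = " "),
         labels = doc_labels)
  })

  corpus <- tibble::tibble(
    doc_id = vapply(docs, `[[`, character(1), "doc_id"),
    title = vapply(docs, `[[`, character(1), "title"),
    abstract = vapply(docs, `[[`, character(1), "abstract"),
    labels = lapply(docs, `[[`, "labels"))
  truth <- tibble::tibble(label = labels, signal_terms = unname(signal))
  list(corpus = corpus, thesaurus = thesaurus, truth = truth)
}

#' Split a corpus into training and test sets
#'
#' Seeded shuffle split: the two parts are disjoint and exhaustive.
#'
#' @param corpus corpus data frame.
#' @param train_frac fraction of documents in the training part (0-1,
#'   exclusive).
#' @param seed integer seed.
#' @return list with `train` and `test` corpus tibbles.
#' @export
split_corpus <- function(corpus, train_frac = 0.5, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  set.seed(seed)
  n <- nrow(corpus)
  idx <- sample.int(n)
  n_train <- floor(n * train_frac)
  list(train = corpus[sort(idx[seq_len(n_train)]), ],
       test = corpus[sort(idx[-seq_len(n_train)]), ])
}
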