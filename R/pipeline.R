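#' Train the full kNN-based multi-label classifier
#'
#' Convenience wrapper wiring the pipeline stages: builds the TF.IDF index
#' over the annotated training corpus, constructs the label training set by
#' leave-one-out neighbour retrieval, and fits the relevance-scoring
#' classifier.
#'
#' @param train_corpus annotated corpus data frame.
#' @param thesaurus a `thesaurus` object.
#' @param k neighbour count (default 25).
#' @param algorithm ranker algorithm, see [train_ranker()].
#' @param seed integer seed for the classifier.
#' @param n_bins discretization bins.
#' @param stopwords stop-word list.
#' @return a `knn_classifier`: list bundling `index`, `model`, `thesaurus`,
#'   precomputed matching patterns, `k` and `seed`.
#' @export
train_classifier <- function(train_corpus, thesaurus, k = 25,
                             algorithm = "rf", seed = 1L, n_bins = 10,
                             stopwords = default_stopwords()) {
  tokens <- tokenize_corpus(train_corpus, stopwords)
  index <- build_index(train_corpus, stopwords, tokens = tokens)
  instances <- build_training_set(train_corpus, index, thesaurus, k = k,
                                  stopwords = stopwords, tokens = tokens)
  model <- train_ranker(instances, algorithm = algorithm, seed = seed,
                        n_bins = n_bins)
  structure(
    list(index = index, model = model, thesaurus = thesaurus,
         patterns = .label_patterns(thesaurus, stopwords), k = as.integer(k),
         algorithm = algorithm, seed = as.integer(seed),
         stopwords = stopwords),
    class = "knn_classifier")
}

#' @export
print.knn_classifier <- function(x, ...) {
  cat("<knn_classifier> k =", x$k, "| algorithm =", x$algorithm,
      "| indexed docs =", x$index$n, "\n")
  invisible(x)
}

#' Classify documents with a trained kNN classifier
#'
#' For each document: retrieve its k nearest neighbours from the training
#' index (a document whose id is present in the index is excluded from its
#' own neighbour set), collect candidate labels, score them with the
#' ranker, and select the final set with the chosen strategy.
#'
#' @param classifier a `knn_classifier` from [train_classifier()].
#' @param docs corpus data frame of documents to classify (labels, if any,
#'   are ignored).
#' @param params a [selection_params()] object.
#' @return tibble with columns `doc_id`, `ranked` (list of tibbles
#'   `label_id`/`score`) and `selected` (list of character vectors; empty
#'   when a document has no neighbour).
#' @export
classify_corpus <- function(classifier, docs, params = selection_params()) {
  tokens <- tokenize_corpus(docs, classifier$stopwords)
  nbrs <- .retrieve_neighbors_batch(classifier$index, tokens,
                                    k = classifier$k, exclude_self = TRUE)
  feats_list <- lapply(seq_len(nrow(docs)), function(i) {
    .candidate_features(tokens[[i]], nbrs[[i]], classifier$index,
                        classifier$patterns, classifier$k,
                        classifier$stopwords)
  })
  n_cand <- vapply(feats_list, nrow, integer(1))
  ranked <- rep(list(tibble::tibble(label_id = character(0),
                                    score = numeric(0))), nrow(docs))
  selected <- rep(list(character(0)), nrow(docs))
  nonempty <- which(n_cand > 0L)
  if (length(nonempty)) {
    # score all candidate rows of all documents in one model call
    all_feats <- do.call(rbind, feats_list[nonempty])
    disc <- discretize_features(all_feats, n_bins = classifier$model$n_bins,
                                edges = classifier$model$edges)
    dat <- as.data.frame(disc$instances[, c("f1", "f2", "f3", "f4", "f5", "f6")])
    scores <- .model_scores(classifier$model, dat)
    grp <- rep(nonempty, n_cand[nonempty])
    for (i in nonempty) {
      feats <- feats_list[[i]]
      sc <- scores[grp == i]
      ord <- order(-sc, -feats$f2, feats$label_id)
      pred <- tibble::tibble(label_id = feats$label_id[ord], score = sc[ord])
      class(pred) <- c("ranked_prediction", class(pred))
      ranked[[i]] <- tibble::tibble(label_id = pred$label_id,
                                    score = pred$score)
      selected[[i]] <- select_labels(pred, params, neighbours = nbrs[[i]],
                                     index = classifier$index)
    }
  }
  tibble::tibble(doc_id = docs$doc_id, ranked = ranked, selected = selected)
}

#' Uniform-random label predictions with matched set sizes
#'
#' Baseline predictor: for each document, draws its labels uniformly at
#' random (without replacement) from the label universe, using a given
#' per-document set size. Used to quantify how much of a classifier's
#' performance is due to actual signal.
#'
#' @param label_universe character vector of all label ids.
#' @param sizes integer vector: number of labels to draw per document.
#' @param seed integer seed.
#' @return list of character label sets.
#' @export
random_predictions <- function(label_universe, sizes, seed = 1L) {
  set.seed(seed)
  lapply(sizes, function(n) {
    n <- min(n, length(label_universe))
    if (n == 0L) return(character(0))
    sample(label_universe, n)
  })
}
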