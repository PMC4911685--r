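#' Collect candidate labels from a neighbour set
#'
#' The candidate labels of a document are the union of the label sets of its
#' k nearest neighbours; only these are eligible for assignment.
#'
#' @param neighbours a `neighbor_set` from [retrieve_neighbors()].
#' @param index the `vsm_index` the neighbours came from (provides each
#'   neighbour's label set).
#' @return sorted character vector of distinct candidate label ids.
#' @export
collect_candidates <- function(neighbours, index) {
  ids <- neighbours$neighbors$doc_id
  sort(unique(unlist(index$labels[ids], use.names = FALSE)))
}

# Precompute stemmed matching patterns for every descriptor: the preferred
# term's token set (feature 3) and each entry term as a token phrase
# (features 4-6). Used so per-document feature extraction does not re-stem
# the thesaurus.
.label_patterns <- function(thesaurus, stopwords = default_stopwords()) {
  pats <- lapply(seq_len(nrow(thesaurus)), function(i) {
    list(pref = preprocess_text(thesaurus$preferred_term[i], stopwords),
         entries = Filter(length, lapply(thesaurus$entry_terms[[i]],
                                         preprocess_text, stopwords = stopwords)))
  })
  names(pats) <- thesaurus$descriptor_id
  pats
}

# Pattern for a label id absent from the thesaurus: derived from the id's
# own text.
.fallback_pattern <- function(label_id, stopwords = default_stopwords()) {
  toks <- preprocess_text(label_id, stopwords)
  list(pref = toks, entries = if (length(toks)) list(toks) else list())
}

# Number of occurrences of `phrase` (token vector) as a contiguous
# subsequence of `tokens`, counting overlaps.
.count_phrase <- function(tokens, phrase) {
  lp <- length(phrase)
  n <- length(tokens)
  if (lp == 0L || n < lp) return(0L)
  if (lp == 1L) return(sum(tokens == phrase))
  starts <- which(tokens == phrase[1L])
  starts <- starts[starts <= n - lp + 1L]
  if (length(starts) == 0L) return(0L)
  hits <- vapply(starts, function(s) {
    all(tokens[s:(s + lp - 1L)] == phrase)
  }, logical(1))
  sum(hits)
}

# Text features f3-f6 of one label pattern against one tokenized document.
.text_features <- function(pattern, title_tokens, abstract_tokens) {
  all_tokens <- c(title_tokens, abstract_tokens)
  f3 <- as.integer(length(pattern$pref) > 0L && all(pattern$pref %in% all_tokens))
  f5 <- 0L
  f6 <- 0L
  for (ph in pattern$entries) {
    # count in title and abstract separately so a phrase cannot straddle
    # the title/abstract boundary
    cnt_title <- .count_phrase(title_tokens, ph)
    f5 <- f5 + cnt_title + .count_phrase(abstract_tokens, ph)
    if (cnt_title > 0L) f6 <- 1L
  }
  f4 <- as.integer(f5 > 0L)
  c(f3 = f3, f4 = f4, f5 = if (f4 == 1L) f5 else 0L, f6 = f6)
}

#' Compute the six features of one candidate label for one document
#'
#' * `f1` — fraction of the k neighbours annotated with the label.
#' * `f2` — sum of cosine similarities to the neighbours annotated with the
#'   label, divided by k (so `f2 <= f1`).
#' * `f3` — 1 when every stemmed token of the preferred term occurs
#'   somewhere in title + abstract (captures multi-word headings whose
#'   words appear disjointly).
#' * `f4` — 1 when some entry term occurs as a contiguous stemmed-token
#'   phrase in title or abstract.
#' * `f5` — total count of such contiguous entry-term occurrences (0 when
#'   `f4` is 0).
#' * `f6` — 1 when some entry term occurs as a contiguous phrase in the
#'   title.
#'
#' @param label candidate label (descriptor id).
#' @param doc tokenized document (list with `title_tokens`,
#'   `abstract_tokens`).
#' @param neighbours `neighbor_set` of the document.
#' @param index `vsm_index` providing neighbour label sets.
#' @param thesaurus `thesaurus` (or `NULL`: features 3-6 fall back to the
#'   label id's own text).
#' @param k the requested neighbour count used as the f1/f2 normalizer
#'   (defaults to the neighbour set's `k`).
#' @param stopwords stop-word list.
#' @return one-row tibble with columns `label_id`, `f1`..`f6`.
#' @export
compute_features <- function(label, doc, neighbours, index, thesaurus = NULL,
                             k = neighbours$k, stopwords = default_stopwords()) {
  nb <- neighbours$neighbors
  has_label <- vapply(index$labels[nb$doc_id], function(ls) label %in% ls,
                      logical(1))
  f1 <- sum(has_label) / k
  f2 <- sum(nb$similarity[has_label]) / k
  pattern <- NULL
  if (!is.null(thesaurus)) {
    hit <- match(label, thesaurus$descriptor_id)
    if (!is.na(hit)) {
      pattern <- list(
        pref = preprocess_text(thesaurus$preferred_term[hit], stopwords),
        entries = Filter(length, lapply(thesaurus$entry_terms[[hit]],
                                        preprocess_text, stopwords = stopwords)))
    }
  }
  if (is.null(pattern)) {
    if (!is.null(thesaurus)) {
      warning("label \"", label, "\" not in thesaurus; matching on its id text",
              call. = FALSE)
    }
    pattern <- .fallback_pattern(label, stopwords)
  }
  tf <- .text_features(pattern, doc$title_tokens, doc$abstract_tokens)
  tibble::tibble(label_id = label, f1 = f1, f2 = f2,
                 f3 = tf[["f3"]], f4 = tf[["f4"]], f5 = tf[["f5"]],
                 f6 = tf[["f6"]])
}

# Feature rows for all candidates of one document (vectorized f1/f2).
# Returns a data.frame label_id, f1..f6.
.candidate_features <- function(doc, neighbours, index, patterns, k,
                                stopwords = default_stopwords()) {
  nb <- neighbours$neighbors
  if (nrow(nb) == 0L) {
    return(data.frame(label_id = character(0), f1 = numeric(0), f2 = numeric(0),
                      f3 = integer(0), f4 = integer(0), f5 = integer(0),
                      f6 = integer(0), stringsAsFactors = FALSE))
  }
  lab_lists <- index$labels[nb$doc_id]
  lens <- lengths(lab_lists)
  lab_flat <- unlist(lab_lists, use.names = FALSE)
  sim_flat <- rep(nb$similarity, lens)
  cand <- sort(unique(lab_flat))
  fl <- factor(lab_flat, levels = cand)
  f1 <- as.numeric(tabulate(fl, nbins = length(cand))) / k
  f2 <- as.numeric(rowsum(sim_flat, fl)[, 1L]) / k
  txt <- t(vapply(cand, function(lab) {
    p <- patterns[[lab]]
    if (is.null(p)) p <- .fallback_pattern(lab, stopwords)
    .text_features(p, doc$title_tokens, doc$abstract_tokens)
  }, c(f3 = 0L, f4 = 0L, f5 = 0L, f6 = 0L)))
  data.frame(label_id = cand, f1 = f1, f2 = f2,
             f3 = txt[, "f3"], f4 = txt[, "f4"], f5 = txt[, "f5"],
             f6 = txt[, "f6"], stringsAsFactors = FALSE)
}

#' Build the labelled training set for the ranker
#'
#' For each annotated training document, its neighbours are retrieved from
#' the index (the document itself is excluded, i.e. leave-one-out when the
#' training documents are the indexed ones), candidate labels are collected
#' and their features computed. The binary class of each instance is 1 when
#' the candidate is among the document's true labels.
#'
#' @param train_docs corpus data frame of annotated documents.
#' @param index `vsm_index` over the retrieval collection.
#' @param thesaurus `thesaurus` used by features 3-6.
#' @param k neighbour count (default 25).
#' @param stopwords stop-word list.
#' @param tokens optional pre-tokenized `train_docs`.
#' @return tibble with columns `doc_id`, `label_id`, `f1`..`f6`, `class`
#'   (integer 0/1), one row per (document, candidate label); directly
#'   exportable with [utils::write.csv()].
#' @export
build_training_set <- function(train_docs, index, thesaurus, k = 25,
                               stopwords = default_stopwords(), tokens = NULL) {
  if (is.null(tokens)) tokens <- tokenize_corpus(train_docs, stopwords)
  patterns <- .label_patterns(thesaurus, stopwords)
  nbrs <- .retrieve_neighbors_batch(index, tokens, k = k, exclude_self = TRUE)
  rows <- lapply(seq_len(nrow(train_docs)), function(i) {
    feats <- .candidate_features(tokens[[i]], nbrs[[i]], index, patterns, k,
                                 stopwords)
    if (nrow(feats) == 0L) return(NULL)
    feats$doc_id <- train_docs$doc_id[i]
    feats$class <- as.integer(feats$label_id %in% train_docs$labels[[i]])
    feats
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no training instances could be built (no document has neighbours)",
         call. = FALSE)
  }
  tibble::as_tibble(out[, c("doc_id", "label_id", "f1", "f2", "f3", "f4",
                            "f5", "f6", "class")])
}

# ---- discretization ----------------------------------------------------

# Interior cut points giving equal-frequency bins: midpoints between
# consecutive order statistics at positions floor(i * n / n_bins).
.ef_edges <- function(x, n_bins) {
  xs <- sort(x)
  n <- length(xs)
  if (n == 0L || n_bins <= 1L) return(numeric(0))
  pos <- unique(pmin(pmax(floor(seq_len(n_bins - 1L) * n / n_bins), 1L), n - 1L))
  edges <- (xs[pos] + xs[pos + 1L]) / 2
  # drop degenerate edges (ties in x collapse bins)
  edges <- unique(edges)
  edges[edges > min(xs) & edges < max(xs)]
}

.apply_edges <- function(x, edges) {
  bins <- findInterval(x, edges) + 1L
  factor(bins, levels = seq_len(length(edges) + 1L), ordered = TRUE)
}

#' Discretize the numeric features into equal-frequency bins
#'
#' The classifiers operate on nominal attributes; the numeric features
#' (`f1`, `f2`, `f5`) are binned into (up to) `n_bins` equal-frequency bins
#' learned on the training data. The learned bin edges are stored in the
#' fitted model and reused verbatim at classification time.
#'
#' @param instances tibble with columns `f1`..`f6` (and optionally `class`).
#' @param n_bins target number of bins (default 10).
#' @param edges optional previously learned edges (named list `f1`, `f2`,
#'   `f5`); when supplied they are applied instead of being re-learned.
#' @return list with `instances` (numeric features replaced by ordered
#'   factors, binary features by 0/1 factors) and `edges`.
#' @export
discretize_features <- function(instances, n_bins = 10, edges = NULL) {
  num_feats <- c("f1", "f2", "f5")
  if (is.null(edges)) {
    edges <- lapply(num_feats, function(f) .ef_edges(instances[[f]], n_bins))
    names(edges) <- num_feats
  }
  out <- instances
  for (f in num_feats) out[[f]] <- .apply_edges(instances[[f]], edges[[f]])
  for (f in c("f3", "f4", "f6")) {
    out[[f]] <- factor(as.integer(instances[[f]]), levels = c(0L, 1L))
  }
  if ("class" %in% names(out)) {
    out$class <- factor(as.integer(instances$class), levels = c(0L, 1L))
  }
  list(instances = out, edges = edges)
}

# ---- classifier -------------------------------------------------------

#' Train a relevance-scoring classifier over label instances
#'
#' Fits one of four pluggable classifiers on the discretized feature
#' vectors: naive Bayes (`"nb"`), a decision tree (`"dt"`), a random forest
#' (`"rf"`, the configuration that performs best in practice) or a
#' multilayer perceptron (`"mlp"`). The fitted model later converts a
#' candidate label's features into its probability of being relevant.
#'
#' @param instances training tibble from [build_training_set()].
#' @param algorithm one of `"nb"`, `"dt"`, `"rf"`, `"mlp"`.
#' @param seed integer seed making training deterministic.
#' @param n_bins bins for [discretize_features()].
#' @param num_trees random-forest size (rf only).
#' @return a `ranker_model`.
#' @export
train_ranker <- function(instances, algorithm = c("rf", "nb", "dt", "mlp"),
                         seed = 1L, n_bins = 10, num_trees = 300) {
  algorithm <- match.arg(algorithm)
  if (nrow(instances) < 2L) stop("need at least 2 training instances", call. = FALSE)
  disc <- discretize_features(instances, n_bins = n_bins)
  dat <- as.data.frame(disc$instances[, c("f1", "f2", "f3", "f4", "f5", "f6",
                                          "class")])
  prior <- mean(instances$class == 1L)
  if (length(unique(instances$class)) < 2L) {
    warning("single-class training data; returning a prior-only model",
            call. = FALSE)
    return(structure(list(algorithm = "prior", fit = NULL, edges = disc$edges,
                          n_bins = n_bins, seed = seed, prior = prior),
                     class = "ranker_model"))
  }
  set.seed(seed)
  fit <- switch(
    algorithm,
    nb = e1071::naiveBayes(class ~ ., data = dat, laplace = 1),
    dt = rpart::rpart(class ~ ., data = dat, method = "class"),
    rf = ranger::ranger(class ~ ., data = dat, probability = TRUE,
                        num.trees = num_trees, seed = seed, num.threads = 1L,
                        verbose = FALSE),
    mlp = nnet::nnet(class ~ ., data = dat, size = 8, decay = 0.1,
                     maxit = 200, trace = FALSE)
  )
  structure(
    list(algorithm = algorithm, fit = fit, edges = disc$edges,
         n_bins = n_bins, seed = seed, prior = prior,
         hyperparameters = switch(algorithm,
                                  rf = list(num_trees = num_trees),
                                  mlp = list(size = 8, decay = 0.1, maxit = 200),
                                  list())),
    class = "ranker_model")
}

#' @export
print.ranker_model <- function(x, ...) {
  cat("<ranker_model> algorithm =", x$algorithm, "| seed =", x$seed,
      "| class-1 prior =", signif(x$prior, 3), "\n")
  invisible(x)
}

.model_scores <- function(model, dat) {
  if (model$algorithm == "prior") return(rep(model$prior, nrow(dat)))
  switch(
    model$algorithm,
    nb = {
      p <- stats::predict(model$fit, newdata = dat, type = "raw")
      as.numeric(p[, "1"])
    },
    dt = {
      p <- stats::predict(model$fit, newdata = dat, type = "prob")
      as.numeric(p[, "1"])
    },
    rf = {
      p <- stats::predict(model$fit, data = dat, num.threads = 1L)$predictions
      as.numeric(p[, "1"])
    },
    mlp = as.numeric(stats::predict(model$fit, newdata = dat, type = "raw"))
  )
}

#' Score and rank candidate labels
#'
#' Applies the fitted model to each candidate's features (discretized with
#' the edges stored at training time) and returns labels ordered by
#' estimated probability of relevance. Ties are broken by descending `f2`
#' (similarity mass) then ascending label id.
#'
#' @param model a `ranker_model`.
#' @param candidates tibble of raw feature rows (`label_id`, `f1`..`f6`).
#' @return a `ranked_prediction`: tibble (`label_id`, `score`) in
#'   non-increasing score order, with the candidate features retained as
#'   attribute `"features"`.
#' @export
score_labels <- function(model, candidates) {
  if (nrow(candidates) == 0L) {
    out <- tibble::tibble(label_id = character(0), score = numeric(0))
    class(out) <- c("ranked_prediction", class(out))
    return(out)
  }
  disc <- discretize_features(candidates, n_bins = model$n_bins,
                              edges = model$edges)
  dat <- as.data.frame(disc$instances[, c("f1", "f2", "f3", "f4", "f5", "f6")])
  score <- .model_scores(model, dat)
  ord <- order(-score, -candidates$f2, candidates$label_id)
  out <- tibble::tibble(label_id = candidates$label_id[ord], score = score[ord])
  attr(out, "features") <- candidates[ord, , drop = FALSE]
  class(out) <- c("ranked_prediction", class(out))
  out
}

# ---- selection of the number of labels --------------------------------

#' Parameters for selecting how many ranked labels to keep
#'
#' @param strategy `"threshold"` (keep labels scoring at least `threshold`),
#'   `"average_size"` (keep the top N where N is the rounded mean label-set
#'   size of the neighbour documents), or `"cutoff"` (truncate the ranked
#'   list at the first rank i where `s[i+1]/s[i] < i/(i+1+alpha)`).
#' @param threshold minimal relevance score for `"threshold"` (default 0.5).
#' @param alpha cut-off constant (default 1.6, the empirically best value).
#' @return a `selection_params` list.
#' @export
selection_params <- function(strategy = c("cutoff", "threshold", "average_size"),
                             threshold = 0.5, alpha = 1.6) {
  strategy <- match.arg(strategy)
  stopifnot(threshold >= 0, threshold <= 1, alpha > 0)
  structure(list(strategy = strategy, threshold = threshold, alpha = alpha),
            class = "selection_params")
}

# round half up (round() rounds half to even)
.round_half_up <- function(x) floor(x + 0.5)

#' Select the final label set from a ranked prediction
#'
#' Whatever the strategy, at least one label (the top-ranked one) is always
#' returned for a non-empty ranking.
#'
#' @param prediction a `ranked_prediction` from [score_labels()].
#' @param params a [selection_params()] object.
#' @param neighbours the document's `neighbor_set` (needed by
#'   `"average_size"`).
#' @param index the `vsm_index` (needed by `"average_size"`).
#' @return character vector of selected label ids (in rank order).
#' @export
select_labels <- function(prediction, params = selection_params(),
                          neighbours = NULL, index = NULL) {
  if (nrow(prediction) == 0L) return(character(0))
  scores <- prediction$score
  n_keep <- switch(
    params$strategy,
    threshold = max(1L, sum(scores >= params$threshold)),
    average_size = {
      if (is.null(neighbours) || is.null(index)) {
        stop("average_size strategy needs the neighbour set and index",
             call. = FALSE)
      }
      sizes <- lengths(index$labels[neighbours$neighbors$doc_id])
      n <- if (length(sizes)) .round_half_up(mean(sizes)) else 1L
      max(1L, min(n, length(scores)))
    },
    cutoff = cutoff_rank(scores, params$alpha)
  )
  prediction$label_id[seq_len(min(n_keep, length(scores)))]
}

#' Score-ratio cut-off rank
#'
#' Scans a descending score list and returns the last rank i before the
#' first violation of `s[i+1]/s[i] >= i/(i+1+alpha)`; rank 1 is always
#' kept. A zero score at position i stops the scan at i (the ratio test has
#' no meaning past it).
#'
#' @param scores numeric vector of non-increasing relevance scores.
#' @param alpha positive constant; larger values keep more labels.
#' @return integer number of labels to keep (>= 1).
#' @export
cutoff_rank <- function(scores, alpha = 1.6) {
  n <- length(scores)
  if (n == 0L) return(0L)
  i <- 1L
  while (i < n) {
    if (scores[i] <= 0) break
    if (scores[i + 1L] / scores[i] < i / (i + 1L + alpha)) break
    i <- i + 1L
  }
  i
}

# ---- feature diagnostics ----------------------------------------------

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of each feature with respect to the class
#'
#' Standard mutual information (in bits) between each discretized feature
#' and the binary class, `H(class) - sum_v p(v) H(class | v)`; used to
#' inspect which features carry predictive signal.
#'
#' @param instances tibble with feature columns `f1`..`f6` (numeric or
#'   factor) and `class`.
#' @param n_bins bins used to discretize numeric features first.
#' @return named numeric vector of gains in bits, one per feature.
#' @export
feature_information_gain <- function(instances, n_bins = 10) {
  disc <- discretize_features(instances, n_bins = n_bins)$instances
  cls <- disc$class
  h_class <- .entropy(as.numeric(table(cls)) / length(cls))
  feats <- c("f1", "f2", "f3", "f4", "f5", "f6")
  gains <- vapply(feats, function(f) {
    v <- disc[[f]]
    tab <- table(v, cls)
    pv <- rowSums(tab) / sum(tab)
    cond <- sum(vapply(seq_len(nrow(tab)), function(r) {
      if (pv[r] == 0) return(0)
      pv[r] * .entropy(tab[r, ] / sum(tab[r, ]))
    }, numeric(1)))
    h_class - cond
  }, numeric(1))
  gains
}
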