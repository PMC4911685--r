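#' Term-concept association statistics of an annotated corpus
#'
#' For every term t and concept (label) c over the training collection:
#' `occ(t)` = number of documents containing t, `occ(c)` = number of
#' documents annotated by c, `cocc(t, c)` = number of documents where t
#' occurs and c is assigned, and `TF(t, c)` = the sum over the documents of
#' c of `freq(t, d) / |d|` where `|d|` is the document's token count after
#' preprocessing.
#'
#' @param corpus annotated corpus data frame.
#' @param stopwords stop-word list.
#' @param tokens optional pre-tokenized corpus.
#' @return an `association_stats` object: list with `terms`, `concepts`,
#'   `occ_t`, `occ_c`, sparse matrices `cocc` and `tf` (concepts x terms),
#'   `n_docs`, `n_concepts` and the term document frequencies `df` used for
#'   query TF.IDF weights.
#' @export
association_stats <- function(corpus, stopwords = default_stopwords(),
                              tokens = NULL) {
  if (nrow(corpus) == 0L) stop("empty corpus", call. = FALSE)
  if (is.null(tokens)) tokens <- tokenize_corpus(corpus, stopwords)
  doc_tokens <- lapply(tokens, function(t) c(t$title_tokens, t$abstract_tokens))
  n <- length(doc_tokens)

  counts <- lapply(doc_tokens, table)
  terms <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
  lens <- vapply(counts, length, integer(1))
  i <- rep(seq_len(n), lens)
  j <- match(unlist(lapply(counts, names), use.names = FALSE), terms)
  cnt <- as.numeric(unlist(counts, use.names = FALSE))
  doc_len <- vapply(doc_tokens, length, integer(1))
  # binary occurrence and length-normalized frequency, docs x terms
  B <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(n, length(terms)))
  Fn <- Matrix::sparseMatrix(i = i, j = j, x = cnt / doc_len[i],
                             dims = c(n, length(terms)))

  concepts <- sort(unique(unlist(corpus$labels, use.names = FALSE)))
  if (length(concepts) == 0L) stop("corpus has no labels", call. = FALSE)
  li <- rep(seq_len(n), lengths(corpus$labels))
  lj <- match(unlist(corpus$labels, use.names = FALSE), concepts)
  L <- Matrix::sparseMatrix(i = li, j = lj, x = 1,
                            dims = c(n, length(concepts)))

  cocc <- Matrix::t(L) %*% B
  tf <- Matrix::t(L) %*% Fn
  dimnames(cocc) <- dimnames(tf) <- list(concepts, terms)

  structure(
    list(terms = terms, concepts = concepts,
         occ_t = stats::setNames(Matrix::colSums(B), terms),
         occ_c = stats::setNames(Matrix::colSums(L), concepts),
         cocc = cocc, tf = tf,
         n_docs = n, n_concepts = length(concepts),
         df = stats::setNames(Matrix::colSums(B), terms)),
    class = "association_stats")
}

#' TF.ICF association score between a term and a concept
#'
#' The TF.IDF scheme re-targeted from documents to concepts:
#' `TF(t, c) * log10(N / n_i)` where N is the total number of concepts and
#' `n_i` the number of concepts whose documents contain t. Base-10
#' logarithm (the base uniformly rescales scores and is fixed for
#' determinism).
#'
#' @param t term (character scalar).
#' @param c concept id (character scalar).
#' @param stats an `association_stats` object.
#' @param n_concepts total number of concepts N (defaults to the corpus
#'   value).
#' @return non-negative score; 0 when t does not occur in the documents of
#'   c.
#' @export
compute_tf_icf <- function(t, c, stats, n_concepts = stats$n_concepts) {
  ti <- match(t, stats$terms); ci <- match(c, stats$concepts)
  if (is.na(ti) || is.na(ci)) return(0)
  tf <- stats$tf[ci, ti]
  if (tf == 0) return(0)
  n_i <- sum(stats$cocc[, ti] > 0)
  if (n_i == 0) stop("inconsistent stats: TF > 0 with no associated concept",
                     call. = FALSE)
  tf * log10(n_concepts / n_i)
}

#' Jaccard association score between a term and a concept
#'
#' `cocc(t, c) / (occ(t) + occ(c) - cocc(t, c))`: the Jaccard coefficient
#' of the term's document support and the concept's document support. 0
#' when both supports are empty.
#'
#' @inheritParams compute_tf_icf
#' @return score in `[0, 1]`.
#' @export
compute_jaccard <- function(t, c, stats) {
  ti <- match(t, stats$terms); ci <- match(c, stats$concepts)
  occ_t <- if (is.na(ti)) 0 else stats$occ_t[[ti]]
  occ_c <- if (is.na(ci)) 0 else stats$occ_c[[ci]]
  cocc <- if (is.na(ti) || is.na(ci)) 0 else stats$cocc[ci, ti]
  den <- occ_t + occ_c - cocc
  if (den == 0) return(0)
  cocc / den
}

# Full score matrix (concepts x terms) for the chosen measure.
.association_matrix <- function(stats, measure) {
  if (measure == "jaccard") {
    trip <- Matrix::mat2triplet(stats$cocc)
    den <- stats$occ_t[trip$j] + stats$occ_c[trip$i] - trip$x
    sc <- trip$x / den
  } else {
    trip <- Matrix::mat2triplet(stats$tf)
    n_i <- Matrix::colSums(stats$cocc > 0)
    icf <- ifelse(n_i > 0, log10(stats$n_concepts / n_i), 0)
    sc <- trip$x * icf[trip$j]
  }
  M <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = sc,
                            dims = dim(stats$cocc),
                            dimnames = dimnames(stats$cocc))
  Matrix::drop0(M)
}

#' Build the ESA concept index
#'
#' Computes term-concept association scores over an annotated corpus and
#' stores them as an inverted index (term -> related concepts). Two
#' pruning rules keep the index compact and the scores robust: terms
#' occurring in fewer than `min_df` documents are ignored, and each concept
#' keeps only its `top_m` highest-scoring terms (ties at the boundary
#' broken by ascending term string).
#'
#' @param corpus annotated corpus data frame.
#' @param measure `"jaccard"` or `"tficf"`.
#' @param top_m terms kept per concept (default 200).
#' @param min_df minimal document frequency of an indexed term (default 5).
#' @param stopwords stop-word list.
#' @param tokens optional pre-tokenized corpus.
#' @return a `concept_index`: list with the sparse score matrix `scores`
#'   (terms x concepts), the training `df`/`n_docs` used for query TF.IDF
#'   weights, and the pruning settings.
#' @export
build_concept_index <- function(corpus, measure = c("jaccard", "tficf"),
                                top_m = 200, min_df = 5,
                                stopwords = default_stopwords(),
                                tokens = NULL) {
  measure <- match.arg(measure)
  stats <- association_stats(corpus, stopwords, tokens)
  M <- .association_matrix(stats, measure)  # concepts x terms
  eligible <- stats$df >= min_df
  M <- M[, eligible, drop = FALSE]
  terms <- stats$terms[eligible]

  # per concept, keep the top_m highest-scoring terms
  Mt <- as(Matrix::t(M), "CsparseMatrix")  # terms x concepts, column = concept
  p <- Mt@p; ii <- Mt@i; xx <- Mt@x
  keep <- logical(length(xx))
  for (cix in seq_len(ncol(Mt))) {
    idx <- seq.int(p[cix] + 1L, length.out = p[cix + 1L] - p[cix])
    if (length(idx) <= top_m) { keep[idx] <- TRUE; next }
    ord <- idx[order(-xx[idx], terms[ii[idx] + 1L])]
    keep[utils::head(ord, top_m)] <- TRUE
  }
  trip <- data.frame(i = ii + 1L, j = rep(seq_len(ncol(Mt)), diff(p)), x = xx)
  trip <- trip[keep, ]
  scores <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                                 dims = dim(Mt),
                                 dimnames = list(terms, stats$concepts))
  structure(
    list(measure = measure, scores = Matrix::drop0(scores),
         df = stats$df[eligible], n_docs = stats$n_docs,
         concepts = stats$concepts, top_m = top_m, min_df = min_df),
    class = "concept_index")
}

#' @export
print.concept_index <- function(x, ...) {
  cat("<concept_index> measure =", x$measure, "|", nrow(x$scores), "terms x",
      ncol(x$scores), "concepts | top_m =", x$top_m, "min_df =", x$min_df, "\n")
  invisible(x)
}

#' Rank concepts for a document with the ESA classifier
#'
#' The relevance of concept c for document d is
#' `Rel(c, d) = sum_t TF.IDF(t, d) * score(t, c)` over the document's
#' terms, where the TF.IDF weights use the training collection's document
#' frequencies (a frozen snapshot) and `score` is the indexed association
#' score.
#'
#' @param doc tokenized document (list with `title_tokens`,
#'   `abstract_tokens`) or plain token vector.
#' @param index a `concept_index`.
#' @param n_labels number of top concepts to return, or `"auto"` to use the
#'   size of `true_labels` (evaluation mode, where the number of relevant
#'   concepts is known), or `NULL` for the full ranking.
#' @param true_labels the document's gold label set (required when
#'   `n_labels = "auto"`).
#' @return a `concept_ranking` tibble (`concept`, `rel`) in non-increasing
#'   relevance order; zero rows (with a warning) when the document shares
#'   no indexed term.
#' @export
classify_esa <- function(doc, index, n_labels = NULL, true_labels = NULL) {
  if (identical(n_labels, "auto")) {
    if (is.null(true_labels)) {
      stop("n_labels = \"auto\" requires true_labels", call. = FALSE)
    }
    n_labels <- length(true_labels)
  }
  tokens <- .doc_token_vector(doc)
  tokens <- tokens[tokens %in% rownames(index$scores)]
  if (length(tokens) == 0L) {
    warning("document shares no indexed term; empty concept ranking",
            call. = FALSE)
    out <- tibble::tibble(concept = character(0), rel = numeric(0))
    class(out) <- c("concept_ranking", class(out))
    return(out)
  }
  tf <- table(tokens)
  w <- tfidf_weight(as.numeric(tf), index$df[names(tf)], index$n_docs)
  rel <- as.numeric(Matrix::crossprod(index$scores[names(tf), , drop = FALSE],
                                      w))
  names(rel) <- index$concepts
  pos <- which(rel > 0)
  ord <- pos[order(-rel[pos], index$concepts[pos])]
  if (!is.null(n_labels)) ord <- utils::head(ord, n_labels)
  out <- tibble::tibble(concept = index$concepts[ord], rel = unname(rel[ord]))
  class(out) <- c("concept_ranking", class(out))
  out
}

# Batch ESA classification: returns a list of character label sets, one per
# tokenized document; n = "auto" uses each document's gold set size.
.classify_esa_batch <- function(tokens_list, index, n = "auto",
                                true_labels = NULL) {
  lapply(seq_along(tokens_list), function(i) {
    nl <- if (identical(n, "auto")) length(true_labels[[i]]) else n
    rk <- suppressWarnings(classify_esa(tokens_list[[i]], index,
                                        n_labels = nl))
    rk$concept
  })
}

#' Persist a concept index as plain-text tables
#'
#' @param index a `concept_index`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_concept_index <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trip <- Matrix::mat2triplet(index$scores)
  tab <- data.frame(term = rownames(index$scores)[trip$i],
                    concept = colnames(index$scores)[trip$j],
                    score = trip$x, stringsAsFactors = FALSE)
  tab <- tab[order(tab$concept, -tab$score, tab$term), ]
  utils::write.table(tab, file.path(dir, "associations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(term = names(index$df), df = unname(index$df)),
    file.path(dir, "df.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("measure\t", index$measure),
               paste0("n_docs\t", index$n_docs),
               paste0("top_m\t", index$top_m),
               paste0("min_df\t", index$min_df),
               paste0("concepts\t", paste(index$concepts, collapse = ","))),
             file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' Load a concept index written by [write_concept_index()]
#'
#' @param dir directory with the index tables.
#' @return a `concept_index`.
#' @export
read_concept_index <- function(dir) {
  meta <- utils::read.delim(file.path(dir, "meta.tsv"), header = FALSE,
                            colClasses = "character")
  get <- function(k) meta$V2[meta$V1 == k]
  concepts <- strsplit(get("concepts"), ",", fixed = TRUE)[[1L]]
  dftab <- utils::read.delim(file.path(dir, "df.tsv"),
                             colClasses = c("character", "integer"))
  tab <- utils::read.delim(file.path(dir, "associations.tsv"),
                           colClasses = c("character", "character", "numeric"))
  terms <- dftab$term
  scores <- Matrix::sparseMatrix(i = match(tab$term, terms),
                                 j = match(tab$concept, concepts),
                                 x = tab$score,
                                 dims = c(length(terms), length(concepts)),
                                 dimnames = list(terms, concepts))
  structure(
    list(measure = get("measure"), scores = scores,
         df = stats::setNames(dftab$df, terms),
         n_docs = as.integer(get("n_docs")), concepts = concepts,
         top_m = as.integer(get("top_m")), min_df = as.integer(get("min_df"))),
    class = "concept_index")
}
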