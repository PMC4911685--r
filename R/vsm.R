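#' TF.IDF term weight
#'
#' Weight of a term in a document: raw term count times the natural-log
#' inverse document frequency, `tf * ln(n / df)`. A term occurring in every
#' document (df = n) or absent from the document (tf = 0) gets weight 0.
#'
#' @param tf term count in the document (vectorized, >= 0).
#' @param df document frequency of the term (0 <= df <= n).
#' @param n number of documents in the collection (>= 1).
#' @return numeric vector of non-negative weights.
#' @examples
#' tfidf_weight(2, 1, 10) # 2 * ln(10)
#' @export
tfidf_weight <- function(tf, df, n) {
  stopifnot(length(n) == 1L, n >= 1, all(tf >= 0), all(df >= 0), all(df <= n))
  if (any(df == 0 & tf > 0)) {
    stop("inconsistent index: tf > 0 but df = 0", call. = FALSE)
  }
  ifelse(tf == 0, 0, tf * log(n / df))
}

#' Cosine similarity between two sparse term vectors
#'
#' `Sim(a, b) = sum_k a_k b_k / (||a|| ||b||)`. Vectors are named numeric
#' vectors (term -> weight); an all-zero or empty vector has similarity 0
#' with anything by convention.
#'
#' @param a,b named numeric vectors of non-negative term weights.
#' @return similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) return(0)
  sum(a[shared] * b[shared]) / (na * nb)
}

#' Build a TF.IDF inverted index over an annotated corpus
#'
#' Each document is represented by the concatenation of its title and
#' abstract tokens; stored weights are [tfidf_weight()] computed from the
#' whole corpus. The index also records each document's label set, which the
#' label ranker reads when collecting candidate labels from neighbours.
#'
#' @param corpus corpus data frame (`doc_id`, `title`, `abstract`, `labels`).
#' @param stopwords stop-word list for preprocessing.
#' @param tokens optional pre-tokenized corpus (as from [tokenize_corpus()]);
#'   when supplied, `corpus` text columns are not re-processed.
#' @return a `vsm_index` object.
#' @export
build_index <- function(corpus, stopwords = default_stopwords(), tokens = NULL) {
  if (nrow(corpus) == 0L) stop("cannot index an empty corpus", call. = FALSE)
  if (is.null(tokens)) tokens <- tokenize_corpus(corpus, stopwords)
  doc_tokens <- lapply(tokens, function(t) c(t$title_tokens, t$abstract_tokens))
  n <- length(doc_tokens)
  doc_ids <- corpus$doc_id

  counts <- lapply(doc_tokens, function(tk) table(tk))
  vocab <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
  if (length(vocab) == 0L) stop("corpus contains no tokens", call. = FALSE)

  i <- rep(seq_len(n), vapply(counts, length, integer(1)))
  j <- match(unlist(lapply(counts, names), use.names = FALSE), vocab)
  x <- as.numeric(unlist(counts, use.names = FALSE))
  tf <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, length(vocab)),
                             dimnames = list(doc_ids, vocab))
  df <- Matrix::colSums(tf > 0)
  idf <- log(n / df)
  dtm <- tf %*% Matrix::Diagonal(x = idf)
  dimnames(dtm) <- dimnames(tf)
  dtm <- Matrix::drop0(dtm)
  norms <- sqrt(Matrix::rowSums(dtm^2))

  labels <- corpus$labels
  names(labels) <- doc_ids
  structure(
    list(n = n, doc_ids = doc_ids, vocab = vocab, df = df,
         dtm = dtm, norms = norms, labels = labels),
    class = "vsm_index")
}

#' @export
print.vsm_index <- function(x, ...) {
  cat("<vsm_index> ", x$n, " documents, ", length(x$vocab), " terms, ",
      length(unique(unlist(x$labels))), " distinct labels\n", sep = "")
  invisible(x)
}

#' TF.IDF query vector for a tokenized document
#'
#' Weights use the index's global document frequencies and collection size
#' (the query is treated as an unseen document). Tokens absent from the
#' index vocabulary are dropped.
#'
#' @param index a `vsm_index`.
#' @param tokens character vector of preprocessed tokens.
#' @return named numeric vector of TF.IDF weights (possibly empty).
#' @export
query_vector <- function(index, tokens) {
  tokens <- tokens[tokens %in% index$vocab]
  if (length(tokens) == 0L) return(stats::setNames(numeric(0), character(0)))
  tf <- table(tokens)
  terms <- names(tf)
  w <- tfidf_weight(as.numeric(tf), index$df[terms], index$n)
  stats::setNames(w, terms)
}

.doc_token_vector <- function(doc) {
  if (is.character(doc)) doc else c(doc$title_tokens, doc$abstract_tokens)
}

#' Retrieve the k nearest neighbours of a document
#'
#' Ranks indexed documents by cosine similarity to the query's TF.IDF
#' vector. Only documents with positive similarity are returned (an indexed
#' document sharing no term with the query is not a neighbour); ties at the
#' boundary are broken by ascending `doc_id`. A document already present in
#' the index is excluded from its own neighbour set via its `doc_id`.
#'
#' @param index a `vsm_index`.
#' @param query a tokenized document (list with `doc_id`, `title_tokens`,
#'   `abstract_tokens`) or a plain character vector of tokens.
#' @param k number of neighbours requested (default 25, the value at which
#'   the retrieval stage is operated).
#' @param exclude document ids to exclude; defaults to the query's own id.
#' @return a `neighbor_set`: list with `query_id`, `k` and a data frame
#'   `neighbors` (`doc_id`, `similarity`, descending).
#' @export
retrieve_neighbors <- function(index, query, k = 25, exclude = NULL) {
  stopifnot(k >= 1)
  query_id <- if (is.list(query) && !is.null(query$doc_id)) query$doc_id else NA_character_
  if (is.null(exclude) && !is.na(query_id)) exclude <- query_id
  q <- query_vector(index, .doc_token_vector(query))
  sims <- .cosine_to_index(index, q)
  if (!is.null(exclude)) sims[index$doc_ids %in% exclude] <- 0
  keep <- which(sims > 0)
  ord <- keep[order(-sims[keep], index$doc_ids[keep])]
  ord <- utils::head(ord, k)
  structure(
    list(query_id = query_id, k = as.integer(k),
         neighbors = data.frame(doc_id = index$doc_ids[ord],
                                similarity = unname(sims[ord]),
                                stringsAsFactors = FALSE)),
    class = "neighbor_set")
}

# Cosine similarities of a query weight vector against every indexed doc.
.cosine_to_index <- function(index, q) {
  if (length(q) == 0L) return(numeric(index$n))
  qs <- Matrix::sparseVector(x = unname(q),
                             i = match(names(q), index$vocab),
                             length = length(index$vocab))
  num <- as.numeric(index$dtm %*% qs)
  den <- index$norms * sqrt(sum(q^2))
  sims <- ifelse(den > 0, num / den, 0)
  sims
}

# Batch neighbour retrieval for many tokenized documents against one index.
# Returns a list of neighbor_set objects. exclude_self drops the document's
# own id (leave-one-out when the queries are the indexed documents).
.retrieve_neighbors_batch <- function(index, tokens, k = 25, exclude_self = TRUE) {
  n_q <- length(tokens)
  counts <- lapply(tokens, function(t) {
    tk <- .doc_token_vector(t)
    tk <- tk[tk %in% index$vocab]
    if (length(tk) == 0L) return(integer(0))
    table(tk)
  })
  lens <- vapply(counts, length, integer(1))
  i <- rep(seq_len(n_q), lens)
  terms <- unlist(lapply(counts, names), use.names = FALSE)
  qmat <- Matrix::sparseMatrix(
    i = i, j = match(terms, index$vocab),
    x = tfidf_weight(as.numeric(unlist(counts, use.names = FALSE)),
                     index$df[terms], index$n),
    dims = c(n_q, length(index$vocab)))
  qnorm <- sqrt(Matrix::rowSums(qmat^2))
  S <- as.matrix(qmat %*% Matrix::t(index$dtm))
  den <- outer(qnorm, index$norms)
  S <- ifelse(den > 0, S / den, 0)
  ids <- vapply(tokens, function(t) {
    if (!is.null(t$doc_id)) t$doc_id else NA_character_
  }, character(1))
  lapply(seq_len(n_q), function(qi) {
    sims <- S[qi, ]
    if (exclude_self && !is.na(ids[qi])) sims[index$doc_ids == ids[qi]] <- 0
    keep <- which(sims > 0)
    ord <- keep[order(-sims[keep], index$doc_ids[keep])]
    ord <- utils::head(ord, k)
    structure(
      list(query_id = ids[qi], k = as.integer(k),
           neighbors = data.frame(doc_id = index$doc_ids[ord],
                                  similarity = unname(sims[ord]),
                                  stringsAsFactors = FALSE)),
      class = "neighbor_set")
  })
}

#' Persist a VSM index as plain-text tables
#'
#' Writes `postings.tsv` (term, df, doc_id, weight), `norms.tsv`,
#' `labels.tsv` and `meta.tsv` into a directory.
#'
#' @param index a `vsm_index`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_index <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trip <- as.data.frame(Matrix::mat2triplet(index$dtm))
  post <- data.frame(term = index$vocab[trip$j],
                     df = unname(index$df[index$vocab[trip$j]]),
                     doc_id = index$doc_ids[trip$i],
                     weight = trip$x, stringsAsFactors = FALSE)
  post <- post[order(post$term, post$doc_id), ]
  utils::write.table(post, file.path(dir, "postings.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(doc_id = index$doc_ids, norm = unname(index$norms)),
    file.path(dir, "norms.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(doc_id = rep(index$doc_ids, lengths(index$labels)),
               label = unlist(index$labels, use.names = FALSE)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  # df of every term (including weight-0 terms with df = n) and corpus size
  utils::write.table(
    data.frame(term = index$vocab, df = unname(index$df)),
    file.path(dir, "df.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0("n\t", index$n), file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' Load a VSM index written by [write_index()]
#'
#' @param dir directory containing the index tables.
#' @return a `vsm_index`.
#' @export
read_index <- function(dir) {
  meta <- utils::read.delim(file.path(dir, "meta.tsv"), header = FALSE)
  n <- as.integer(meta$V2[meta$V1 == "n"])
  dftab <- utils::read.delim(file.path(dir, "df.tsv"), colClasses = c("character", "integer"))
  normtab <- utils::read.delim(file.path(dir, "norms.tsv"),
                               colClasses = c("character", "numeric"))
  post <- utils::read.delim(file.path(dir, "postings.tsv"),
                            colClasses = c("character", "integer", "character", "numeric"))
  labtab <- utils::read.delim(file.path(dir, "labels.tsv"),
                              colClasses = c("character", "character"))
  doc_ids <- normtab$doc_id
  vocab <- dftab$term
  dtm <- Matrix::sparseMatrix(i = match(post$doc_id, doc_ids),
                              j = match(post$term, vocab),
                              x = post$weight,
                              dims = c(length(doc_ids), length(vocab)),
                              dimnames = list(doc_ids, vocab))
  labels <- split(labtab$label, factor(labtab$doc_id, levels = doc_ids))
  labels <- lapply(labels, as.character)
  structure(
    list(n = n, doc_ids = doc_ids, vocab = vocab,
         df = stats::setNames(dftab$df, vocab), dtm = dtm,
         norms = stats::setNames(normtab$norm, doc_ids), labels = labels),
    class = "vsm_index")
}
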