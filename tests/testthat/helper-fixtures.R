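# Hand-built fixtures and independent oracles used across the suite.

# Small corpus of real-word citations with descriptor labels.
tiny_corpus <- function() {
  tibble::tibble(
    doc_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    title = c(
      "Body mass index and obesity",
      "Waist circumference as an obesity marker",
      "Postoperative care after elective surgery",
      "Surgical errors and patient safety",
      "Obesity and body fat in adults",
      "Patient safety in postoperative wards"),
    abstract = c(
      "We study body mass index and waist circumference in obese adults.",
      "Waist circumference predicts obesity better than body mass index.",
      "Failures in postoperative care after major elective general surgery.",
      "Medical errors in surgery threaten patient safety and care quality.",
      "Body fat and obesity measured by anthropometric indices in adults.",
      "Improving patient safety in postoperative care units."),
    labels = list(
      c("D001", "D002"), c("D001", "D002"), c("D003", "D004"),
      c("D004", "D005"), c("D001", "D002"), c("D003", "D005"))
  )
}

tiny_thesaurus <- function() {
  new_thesaurus(
    descriptor_id = c("D001", "D002", "D003", "D004", "D005"),
    preferred_term = c("Body Mass Index", "Obesity", "Postoperative Care",
                       "General Surgery", "Patient Safety"),
    entry_terms = list(c("BMI", "Quetelet Index"), c("Adiposity"),
                       c("Care, Postoperative"), c("Surgery"),
                       c("Safety, Patient")))
}

# A 10-document, 3-concept corpus with a transparent token layout, used to
# brute-force the ESA association scores by hand.
esa_hand_corpus <- function() {
  txt <- list(
    c("alpha", "alpha", "beta"),          # C1
    c("alpha", "gamma"),                   # C1
    c("alpha", "beta", "beta"),         # C1, C2
    c("beta", "gamma"),                  # C2
    c("beta", "beta", "delta"),         # C2
    c("gamma", "delta"),                   # C3
    c("gamma", "gamma", "alpha"),         # C3
    c("delta", "delta", "gamma"),          # C3
    c("alpha", "alpha"),                    # C1, C3
    c("beta", "gamma", "delta"))         # C2, C3
  labs <- list("C1", "C1", c("C1", "C2"), "C2", "C2", "C3", "C3", "C3",
               c("C1", "C3"), c("C2", "C3"))
  tibble::tibble(
    doc_id = sprintf("e%02d", 1:10),
    title = vapply(txt, function(x) paste(x[1], collapse = " "), character(1)),
    abstract = vapply(txt, function(x) paste(x[-1], collapse = " "), character(1)),
    labels = labs)
}

# Independent brute-force kNN oracle: plain-R TF.IDF weights and cosine,
# no package index structures.
brute_force_neighbors <- function(corpus, query_tokens, k, exclude = NULL) {
  docs <- lapply(seq_len(nrow(corpus)), function(i) {
    c(preprocess_text(corpus$title[i]), preprocess_text(corpus$abstract[i]))
  })
  n <- length(docs)
  vocab <- unique(unlist(docs))
  df <- vapply(vocab, function(t) sum(vapply(docs, function(d) t %in% d,
                                             logical(1))), numeric(1))
  names(df) <- vocab
  weigh <- function(tokens) {
    tokens <- tokens[tokens %in% vocab]
    if (length(tokens) == 0L) return(numeric(0))
    tf <- table(tokens)
    w <- as.numeric(tf) * log(n / df[names(tf)])
    names(w) <- names(tf)
    w
  }
  qw <- weigh(query_tokens)
  qn <- sqrt(sum(qw^2))
  sims <- vapply(seq_len(n), function(i) {
    dw <- weigh(docs[[i]])
    dn <- sqrt(sum(dw^2))
    if (qn == 0 || dn == 0) return(0)
    shared <- intersect(names(qw), names(dw))
    if (!length(shared)) return(0)
    sum(qw[shared] * dw[shared]) / (qn * dn)
  }, numeric(1))
  if (!is.null(exclude)) sims[corpus$doc_id %in% exclude] <- 0
  keep <- which(sims > 1e-15)
  ord <- keep[order(-sims[keep], corpus$doc_id[keep])]
  ord <- head(ord, k)
  data.frame(doc_id = corpus$doc_id[ord], similarity = sims[ord],
             stringsAsFactors = FALSE)
}

# Relevance scores printed for the worked selection example: a descending
# list of 16 candidate-label scores.
worked_example_scores <- function() {
  c(0.99, 0.75, 0.60, 0.60, 0.32, 0.32, 0.32, 0.32, 0.32,
    0.26, 0.26, 0.25, 0.21, 0.21, 0.20, 0.20)
}

# Run the full kNN pipeline on one generated corpus; returns the evaluation
# reports of the classifier and of a matched-size random baseline.
run_pipeline_once <- function(seed, signal_strength = 0.8, n_docs = 2000,
                              n_labels = 50, algorithm = "rf",
                              params = selection_params("cutoff", alpha = 1.6)) {
  gen <- generate_corpus(generator_config(
    n_docs = n_docs, n_labels = n_labels, signal_strength = signal_strength,
    seed = seed))
  sp <- split_corpus(gen$corpus, 0.5, seed = seed)
  clf <- train_classifier(sp$train, gen$thesaurus, k = 25,
                          algorithm = algorithm, seed = seed)
  preds <- classify_corpus(clf, sp$test, params)
  baseline <- random_predictions(gen$truth$label, lengths(preds$selected),
                                 seed = seed + 1L)
  list(
    model = evaluate_predictions(sp$test$labels, preds$selected,
                                 doc_ids = sp$test$doc_id),
    baseline = evaluate_predictions(sp$test$labels, baseline,
                                    doc_ids = sp$test$doc_id),
    predictions = preds, split = sp, generated = gen, classifier = clf)
}
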