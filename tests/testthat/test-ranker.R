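# Minimal hand-built index / neighbour-set constructors.
fake_index <- function(labels_of) {
  structure(list(n = length(labels_of), doc_ids = names(labels_of),
                 labels = labels_of), class = "vsm_index")
}

fake_neighbors <- function(doc_ids, sims, k = length(doc_ids)) {
  structure(list(query_id = "q", k = as.integer(k),
                 neighbors = data.frame(doc_id = doc_ids, similarity = sims,
                                        stringsAsFactors = FALSE)),
            class = "neighbor_set")
}

test_that("candidate labels are the union of neighbour label sets", {
  idx <- fake_index(list(n1 = c("A", "B"), n2 = c("B", "C"), n3 = "A"))
  expect_equal(collect_candidates(fake_neighbors(c("n1", "n2"), c(.9, .8)), idx),
               c("A", "B", "C"))
  expect_equal(collect_candidates(fake_neighbors("n3", .5), idx), "A")
  nb <- fake_neighbors(c("n1", "n2", "n3"), c(.9, .8, .7))
  expect_lte(length(collect_candidates(nb, idx)),
             sum(lengths(idx$labels)))
})

test_that("f1 and f2 follow the neighbour-vote formulas", {
  th <- tiny_thesaurus()
  doc <- list(doc_id = "q", title_tokens = character(0),
              abstract_tokens = c("bodi", "mass"))
  # label on all k neighbours -> f1 = 1
  idx <- fake_index(list(n1 = "D001", n2 = "D001", n3 = "D001"))
  nb <- fake_neighbors(c("n1", "n2", "n3"), c(.9, .8, .7), k = 3)
  fv <- compute_features("D001", doc, nb, idx, th, k = 3)
  expect_equal(fv$f1, 1)
  expect_equal(fv$f2, (0.9 + 0.8 + 0.7) / 3)
  # label on 1 of 25 requested neighbours with similarity 0.3 -> f2 = 0.012
  idx2 <- fake_index(list(n1 = "D001"))
  nb2 <- fake_neighbors("n1", 0.3, k = 25)
  fv2 <- compute_features("D001", doc, nb2, idx2, th, k = 25)
  expect_equal(fv2$f1, 1 / 25)
  expect_equal(fv2$f2, 0.012)
})

test_that("title/entry-term features fire on a realistic surgical citation", {
  title <- paste("An observational study of the frequency, severity, and",
                 "etiology of failures in postoperative care after major",
                 "elective general surgery")
  doc <- list(doc_id = "q", title_tokens = preprocess_text(title),
              abstract_tokens = character(0))
  th <- tiny_thesaurus()
  idx <- fake_index(list(n1 = c("D003", "D004")))
  nb <- fake_neighbors("n1", .5, k = 25)
  # "Postoperative Care" occurs verbatim in the title -> feature 6
  f_care <- compute_features("D003", doc, nb, idx, th, k = 25)
  expect_equal(f_care$f6, 1)
  expect_equal(f_care$f4, 1)
  expect_gte(f_care$f5, 1)
  # tokens of "General Surgery" both occur in the title -> feature 3
  f_surg <- compute_features("D004", doc, nb, idx, th, k = 25)
  expect_equal(f_surg$f3, 1)
  # a label whose terms never occur scores 0 on all text features
  f_bmi <- compute_features("D001", doc, nb, idx, th, k = 25)
  expect_equal(unlist(f_bmi[c("f3", "f4", "f5", "f6")], use.names = FALSE),
               c(0, 0, 0, 0))
})

test_that("a label absent from the thesaurus falls back to its id text", {
  doc <- list(doc_id = "q", title_tokens = c("bodi", "mass"),
              abstract_tokens = character(0))
  idx <- fake_index(list(n1 = "Body Mass"))
  nb <- fake_neighbors("n1", .5, k = 5)
  expect_warning(
    fv <- compute_features("Body Mass", doc, nb, idx, tiny_thesaurus(), k = 5),
    "not in thesaurus")
  expect_equal(fv$f3, 1)
  expect_equal(fv$f6, 1)
})

test_that("entry-term phrases must be contiguous, feature 3 need not be", {
  th <- new_thesaurus("D9", "alpha beta", list(character(0)))
  idx <- fake_index(list(n1 = "D9"))
  nb <- fake_neighbors("n1", .5, k = 5)
  # disjoint tokens: f3 fires, f4/f5/f6 do not
  doc <- list(doc_id = "q", title_tokens = c("alpha", "gamma", "beta"),
              abstract_tokens = character(0))
  fv <- compute_features("D9", doc, nb, idx, th, k = 5)
  expect_equal(unlist(fv[c("f3", "f4", "f5", "f6")], use.names = FALSE),
               c(1, 0, 0, 0))
  # contiguous occurrences are counted, including repeats
  doc2 <- list(doc_id = "q", title_tokens = c("alpha", "beta"),
               abstract_tokens = c("alpha", "beta", "alpha", "beta"))
  fv2 <- compute_features("D9", doc2, nb, idx, th, k = 5)
  expect_equal(unlist(fv2[c("f3", "f4", "f5", "f6")], use.names = FALSE),
               c(1, 1, 3, 1))
})

test_that("single- and batch-path feature extraction agree", {
  gen <- generate_corpus(generator_config(n_docs = 60, n_labels = 6,
                                          vocab_size = 240, seed = 21))
  idx <- build_index(gen$corpus)
  tok <- tokenize_corpus(gen$corpus)
  nb <- retrieve_neighbors(idx, tok[[10]], k = 10)
  pats <- semindex:::.label_patterns(gen$thesaurus)
  batch <- semindex:::.candidate_features(tok[[10]], nb, idx, pats, k = 10)
  for (r in seq_len(nrow(batch))) {
    single <- compute_features(batch$label_id[r], tok[[10]], nb, idx,
                               gen$thesaurus, k = 10)
    expect_equal(unlist(batch[r, c("f1", "f2", "f3", "f4", "f5", "f6")]),
                 unlist(single[, c("f1", "f2", "f3", "f4", "f5", "f6")]),
                 tolerance = 1e-12)
  }
})

test_that("training-set construction labels instances and keeps f2 <= f1", {
  gen <- generate_corpus(generator_config(n_docs = 120, n_labels = 10,
                                          vocab_size = 400, seed = 13))
  idx <- build_index(gen$corpus)
  inst <- build_training_set(gen$corpus, idx, gen$thesaurus, k = 10)
  # class is 1 exactly when the candidate is a true label of the document
  truth <- gen$corpus$labels
  names(truth) <- gen$corpus$doc_id
  expect_equal(inst$class,
               as.integer(mapply(function(d, l) l %in% truth[[d]],
                                 inst$doc_id, inst$label_id)))
  # per-document instance count equals the candidate-set size
  one_doc <- inst[inst$doc_id == gen$corpus$doc_id[5], ]
  nb <- retrieve_neighbors(idx, tokenize_corpus(gen$corpus[5, ])[[1]], k = 10)
  expect_equal(sort(one_doc$label_id), collect_candidates(nb, idx))
  # f2 never exceeds f1 (each summed similarity is at most 1)
  expect_true(all(inst$f2 <= inst$f1 + 1e-12))
  expect_true(all(inst$f1 > 0 & inst$f1 <= 1))
  # f5 > 0 iff f4 = 1
  expect_equal(inst$f5 > 0, inst$f4 == 1)
})

test_that("equal-frequency discretization is balanced and reusable", {
  # constant feature -> a single bin
  const <- tibble::tibble(f1 = rep(0.5, 20), f2 = runif(20), f3 = 0, f4 = 0,
                          f5 = 0, f6 = 0)
  d <- discretize_features(const, n_bins = 10)
  expect_equal(nlevels(d$instances$f1), 1)
  # ties-free data: bin populations differ by at most 1
  set.seed(8)
  x <- tibble::tibble(f1 = sample(seq(0.01, 1, length.out = 100)),
                      f2 = runif(100), f3 = 0, f4 = 0, f5 = 0, f6 = 0)
  d2 <- discretize_features(x, n_bins = 10)
  pops <- table(d2$instances$f1)
  expect_lte(max(pops) - min(pops), 1)
  expect_equal(length(pops), 10)
  # stored edges reproduce training bins exactly
  d3 <- discretize_features(x, edges = d2$edges)
  expect_equal(d3$instances$f1, d2$instances$f1)
  expect_equal(d3$instances$f2, d2$instances$f2)
})

test_that("training is deterministic given a seed", {
  set.seed(99)
  n <- 400
  inst <- tibble::tibble(
    f1 = runif(n), f2 = runif(n) * 0.5, f3 = rbinom(n, 1, .3),
    f4 = rbinom(n, 1, .3), f5 = rpois(n, 1), f6 = rbinom(n, 1, .2),
    class = rbinom(n, 1, plogis(3 * (runif(n) - 0.5))))
  inst$class <- as.integer(inst$f1 + runif(n) > 0.9)
  held <- inst[1:50, ]
  for (alg in c("nb", "dt", "rf", "mlp")) {
    m1 <- train_ranker(inst, alg, seed = 7)
    m2 <- train_ranker(inst, alg, seed = 7)
    s1 <- score_labels(m1, tibble::tibble(label_id = sprintf("L%02d", 1:50),
                                          held[, 1:6]))
    s2 <- score_labels(m2, tibble::tibble(label_id = sprintf("L%02d", 1:50),
                                          held[, 1:6]))
    expect_equal(s1, s2, info = alg)
    expect_true(all(s1$score >= 0 & s1$score <= 1), info = alg)
  }
})

test_that("a separable training set is ranked perfectly", {
  n <- 200
  set.seed(5)
  inst <- tibble::tibble(
    f1 = c(runif(n / 2, 0.8, 1), runif(n / 2, 0, 0.2)),
    f2 = c(runif(n / 2, 0.4, 0.5), runif(n / 2, 0, 0.1)),
    f3 = rep(c(1L, 0L), each = n / 2), f4 = rep(c(1L, 0L), each = n / 2),
    f5 = rep(c(3L, 0L), each = n / 2), f6 = 0L,
    class = rep(c(1L, 0L), each = n / 2))
  m <- train_ranker(inst, "rf", seed = 3)
  sc <- score_labels(m, tibble::tibble(label_id = sprintf("L%03d", 1:n),
                                       inst[, 1:6]))
  ranked_class <- inst$class[match(sc$label_id, sprintf("L%03d", 1:n))]
  expect_equal(ranked_class, rep(c(1L, 0L), each = n / 2))
})

test_that("single-class data yields a prior-only model with a warning", {
  inst <- tibble::tibble(f1 = runif(10), f2 = runif(10), f3 = 0, f4 = 0,
                         f5 = 0, f6 = 0, class = 1L)
  expect_warning(m <- train_ranker(inst, "rf", seed = 1), "single-class")
  sc <- score_labels(m, tibble::tibble(label_id = letters[1:3],
                                       f1 = c(.1, .5, .9), f2 = 0, f3 = 0,
                                       f4 = 0, f5 = 0, f6 = 0))
  expect_equal(sc$score, rep(1, 3))
})

test_that("identical feature vectors receive identical scores", {
  set.seed(2)
  n <- 100
  inst <- tibble::tibble(f1 = runif(n), f2 = runif(n) / 2,
                         f3 = rbinom(n, 1, .5), f4 = 0L, f5 = 0L, f6 = 0L,
                         class = rbinom(n, 1, .5))
  m <- train_ranker(inst, "nb", seed = 1)
  dup <- tibble::tibble(label_id = c("a", "b"), f1 = .4, f2 = .2, f3 = 1L,
                        f4 = 0L, f5 = 0L, f6 = 0L)
  sc <- score_labels(m, dup)
  expect_equal(sc$score[1], sc$score[2])
})

test_that("selection strategies implement their rules", {
  mk_pred <- function(scores) {
    p <- tibble::tibble(label_id = sprintf("L%02d", seq_along(scores)),
                        score = scores)
    class(p) <- c("ranked_prediction", class(p))
    p
  }
  # threshold is inclusive
  expect_equal(select_labels(mk_pred(c(0.6, 0.5, 0.4)),
                             selection_params("threshold", threshold = 0.5)),
               c("L01", "L02"))
  # at least one label even when nothing reaches the threshold
  expect_equal(select_labels(mk_pred(c(0.2, 0.1)),
                             selection_params("threshold", threshold = 0.5)),
               "L01")
  # average neighbour label-set size, rounded
  idx <- fake_index(list(a = sprintf("x%02d", 1:10), b = sprintf("y%02d", 1:12),
                         c = sprintf("z%02d", 1:14)))
  nb <- fake_neighbors(c("a", "b", "c"), c(.9, .8, .7))
  sel <- select_labels(mk_pred(seq(0.99, 0.20, length.out = 15)),
                       selection_params("average_size"), nb, idx)
  expect_length(sel, 12)
  # the worked cut-off example: 16 scores, alpha = 1.6, 4 labels kept
  expect_equal(cutoff_rank(worked_example_scores(), alpha = 1.6), 4)
  expect_equal(select_labels(mk_pred(worked_example_scores()),
                             selection_params("cutoff", alpha = 1.6)),
               sprintf("L%02d", 1:4))
})

test_that("the cut-off rule ignores zero scores past the cut and grows with alpha", {
  s <- worked_example_scores()
  base <- cutoff_rank(s, 1.6)
  expect_equal(cutoff_rank(c(s, rep(0, 10)), 1.6), base)
  set.seed(31)
  for (i in 1:40) {
    scores <- sort(runif(sample(3:20, 1)), decreasing = TRUE)
    alphas <- sort(runif(4, 0.1, 10))
    keeps <- vapply(alphas, function(a) cutoff_rank(scores, a), integer(1))
    expect_true(all(diff(keeps) >= 0))
    expect_gte(keeps[1], 1)
  }
})

test_that("information gain matches hand-computed entropies", {
  inst <- tibble::tibble(
    f1 = 0.5, f2 = 0.1, f5 = 0L,
    f3 = c(1L, 1L, 0L, 0L),   # identical to the class
    f4 = c(1L, 0L, 1L, 0L),   # independent of the class
    f6 = c(1L, 1L, 1L, 0L),
    class = c(1L, 1L, 0L, 0L))
  g <- feature_information_gain(inst)
  expect_equal(unname(g["f3"]), 1)          # = H(class)
  expect_equal(unname(g["f4"]), 0, tolerance = 1e-12)
  expect_equal(unname(g["f1"]), 0, tolerance = 1e-12)  # constant feature
  h_cond <- 0.75 * (-(1 / 3) * log2(1 / 3) - (2 / 3) * log2(2 / 3))
  expect_equal(unname(g["f6"]), 1 - h_cond)
})
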