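---
title: "Methods: kNN label ranking and ESA concept classification from partial text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kNN label ranking and ESA concept classification from partial text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biomedical citations are indexed with controlled-vocabulary descriptors
(MeSH main headings), but for most articles only the title and abstract are
freely available. `semindex` suggests a descriptor set for a document from
that partial information alone, given a large collection of already
annotated citations. It implements two independent classifiers plus the
example-based evaluation metrics used to compare them, and a synthetic
corpus generator so that everything is testable offline.

## The kNN label ranker

A document $d$ is represented as a sparse vector of Porter-stemmed,
stop-word-filtered unigrams weighted by TF.IDF,
$w_k = \mathrm{tf}_k \cdot \ln(n/\mathrm{df}_k)$, and compared to the
annotated collection with the cosine measure

$$\mathrm{Sim}(d_i, d_j) =
  \frac{\sum_k w_k^i w_k^j}{\lVert d_i \rVert \, \lVert d_j \rVert}.$$

The labels of the $k = 25$ nearest neighbours form the candidate set; every
other descriptor is ignored. Each candidate $l$ is described by six
features:

* $f_1(l) = \frac{1}{k} \sum_i \mathrm{assigned}(l, d_i)$ — the fraction of
  neighbours annotated with $l$;
* $f_2(l) = \frac{1}{k} \sum_{l \in d_i} \mathrm{Sim}(d, d_i)$ — the
  similarity mass of those neighbours (so $f_2 \le f_1$);
* $f_3$ — 1 when every stemmed token of the preferred term occurs somewhere
  in title + abstract (multi-word headings often appear with their words
  disjoint);
* $f_4$ — 1 when some entry term (synonym) occurs as a *contiguous*
  stemmed-token phrase;
* $f_5$ — the total count of such contiguous occurrences (0 when $f_4 = 0$);
* $f_6$ — 1 when an entry term occurs contiguously in the title.

A classifier trained on these features (class 1 when the candidate is among
the document's gold labels) supplies each candidate's probability of
relevance; candidates are ranked by that score, ties broken by descending
$f_2$ then ascending label id. Four algorithms are pluggable — naive Bayes,
a decision tree, a random forest and a multilayer perceptron — behind one
`train_ranker()` surface; the random forest is the recommended default.
Training instances are built leave-one-out: each training document's own id
is excluded from its neighbour search.

### Choosing how many labels to keep

Three strategies convert the ranked list into a label set:

* **threshold** — keep every label with score $\ge 0.5$;
* **average size** — keep the top $N$ where $N$ is the rounded mean
  label-set size of the neighbour documents;
* **cut-off** — truncate at the first rank $i$ violating
  $s_{i+1}/s_i \ge i/(i + 1 + \alpha)$ with $\alpha = 1.6$.

All strategies return at least the top-ranked label: an empty prediction is
never useful, and the cut-off ratio test needs a predecessor anyway. On the
worked 16-score example the cut-off rule keeps exactly 4 labels (the first
violation is $0.32/0.60 < 4/6.6$ at rank 4).

## The ESA concept classifier

The second method builds, from the annotated collection itself (not from an
external encyclopedia), an inverted index mapping each term to the concepts
it is associated with. Two association measures are implemented:

* **TF.ICF**: $TF(t,c) \cdot \log_{10}(N/n_t)$, where
  $TF(t,c) = \sum_{d \in D_c} \mathrm{freq}(t,d)/|d|$, $N$ is the number of
  concepts and $n_t$ the number of concepts whose documents contain $t$;
* **Jaccard**: $\mathrm{cocc}(t,c) / (\mathrm{occ}(t) + \mathrm{occ}(c) -
  \mathrm{cocc}(t,c))$ over document supports.

Each concept keeps its 200 highest-scoring terms and terms must appear in
at least 5 documents (both configurable). A new document is scored by
$\mathrm{Rel}(c,d) = \sum_{t \in d} \mathrm{TF.IDF}(t,d) \cdot
\mathrm{score}(t,c)$ and concepts are returned in descending relevance. In
evaluation mode the number of returned concepts is set to the size of the
document's gold set, which makes example-based precision and recall
coincide.

## Evaluation measures

For gold set $Y_i$ and prediction $Z_i$, per document:
$p = |Y_i \cap Z_i|/|Z_i|$, $r = |Y_i \cap Z_i|/|Y_i|$,
$F = 2|Y_i \cap Z_i|/(|Y_i|+|Z_i|)$ and
$\mathrm{Acc} = |Y_i \cap Z_i|/|Y_i \cup Z_i|$; corpus values (EBP, EBR,
EBF, Acc) are arithmetic means over the $m$ documents with non-empty gold
sets, and MiF is the micro-averaged F over all label decisions,
$2TP/(2TP+FP+FN)$. The F definition here is the standard harmonic-mean
form; `literal_f = TRUE` exposes a variant without the factor 2 (exactly
half the value) for comparison with sources that print the formula that
way. An empty prediction set has precision 0 by convention.

## The synthetic corpus generator

`generate_corpus()` emulates what matters statistically about annotated
citation collections: short title + longer abstract, several descriptors
per document, and vocabulary whose distribution shifts with the assigned
descriptors. Each of 50 labels owns 10 disjoint signal terms; a document
samples a truncated-Poisson number of labels (mean 5, min 1) and emits each
of its 110 tokens (10 title + 100 abstract) from a chosen label's signal
terms with probability `signal_strength` (default 0.8) or from a Zipf-like
background (exponent 1.1) over the 2000-term vocabulary otherwise. Entry
terms are drawn from the label's signal terms — the preferred term is a
two-token signal phrase — so the phrase-matching features and the
term–concept association statistics are exercised end to end. Tokens are
emitted as pre-stemmed strings (`"t0001"`…), making the stemmer a no-op on
them; the stemming path is tested separately on real words.

What the generator does *not* emulate: natural-language syntax, correlated
label co-occurrence structure, hierarchical vocabularies, and the sheer
scale and label sparsity of real citation collections (millions of
documents, tens of thousands of descriptors with heavy-tailed frequencies).
Consequently the package's end-to-end scores on synthetic corpora are far
higher than anything attainable on real collections and should be read only
as evidence that the machinery recovers planted structure, not as a
performance forecast.

## Numerical and design choices

* **TF.IDF variant.** Raw term count times $\ln(n/\mathrm{df})$. The
  weighting scheme's name does not pin down a variant; this is the plainest
  one and is deterministic. Queries are weighted with the index's global
  df/n statistics (they are unseen documents).
* **Neighbour ties and zero similarity.** Only documents with positive
  cosine are neighbours; ties at the k-boundary break by ascending doc id
  for reproducibility.
* **Stemming.** A faithful single-pass Porter (1980) implementation ships
  with the package. Porter is not idempotent on every word
  ("circumference" → "circumfer" → "circumf"), so pipeline idempotence
  holds only on stem-stable vocabulary — which includes all synthetic
  tokens. Stop words are filtered both before and after stemming (a word
  such as "canning" stems to the stop word "can").
* **Sentence segmentation** is skipped: in a bag-of-words model it has no
  downstream effect, and tokenization runs directly on Unicode
  letter/digit runs. One-letter and numeric tokens are kept — the method
  defines no such filters.
* **Discretization.** The classifiers see nominal features: $f_1, f_2, f_5$
  are binned into up to 10 equal-frequency bins whose edges are learned on
  the training instances and frozen into the model.
* **Classifier backends.** naive Bayes (`e1071`, Laplace 1 to avoid
  zero-frequency collapse), decision tree (`rpart`), random forest
  (`ranger`, 300 single-threaded trees, seeded), MLP (`nnet`, size 8,
  decay 0.1; recorded in the model object). The relevance score is the
  predicted probability of class 1.
* **ESA logs.** ICF uses base-10 logarithms; the base only rescales scores
  uniformly per $n_t$ and is fixed for determinism. The Rel weights use a
  frozen snapshot of the training corpus's document frequencies rather
  than being recomputed against a growing collection.
* **Degenerate inputs.** A query sharing no term with the index yields an
  empty neighbour set (signalled, not an error); single-class training
  data yields a prior-only model with a warning; a document with an empty
  gold set is excluded from evaluation and counted.

## Problem sizes used in the checks

The end-to-end checks run the full pipeline at the generator's canonical
conditions (2000 documents, 50 labels, signal 0.8, five seeds, with a
matched-size uniform-random baseline), the retrieval oracle comparison on a
200-document corpus with 20 queries and $k \in \{1, 5, 25\}$, and the
signal-strength monotonicity sweep at a reduced 600-document size over five
seeds. These sizes were chosen so the whole suite exercises every stage at
realistic candidate-set sizes while remaining comfortable to run on a
laptop.

## Known limitations

* Scores from different ranker algorithms are not calibrated against each
  other; only their induced rankings are comparable.
* The thesaurus fallback (matching a label id's own text when it is absent
  from the thesaurus) is a convenience for toy corpora, not a substitute
  for real entry terms.
* The ESA classifier depends entirely on labels being lexically reflected
  in their documents' vocabulary; on collections where labels are rarely
  mentioned it degrades sharply, which is intrinsic to the method.
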