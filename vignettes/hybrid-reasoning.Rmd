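---
title: "Hybrid model- and rule-based syndrome-pattern diagnosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid model- and rule-based syndrome-pattern diagnosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The diagnostic problem

A diagnosis in Chinese integrative medicine pairs a modern-medicine disease
label with a TCM *syndrome pattern* — a categorized summary of the
patient's symptoms and signs at a stage of disease. Patterns are composites:
each decomposes into a small set of *syndrome elements*, the atomic units of
TCM classification. This package works with a lung-ward inventory of 10
pattern types, 9 element types and 8 diseases, and with clinical cases
represented as ordered token streams extracted from the record's chief
complaint, syndromes, and chest/tongue/pulse signs.

Two reasoning paths map a record to a pattern:

* **MBR** — embed the token stream, then apply a multiclass classifier with
  the 10 patterns as outputs.
* **MBR+RBR** — apply a multilabel classifier with the 9 elements as
  outputs, then combine the predicted element set into a pattern through a
  rule knowledge base.

The hybrid path trades a little accuracy for explainability: a physician
can inspect the predicted elements and the rule that fired.

## The rule knowledge base

A rule maps a set of elements to a pattern. Inference
(`pattern_for_elements()`) is deliberately simple and total:

1. exact set equality with a single rule → `exact`;
2. otherwise score every rule by Jaccard overlap
   $|E \cap R| / |E \cup R|$; a unique maximiser at or above the
   partial-match floor → `partial`;
3. tied maximisers → `ambiguous`, resolved to the lowest priority rank
   (all tied rules are reported);
4. nothing at or above the floor → `none`, no pattern.

The floor defaults to 0.5 so that a single stray element cannot be promoted
to a full diagnosis; priorities are explicit integers rather than file
order, so re-serialising a rule file cannot change tie-breaking. Both
choices exist for reproducibility, not statistical reasons.

The shipped default table decomposes each of the 10 pattern names into its
constituent elements. Two editorial decisions were needed:

* Every pattern's set includes `lung`: in a lung-ward corpus the lung
  element is present in every case, and pattern names such as "deficiency
  of qi and yin" leave the organ implicit.
* The two wheezing patterns carry a `wind` component
  (`cold wheezing` = {wind, cold, phlegm, lung}, `hot wheezing` = {wind,
  heat, phlegm, lung}). Wheezing in TCM is retained phlegm activated by an
  exogenous trigger, so the trigger element is defensible — and it keeps
  the table *injective*: without it, "hot wheezing" and "phlegm-heat
  obstruction in lung" would share {heat, phlegm, lung} and decomposition
  could not be inverted. The engine still copes with non-injective tables
  (validation reports duplicate element sets; inference resolves them by
  priority), but a shipped default in which decompose-then-recombine is the
  identity for every pattern is strictly more useful. The table is a plain
  JSON file; an authoritative clinical rule table can be dropped in.

`validate_rulebase()` reports uncovered patterns, duplicate sets, unused
elements, and the round-trip property per pattern.

## The synthetic corpus generator

Real integrative-medicine EMR corpora are private, so every stage is
exercised against a generator that emulates the corpus *structure*:

* disease marginals follow the published lung-ward proportions, and
  pattern marginals the published per-pattern test supports;
* the 8×10 disease-conditional pattern table is built from a hand-specified
  clinical plausibility mask (each disease compatible with 2–4 patterns)
  balanced to both published margins by iterative proportional fitting —
  deterministic, and config-overridable. It is invented structure whose
  only asserted property is that the diagnosis is *informative* about the
  pattern, the premise behind corpus variant 2;
* each record's element set comes from the rule base, so labels are
  rule-consistent by construction;
* each element contributes a Poisson number of tokens (mean
  `tokens_per_element`, floor 1) drawn from its 24-token lexicon, routed
  round-robin to the four sign sections; the chief complaint draws from a
  shared pool of nonspecific complaint tokens, so it carries only a weak
  disease signal; noise tokens are interspersed at `noise_token_rate`
  (default 0.25 — free-text narratives carry substantial non-diagnostic
  vocabulary);
* corpus variant 2 appends exactly one diagnosis token at the end of the
  document, so the two corpora differ by a deterministic one-token delta.

Tokens are abstract ASCII identifiers: the pipeline operates on token
sequences, not on any particular language, and raw text enters only through
a user-supplied segmenter. What the generator does **not** emulate: symptom
co-occurrence semantics, negation, section-classification errors, label
noise, or inter-annotator disagreement. Passing tests therefore demonstrate
pipeline correctness and calibration, not clinical performance; published
real-data accuracies are not reproduction targets here.

With the default configuration the mean element count per record is ~2.6–
2.8, bracketing the published corpus density of 2.56 elements per pattern.
Splitting follows the published arithmetic: ratio 4:1 with the remainder of
a non-divisible split assigned to train (14,075 → 2,815 test records);
stratified splitting uses largest-remainder apportionment, keeping
per-pattern test proportions within one record.

## Embeddings

No embedding trainer exists in the R dependency stack used here, and the
embedding stage is part of the method, so both trainers are implemented in
compiled code:

* **word2vec** — skip-gram with negative sampling (5 negatives,
  unigram^0.75 table, reduced windows, linearly decaying learning rate).
  Defaults: 256 dimensions, window 5, min count 10.
* **doc2vec** — distributed bag-of-words paragraph vectors: one trainable
  vector per document optimised to predict its tokens under negative
  sampling. Defaults: 192 dimensions. Unseen documents are inferred by
  gradient steps against the frozen output layer under a fixed inference
  seed.

Both are single-threaded with explicit seeds: the same corpus and seed give
bit-identical vectors, which the determinism tests assert. Pipelines
default to 10 epochs at learning rate 0.05 — ward-scale corpora (a few
thousand short documents) need more passes and a hotter rate than the
single-digit epochs conventional for web-scale text; the stand-alone
trainers keep the conventional 0.025 default. Pre-trained vectors can be
loaded from the standard `vocab_size dimension` text format instead.

Classifier input is produced by `represent()`:

* `mean_vector` — unweighted mean of in-vocabulary token vectors, for all
  classical classifiers. Mean pooling is the minimal convention when no
  pooling rule is prescribed; it is permutation-invariant, and a record
  with no known token maps to the zero vector with a warning rather than
  an error.
* `index_sequence` — 1-based vocabulary indices, 0 for padding/unknown,
  right-padded and truncated keeping the earliest tokens, for the CNN.
  `max_len` defaults to the 95th percentile of training-document lengths:
  long enough for typical records without letting outliers set the input
  width.
* `doc_vector` — paragraph-vector inference (document models only).

## Classifiers

Six families, in multiclass (pattern) and multilabel (element) modes, with
stated hyperparameters where the literature gives them and explicit
recorded defaults where it is silent:

| family  | fixed by the literature        | recorded defaults                  |
|---------|--------------------------------|------------------------------------|
| rf      | 1000 trees                     | ranger defaults otherwise          |
| xgboost | —                              | 100 rounds, depth 6, eta 0.3       |
| svm     | linear kernel                  | cost 1; excluded from multilabel   |
| knn     | —                              | k = 5, Euclidean, vote fractions   |
| mlp     | 6 hidden layers, widths 64–1024| ramp (1024,512,256,128,64,64)      |
| cnn     | embed → conv → max-pool → 2 FC | 128 filters width 3, dense 128     |

The MLP and CNN are compiled implementations (ReLU, Adam, mini-batches of
32, 10% validation split with early stopping, patience 5), seeded and
single-threaded. The CNN's embedding layer is initialised from the trained
word vectors and fine-tuned by default (freezable); the padding row is
pinned to zero. Multilabel mode uses native sigmoid outputs for the
networks and binary relevance (one fit per element) for rf/xgboost/knn; a
label observed at a single value — `lung`, present in every record — gets a
constant-probability stub rather than a degenerate fit. The linear SVM is a
single-output model and is not offered in multilabel mode. Hard labels:
argmax with lexicographic tie-break (multiclass) or probability ≥ 0.5
(multilabel, configurable); the empty predicted set is legal and flows
downstream.

## The hybrid path and its scoring

`diagnose_mbr_rbr()` thresholds the element probabilities and applies the
rule engine per record. Two fallback policies exist:

* `best_overlap` (default) — partial and ambiguous matches resolve to the
  best-overlap rule; mirrors production use, where some diagnosis is
  usually wanted.
* `none` — only exact matches diagnose; everything else stays undiagnosed
  and is *scored as incorrect* (undiagnosed records are never excluded,
  which would inflate accuracy).

Hybrid metrics follow the reporting convention in which **accuracy** is
end-to-end pattern exact-match while **precision/recall/F1** are
support-weighted per-element scores. Element metrics therefore typically
exceed pattern accuracy — one missed element can break a pattern while
barely moving the element scores. The end-to-end recovery check in the test
suite measures the hybrid path under the `none` policy, where pattern
accuracy equals the exact element-recovery rate and this ordering is
near-structural, and evaluates over the held-out split pooled with an
independently generated external test set (mirroring the reference design
of a development set plus an external set); under the rescue fallback a
recovered element error can invert the ordering, which is a property of the
fallback, not of the classifier.

## Evaluation protocol

* Per-class precision/recall/F1 with the 0-convention for empty
  denominators; weighted averages use true-class supports (the
  "average (weighted)" convention), and the weighted identity
  $\bar{F}_1 = \sum_c s_c F_{1,c} / \sum_c s_c$ is asserted to 1e-12
  against a brute-force confusion-matrix oracle.
* Repeated stratified cross-validation: 5 folds × 20 repeats by default
  (100 scores), folds reshuffled each repeat from the seed stream, the
  embedding retrained inside every fold. The 95% CI is the empirical
  2.5/97.5 percentile of the scores — no CI formula is prescribed in the
  source protocol, and percentiles are distribution-free; a
  normal-approximation option exists. Test runs use reduced shapes
  (3 folds × 2 repeats on a few hundred records) to keep the suite fast;
  the protocol is identical.
* The corpus comparison trains the identical pipeline twice on one frozen
  split — variant 1 vs variant 2 — with identical seeds, so the arms
  differ only by the diagnosis token. The comparison is run at the
  generator's default noise (0.25) with sparse per-element token draws
  (mean 2): the contrast is only informative off the accuracy ceiling,
  where the token has headroom to help. With an uninformative
  disease-conditional table the paired delta is expected to be small.

## Accuracy-scaling analysis

`run_scaling_grid()` reproduces the sample-size experiment: per column a
random subset of `n_classes` patterns is fixed (seeded per column, logged
in the grid), and per cell a balanced corpus of `per_class_n` records per
pattern is generated, split 4:1 and scored once — one train/test split per
cell, matching the one-number-per-cell reporting convention (repeated
splits are a configuration away). `first_crossing()` finds the smallest
size reaching a threshold per column, reporting never-crossing columns as
censored; `fit_size_vs_classes()` regresses crossing size on class count by
OLS with the standard t-test p-value, requiring ≥ 3 non-censored points.

Refitting the published accuracy grid with this crossing-then-OLS procedure
gives coefficients in the vicinity of, but not identical to, the published
regression lines; the published fits evidently used interpolation or
unprinted granularity, so they are treated as context rather than as
reproduction targets. On synthetic crossings with known truth (slope 35,
noise sd 20, n = 9) the procedure recovers the slope, which is what the
acceptance checks assert.

## Numerical and degenerate-input choices

* All stochastic stages take explicit integer seeds; library backends run
  single-threaded. Derived child seeds keep the generator, split, embedding
  and classifier streams independent.
* Probability tables must row-sum to 1 within 1e-9; multiclass probability
  vectors are renormalised and checked to 1e-6.
* Ties: rule matching by priority; argmax by lexicographic label order;
  k-NN distance ties by training index.
* Degenerate inputs: empty record sets produce empty outputs; all-OOV
  records produce zero-vector representations (flagged) rather than
  errors; empty predicted element sets map to "undiagnosed"; a truncated
  JSONL line errors with its line number.
* Test and acceptance runs use desk-scale shapes chosen for the package:
  2,000-record corpora, 32-dimensional embeddings, and a 1,000-record
  external set. The pipeline is structurally identical at the published
  defaults (256/192 dimensions); only cost changes.

## Known limitations

* The rule table's wheezing decompositions and the disease-to-pattern
  table are editorial/synthetic; both are designed to be replaced by
  authoritative clinical tables.
* The generator's independence assumptions (tokens i.i.d. within element,
  noise independent of class) make the synthetic task easier than clinical
  text; accuracies on synthetic data are pipeline diagnostics, not
  clinical claims.
* Doc2vec inference is stochastic-by-seed; two different inference seeds
  give different (nearby) vectors, which is inherent to the method.
* No calibrated probabilities are attempted for the multilabel threshold;
  0.5 is a convention, configurable per pipeline.
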