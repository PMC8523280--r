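---
title: "Predicting membrane protein types from domain embeddings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting membrane protein types from domain embeddings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptype)
```

## The problem

Human membrane proteins are classified into six types (GPI-anchor,
lipid-anchor, multipass, peripheral, single-pass type I, single-pass
type II), and a protein may hold one to three of them simultaneously — in
the reference human dataset about 97% of proteins carry a single type, a
few dozen carry two and a handful carry three. Assigning types is therefore
a *multilabel* classification problem. The predictive signal used here is
the protein's functional-domain annotation: the set of InterPro IPR terms
(or any comparable term vocabulary — GO terms, pathway identifiers) recorded
for the protein.

`mptype` implements the full pipeline: domain-term embeddings, protein
featurization, RAKEL and Binary Relevance ensembles over pluggable base
classifiers, the four standard multilabel measurements under tenfold
cross-validation, grid search, and a synthetic data generator that makes the
whole chain testable offline.

## Feature model

### Domains as words

Each protein's term list is treated as a sentence over an opaque token
vocabulary, and term vectors are learned with a word2vec-style shallow
network: CBOW (default) or skip-gram, optimised by negative sampling with a
per-position dynamically shrunk context window and a linearly decaying
learning rate. The trainer is implemented natively (C++), runs
single-threaded and uses its own linear congruential generator, so a given
corpus, hyperparameter set and seed reproduce vectors bit-for-bit on any
platform — a property the test suite asserts.

The assumption behind the sentence metaphor is co-occurrence: domains that
appear on the same proteins end up with similar vectors, so proteins sharing
domain context end up near each other after averaging. Domain sets are
unordered, which has two consequences for the defaults:

* **Sentence token order** defaults to lexicographic (`build_corpus()`),
  so the corpus — and hence the embedding — does not depend on annotation
  file row order. `"file-order"` is available when the input order is
  meaningful.
* **Window**: the conventional window of 5 is kept as the default, but
  because truncating an unordered set at distance 5 is arbitrary,
  `window = "max"` widens the context to whole sentences.

### Hyperparameters

| parameter | default | rationale |
|---|---|---|
| `architecture` | CBOW | conventional default for this corpus size |
| `dimension` | 100 | grid 50–500 (step 50) is the studied range; 350 won on the real data |
| `window` | 5 | conventional default; `"max"` covers whole sentences |
| `negative` | 5 | negative samples per positive update |
| `epochs` | 5 | passes over the corpus |
| `alpha` → `min_alpha` | 0.025 → 1e-4 | linear decay over all updates |
| `min_count` | 1 | domain sentences are short and rare domains are informative; the common default of 5 would silently zero out proteins whose only terms are rare |
| `sample` | 0 (off) | frequent-word subsampling assumes a natural-language frequency distribution; in a vocabulary of at most a few thousand terms every term exceeds the usual 1e-3 relative-frequency threshold and subsampling would discard most of an already short corpus |

All settings are recorded in the returned `embedding_table` so a feature
matrix can always be traced to its training configuration.

### Protein featurization

A protein's feature vector is the arithmetic mean of its terms' vectors
(`protein_vectors()`); a protein annotated with three terms gets the average
of those three vectors. Terms outside the embedding vocabulary are skipped;
a protein with no in-vocabulary terms receives the zero vector and a
warning rather than being dropped — exclusion of proteins without domain
information is a dataset-construction step (`filter_annotated()`), not a
featurization side effect. The one-hot encoding (`one_hot_encode()`) is the
baseline: one binary column per vocabulary term.

Embeddings are trained once on the full annotation corpus, not re-trained
inside each cross-validation fold. The corpus carries no type labels, so
this does not leak label information into held-out folds; it also mirrors
how such embeddings are trained in practice (on all annotated proteins, a
superset of the labelled study set).

## RAKEL

Given *l* labels, `rakel()` draws `m_subsets` random label subsets of size
`k` and trains one label-powerset classifier per subset: a training sample's
class is its label set intersected with the subset (possibly empty), encoded
as a single categorical class. Prediction tallies, for each label, the
proportion of classifiers *involving* that label which predict a class
containing it, and assigns the label when the proportion strictly exceeds
the threshold (default 0.5).

Decisions worth calling out:

* **Strict inequality at the threshold.** A vote proportion of exactly 0.5
  yields a *negative* prediction. This matters whenever a label is covered
  by an even number of classifiers (e.g. votes of 2/4); the convention is
  applied consistently and is asserted by a hand-counted test example.
* **Subset sampling.** While `choose(l, k) >= m_subsets`, subsets are
  sampled without replacement (all distinct). When fewer distinct subsets
  exist — notably the k = l configuration, where only one subset exists —
  sampling falls back to with-replacement draws and says so. Duplicate
  subsets are still useful with a stochastic base classifier: per-model
  seeds (`base$seed + model index`) decorrelate them through the base
  learner's own randomness, random-forest resampling in particular.
* **Empty predictions are returned as-is.** No argmax fallback forces a
  label; the count of empty predicted sets is attached as the `n_empty`
  attribute so callers can report it.
* **Unseen powerset classes.** Base classifiers can only predict classes
  observed in training; a label combination absent from the training fold
  is simply never predictable in that model — the standard label-powerset
  semantics.
* **Degenerate subsets.** If all training samples collapse to one powerset
  class, that model becomes a constant predictor (with a message), not an
  error.

With k = l and one subset, RAKEL reduces exactly to a single label-powerset
classifier; with k = 1 and one subset per label its votes reduce to Binary
Relevance decisions. Both reductions, and equivalence with brute-force
per-label vote counting over all small configurations (l ≤ 4, k ≤ l,
m ≤ 6), are asserted in the test suite using an exact-recall base
classifier.

### Base classifiers

The contract is minimal — fit(features, classes), predict(features) →
classes — and satisfied by `randomForest` (random forest; `trees` from the
studied grid 100–500) and `e1071::svm` (polynomial kernel with cost and
exponent grids 1–4; RBF kernel with gamma in 0.01–0.05). SVMs are called
with `scale = FALSE`: one-hot and averaged-embedding features can contain
zero-variance columns, which internal scaling would turn into NaNs. Two
additional bases exist for verification: `"memorize"` (exact recall of
training rows, majority class otherwise) and `"majority"` (constant). The
RAKEL and Binary Relevance ensemble logic is native to this package; only
the single-label learners are delegated.

## Evaluation

`kfold_indices()` divides samples randomly into folds whose sizes differ by
at most one; there is no stratification, matching a plain "randomly and
equally divides" protocol. `cross_validate()` trains on nine folds, predicts
the tenth, pools all out-of-fold predictions and computes one
`metrics_record` over the pooled set — each sample is predicted exactly
once, so the measurements are single sums over n, not averages of per-fold
values. The four measurements are exact match, Jaccard accuracy, hamming
loss (symmetric difference divided by the label count, 6 in the membrane
problem) and their product-form integrated score, the model-selection
criterion.

One definitional edge case: the Jaccard term for a sample whose true and
predicted sets are both empty is 0/0. It is defined here as 1 — a perfectly
predicted empty set should not be penalised. The case cannot arise with
membrane-protein truth sets (every protein has a type) but can with empty
*predictions* against empty subsets in synthetic stress tests.

`grid_search()` evaluates a list of configurations with a common seed (same
fold assignments) and returns the argmax of integrated score, breaking ties
towards simpler models: fewer trees, then smaller dimension, then smaller
k. Ties are practically impossible with real-valued scores from distinct
stochastic models but are fixed deterministically for reproducibility.

Seeds are expanded deterministically: one user seed yields independent
per-stage seeds (fold assignment, per-fold model fitting; within a RAKEL
fit, subset sampling and per-model base seeds), so any stage can be
reproduced in isolation and repeated runs differ only where they should.

## Synthetic data

`generate_dataset()` emulates the structure of the real study: by default
2729 proteins (configurable), six types, label multiplicity drawn from the
real data's proportions (≈97.2% one type, 2.7% two, 0.15% three, capped at
three), types drawn uniformly, 3–8 terms per protein, one disjoint pool of
8 type-specific terms per type plus 20 shared background terms. The
`signal` parameter (default 0.8) is the fraction of a protein's terms drawn
from the union of its own types' pools; the remainder comes from the
background pool.

What the generator does and does not emulate:

* It reproduces the *label structure* (six types, skewed multiplicity) and
  a controllable *annotation-to-type association*. At `signal = 1` with
  disjoint pools the type set is exactly recoverable from the terms, and
  the pipeline's tenfold exact match approaches 1 (tested at n = 500,
  dimension 50, with k = 6, 10 subsets and a 100-tree forest: exact match
  ≥ 0.9). At `signal = 0` features carry no type information and exact
  match collapses to roughly the frequency of the majority label set
  (tested within ±0.1).
* It does **not** emulate the heavy-tailed frequency distribution of real
  IPR terms, domain co-occurrence structure, the real types' very
  imbalanced sizes, or between-type domain sharing. Passing synthetic tests
  therefore demonstrates algorithmic correctness and recoverability under
  controlled signal, not real-data performance: the real study's headline
  numbers (exact match ≈ 0.85 on 2729 proteins) require the actual
  InterPro/UniProt data.

Uniform term counts are used because no per-protein term-count distribution
is available to copy; the range endpoints are configurable.

## Problem sizes in the shipped tests

The test-suite simulations are sized to make their properties sharp while
keeping the whole suite fast: parameter-recovery and noise-collapse runs
use n = 500 proteins at dimension 50, embedding-separation checks use
n = 300 with dimension 16, oracle-equivalence sweeps use n ≤ 12 with l ≤ 4
where exhaustive counting is feasible, and the study-scale bookkeeping test
generates the full 2729-protein label structure (cheap, label-only). A
12-protein frozen fixture (`generate_fixture_small()`) backs the format
round-trip and documentation examples.

## Known limitations

* The embedding trainer is intentionally single-threaded; corpora of a few
  hundred thousand sentences train in minutes, but this is not a
  large-corpus tool.
* Base-classifier probability calibration is out of scope; RAKEL votes are
  proportions of hard predictions, not probabilities.
* Ranking-style multilabel metrics (one-error, coverage, average
  precision) are not implemented; the four measurements above define the
  evaluation.
* `load_ensemble()` restores models saved by the same package version;
  serialized base models are R objects, not a portable format.
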