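# mptype

Multilabel prediction of membrane protein types from functional domain
annotations.

Membrane proteins fall into six types — GPI-anchor, lipid-anchor, multipass,
peripheral, single-pass type I and single-pass type II — and a protein can
belong to up to three of them, so type assignment is a multilabel
classification problem. `mptype` implements a pipeline that predicts these
types from a protein's functional-domain annotations (InterPro IPR terms, or
any opaque term vocabulary such as GO terms or pathway identifiers):

1. **Domains as words, proteins as sentences.** Each protein's set of domain
   terms is treated as a sentence; a word2vec-style embedding (CBOW or
   skip-gram with negative sampling, implemented natively in C++ for
   bit-reproducible single-threaded training) learns a vector for every
   term. A protein is represented by the arithmetic mean of its term
   vectors. A one-hot domain-composition encoding is provided as the
   baseline.
2. **RAKEL (random k-labelsets).** From *l* labels, *m* random subsets of
   size *k* are drawn; each subset induces a label-powerset classifier in
   which every observed subset of the labelset is one categorical class.
   A label is predicted for a query when the proportion of classifiers
   involving that label which vote for it strictly exceeds a threshold
   (default 0.5). Binary Relevance (one independent binary classifier per
   label) is the comparison scheme. Base classifiers are pluggable: random
   forest, SVM with polynomial or RBF kernel, plus exact-recall and
   majority baselines for algorithm verification.
3. **Evaluation.** Tenfold cross-validation pools the out-of-fold
   predictions and scores them with the four standard measurements

   - exact match = (1/n) Σᵢ I(Lᵢ = Lᵢ′)
   - accuracy = (1/n) Σᵢ |Lᵢ ∩ Lᵢ′| / |Lᵢ ∪ Lᵢ′|
   - hamming loss = (1/n) Σᵢ |Lᵢ Δ Lᵢ′| / m
   - integrated score = exact match × accuracy × (1 − hamming loss)

   where Lᵢ and Lᵢ′ are the true and predicted label sets of sample *i* and
   *m* the number of labels. Repeated CV and integrated-score grid search
   select the best configuration.
4. **Synthetic data.** A generator emulates the statistical structure of
   the real study (six types, ~97% single-label multiplicity,
   type-specific domain pools plus uninformative background terms, a
   tunable signal fraction), so the whole pipeline is testable end to end
   without database downloads.

## Worked example

```r
library(mptype)

spec <- synthetic_spec(n_proteins = 500, seed = 1)   # study-like defaults
ds   <- generate_dataset(spec)
summarize_labels(ds$labels)
#> Label summary over 500 proteins, 514 assignments
#> Multiplicity (types per protein -> proteins):
#>   1   2
#> 486  14

emb <- train_domain_embeddings(build_corpus(ds$annotations),
                               dimension = 50, seed = 1)
x   <- protein_vectors(ds$annotations, emb)

cfg <- grid_config(dimension = 50, k = 6, m_subsets = 10,
                   base = base_spec("random_forest", trees = 100))
res <- cross_validate(x, unclass(ds$labels), cfg, seed = 1)
res$record
#> Multilabel evaluation over 500 samples (6 labels)
#>   exact match:      0.972
#>   accuracy:         0.983
#>   hamming loss:     0.006
#>   integrated score: 0.9497
```

With the default signal fraction (0.8 of each protein's terms drawn from its
types' domain pools) the embedding features separate the types almost
perfectly: 97.2% of the 500 synthetic proteins get exactly the right type
set, and the mean per-sample Jaccard overlap between predicted and true type
sets is 0.983. The integrated score multiplies the three measurements into
the single model-selection criterion used by `grid_search()`.

A single fitted ensemble works like any R model object:

```r
fit  <- rakel(x, unclass(ds$labels), k = 6, m_subsets = 10,
              base = base_spec("random_forest", trees = 100), seed = 1)
pred <- predict(fit, x)                 # binary protein x type matrix
prop <- predict(fit, x, type = "votes") # vote proportions in [0, 1]
```

## Command-line pipeline

The same stages are scriptable via the installed front-end
(`system.file("cli", "mptype.R", package = "mptype")`):

```sh
Rscript mptype.R simulate  --out data --n 500 --seed 1
Rscript mptype.R embed     --annotations data/annotations.tsv --out emb.txt --dimension 50
Rscript mptype.R featurize --annotations data/annotations.tsv --embeddings emb.txt --out features.tsv
Rscript mptype.R cv        --features features.tsv --labels data/labels.tsv --out cv --m 10 --trees 100
```

Every command writes a JSON manifest (inputs, options, configuration hash,
package version) next to its outputs, so identical reruns are verifiable.

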