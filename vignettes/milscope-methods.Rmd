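---
title: "Assessing Meaning in Life from microblog text: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing Meaning in Life from microblog text: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milscope)
```

# Overview

milscope implements a three-part pipeline for assessing Meaning in Life
(MIL) from short social-media posts. MIL is usually measured along two
components: the *presence of meaning* (POM; the degree to which life is
currently experienced as meaningful) and the *search for meaning* (SFM;
the degree to which meaning is actively sought). The pipeline takes a raw
post collection and produces, in order:

1. a cleaned, seed-screened, consensus-annotated, augmentation-expanded
   labeled corpus (`clean_corpus()`, `screen_seeds()`,
   `merge_consensus()`, `augment_to_target()`);
2. post-level predictions from a three-stage classifier cascade —
   relevance to MIL, then SFM level and POM level for relevant posts
   (`train_model()`, `predict_cascade()`);
3. MIL-associated factor terms extracted from semantic dependency graphs
   and mapped to closed-vocabulary lexicon categories
   (`build_graph()`, `reason_expansion()`, `factor_assignments()`);
4. psychometric networks of those factors in eight POM-by-SFM subgroups,
   with expected-influence centrality, Louvain communities, and
   permutation-based network comparisons (`estimate_network()`,
   `expected_influence()`, `louvain_communities()`,
   `compare_networks()`).

Every stage consumes and produces plain tabular data, so stages can be
used independently.

# Corpus, annotation, and augmentation

**Cleaning.** Two rules, applied in the order noise-then-dedup: a post is
dropped if its normalized text contains any term of a user-supplied noise
list (advertisement phrases, `http` link markers, platform hashtag
boilerplate); among survivors, posts with identical normalized text
strictly longer than `dedup_min_chars` (default 10) characters keep only
their first occurrence. The strict inequality means a duplicated
10-character post is retained. Normalization is Unicode NFKC plus
lower-casing; Chinese has no case, but Latin-token test fixtures do.
The cleaning report conserves counts (input = noise + duplicates +
retained) and cleaning is idempotent.

**Seed screening** retains exactly the posts containing at least one seed
keyword as a substring. An empty seed lexicon is an error rather than a
silent empty result.

**Consensus labels.** Each post is annotated by a fixed number of
annotators (default 2) on three binary tasks with an unable-to-judge
option. Merging applies UNABLE precedence first (any UNABLE annotator
excludes the post as UNABLE), then unanimity (any disagreement is
INCONSISTENT). This precedence makes the unable and inconsistent
exclusion sets disjoint, which is what makes exclusion accounting additive.
Cohen's kappa is computed on the paired pre-consensus labels; by default
UNABLE is kept as a third category (agreement on the task as it was
performed), with `drop_unable = TRUE` available because either convention
appears in practice. With a degenerate table (expected agreement 1),
kappa is defined as 1 when observed agreement is also 1.

**Augmentation** expands a labeled set to a task-specific target size
with two operations: random deletion of one or two noncritical tokens
(adverbs/intensifiers/particles per a pluggable tagger; a fixed
function-word list by default) and synonym replacement gated by embedding
cosine similarity strictly greater than 0.80. The shipped embedding
stand-in is a deterministic character-trigram hashing vectorizer
(`ngram_embedding()`), under which morphological near-variants pass the
gate and unrelated words do not; a sentence-embedding model can be
plugged in through the same one-argument interface. Generated items are
allocated to label classes proportionally to the input class mix
(largest-remainder rounding) because the post-augmentation class
composition is otherwise unconstrained; operations alternate
deletion/replacement round-robin over source posts. Labels are conserved
by construction, every item carries `source_id` and `aug_op` provenance,
and a 10% sample of augmented items is emitted for manual review — the
manual-discard step is deliberately left manual.

# The classifier cascade

Each stage shares one architecture. An encoder adapter maps a tokenized
post to one summary (CLS) vector per transformer block; the L block
vectors are stacked into an L-by-d matrix, so shallow-to-deep semantics
appear as rows. Convolution filters of window sizes 3, 4 and 5 (defaults;
each window spans the full embedding width) slide over the block axis,
giving feature maps of length L − w + 1 which are ReLU-activated,
max-pooled to one scalar per filter, concatenated across window sizes,
and classified by a dense softmax layer. Defaults follow the production
configuration: L = 12, d = 768, m = 128 filters per window, sequence
length 164, batch size 32, learning rate 2e-5, Adam, early stopping
after 1,000 update steps without validation improvement, class-weighted
cross-entropy with w_c = n/(K·n_c). The filter count m is not fixed by
the architecture description, so it is configurable with 128 as a
conventional default.

Two protocol details were genuinely open and resolved as follows:

* *8:1:1 split vs 10-fold cross-validation.* The 10% test split is held
  out once; 10-fold cross-validation runs over the remaining 90% for
  robust evaluation; the final model is refit on the full 90% with an
  internal validation split (the validation share of the 8:1:1 ratio)
  for early stopping, and evaluated once on the held-out test set. When
  the validation share is zero (desk-scale overfitting checks), early
  stopping tracks the training loss.
* *Encoder sharing.* The three stages train independent heads (and, in a
  production setting, independent fine-tuned encoder copies); nothing in
  the cascade requires shared parameters beyond a common tokenizer.

The pretrained 12-block Chinese encoder is an adapter boundary: tests and
examples use `toy_encoder()`, a frozen, randomly initialized, seeded
4-block encoder with d = 32 whose mean-pooled token embeddings pass
through tanh blocks. This keeps the package runnable without downloads
while exercising every line of the head and training code. Exact decision
ties at probability 0.5 resolve to the positive class (RELATED / HIGH).

Cascade semantics are a hard invariant: the SFM and POM models run only
on posts the relevance model labels RELATED, and gated posts carry NA
levels. Validation utilities implement stratified quadrant sampling (with
either a fraction-plus-minimum rule or explicit per-stratum counts),
joint-label accuracy (both levels simultaneously correct), and the
per-user correlation between predicted MIL-related proportion and an
external meaning score (Pearson, two-sided).

# Semantic graphs and factor extraction

The extraction stage consumes role triples `<(wordA, wordB), Role>` from
any external semantic-role parser (the reference pipeline uses a Chinese
neural parser; parsing itself is out of scope). Nine roles are
recognized: REAS (reason), AGT, EXP, PAT, CONT, DATV, LINK, TIME, LOC.
Texts split into linguistic units at terminal punctuation (`.`, `!`, `?`
and CJK equivalents), with trailing text forming a final unit.

The graph has one node per normalized surface form (no stemming; stop
words and pure punctuation excluded), undirected edges weighted by corpus
link counts with the role set retained, self-links removed, and edges
below `min_edge_weight` pruned (default 2 — "very low frequency" is
otherwise unquantified). Edges are stored undirected because the
expansion is a co-occurrence spread; the original direction survives in
the role annotation of the triple files.

Factor candidates come from a reason-anchored breadth-first expansion:
layer 0 is the endpoints of REAS edges; layer k holds nodes linked by any
role to layer k − 1 and not yet assigned, up to `max_layers = 3`. A node
reachable at several depths takes the smallest, and the result is
invariant to triple input order. Units without a REAS anchor are flagged
unextractable — on real corpora most units have no reason structure, so
extraction yield well below 100% is expected behavior, not failure.
Candidates are ordered by (layer, corpus frequency descending, term).

Terms then map to a category lexicon: each candidate increments every
category containing it (multi-category words inflate counts by design),
Top-k categories are ranked count-descending with lexicographic
tie-break, and per-subgroup category proportions are the percentage of a
subgroup's posts hitting each category (multi-label rows; no sum
constraint). The proprietary LIWC Chinese dictionary is not
redistributable, so the lexicon is pluggable via two TSV files; a
52-category, 9-group toy lexicon over Latin tokens ships for tests and
examples. Substantive category-level results therefore depend on the
dictionary the user supplies.

# Subgroup networks

Posts labeled on both dimensions split into four marginal sub-datasets
(S1 = high SFM, S0, P1, P0) and four quadrants (S1P1, S1P0, S0P1, S0P0);
marginals pool their quadrants, so each post sits in one quadrant and two
marginals. Node values are per-post category counts (not binarized;
the document-by-category encoding is otherwise unspecified, and counts
retain more information).

**Estimation.** Pearson correlations feed a graphical lasso
(block coordinate descent, implemented in compiled code, penalizing
off-diagonal entries only, so fitted variances equal sample variances)
over a 100-point log-spaced penalty grid from the empty-graph penalty
down to 1% of it. The penalty is selected by the extended Bayesian
information criterion,

$$EBIC(\lambda) = -2\ell + E\log n + 4E\gamma\log p,\qquad
\ell = \tfrac{n}{2}(\log\det\Theta - \mathrm{tr}(S\Theta)),$$

with γ = 0.5 (the conventional default) and E the number of surviving
upper-triangle edges. Edges are reported as regularized partial
correlations. By default, partial correlations below the consistency
threshold log(p(p−1)/2)/√n are set to zero along the path before edge
counting: without this step, the EBIC-optimal penalty admits weak
spurious edges as n grows, and planted sparse structures are no longer
recovered cleanly. The solver is validated in the test suite against its
Karush–Kuhn–Tucker optimality conditions and against planted precision
matrices (chain structure, p = 10, n = 2000, 20 replicates: mean edge
precision and recall are required to reach at least 0.9). Degenerate
inputs are handled explicitly: fewer than 3 rows is an error,
zero-variance columns are dropped with a warning, and a singular
correlation matrix receives a small ridge adjustment with a warning.

**Description.** Expected influence is the signed one-step sum
EI_i = Σ_j w_ij (reported raw and z-standardized); density is
2E/(N(N−1)); modularity follows the standard weighted Newman definition.
Community detection uses the Louvain method on absolute edge weights
(signed modularity is not well defined, and taking magnitudes is the
usual convention for partial-correlation networks). Determinism and
quality are obtained by seeded restarts: half the restarts run the
aggregation-based Louvain pass under a random vertex permutation, half
start from the singleton partition, and every restart is finished by
greedy single-node moves plus community merges repeated until modularity
stops improving; the best partition over restarts is returned. On small
graphs this reliably attains the exhaustive-search maximum (verified in
the tests against brute-force enumeration up to 8 nodes).

**Comparison.** Two networks are compared on global strength
(|Σ|w|_A − Σ|w|_B|) and maximum edge-weight difference, with a
permutation null built by reshuffling the post-to-group assignment and
re-estimating both networks; p-values use the add-one estimator
(1 + exceedances)/(1 + n_perm) with 1,000 permutations by default (the
test itself is named in the source methodology; the count and estimator
are this package's choices).

# The synthetic-data generator

`gen_posts()` and friends define the desk-scale study conditions: short
whitespace-tokenized pseudo-posts in which every MIL-related post carries
a seed term and SFM/POM levels inject class-marker tokens with
probability `margin` (1 by default, giving linearly separable classes);
two-annotator label tables with independent flip and UNABLE rates;
per-post role-triple files where a configurable fraction of units gets a
REAS-anchored chain of depth up to 4; and multivariate Gaussian samples
from planted sparse precision matrices (chain, block, or empty) with the
true edge set returned for recovery scoring. All generators are pure
functions of (configuration, seed).

What passing tests on these fixtures shows — and does not show: they
verify the mechanics (gating, accounting conservation, recovery of
planted structure, agreement algebra) under clean, separable,
low-dimensional conditions. They do not show that a random toy encoder
measures MIL in real Chinese microblogs, that the toy lexicon
approximates a licensed dictionary, or that real posts have the triple
structures the generator plants. The real-language path differs exactly
at the adapter boundaries: tokenizer/encoder, semantic-role parser, and
dictionary.

# Problem sizes and reproducibility

The test suite and the acceptance script run at desk scale by design:
cascade checks use 40–200 posts with the 4-block toy encoder and a few
hundred optimization steps; network recovery uses p = 10, n = 2000 with
20 replicates; null calibration uses 20 data splits with 200
permutations each; Louvain is verified against exhaustive enumeration on
graphs of up to 8 nodes. `scripts/acceptance.R --seed S --out f.json`
recomputes the published dataset-accounting arithmetic from its printed
inputs and all desk-scale measurements from scratch; every random draw
derives from the single `--seed`.

# Known limitations

* The package ships no pretrained encoder, no licensed dictionary, and
  no real corpus; headline classification accuracies from the source
  study are properties of those assets and are not reproduced here.
* Fleiss-style agreement for more than two raters is not implemented;
  consensus generalizes to n raters but kappa is pairwise.
* Bootstrapped edge-stability intervals for the networks are out of
  scope, as is any figure rendering (numeric tables only).
* Marginal subnetworks pool their quadrants; if the source design
  estimated them on separate samples, pooled estimates will differ.
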