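---
title: "Classifying participation-focused caregiver strategies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying participation-focused caregiver strategies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratclass)
```

## The classification problem

Caregivers of children and youth with disabilities, asked how they support
their child's participation in everyday activities, answer in short free
text: a median strategy is about seven words. Each record carries one of
five labels. One class is extrinsic — the strategy changes the child's
**environment or context** (`ENV`): schedules, equipment, quiet rooms,
helpers. Three classes are intrinsic — the strategy works on the child's
**sense of self** (`SELF`), **preferences** (`PREF`) or **activity
competence** (`COMP`). The fifth class (`NONSTRAT`) collects records that
describe no strategy at all ("none", "no strategies needed").

The label structure motivates four tasks: (1) strategy vs non-strategy
over all records, (2) extrinsic vs intrinsic over strategies only,
(3) the three intrinsic constructs over intrinsic strategies only, and
(4) the flat five-class problem. Tasks 1–3 also compose into a cascade:
a record stopped at stage 1 is `NONSTRAT`, a stage-2 extrinsic decision
yields `ENV`, and only the remainder reaches stage 3. Class imbalance is
severe (roughly 62% `ENV`, 5% `PREF`), which is why all evaluation is
macro-averaged: each gold class contributes its precision, recall and
F1 = 2PR/(P+R) with equal weight, and a class never predicted still
contributes an F1 of zero.

## The synthetic corpus: what it emulates, and what it does not

The original study corpus is not public; only aggregates were published.
The generator in `corpus_spec()`/`generate_corpus()` is calibrated to
exactly those aggregates and invents the rest:

* **Published, fixed by default**: per-class record counts
  975/307/84/104/106 (total 1,576) and per-class mean token lengths
  7.20/6.60/7.64/5.85/5.21.
* **Calibration choices** (no published counterpart; chosen once):
  shared vocabulary of 2,000 types topped by ~150 common everyday words,
  40 keywords per class, discriminability 0.8, all five noise rates 0.05,
  refusal probability 0.3, default seed 42. With these defaults a
  generated corpus has a vocabulary in the low two-thousands, in line
  with the published figure of 2,337 types over 10,804 tokens, and is
  learnable but not trivial.

Record lengths are shifted-Poisson, `1 + Poisson(mean - 1)`, which is
positive, mean-matched and needs no variance parameter (none was
published). Because `NONSTRAT` refusals are fixed short templates
(1–4 tokens), non-refusal `NONSTRAT` lengths are drawn with a compensated
mean so the class-level expectation still equals 5.21. Content tokens come
from the record's class keyword pool with probability equal to
`discriminability`, otherwise from the shared vocabulary; at
`discriminability = 0` the keyword pools are never consulted, making the
class-conditional content distributions identical by construction (a
property the test suite asserts). Surface noise — random single-edit
misspellings, capitalized personal names from a fixed gazetteer, digit
tokens, attached punctuation, stopwords — is injected per token at the
configured rates.

What the generator does **not** emulate: real lexical topicality and
discourse (keywords are drawn independently, there is no syntax beyond
what the rule taggers can see), annotator disagreement (gold labels are
exact by construction), setting covariates (home/school/community), and
the long tail of real vocabulary growth. Passing the recovery tests
therefore shows that the pipeline's machinery is correct and that the
planted class signal is recoverable; it does not certify the accuracy
levels reachable on real caregiver text, and the published headline
accuracies of the original study (94.92/85.71/83.84/78.10) are explicitly
out of reach of desk-scale reproduction because the data are private.

## Preprocessing

Six deterministic, order-preserving transforms: (1) lowercasing,
(2) spelling correction, (3) entity placeholders, (4) punctuation
removal, (5) stopword removal, then lemmatization.

Design points where the procedure was genuinely open:

* **Step order.** Entity replacement runs before punctuation removal so
  the bracketed placeholders `[name]`/`[number]` survive; a placeholder
  with attached punctuation ("`[name],`") is reduced to the bare
  placeholder at step 4.
* **Correction dictionary.** The union of a bundled ~500-word list
  (keyword pools, common words, stopwords) and the corpus vocabulary,
  augmented with the lemmas of every dictionary word. The augmentation
  makes the pipeline idempotent on its own detokenized output, which the
  suite asserts. Tokens already valid, placeholders, digit-bearing tokens
  and gazetteer names are exempt. The edit-distance bound is 2; ties are
  broken by higher corpus frequency, then lexicographically.
* **Stopwords.** A fixed 127-word English list is shipped rather than
  deferring to an external library, so results are byte-stable.
* **Lemmatization.** A 64-row irregular-form table plus suffix rules for
  `-s/-es/-ies`, `-ing`, `-ed` with consonant undoubling and
  e-restoration validated against the dictionary; stems shorter than
  three characters are rejected ("need" is not stripped to "ne").
  Like any rule stemmer it has quirks on out-of-dictionary words; they
  are harmless for classification because they are applied consistently.
* **Empty outputs.** A record that loses every token (pure punctuation,
  all stopwords) is retained with an `empty` flag so record counts
  reconcile; it is never an error.

Personal-name recognition in the original pipeline involved manual
checking, which cannot be automated; the bundled recognizer (gazetteer +
digit regex) is a documented stand-in.

## Representations and feature blocks

**TF-IDF.** Vocabulary is capped at the 5,000 most frequent training
terms (frequency ties broken lexicographically — the cap is read as a
frequency ranking, not a weight ranking); `idf(t) = ln((1+N)/(1+df(t))) + 1`;
raw term frequency times idf; L2 normalization; out-of-vocabulary tokens
ignored. The dialect string is recorded in the fitted model.

**Paragraph vectors.** Distributed-memory training with negative sampling
(5 negatives, unigram^0.75 distribution), window 5, dim 100, minimum
count 1, exactly 30 epochs, learning rate decaying linearly 0.025 → 1e-4.
Implemented in plain R, single-threaded and fully seeded: the published
hyperparameters (dim/min count/epochs) are kept, the remaining settings
follow common word2vec practice. Unseen documents are embedded by
gradient inference against frozen word matrices, each document under its
own reseeded stream, so inference depends only on tokens, model and seed.
At package scale (a few thousand token positions in the tests) training
takes seconds; the implementation favours determinism and auditability
over raw speed.

**PMI likely word sets.** For each class, the `k = 20` words with the
highest `PMI(w, c) = ln p(w,c) / (p(w) p(c))` among words seen at least
twice, with additive smoothing `alpha = 0.5` applied to the joint counts
and marginals taken from the smoothed joint (so they stay consistent).
Natural log: the base only rescales a ranking. The feature block is one
count per class (how many tokens fall in that class's set); counts were
chosen over indicators because they preserve repetition information in
these short texts, and an indicator encoding remains available. Sets are
built from training folds only — the builder's interface accepts nothing
else.

**Syntactic counts.** Fixed-length count vectors over the 36 Penn
Treebank tags and 37 universal dependency relations. The bundled tagger
is a deterministic rule system (placeholders, digits, a closed-class
lexicon, a base-verb lexicon, suffix rules, default NN); the bundled
"parser" roots the first verb and assigns shallow relations from the
tags. Both are pluggable — a statistical tagger can be substituted, and
any emitted tag outside the fixed sets is an error — but the bundled
rules keep the package download-free and its tests exact.

**Concept features.** The 71-concept lexicon assigns a concept whenever
one of its trigger keywords matches a preprocessed token; assigned
concept names are tokenized and encoded with the active base
representation fitted on the concept-name vocabulary. The original
concept mapping was a manual expert process; trigger matching is the
automated stand-in and a known fidelity gap.

Feature vectors concatenate `[base | pos | dep | pmi | concept]`, enabled
blocks only, with a recorded segment layout that is identical for every
document under one configuration.

## Classifiers

* **Majority**: stores the modal training label; ties, like all argmax
  ties in the package, break to the lexicographically smallest label.
* **Naive Bayes**: multinomial event model over token counts with
  Laplace add-one smoothing; unknown test tokens are deleted; an
  all-unknown document falls back to the priors. Per-class likelihoods
  normalize to 1 over the training vocabulary (asserted at 1e-9).
* **Logistic regression**: softmax cross-entropy (sigmoid being its
  two-class special case) with penalty `lambda/(2n)·||W||²`, minimized by
  mini-batch SGD — batch 32, learning rate `0.1/sqrt(t)`, at most 100
  epochs (the published "max_iter = 100" read as an epoch cap), early
  stop when the full-data loss improves by less than 1e-4. Batch size,
  rate and tolerance are package choices; nothing was published beyond
  the loss, the optimizer family and the cap.
* **Linear SVM**: primal `½‖w‖² + C·Σ hinge` with the bias as an
  augmented (hence regularized) feature, solved by cyclic dual coordinate
  descent — deterministic, no RNG, converges to the optimum (the test
  suite checks the objective against a dense grid search and the
  separating threshold against closed forms). Multiclass is one-vs-rest,
  since only a binary formulation was specified. `C = 1` and
  `lambda = 1` are defaults, exposed for tuning; whether the original
  study tuned them during cross-validation is unknown.

## Splitting, selection and evaluation

The 80/20 split is stratified with **largest-remainder allocation**:
per-stratum test counts are the floors of `0.2 × size`, then the largest
fractional remainders receive +1 until the rounded global total is
reached. This rule was chosen because it is the unique simple allocation
that reproduces every published test denominator simultaneously
(21 non-strategy, 99 intrinsic, 17 preferences, and the task totals 315
and 294) — and with them the published baseline accuracies 294/315 =
93.33%, 195/294 = 66.33%, 61/99 = 61.62% and 195/315 = 61.90%. The last
fraction appears in the original results table as 61.91, one unit above
its two-decimal rounding; the discrepancy is a double-rounding artifact
(61.9048 → 61.905 → 61.91), and the package reports the exact fraction.

Model selection uses repeated stratified 10-fold cross-validation on the
training set, 3 repeats by default ("repeated" was published without a
count), selecting by mean accuracy with macro-F1 as tie-break and
candidate order as final tie-break. All feature fitting — TF-IDF
vocabulary, embeddings, PMI sets, concept encoders — happens inside each
training fold; the suite asserts that deleting the held-out records
changes no fitted parameter. When the smallest stratum is smaller than
the fold count, folds are reduced with a warning. A single candidate is
returned without fold evaluation.

Accuracy gains over the baseline are reported as absolute
percentage-point differences, matching the original report style.

## Problem sizes and runtime choices

The test suite and the acceptance script exercise the pipeline at the
published corpus size (1,576 records) for the parameter-recovery checks —
three generator seeds, four tasks, linear SVM over TF-IDF — and at
50–300 records for unit and property tests; oracle suites run 50–200
randomized cases each under fixed seeds. These sizes were chosen so the
whole suite completes in a few minutes while still covering the full
corpus scale where it matters. Embedding-based experiments are exercised
at small scale only; the TF-IDF route is the default throughout, mirroring
the representation that performed best in the original study.

## Known limitations

* The generator's independence assumptions make synthetic text easier
  than real caregiver text at the same discriminability; recovery scores
  (macro-F1 ≈ 0.98 on task 3 at the defaults) should be read as
  machinery checks, not performance claims.
* The rule-based tagger and shallow parser are crude approximations of
  statistical models; their feature blocks are correspondingly weak
  signals.
* Trigger-based concept assignment cannot capture the judgment in the
  original manual mapping.
* No contextual (transformer) representations and no significance
  testing between models — both out of scope by design.
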