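---
title: "Hybrid entity extraction and terminology code mapping for pathology reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid entity extraction and terminology code mapping for pathology reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathocode)
```

## The problem

Anatomopathological reports are narrative documents: a specimen description,
the techniques applied to it, and the diagnostic conclusion are written as
free text. Making them computable requires two steps:

1. **Entity extraction** — locate typed spans in the text: *sample type*
   (the specimen), *test performed* (the histological technique), and
   *finding* (the diagnosis).
2. **Code normalization** — map each mention to standard terminologies:
   clinical concepts (SNOMED CT-style), laboratory observations
   (LOINC-style) and disease classification (ICD-11-style). Specimens route
   to the clinical-concept terminology, techniques to the laboratory one,
   and findings to both the clinical and the disease-classification
   terminologies (`route_terminologies()`).

`pathocode` implements a hybrid normalizer: a supervised softmax
classification head over mention embeddings is **fused** with terminology
retrieval — dense (embedding cosine similarity) and sparse (Okapi BM25) —
and a confidence-based fallback lets retrieval override the classifier when
its maximum probability is low. The package also contains the complete
statistical harness used to compare system variants, and a seeded synthetic
corpus generator so that every claim in the test suite is reproducible from
code alone.

## Models and procedures

### Token tagging

Sentences are word-tokenized (Unicode-aware, punctuation kept as tokens)
and labelled with a 7-label BIO scheme (`O` plus `B-`/`I-` per entity
type). The reference tagger is a multinomial softmax head over *windowed
hashing features*: each token's feature row concatenates the
character-n-gram hashing embeddings of the token and its two neighbours on
each side (zero padding at edges). It is trained by minibatch AdamW on the
masked cross-entropy objective

$$L = -\textstyle\sum_i y_i \log \hat y_i,$$

with label id $-100$ marking positions excluded from both loss and metrics
(the same convention used when word labels are re-aligned to subword
tokenizations; `align_labels()` implements the first-subword strategy by
default, with an all-subwords mode). Decoding is argmax per token followed
by BIO repair: an `I-t` after `O`, after a different type, or at the start
of a sequence becomes `B-t`.

This windowed head deliberately stands in for a fine-tuned transformer at
desk scale; the `attention()` / `softmax()` / `cross_entropy()` kernels
exist as verifiable reference implementations of the underlying
operations, and the `external_encoder()` adapter lets a transformer-based
sentence or mention encoder plug into every stage unchanged.

### Embeddings

`hash_encoder()` maps text to unit-norm vectors by signed feature hashing
of character 3–5-grams (64–256 dimensions in this package's default
configurations). Two properties matter here: it is *deterministic across
platforms* (integer arithmetic kept exact in doubles, with a
multiplicative scramble so bucket and sign are decorrelated), and it is
*surface-robust*: single-character typos and word reorderings move a
vector only slightly, and French/English morphological cognates
("mélanome" / "melanoma") retain measurable similarity. It does not model
synonymy beyond the character level — an abbreviation like "H&E" shares
almost nothing with "hematoxylin and eosin" — which is exactly the regime
in which the supervised classifier must carry the decision.

### Retrieval

Every concept contributes one index entry per label and per synonym;
a code's score against a query is the **maximum over its entries**
(concatenating synonyms into one document was rejected because it dilutes
matching). Dense search is exact exhaustive cosine over unit-norm rows.
Sparse search is Okapi BM25,

$$\mathrm{score}(q, d) = \sum_{t \in q} \ln\!\Big(\tfrac{N - df_t + 0.5}{df_t + 0.5} + 1\Big)\,
  \frac{tf_{t,d}\,(k_1 + 1)}{tf_{t,d} + k_1 (1 - b + b\,|d|/\overline{|d|})},$$

with $k_1 = 1.5$, $b = 0.75$ and the $+1$ inside the logarithm so idf is
never negative; all three are configurable. Ties in any ranking break to
the lexicographically smaller code, so results are total-order
deterministic.

### Fusion

For a mention with classifier candidate set and retrieval candidate set,
the pool is the union of their codes and the fused score is

$$s(c) = w\,p_{\mathrm{clf}}(c) + (1 - w)\,\mathrm{sim}_{01}(c),$$

where $\mathrm{sim}_{01}$ rescales retrieval scores into $[0,1]$ (cosine
via $(\cos + 1)/2$; BM25 by division by the in-set maximum, since BM25 is
unbounded) and a missing component reads 0. If the classifier's maximum
probability falls below the threshold $\tau$, the retrieval rank-1 code is
returned regardless of the fused scores — this fallback is what handles
codes absent from the classifier's label space. `optimize_fusion()` picks
$(w, \tau)$ by exhaustive grid search ($w \in \{0, 0.1, \dots, 1\}$,
$\tau \in \{0, \dots, 0.9\}$) maximizing mean 5-fold cross-validated
accuracy, folds stratified by code, ties to smaller $\tau$ then smaller
$w$. The two degenerate corners reproduce the baselines exactly: $w = 1,
\tau = 0$ is the classifier alone, $w = 0$ is dense retrieval alone.

A design note on the BM25 baseline: `fuse()` keeps the union-pool
semantics when BM25 candidates are substituted for dense ones, so the
hybrid sparse system can only *fall below* the classifier when the
fallback fires on a misleading BM25 rank-1. A pool-restricted
retrieve-then-rerank architecture (classifier confined to the BM25
candidates) would degrade much further when sparse retrieval is poor; we
chose the union semantics because it makes the fallback rule and the
degenerate corners exact, and we report the pure BM25 system (`sparse`)
alongside the hybrid (`sparse_fusion`) so both readings are visible.

### Per-terminology heads

Each terminology gets an independent single-label softmax head over
mention embeddings (findings therefore receive two independent decisions,
one clinical-concept code and one disease-classification code). Training
follows the standardization protocol: AdamW, at most 10 epochs, early
stopping when a seeded 10% validation split fails to improve for 2
consecutive epochs, with the best-validation weights restored. The
"multi-label" formulation collapses to one code per terminology per
mention because that is what the annotation model provides; a true
multi-label head is a noted extension.

## Statistical evaluation

* `prf()` — per-label precision/recall/F1 from the confusion matrix, with
  unweighted macro averages; zero denominators report 0 with a warning.
  Extraction tables print at 2 decimals, coding tables at 4.
* `error_rates()` — absolute error is the off-diagonal mass of a label's
  gold row; relative error is **absolute / own gold support**. That is the
  only self-consistent definition of a per-label relative error rate, and
  the one this package uses everywhere.
* `bootstrap_ci()` — percentile interval over resampled units; the unit is
  the *report* for tagging metrics and the *mention* for coding metrics.
  Undefined resamples are redrawn, counted and warned about. Default
  10,000 iterations.
* `one_sample_t()` — performance vs a fixed baseline (default 0.5); errors
  on zero-variance samples rather than fabricating a statistic.
* `cohen_kappa()`, `mcc()` — chance-corrected agreement and the
  generalized multiclass Matthews coefficient (covariance form); a
  zero-variance marginal yields MCC 0 with a warning by convention.
* `mcnemar_exact()` — exact binomial test on the discordant-pair counts.
  The default two-sided p is $\min(1, 2\cdot\text{min tail})$; a one-sided
  mode ships as well because with $b = 0$ the one-sided tail halves the
  p-value, and which convention a given report used is often ambiguous.
* `permutation_test()` — paired sign-flip test on the accuracy difference,
  raw-proportion p by default (an add-one smoothed variant is a flag);
  10,000 iterations by default, vectorised in blocks.

Two honesty notes on calibration, both verified analytically in the test
suite's development. First, the exact McNemar test is *conservative*: at
a paired sample of 53 with per-system accuracy near 0.7, its true type-I
error at nominal 0.05 is 0.029, a direct consequence of the discreteness
of the binomial — not an implementation artifact. Second, the sign-flip
permutation test on paired binary outcomes is distributionally the same
test (flipping a concordant pair changes nothing; flipping discordant
pairs is the symmetric binomial), so it inherits the same conservatism.
The two procedures remain what they claim to be — exact-level tests whose
size never exceeds the nominal level.

Multiple-testing correction is deliberately not applied to the paired
comparisons.

## The synthetic corpus generator

`generate_corpus()` emulates the data regime of a single-institution,
French-language pathology corpus coded against standard terminologies,
which is the regime the pipeline is designed for:

* **Entity structure** — 1–5 template sentences per report, each carrying
  exactly one sample-type, one test-performed and one finding mention;
  gold offsets are exact by construction.
* **Vocabulary gap** — every concept has four surface forms (English
  label, English reorder, French label, institution-local French
  phrasing). The terminology tables follow real language coverage: the
  clinical-concept table carries English entries only, while the
  laboratory and disease-classification tables include official-style
  French synonyms. The local French phrasing is never in any table, so a
  lexical retriever faces genuine out-of-vocabulary queries.
* **Distractors** — tables also hold concepts that never occur in the
  corpus but share sites, morphologies and technique vocabulary, many for
  the clinical-concept table and few for the laboratory table, mirroring
  how subset sizes differ between real terminologies.
* **Long tail** — concept usage follows a Zipf law (default exponent
  1.2); optionally a configurable fraction of test-partition mentions is
  drawn from codes guaranteed absent from the training block, which is
  the regime in which the retrieval fallback earns its keep.
* **Noise** — half of mentions use a non-canonical form; a fixed
  abbreviation table ("hematoxylin and eosin" → "H&E", and similar)
  fires at rate 0.2 on abbreviable surfaces; single-character typos at
  0.1; case flips at 0.1. All rates are configuration.

What the generator does **not** emulate: real clinical prose (templates
are rigid), annotation disagreement, boundary ambiguity between adjacent
entities, section structure, de-identification artifacts, and true
semantic synonymy unreachable by character similarity. Tests passing on
this corpus therefore demonstrate that the machinery is correct and that
the fusion behaves as designed under a controlled vocabulary gap and long
tail — they do not certify performance on real reports.

## Problem sizes and numerical choices

The default study corpus is 560 reports (40/30/60 corpus concepts per
entity type plus 60/6/140 distractors); the test suite exercises
end-to-end recovery at 500 noise-free reports and a 300-report long-tail
run with 25% unseen test codes, sizes chosen so the whole suite completes
in a few minutes on one CPU. Softmax and attention subtract the row
maximum before exponentiation; cross-entropy uses the natural log with a
$10^{-12}$ probability floor; every stochastic procedure takes an explicit
seed and restores the caller's RNG state, so any two runs with the same
configuration are bit-identical. Stage seeds derive from the pipeline seed
through a string-keyed hash, so stages are decoupled: changing the number
of bootstrap iterations cannot change which reports land in the test
split.

## Limitations

* The reference tagger and heads are shallow; they demonstrate and test
  the pipeline's contracts, not state-of-the-art extraction quality.
* Cross-validated fusion weights are optimized on training mentions,
  where every code is seen; under a heavy unseen-code tail the selected
  $(w, \tau)$ can be classifier-heavier than ideal. This is a property of
  the protocol, visible in the pipeline's outputs, and is the reason the
  fallback threshold exists at all.
* Codes are opaque strings: no checksum validation, no cross-terminology
  equivalence reasoning, and no enforcement of consistency between the
  two finding codes.
* Exact search only; an approximate-nearest-neighbour backend must meet
  the same contract tests before substituting.
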