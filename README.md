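# pathocode

Hybrid clinical entity extraction and multi-terminology code mapping for
anatomopathological (pathology) report text, in R.

Pathology reports are unstructured narratives, yet almost every downstream
use — registries, epidemiology, billing, interoperability — needs three
things pulled out of them and standardized: the **sample type** (specimen),
the **test performed** (histological technique) and the **finding**
(diagnosis), each mapped to codes in the standard terminologies: SNOMED CT
for clinical concepts, LOINC for laboratory observations and ICD-11 for
disease classification. `pathocode` is a complete, dependency-light
implementation of that pipeline for methodologists and clinical-NLP
engineers: a token-level BIO tagger, per-terminology classification heads,
dense and sparse terminology retrieval, a learned fusion rule with a
confidence fallback, a statistical comparison harness, and a seeded
synthetic corpus generator standing in for protected clinical data.

## The method

**Extraction.** Sentences are word-tokenized and tagged with a 7-label BIO
scheme; the reference tagger is a softmax head over windowed
character-n-gram hashing embeddings, trained by minibatch AdamW on the
masked cross-entropy loss $L = -\sum_i y_i \log \hat y_i$ (label id $-100$
marks positions excluded from loss and metrics, the same convention used
for subword label alignment).

**Normalization.** Each extracted mention routes to its terminologies
(specimen → clinical concepts; technique → laboratory; finding → clinical
concepts *and* disease classification). For each routed terminology three
signals exist:

* a supervised softmax classifier over mention embeddings,
  $p_\mathrm{clf}(c)$;
* dense retrieval: exhaustive cosine similarity against every terminology
  entry (one entry per label and synonym, code score = max over entries);
* sparse retrieval: Okapi BM25
  ($k_1 = 1.5$, $b = 0.75$, non-negative idf).

The fused decision scores the union of candidate codes,

$$s(c) = w\,p_\mathrm{clf}(c) + (1-w)\,\mathrm{sim}_{01}(c),$$

and, whenever the classifier's top probability falls below a threshold
$\tau$, returns the retrieval rank-1 code instead — the fallback that
handles rare and never-seen codes. $(w, \tau)$ are chosen by exhaustive
grid search under 5-fold cross-validation.

**Evaluation.** Per-label precision/recall/F1 and error rates, bootstrap
percentile confidence intervals (10,000 iterations), one-sample t-tests
against a 0.5 baseline, Cohen's kappa, multiclass Matthews correlation,
exact McNemar tests on paired correctness, and sign-flip permutation tests
on accuracy differences (10,000 iterations). All seeded, all
bit-reproducible.

## Worked example

```r
library(pathocode)

cfg <- pipeline_config(
  generator = generator_config(n_reports = 200, unseen_code_fraction = 0.25),
  n_boot = 2000, n_perm = 2000, seed = 42)
res <- run_pipeline(cfg)
print(res)
```

```
<pipeline_result> seed=42 hash=44bef40 | 200 reports (160 train / 40 test)
NER micro-F1 0.977 (95% CI 0.957-0.985)

SNOMEDCT coding (N = 218):
        system accuracy precision_macro recall_macro f1_macro  kappa    mcc
    classifier   0.6514          0.3390       0.4489   0.3701 0.6374 0.6412
         dense   0.6743          0.5782       0.4913   0.5139 0.6665 0.6714
        sparse   0.6055          0.7234       0.5945   0.6280 0.5963 0.6323
 sparse_fusion   0.8578          0.7666       0.7312   0.7320 0.8521 0.8569
        fusion   0.8945          0.7267       0.6925   0.7004 0.8902 0.8910
```

Reading the table: on a 200-report synthetic corpus where a quarter of the
test mentions carry codes the classifier never saw, the classifier alone
reaches 0.65 accuracy on the clinical-concept task and lexical BM25
retrieval 0.61 (French institution-local phrasings are not in the
knowledge base); fusing the classifier with dense retrieval lifts accuracy
to 0.89 because the confidence fallback routes unseen-code mentions to
retrieval. Paired significance for any two systems:

```r
print(res$comparisons$ICD11$fusion_vs_classifier)
```

```
Paired system comparison (N = 109)
  accuracy A: 0.9817 (107/109)   accuracy B: 0.6606 (72/109)
  accuracy difference: 0.3211
  McNemar exact: b=35 c=0 p=5.821e-11   permutation p=0
  kappa A/B: 0.9805/0.6364   MCC A/B: 0.9806/0.6418
```

The lower-level API is exported too: `read_reports()` / `write_reports()`
(JSONL with character-offset annotations), `spans_to_bio()` /
`bio_to_spans()` / `align_labels()`, `load_concepts()` / `select_subset()`
/ `text_entries()`, `build_dense_index()` / `dense_search()` /
`build_sparse_index()` / `sparse_search()`, `train_tagger()` /
`tag_report()`, `fit_code_classifier()` / `fuse()` / `optimize_fusion()` /
`normalize_mentions()`, and the statistics in `prf()`, `bootstrap_ci()`,
`cohen_kappa()`, `mcc()`, `mcnemar_exact()`, `permutation_test()`,
`compare_systems()`. A thin command-line wrapper ships at
`inst/cli/pathocode.R` (`simulate`, `run`, `evaluate`, `compare`).

Licensed terminology content is never bundled: users holding SNOMED CT /
LOINC / ICD-11 licenses import their own release through the documented
TSV schema, and the synthetic generator provides schema-compatible
fixtures for everyone else.

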