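# shared fixture builders; everything is generated in code

tiny_report <- function() {
  report("rpt1",
         "Biopsy of thyroid received. Immunohistochemistry shows osteosarcoma.",
         language = "en",
         sentences = list(c(0L, 27L), c(28L, 68L)),
         entities = list(
           entity_mention(0, 17, "SAMPLE_TYPE", "Biopsy of thyroid",
                          codes = list(SNOMEDCT = "111009")),
           entity_mention(28, 48, "TEST_PERFORMED", "Immunohistochemistry",
                          codes = list(LOINC = "12345-6")),
           entity_mention(55, 67, "FINDING", "osteosarcoma",
                          codes = list(SNOMEDCT = "222009", ICD11 = "2B51.0"))))
}

tiny_concepts <- function(terminology = "SNOMEDCT") {
  concept_table(data.frame(
    terminology = terminology,
    code = c("111009", "222009", "333009"),
    label = c("biopsy of thyroid", "osteosarcoma of the bone", "biopsy of bone"),
    synonyms = c("thyroid biopsy", "bone osteosarcoma|ostéosarcome de l'os", ""),
    group = c("specimen", "morphologic abnormality", "specimen"),
    parent = c("", "", "111009"),
    stringsAsFactors = FALSE))
}

# a small deterministic corpus for training tests
small_corpus <- function(n_reports = 60, noise = NULL, seed = 11, ...) {
  args <- list(n_reports = n_reports, seed = seed, ...)
  if (!is.null(noise)) args$noise <- noise
  generate_corpus(do.call(generator_config, args))
}

zero_noise <- list(synonym_swap = 0, abbreviation = 0, typo = 0, case = 0)

# random small confusion matrix as gold/pred label vectors
random_labels <- function(n_labels, n, labels = LETTERS[seq_len(n_labels)]) {
  list(gold = sample(labels, n, replace = TRUE),
       pred = sample(labels, n, replace = TRUE))
}

# independent brute-force counting oracle for per-label metrics
count_oracle <- function(gold, pred, labels) {
  out <- lapply(labels, function(l) {
    tp <- sum(gold == l & pred == l)
    fp <- sum(gold != l & pred == l)
    fn <- sum(gold == l & pred != l)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    list(precision = p, recall = r,
         f1 = if (p + r > 0) 2 * p * r / (p + r) else 0,
         absolute = fn, support = sum(gold == l))
  })
  names(out) <- labels
  out
}
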