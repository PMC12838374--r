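# Annotated report data model, JSONL serialization, BIO tagging and subword
# label alignment.
#
# Character offsets are 0-based half-open [start, end) on the NFC-normalised
# report text; the serialized form stores offsets, never tokenized text, so
# downstream tokenizers can vary freely.

#' Construct an entity mention
#'
#' A typed character span inside a report, optionally carrying gold codes in
#' one or more terminologies.
#'
#' @param start,end 0-based half-open character offsets into the report text.
#' @param entity_type one of [entity_types()].
#' @param surface the text slice `[start, end)`.
#' @param codes optional named list/character vector, names in
#'   [terminologies()].
#' @return An object of class `entity_mention`.
#' @export
entity_mention <- function(start, end, entity_type, surface, codes = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stopf("invalid span [%s, %s)", start, end)
  if (!entity_type %in% entity_types())
    stopf("unknown entity type '%s'", entity_type)
  if (!is.null(codes)) {
    codes <- as.list(codes)
    bad <- setdiff(names(codes), terminologies())
    if (length(bad)) stopf("unknown terminology key(s): %s", paste(bad, collapse = ", "))
  }
  structure(list(start = start, end = end, entity_type = entity_type,
                 surface = surface, codes = codes),
            class = "entity_mention")
}

#' Construct an annotated report
#'
#' @param report_id unique identifier string.
#' @param text report text (normalised to NFC on construction).
#' @param language BCP-47-ish language tag (e.g. `"fr"`, `"en"`).
#' @param sentences list of 0-based half-open `[start, end)` sentence spans,
#'   sorted and non-overlapping.
#' @param entities list of [entity_mention()] objects; gold entities must be
#'   pairwise non-overlapping and each surface must equal its text slice.
#' @return An object of class `pathology_report`.
#' @export
report <- function(report_id, text, language = "en",
                   sentences = list(), entities = list()) {
  stopifnot(is_string(report_id), is_string(text))
  text <- stringi::stri_trans_nfc(text)
  r <- structure(list(report_id = report_id, text = text, language = language,
                      sentences = lapply(sentences, as.integer),
                      entities = entities),
                 class = "pathology_report")
  validate_report(r)
}

#' @rdname report
#' @param x a `pathology_report`.
#' @export
validate_report <- function(x) {
  n <- nchar(x$text)
  prev_end <- 0L
  for (s in x$sentences) {
    if (length(s) != 2L || s[1] < 0L || s[1] >= s[2] || s[2] > n)
      stopf("report %s: invalid sentence span [%s, %s)", x$report_id, s[1], s[2])
    if (s[1] < prev_end)
      stopf("report %s: overlapping/unsorted sentence spans", x$report_id)
    prev_end <- s[2]
  }
  if (length(x$entities)) {
    spans <- vapply(x$entities, function(e) c(e$start, e$end), integer(2))
    o <- order(spans[1, ], spans[2, ])
    spans <- spans[, o, drop = FALSE]
    if (any(spans[1, -1] < spans[2, -ncol(spans)]))
      stopf("report %s: overlapping gold entities are not supported", x$report_id)
    for (e in x$entities) {
      if (e$end > n)
        stopf("report %s: entity span [%s, %s) outside text of length %s",
              x$report_id, e$start, e$end, n)
      slice <- substr(x$text, e$start + 1L, e$end)
      if (!identical(slice, e$surface))
        stopf("report %s: surface '%s' != text slice '%s' at [%s, %s)",
              x$report_id, e$surface, slice, e$start, e$end)
    }
  }
  invisible(x)
}

#' @export
print.pathology_report <- function(x, ...) {
  cat(sprintf("<pathology_report %s> %d chars, %d sentence(s), %d entit(ies), lang=%s\n",
              x$report_id, nchar(x$text), length(x$sentences),
              length(x$entities), x$language))
  invisible(x)
}

mention_to_list <- function(e) {
  out <- list(start = e$start, end = e$end, type = e$entity_type)
  if (!is.null(e$codes) && length(e$codes)) out$codes <- e$codes
  out
}

#' Read / write annotated reports as JSONL
#'
#' One JSON object per line with fields `report_id`, `text`, `language`,
#' `sentences` (list of `[start, end)` pairs) and `entities`
#' (`start`/`end`/`type`/`codes`). Surfaces are reconstructed from offsets at
#' load time and every span is validated; `write_reports()` then
#' `read_reports()` is the identity.
#'
#' @param path file path.
#' @return `read_reports()`: a list of [report()] objects.
#' @export
read_reports <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) stopf("parse error on line %d: %s", i, conditionMessage(e)))
    text <- stringi::stri_trans_nfc(obj$text)
    ents <- lapply(obj$entities %||% list(), function(e) {
      if (e$end > nchar(text))
        stopf("report %s: entity span [%s, %s) outside text bounds",
              obj$report_id, e$start, e$end)
      entity_mention(e$start, e$end, e$type,
                     substr(text, as.integer(e$start) + 1L, as.integer(e$end)),
                     codes = e$codes %||% NULL)
    })
    out[[i]] <- report(obj$report_id, text, obj$language %||% "en",
                       sentences = obj$sentences %||% list(), entities = ents)
  }
  out
}

#' @rdname read_reports
#' @param reports list of reports.
#' @export
write_reports <- function(reports, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in reports) {
    validate_report(r)
    obj <- list(report_id = r$report_id, text = r$text, language = r$language,
                sentences = r$sentences,
                entities = lapply(r$entities, mention_to_list))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

#' Unicode-aware word tokenization with character offsets
#'
#' Splits on whitespace; runs of letters/digits form word tokens and each
#' punctuation character is kept as its own token. Diacritics are preserved.
#'
#' @param text string to tokenize.
#' @param shift offset added to the reported positions (use the sentence
#'   start when tokenizing a sentence slice).
#' @return data.frame with columns `token`, `start`, `end` (0-based half-open).
#' @export
word_tokenize <- function(text, shift = 0L) {
  m <- stringi::stri_locate_all_regex(text, "[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]")[[1]]
  if (nrow(m) == 0L || is.na(m[1, 1]))
    return(data.frame(token = character(0), start = integer(0), end = integer(0)))
  data.frame(token = stringi::stri_sub(text, m[, 1], m[, 2]),
             start = as.integer(m[, 1] - 1L + shift),
             end = as.integer(m[, 2] + shift),
             stringsAsFactors = FALSE)
}

#' Project entity spans onto BIO word tags
#'
#' Tokenizes one sentence of a report and assigns each word a BIO label: the
#' first word overlapping an entity (by at least one character) gets
#' `B-<type>`, later overlapping words `I-<type>`, all others `O`. Entities
#' are clipped to the sentence.
#'
#' @param rep a [report()].
#' @param sentence 1-based sentence index.
#' @return An object of class `tagged_sequence`: list with `tokens`, `tags`,
#'   `offsets` (data.frame of word `[start, end)`).
#' @export
spans_to_bio <- function(rep, sentence) {
  s <- rep$sentences[[sentence]]
  toks <- word_tokenize(substr(rep$text, s[1] + 1L, s[2]), shift = s[1])
  tags <- rep("O", nrow(toks))
  for (e in rep$entities) {
    a <- max(e$start, s[1]); b <- min(e$end, s[2])
    if (a >= b) next
    hit <- which(toks$start < b & toks$end > a)
    if (length(hit)) {
      tags[hit[1]] <- paste0("B-", e$entity_type)
      if (length(hit) > 1) tags[hit[-1]] <- paste0("I-", e$entity_type)
    }
  }
  tagged_sequence(toks$token, tags, toks[, c("start", "end")])
}

#' @rdname spans_to_bio
#' @param tokens,tags equal-length character vectors; tags drawn from
#'   [bio_labels()].
#' @param offsets data.frame with per-word `start`, `end`.
#' @export
tagged_sequence <- function(tokens, tags, offsets = NULL) {
  if (length(tokens) != length(tags))
    stopf("tokens (%d) and tags (%d) differ in length", length(tokens), length(tags))
  bad <- setdiff(tags, bio_labels())
  if (length(bad)) stopf("unknown BIO tag(s): %s", paste(bad, collapse = ", "))
  structure(list(tokens = tokens, tags = tags, offsets = offsets),
            class = "tagged_sequence")
}

#' @export
print.tagged_sequence <- function(x, ...) {
  cat(paste(x$tokens, x$tags, sep = "/", collapse = " "), "\n")
  invisible(x)
}

# repair an illegal I-t (after O, sequence start, or a different type) as B-t
repair_bio <- function(tags) {
  prev_type <- NULL
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (startsWith(t, "I-")) {
      ty <- substring(t, 3)
      if (is.null(prev_type) || !identical(prev_type, ty)) tags[i] <- paste0("B-", ty)
      prev_type <- ty
    } else if (startsWith(t, "B-")) {
      prev_type <- substring(t, 3)
    } else prev_type <- NULL
  }
  tags
}

#' Decode BIO word tags back to entity spans
#'
#' Inverse of [spans_to_bio()] on well-formed sequences. An illegal `I-t`
#' (following `O`, the sequence start, or a tag of a different type) is
#' repaired as `B-t` before decoding.
#'
#' @param tagged a [tagged_sequence()] carrying word offsets, or tags plus an
#'   `offsets` data.frame.
#' @param text optional source text used to recover exact surfaces (spans are
#'   word-extent based otherwise, with surfaces joined by single spaces).
#' @return list of [entity_mention()] objects (without codes).
#' @export
bio_to_spans <- function(tagged, text = NULL) {
  tags <- repair_bio(tagged$tags)
  off <- tagged$offsets
  if (is.null(off) || nrow(off) != length(tags))
    stopf("offsets missing or length-mismatched with tags")
  out <- list()
  i <- 1L
  while (i <= length(tags)) {
    if (startsWith(tags[i], "B-")) {
      ty <- substring(tags[i], 3)
      j <- i
      while (j + 1L <= length(tags) && tags[j + 1L] == paste0("I-", ty)) j <- j + 1L
      a <- off$start[i]; b <- off$end[j]
      surface <- if (!is.null(text)) substr(text, a + 1L, b) else
        paste(tagged$tokens[i:j], collapse = " ")
      out[[length(out) + 1L]] <- entity_mention(a, b, ty, surface)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Align word-level BIO labels to subword tokens
#'
#' Mirrors transformer-style label alignment: each subword is mapped to its
#' source word (or `NA` for special/filler tokens). With the default
#' `"first"` strategy only the first subword of each word carries the word's
#' label id; continuation subwords and all `NA` positions get the ignore
#' index `-100`. The `"all"` strategy labels every subword of a word.
#'
#' @param tagged a [tagged_sequence()].
#' @param subword_map integer vector, one element per subword: 1-based source
#'   word index or `NA` for special tokens.
#' @param subwords optional character vector of subword strings (carried
#'   through for inspection).
#' @param strategy `"first"` (default) or `"all"`.
#' @return An object of class `aligned_example`: list with equal-length
#'   `subwords`, `word_index`, `label_ids`.
#' @export
align_labels <- function(tagged, subword_map, subwords = NULL,
                         strategy = c("first", "all")) {
  strategy <- match.arg(strategy)
  n_words <- length(tagged$tags)
  subword_map <- as.integer(subword_map)
  if (any(!is.na(subword_map) & (subword_map < 1L | subword_map > n_words)))
    stopf("subword_map word index out of range 1..%d", n_words)
  ids <- rep(IGNORE_INDEX, length(subword_map))
  word_ids <- bio_label_id(tagged$tags)
  seen <- rep(FALSE, n_words)
  for (i in seq_along(subword_map)) {
    w <- subword_map[i]
    if (is.na(w)) next
    if (strategy == "all" || !seen[w]) ids[i] <- word_ids[w]
    seen[w] <- TRUE
  }
  if (is.null(subwords)) subwords <- rep(NA_character_, length(subword_map))
  if (length(subwords) != length(subword_map))
    stopf("subwords and subword_map differ in length")
  structure(list(subwords = subwords, word_index = subword_map, label_ids = ids),
            class = "aligned_example")
}

#' Export reports in CoNLL style
#'
#' One `token<TAB>tag` line per word, blank line between sentences.
#'
#' @param reports list of reports.
#' @param path output file.
#' @export
write_conll <- function(reports, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in reports) {
    for (si in seq_along(r$sentences)) {
      ts <- spans_to_bio(r, si)
      writeLines(paste(ts$tokens, ts$tags, sep = "\t"), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Extract gold mentions from reports
#'
#' Flattens all annotated entities into one data.frame, one row per mention,
#' with any attached gold codes spread into per-terminology columns.
#'
#' @param reports list of reports.
#' @return data.frame with columns `report_id`, `entity_type`, `surface`,
#'   `start`, `end`, and one column per terminology (NA when absent).
#' @export
collect_mentions <- function(reports) {
  rows <- list()
  for (r in reports) {
    for (e in r$entities) {
      row <- data.frame(report_id = r$report_id, entity_type = e$entity_type,
                        surface = e$surface, start = e$start, end = e$end,
                        stringsAsFactors = FALSE)
      for (t in terminologies())
        row[[t]] <- if (!is.null(e$codes[[t]])) e$codes[[t]] else NA_character_
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) {
    out <- data.frame(report_id = character(0), entity_type = character(0),
                      surface = character(0), start = integer(0), end = integer(0))
    for (t in terminologies()) out[[t]] <- character(0)
    return(out)
  }
  do.call(rbind, rows)
}
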