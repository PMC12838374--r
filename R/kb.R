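# Concept tables for the three terminologies: load/save, subset selection by
# organisational group (with transitive parent closure for the SNOMED-style
# hierarchy), and expansion into indexable text entries.
#
# Real SNOMED CT / LOINC / ICD-11 content is licensed and never bundled;
# users holding licences import their own release through the same TSV
# schema, and the synthetic generator produces schema-compatible fixtures.

#' Construct a concept table
#'
#' One table holds the concepts of a single terminology. Codes are opaque
#' unique strings; `group` is the organisational unit used for subsetting
#' (hierarchy root for SNOMED CT-style tables, class for LOINC-style,
#' chapter for ICD-11-style); `parent` optionally links into an in-table
#' hierarchy.
#'
#' @param df data.frame with columns `terminology`, `code`, `label`,
#'   `synonyms` (pipe-separated, possibly empty), `group`, `parent` (empty
#'   string or NA for roots).
#' @return object of class `concept_table`.
#' @export
concept_table <- function(df) {
  need <- c("terminology", "code", "label", "synonyms", "group", "parent")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)[need]
  for (cc in need) df[[cc]] <- as.character(df[[cc]])
  df$synonyms[is.na(df$synonyms)] <- ""
  df$parent[is.na(df$parent)] <- ""
  term <- unique(df$terminology)
  if (length(term) != 1L) stopf("a concept table holds one terminology, got: %s",
                                paste(term, collapse = ", "))
  if (!term %in% terminologies()) stopf("unknown terminology tag '%s'", term)
  if (any(!nzchar(df$code)) || any(!nzchar(df$label)))
    stop("codes and labels must be non-empty")
  dup <- df$code[duplicated(df$code)]
  if (length(dup)) stopf("duplicated code(s): %s", paste(unique(dup), collapse = ", "))
  dangling <- setdiff(df$parent[nzchar(df$parent)], df$code)
  if (length(dangling)) stopf("dangling parent code(s): %s",
                              paste(unique(dangling), collapse = ", "))
  structure(list(terminology = term, concepts = df), class = "concept_table")
}

#' @export
print.concept_table <- function(x, ...) {
  cat(sprintf("<concept_table %s> %d concepts, %d group(s)\n", x$terminology,
              nrow(x$concepts), length(unique(x$concepts$group))))
  invisible(x)
}

#' Load / save a concept table (TSV)
#'
#' Tab-separated with header `terminology code label synonyms group parent`;
#' synonyms pipe-separated. The write/load round trip is the identity.
#'
#' @param path TSV file path.
#' @return `load_concepts()`: a [concept_table()].
#' @export
load_concepts <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", quote = "",
                          fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  concept_table(df)
}

#' @rdname load_concepts
#' @param table a [concept_table()].
#' @export
write_concepts <- function(table, path) {
  utils::write.table(table$concepts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Select a terminology subset by organisational group
#'
#' Keeps concepts whose `group` is in `groups`. For SNOMED CT-style tables
#' the selection additionally closes over the hierarchy: every descendant
#' (by parent chains) of a selected concept is kept even when it carries
#' another group tag. LOINC-/ICD-11-style tables subset flat on group.
#'
#' @param table a [concept_table()].
#' @param groups character vector of group identifiers.
#' @return a [concept_table()] that is a sub-table of the input.
#' @export
select_subset <- function(table, groups) {
  df <- table$concepts
  keep <- df$group %in% groups
  if (table$terminology == "SNOMEDCT" && any(keep)) {
    # transitive closure over parent links, brute reachability
    selected <- df$code[keep]
    repeat {
      more <- df$parent %in% selected & !df$code %in% selected
      if (!any(more)) break
      selected <- c(selected, df$code[more])
    }
    keep <- df$code %in% selected
  }
  if (!any(keep)) {
    warnf("empty subset for group(s): %s", paste(groups, collapse = ", "))
    out <- df[0, , drop = FALSE]
  } else out <- df[keep, , drop = FALSE]
  # drop parent links that now point outside the subset
  out$parent[!out$parent %in% out$code] <- ""
  rownames(out) <- NULL
  structure(list(terminology = table$terminology, concepts = out),
            class = "concept_table")
}

#' Expand a concept table into indexable text entries
#'
#' One entry per label and one per synonym; a code may own several entries.
#'
#' @param table a [concept_table()].
#' @return data.frame with columns `text`, `code`.
#' @export
text_entries <- function(table) {
  df <- table$concepts
  if (!nrow(df)) stop("empty concept table")
  texts <- as.list(df$label)
  codes <- as.list(df$code)
  for (i in seq_len(nrow(df))) {
    if (nzchar(df$synonyms[i])) {
      syn <- strsplit(df$synonyms[i], "|", fixed = TRUE)[[1]]
      syn <- syn[nzchar(syn)]
      if (length(syn)) {
        texts[[i]] <- c(texts[[i]], syn)
        codes[[i]] <- rep(df$code[i], length(syn) + 1L)
      }
    }
  }
  data.frame(text = unlist(texts), code = unlist(codes), stringsAsFactors = FALSE)
}

#' Export a concept table as JSON
#'
#' Mirrors the TSV fields; synonyms become arrays.
#'
#' @param table a [concept_table()].
#' @param path output path.
#' @export
write_concepts_json <- function(table, path) {
  df <- table$concepts
  objs <- lapply(seq_len(nrow(df)), function(i) {
    syn <- strsplit(df$synonyms[i], "|", fixed = TRUE)[[1]]
    list(terminology = df$terminology[i], code = df$code[i], label = df$label[i],
         synonyms = syn[nzchar(syn)], group = df$group[i],
         parent = if (nzchar(df$parent[i])) df$parent[i] else NULL)
  })
  writeLines(jsonlite::toJSON(objs, auto_unbox = TRUE, null = "null", pretty = TRUE),
             path, useBytes = TRUE)
  invisible(path)
}
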