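# Seeded generator of schema-compatible terminology fixtures and annotated
# pathology-style reports. It emulates the shape of a manually annotated
# anatomopathological corpus: three entity types per sentence, mention
# surfaces drawn from concept labels/synonyms with controllable
# abbreviation/typo/case noise, bilingual (French/English) sentence
# templates, a long-tailed (Zipf) code frequency distribution, and an
# optional guaranteed fraction of test-only codes to exercise the retrieval
# fallback. All content is synthetic; no licensed terminology text and no
# patient-derived text.

#' Generator configuration
#'
#' Defaults reproduce the study conditions the package's evaluation harness
#' assumes: a 560-report corpus, three entity types, a Zipf exponent of 1.2
#' over concept frequencies, and clinically realistic surface variation —
#' half of all mentions use a non-canonical form (a terminology synonym or
#' an institution-local French phrasing absent from the knowledge base),
#' one in five abbreviable mentions is abbreviated, one in ten carries a
#' single-character typo. Half the reports use French templates, half
#' English.
#'
#' Mentions are written in mixed French/English while the terminology
#' tables follow real language coverage: the clinical-concept table carries
#' English entries only, whereas the laboratory and disease-classification
#' tables include official French translations. Lexical retrieval therefore
#' faces a genuine cross-language gap exactly where real coding pipelines
#' do.
#'
#' The generated tables additionally hold distractor concepts that never
#' occur in report text but share sites, morphologies and technique
#' vocabulary with the corpus concepts. They model the realistic asymmetry
#' between terminologies: a clinical-concept subset is far larger than the
#' set of concepts any corpus uses (many near-neighbour distractors, so
#' lexical retrieval is hard), while a laboratory-test subset is small and
#' constrained (few distractors, retrieval easy).
#'
#' @param n_reports number of reports (>= 1).
#' @param n_concepts named integer vector: concepts per entity type
#'   (`sample_type`, `test_performed`, `finding`) that occur in reports.
#' @param distractor_concepts named integer vector: additional per-type
#'   concepts present in the terminology tables only.
#' @param synonyms_range integer `c(min, max)` knowledge-base synonyms per
#'   concept, capped by each terminology's language coverage (see Details).
#' @param zipf_exponent exponent of the rank-frequency law (> 0).
#' @param noise named list of rates in `[0, 1]`: `synonym_swap` (surface is
#'   a random non-canonical form rather than the label), `abbreviation`
#'   (fixed-table substitution, e.g. "hematoxylin and eosin" -> "H&E"),
#'   `typo` (one random character insert/delete/adjacent-swap), `case`
#'   (case flip of the first character).
#' @param languages named numeric vector of template-language weights.
#' @param sentences_range integer `c(min, max)` sentences per report.
#' @param unseen_code_fraction fraction of test-partition mentions drawn
#'   from concepts guaranteed absent from the training partition (0
#'   disables the construction).
#' @param train_frac fraction of reports in the training block when
#'   `unseen_code_fraction > 0`.
#' @param seed master seed; every stage derives from it.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_reports = 560L,
                             n_concepts = c(sample_type = 40L,
                                            test_performed = 30L,
                                            finding = 60L),
                             distractor_concepts = c(sample_type = 60L,
                                                     test_performed = 6L,
                                                     finding = 140L),
                             synonyms_range = c(1L, 3L),
                             zipf_exponent = 1.2,
                             noise = list(synonym_swap = 0.5, abbreviation = 0.2,
                                          typo = 0.1, case = 0.1),
                             languages = c(en = 0.5, fr = 0.5),
                             sentences_range = c(1L, 5L),
                             unseen_code_fraction = 0,
                             train_frac = 0.8,
                             seed = 42L) {
  stopifnot(n_reports >= 1L, zipf_exponent > 0,
            all(unlist(noise) >= 0), all(unlist(noise) <= 1),
            unseen_code_fraction >= 0, unseen_code_fraction <= 1)
  if (any(n_concepts < 2L)) stop("need at least 2 concepts per entity type")
  structure(list(n_reports = as.integer(n_reports), n_concepts = n_concepts,
                 distractor_concepts = distractor_concepts,
                 synonyms_range = as.integer(synonyms_range),
                 zipf_exponent = zipf_exponent, noise = noise,
                 languages = languages,
                 sentences_range = as.integer(sentences_range),
                 unseen_code_fraction = unseen_code_fraction,
                 train_frac = train_frac, seed = as.integer(seed)),
            class = "generator_config")
}

# -- pathology-flavoured lexicon --------------------------------------------

lex_sites <- function() {
  data.frame(
    en = c("thyroid", "bone", "prostate", "skin", "lung", "liver", "colon",
           "breast", "kidney", "stomach", "bladder", "lymph node", "pancreas",
           "uterus", "ovary", "esophagus", "spleen", "tonsil", "appendix",
           "rectum"),
    fr = c("thyroïde", "os", "prostate", "peau", "poumon", "foie",
           "côlon", "sein", "rein", "estomac", "vessie",
           "ganglion lymphatique", "pancréas", "utérus", "ovaire",
           "œsophage", "rate", "amygdale", "appendice", "rectum"),
    stringsAsFactors = FALSE)
}

lex_techniques <- function() {
  data.frame(
    en = c("hematoxylin and eosin stain", "immunohistochemistry",
           "periodic acid-Schiff stain", "Giemsa stain",
           "Masson trichrome stain", "Gram stain", "Ziehl-Neelsen stain",
           "Congo red stain", "flow cytometry", "frozen section examination",
           "fluorescence in situ hybridization", "polymerase chain reaction",
           "reticulin stain", "alcian blue stain",
           "Grocott methenamine silver stain", "direct immunofluorescence",
           "electron microscopy", "cytogenetic analysis",
           "toluidine blue stain", "von Kossa stain", "mucicarmine stain",
           "Perls Prussian blue stain", "oil red O stain",
           "terminal deoxynucleotidyl transferase assay",
           "in situ hybridization", "molecular karyotyping",
           "chromogenic in situ hybridization", "digital image analysis",
           "liquid-based cytology", "cell block preparation",
           "bone marrow aspirate smear review", "touch imprint cytology",
           "special stain panel", "proliferation index assessment",
           "hormone receptor assay", "microsatellite instability testing"),
    fr = c("coloration hématoxyline et éosine", "immunohistochimie",
           "coloration acide périodique de Schiff", "coloration de Giemsa",
           "trichrome de Masson", "coloration de Gram",
           "coloration de Ziehl-Neelsen", "coloration au rouge Congo",
           "cytométrie en flux", "examen extemporané",
           "hybridation in situ en fluorescence",
           "réaction de polymérisation en chaîne",
           "coloration à la réticuline", "coloration au bleu alcian",
           "imprégnation argentique de Grocott",
           "immunofluorescence directe", "microscopie électronique",
           "analyse cytogénétique", "coloration au bleu de toluidine",
           "coloration de von Kossa", "coloration au mucicarmin",
           "coloration de Perls", "coloration oil red O",
           "test de la transférase terminale",
           "hybridation in situ", "caryotype moléculaire",
           "hybridation in situ chromogénique",
           "analyse d'images numériques", "cytologie en milieu liquide",
           "préparation de bloc cellulaire",
           "relecture de frottis médullaire", "cytologie d'apposition",
           "panel de colorations spéciales",
           "évaluation de l'index de prolifération",
           "dosage des récepteurs hormonaux",
           "recherche d'instabilité microsatellitaire"),
    stringsAsFactors = FALSE)
}

lex_morphologies <- function() {
  data.frame(
    en = c("adenocarcinoma", "squamous cell carcinoma", "osteosarcoma",
           "melanoma", "lymphoma", "lipoma", "fibroadenoma", "granuloma",
           "chronic inflammation", "mesothelioma", "leiomyoma",
           "carcinoid tumor", "basal cell carcinoma", "papillary carcinoma",
           "follicular adenoma", "high-grade dysplasia", "hyperplasia",
           "caseating necrosis", "fibrosis", "amyloidosis"),
    fr = c("adénocarcinome", "carcinome épidermoïde",
           "ostéosarcome", "mélanome", "lymphome", "lipome",
           "fibroadénome", "granulome", "inflammation chronique",
           "mésothéliome", "léiomyome", "tumeur carcinoïde",
           "carcinome basocellulaire", "carcinome papillaire",
           "adénome folliculaire", "dysplasie de haut grade",
           "hyperplasie", "nécrose caséeuse", "fibrose",
           "amyloïdose"),
    stringsAsFactors = FALSE)
}

# fixed abbreviation table (applied by corrupt_surface and nowhere else)
abbreviation_table <- function() {
  c("hematoxylin and eosin" = "H&E",
    "hématoxyline et éosine" = "H&E",
    "immunohistochemistry" = "IHC",
    "immunohistochimie" = "IHC",
    "fluorescence in situ hybridization" = "FISH",
    "polymerase chain reaction" = "PCR",
    "réaction de polymérisation en chaîne" = "PCR",
    "periodic acid-Schiff" = "PAS",
    "acide périodique de Schiff" = "PAS",
    "squamous cell carcinoma" = "SCC",
    "basal cell carcinoma" = "BCC",
    "lymph node" = "LN",
    "ganglion lymphatique" = "ganglion")
}

# Deterministic lexicon of n concepts for one entity type. Each concept has
# four surface forms: the English canonical label, an English word-order
# variant, the French label, and a French institution-local phrasing.
# Report text may use any of them; which forms each terminology table
# carries as synonyms is decided per terminology (language-coverage
# policy) in generate_terminology(). All forms are unique within the pool
# by construction.
make_lexicon <- function(kind, n, seed) {
  sites <- lex_sites()
  combos <- switch(kind,
    sample_type = {
      pat_en <- c("biopsy of %s", "%s resection specimen",
                  "fine needle aspirate of %s", "%s curettage specimen",
                  "%s excision specimen")
      pat_var <- c("%s biopsy", "resected %s specimen",
                   "%s fine needle aspirate", "curettage of %s",
                   "excised %s tissue")
      pat_fr <- c("biopsie de %s", "pièce de résection de %s",
                  "cytoponction de %s", "curetage de %s",
                  "pièce d'exérèse de %s")
      pat_loc <- c("prélèvement biopsique de %s", "pièce opératoire de %s",
                   "produit de ponction de %s", "produit de curetage de %s",
                   "pièce d'exérèse chirurgicale de %s")
      g <- expand.grid(p = seq_along(pat_en), s = seq_len(nrow(sites)))
      data.frame(label = sprintf(pat_en[g$p], sites$en[g$s]),
                 en_var = sprintf(pat_var[g$p], sites$en[g$s]),
                 fr = sprintf(pat_fr[g$p], sites$fr[g$s]),
                 fr_local = sprintf(pat_loc[g$p], sites$fr[g$s]),
                 stringsAsFactors = FALSE)
    },
    test_performed = {
      tech <- lex_techniques()
      data.frame(label = tech$en,
                 en_var = paste(tech$en, "procedure"),
                 fr = tech$fr,
                 fr_local = paste("examen par", tech$fr),
                 stringsAsFactors = FALSE)
    },
    finding = {
      morph <- lex_morphologies()
      g <- expand.grid(m = seq_len(nrow(morph)), s = seq_len(nrow(sites)))
      data.frame(label = sprintf("%s of the %s", morph$en[g$m], sites$en[g$s]),
                 en_var = sprintf("%s %s", sites$en[g$s], morph$en[g$m]),
                 fr = sprintf("%s du %s", morph$fr[g$m], sites$fr[g$s]),
                 fr_local = sprintf("aspect histologique de %s du %s",
                                    morph$fr[g$m], sites$fr[g$s]),
                 stringsAsFactors = FALSE)
    },
    stopf("unknown lexicon kind '%s'", kind))
  if (n > nrow(combos))
    stopf("%s lexicon supports at most %d concepts (%d requested)",
          kind, nrow(combos), n)
  with_seed(seed, {
    take <- sample.int(nrow(combos), n)
    out <- combos[take, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# Knowledge-base synonym policy by terminology, mirroring real language
# coverage: the clinical-concept terminology ships English descriptions
# only (no comprehensive French release), while the laboratory and
# disease-classification terminologies carry official French translations.
# The institution-local French phrasing (fr_local) is never in any table.
# n_syn (from synonyms_range) caps how many of the available forms a
# concept carries; draws use the current RNG stream.
kb_synonyms <- function(lex, terminology, synonyms_range) {
  avail <- switch(terminology,
                  SNOMEDCT = lex["en_var"],
                  LOINC = lex[c("fr", "en_var")],
                  ICD11 = lex["fr"])
  n <- nrow(lex)
  n_syn <- sample(synonyms_range[1]:synonyms_range[2], n, replace = TRUE)
  vapply(seq_len(n), function(i) {
    forms <- unlist(avail[i, ], use.names = FALSE)
    paste(forms[seq_len(min(n_syn[i], length(forms)))], collapse = "|")
  }, "")
}

# The three lexicons a configuration implies (shared by generate_terminology
# and generate_reports). Rows beyond the first n_concepts of each kind are
# table-only distractors (`in_corpus = FALSE`).
corpus_lexicons <- function(cfg) {
  d <- cfg$distractor_concepts %||% c(sample_type = 0L, test_performed = 0L,
                                      finding = 0L)
  one <- function(kind, tag) {
    n <- cfg$n_concepts[[kind]]
    lx <- make_lexicon(kind, n + (d[[kind]] %||% 0L),
                       derive_seed(cfg$seed, tag))
    lx$in_corpus <- seq_len(nrow(lx)) <= n
    lx
  }
  list(sample_type = one("sample_type", "lexicon-sample"),
       test_performed = one("test_performed", "lexicon-test"),
       finding = one("finding", "lexicon-finding"))
}

# terminology-plausible synthetic code shapes; sampled without replacement
# over the full combinatorial space so codes are always unique
make_codes <- function(terminology, n, seed) {
  with_seed(seed, switch(terminology,
    SNOMEDCT = sprintf("%d009", sample(100000:999999, n)),
    LOINC = sprintf("%05d-%d", sample(10000:99999, n), sample(0:9, n, replace = TRUE)),
    ICD11 = {
      idx <- sample.int(9L * 26L * 100L * 10L, n) - 1L
      sprintf("%d%s%02d.%d", idx %% 9L + 1L,
              LETTERS[(idx %/% 9L) %% 26L + 1L],
              (idx %/% (9L * 26L)) %% 100L,
              idx %/% (9L * 26L * 100L))
    },
    stopf("unknown terminology '%s'", terminology)))
}

#' Generate a synthetic concept table
#'
#' Codes follow terminology-plausible shapes (digit strings for the
#' SNOMED CT-like table, `#####-#` for LOINC-like, alphanumeric chapter
#' codes for ICD-11-like); labels and synonyms come from a bilingual
#' pathology-flavoured lexicon under a per-terminology language-coverage
#' policy (French synonyms only where the real terminology publishes
#' them). The SNOMED CT-like table holds both specimen and morphology
#' concepts (its two hierarchy groups) and carries a parent tree; finding
#' labels are shared verbatim with the ICD-11-like table so mentions can
#' be dual-coded. Deterministic per seed.
#'
#' @param cfg a [generator_config()].
#' @param terminology one of [terminologies()].
#' @return a [concept_table()].
#' @export
generate_terminology <- function(cfg, terminology) {
  lex <- corpus_lexicons(cfg)
  finding_lex <- lex$finding
  syn_seed <- derive_seed(cfg$seed, paste0("kb-syn-", terminology))
  tab <- with_seed(syn_seed, switch(terminology,
    SNOMEDCT = {
      sam <- lex$sample_type
      df <- rbind(
        data.frame(label = sam$label,
                   synonyms = kb_synonyms(sam, "SNOMEDCT", cfg$synonyms_range),
                   group = "specimen", stringsAsFactors = FALSE),
        data.frame(label = finding_lex$label,
                   synonyms = kb_synonyms(finding_lex, "SNOMEDCT",
                                          cfg$synonyms_range),
                   group = "morphologic abnormality", stringsAsFactors = FALSE))
      df$code <- make_codes("SNOMEDCT", nrow(df),
                            derive_seed(cfg$seed, "codes-snomed"))
      # shallow parent tree within each group: concept i hangs under
      # concept ceil(i/3) of the previous tier; the first is the root
      df$parent <- ""
      for (g in unique(df$group)) {
        ii <- which(df$group == g)
        if (length(ii) > 1L)
          df$parent[ii[-1]] <- df$code[ii[ceiling((seq_along(ii)[-1] - 1) / 3)]]
      }
      df
    },
    LOINC = {
      tech <- lex$test_performed
      df <- data.frame(label = tech$label,
                       synonyms = kb_synonyms(tech, "LOINC", cfg$synonyms_range),
                       stringsAsFactors = FALSE)
      df$group <- rep(c("PATH.HISTO", "PATH.CYTO", "MICRO"),
                      length.out = nrow(df))
      df$code <- make_codes("LOINC", nrow(df), derive_seed(cfg$seed, "codes-loinc"))
      df$parent <- ""
      df
    },
    ICD11 = {
      df <- data.frame(label = finding_lex$label,
                       synonyms = kb_synonyms(finding_lex, "ICD11",
                                              cfg$synonyms_range),
                       stringsAsFactors = FALSE)
      df$group <- rep(c("02", "01", "08"), length.out = nrow(df))
      df$code <- make_codes("ICD11", nrow(df), derive_seed(cfg$seed, "codes-icd"))
      df$parent <- ""
      df
    },
    stopf("unknown terminology '%s'", terminology)))
  tab$terminology <- terminology
  concept_table(tab)
}

#' Corrupt a mention surface
#'
#' Applies, each with its configured probability: abbreviation substitution
#' from a fixed table, one random single-character edit (insert, delete, or
#' adjacent swap), and a case flip of the first character. Uses the current
#' RNG stream.
#'
#' @param text surface string.
#' @param noise named list of rates (see [generator_config()]).
#' @return corrupted string.
#' @export
corrupt_surface <- function(text, noise) {
  abbr <- abbreviation_table()
  if ((noise$abbreviation %||% 0) > 0 && stats::runif(1) < noise$abbreviation) {
    for (long in names(abbr)) {
      if (grepl(long, text, fixed = TRUE)) {
        text <- sub(long, abbr[[long]], text, fixed = TRUE)
        break
      }
    }
  }
  if ((noise$typo %||% 0) > 0 && stats::runif(1) < noise$typo && nchar(text) >= 3) {
    ch <- strsplit(text, "", fixed = TRUE)[[1]]
    op <- sample(c("insert", "delete", "swap"), 1)
    i <- sample(seq_along(ch), 1)
    ch <- switch(op,
      insert = append(ch, sample(letters, 1), after = i),
      delete = ch[-i],
      swap = {
        if (i == length(ch)) i <- i - 1L
        tmp <- ch[i]; ch[i] <- ch[i + 1L]; ch[i + 1L] <- tmp
        ch
      })
    text <- paste(ch, collapse = "")
  }
  if ((noise$case %||% 0) > 0 && stats::runif(1) < noise$case && nchar(text) >= 1) {
    first <- substr(text, 1, 1)
    flipped <- if (first %in% LETTERS) tolower(first) else toupper(first)
    text <- paste0(flipped, substr(text, 2, nchar(text)))
  }
  text
}

# sentence templates; {S}/{T}/{F} are the three mention slots
report_templates <- function(language) {
  if (language == "fr") {
    list(c("Réception de ", "S", " ; ", "T", " réalisée , concluant à ", "F", " ."),
         c("Le prélèvement ", "S", " a été analysé par ", "T", " , en faveur de ", "F", " ."),
         c("Après ", "T", " sur ", "S", " , le diagnostic retenu est ", "F", " ."))
  } else {
    list(c("Received ", "S", " for evaluation ; ", "T", " was performed and showed ", "F", " ."),
         c("The specimen ", "S", " was examined by ", "T", " , consistent with ", "F", " ."),
         c("Following ", "T", " on ", "S", " , findings are diagnostic of ", "F", " ."))
  }
}

# Zipf rank weights over a pool of n concepts
zipf_weights <- function(n, exponent) {
  w <- (seq_len(n))^(-exponent)
  w / sum(w)
}

#' Generate annotated synthetic reports
#'
#' Each report holds 1-5 template sentences, each embedding exactly one
#' mention per entity type. Surfaces are a concept synonym (with probability
#' `noise$synonym_swap`) or the label, then passed through
#' [corrupt_surface()]; gold spans are exact by construction and gold codes
#' attach per [route_terminologies()] (findings carry both a SNOMED CT-style
#' and an ICD-11-style code, linked by shared labels across the two tables).
#' Concept usage is Zipf-distributed over a seeded rank permutation.
#'
#' When `cfg$unseen_code_fraction > 0` the reports are generated in a
#' train/test block structure (attribute `"split"`): the first
#' `train_frac` of reports never use a designated tail of each concept
#' pool, and each test mention is drawn from that held-out tail with the
#' configured probability (attribute `"holdout_codes"` lists the codes).
#'
#' @param cfg a [generator_config()].
#' @param tables named list of the three [generate_terminology()] tables.
#' @return list of [report()] objects with attributes `"split"` and
#'   `"holdout_codes"`.
#' @export
generate_reports <- function(cfg, tables) {
  for (t in terminologies())
    if (is.null(tables[[t]]) || !nrow(tables[[t]]$concepts))
      stopf("missing or empty table for %s", t)
  lex0 <- corpus_lexicons(cfg)
  in_corpus <- list(
    SAMPLE_TYPE = lex0$sample_type$label[lex0$sample_type$in_corpus],
    TEST_PERFORMED = lex0$test_performed$label[lex0$test_performed$in_corpus],
    FINDING = lex0$finding$label[lex0$finding$in_corpus])
  sn <- tables$SNOMEDCT$concepts
  pools <- list(
    SAMPLE_TYPE = sn[sn$group == "specimen" &
                       sn$label %in% in_corpus$SAMPLE_TYPE, , drop = FALSE],
    TEST_PERFORMED = tables$LOINC$concepts[
      tables$LOINC$concepts$label %in% in_corpus$TEST_PERFORMED, , drop = FALSE],
    FINDING = sn[sn$group == "morphologic abnormality" &
                   sn$label %in% in_corpus$FINDING, , drop = FALSE])
  for (ty in names(pools))
    if (!nrow(pools[[ty]]))
      stopf("tables carry no corpus concepts for %s (config/table mismatch?)", ty)
  icd <- tables$ICD11$concepts
  icd_by_label <- stats::setNames(icd$code, icd$label)
  q <- cfg$unseen_code_fraction
  n_train <- if (q > 0) round(cfg$train_frac * cfg$n_reports) else cfg$n_reports

  with_seed(derive_seed(cfg$seed, "reports"), {
    # seeded Zipf rank order per pool; holdout = tail ranks
    rank_order <- lapply(pools, function(p) sample.int(nrow(p)))
    holdout <- lapply(names(pools), function(ty) {
      n <- nrow(pools[[ty]])
      if (q > 0) rank_order[[ty]][seq.int(n - max(1L, ceiling(q * n)) + 1L, n)]
      else integer(0)
    })
    names(holdout) <- names(pools)

    draw_concept <- function(ty, in_test) {
      ord <- rank_order[[ty]]
      hold <- holdout[[ty]]
      if (in_test && q > 0 && stats::runif(1) < q) {
        pools[[ty]][sample(hold, 1), , drop = FALSE]
      } else {
        avail <- setdiff(ord, hold)
        w <- zipf_weights(length(avail), cfg$zipf_exponent)
        pools[[ty]][avail[sample.int(length(avail), 1, prob = w)], , drop = FALSE]
      }
    }

    all_lex <- do.call(rbind, lapply(lex0, function(l)
      l[c("label", "en_var", "fr", "fr_local")]))
    forms_by_label <- stats::setNames(
      lapply(seq_len(nrow(all_lex)), function(i)
        unlist(all_lex[i, c("en_var", "fr", "fr_local")], use.names = FALSE)),
      all_lex$label)

    mention_surface <- function(concept) {
      surf <- concept$label
      forms <- forms_by_label[[concept$label]]
      if (length(forms) && (cfg$noise$synonym_swap %||% 0) > 0 &&
          stats::runif(1) < cfg$noise$synonym_swap)
        surf <- sample(forms, 1)
      corrupt_surface(surf, cfg$noise)
    }

    reports <- vector("list", cfg$n_reports)
    for (ri in seq_len(cfg$n_reports)) {
      in_test <- ri > n_train
      lang <- sample(names(cfg$languages), 1, prob = cfg$languages)
      templates <- report_templates(lang)
      n_sent <- sample(cfg$sentences_range[1]:cfg$sentences_range[2], 1)
      text <- ""
      sentences <- list()
      entities <- list()
      for (si in seq_len(n_sent)) {
        tpl <- templates[[sample.int(length(templates), 1)]]
        picked <- list(S = draw_concept("SAMPLE_TYPE", in_test),
                       T = draw_concept("TEST_PERFORMED", in_test),
                       F = draw_concept("FINDING", in_test))
        sent_start <- nchar(text)
        for (frag in tpl) {
          if (frag %in% c("S", "T", "F")) {
            con <- picked[[frag]]
            surf <- mention_surface(con)
            a <- nchar(text)
            text <- paste0(text, surf)
            ty <- c(S = "SAMPLE_TYPE", T = "TEST_PERFORMED", F = "FINDING")[[frag]]
            codes <- switch(ty,
              SAMPLE_TYPE = list(SNOMEDCT = con$code),
              TEST_PERFORMED = list(LOINC = con$code),
              FINDING = list(SNOMEDCT = con$code,
                             ICD11 = unname(icd_by_label[[con$label]])))
            entities[[length(entities) + 1L]] <-
              entity_mention(a, nchar(text), ty, surf, codes = codes)
          } else {
            text <- paste0(text, frag)
          }
        }
        sentences[[si]] <- c(sent_start, nchar(text))
        if (si < n_sent) text <- paste0(text, " ")
      }
      reports[[ri]] <- report(sprintf("R%04d", ri), text, language = lang,
                              sentences = sentences, entities = entities)
    }
    holdout_codes <- lapply(names(pools), function(ty)
      pools[[ty]]$code[holdout[[ty]]])
    names(holdout_codes) <- names(pools)
    structure(reports,
              split = if (q > 0)
                rep(c("train", "test"), c(n_train, cfg$n_reports - n_train))
              else NULL,
              holdout_codes = if (q > 0) holdout_codes else NULL)
  })
}

#' Generate a full synthetic corpus
#'
#' Convenience wrapper: builds the three concept tables and the report set
#' from one configuration.
#'
#' @param cfg a [generator_config()].
#' @return list with `tables` (named list of concept tables) and `reports`.
#' @export
generate_corpus <- function(cfg = generator_config()) {
  tables <- stats::setNames(lapply(terminologies(), function(t)
    generate_terminology(cfg, t)), terminologies())
  list(tables = tables, reports = generate_reports(cfg, tables), config = cfg)
}

#' Write a synthetic corpus to disk
#'
#' Writes `reports.jsonl`, one concept TSV per terminology, and a
#' `manifest.json` recording the seed and configuration.
#'
#' @param corpus a [generate_corpus()] result.
#' @param dir output directory.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_reports(corpus$reports, file.path(dir, "reports.jsonl"))
  for (t in names(corpus$tables))
    write_concepts(corpus$tables[[t]], file.path(dir, paste0(tolower(t), ".tsv")))
  cfg <- corpus$config
  manifest <- list(seed = cfg$seed, n_reports = cfg$n_reports,
                   config = unclass(cfg))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
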