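# Seeded synthetic corpora with the statistical structure the method
# assumes: sectioned notes containing long unambiguous rare-disease terms
# and short ambiguous abbreviations whose true sense is cued by nearby
# context words; a skewed per-concept candidate frequency distribution (a
# few concepts far above the prevalence threshold, many below); admission
# groupings; and deliberately under-coded ICD-9 lists.
#
# Cue-word injection makes the mention's sense a linear function of its
# bag of neighbours — exactly the structure a mean-pooled contextual vector
# plus logistic regression can learn, which is the minimal setting in which
# weak supervision can demonstrably beat the unfiltered linker.

#' Synthetic corpus configuration
#'
#' @param n_docs Number of documents.
#' @param concepts data.frame describing the concept inventory, one row per
#'   rare-disease concept: `umls_id`, `ordo_id`, `long_term` (unambiguous
#'   surface form), `abbreviation` (short ambiguous form, `NA` for none),
#'   `freq_target` (target fraction of all candidate links), `is_group`
#'   (group-of-disorders flag), `abbrev_share` (fraction of the concept's
#'   occurrences surfacing as the abbreviation), `disease_sense_rate`
#'   (probability an abbreviation occurrence truly denotes the disease), and
#'   list-columns `disease_cues` / `nondisease_cues` (context cue words for
#'   the disease and the competing non-disease sense).
#' @param mentions_per_doc Mean mention events per document (default 4).
#' @param docs_per_admission Range of documents per admission (default 1:3).
#' @param sections Section names notes are built from.
#' @param shared_disease_cues,shared_nondisease_cues Cue words shared across
#'   all disease (resp. non-disease) senses.
#' @param filler_words Neutral vocabulary.
#' @param cue_strength Probability each cue slot actually receives a cue
#'   word (default 1.0 = fully cued).
#' @param negation_rate Fraction of disease mentions wrapped in a negation
#'   template and flagged (default 0).
#' @param icd_undercoding_rate Fraction of true admission phenotypes omitted
#'   from the ICD code lists (default 0.5; real code lists miss many true
#'   phenotypes, which is what motivates text-based identification).
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A `corpus_config` object.
#' @export
corpus_config <- function(n_docs, concepts, mentions_per_doc = 4L,
                          docs_per_admission = c(1L, 3L),
                          sections = c("HPI", "PMH", "IMPRESSION", "PLAN"),
                          shared_disease_cues = c("diagnosed", "hereditary",
                            "genetic", "progressive", "deficiency",
                            "congenital", "confirmed", "phenotype"),
                          shared_nondisease_cues = c("routine", "device",
                            "schedule", "dose", "monitor", "unit"),
                          filler_words = c("patient", "noted", "stable",
                            "review", "continue", "daily", "today",
                            "chart", "plan", "followup", "ward", "seen",
                            "recent", "status", "hyperlipidemia"),
                          cue_strength = 1.0, negation_rate = 0,
                          icd_undercoding_rate = 0.5, seed = 42L) {
  if (nrow(concepts) == 0) stop("infeasible config: no concepts")
  needed <- c("umls_id", "ordo_id", "long_term", "abbreviation",
              "freq_target", "is_group", "abbrev_share", "disease_sense_rate",
              "disease_cues", "nondisease_cues")
  missing_cols <- setdiff(needed, names(concepts))
  if (length(missing_cols) > 0) {
    stop("concept table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(concepts$freq_target <= 0 | concepts$freq_target > 1)) {
    stop("concept frequency targets must be in (0, 1]")
  }
  all_disease <- unique(c(shared_disease_cues,
                          unlist(concepts$disease_cues, use.names = FALSE)))
  all_nondis <- unique(c(shared_nondisease_cues,
                         unlist(concepts$nondisease_cues, use.names = FALSE)))
  if (length(intersect(all_disease, all_nondis)) > 0) {
    stop("cue vocabularies must be disjoint across senses")
  }
  structure(list(n_docs = as.integer(n_docs), concepts = concepts,
                 mentions_per_doc = as.integer(mentions_per_doc),
                 docs_per_admission = as.integer(docs_per_admission),
                 sections = sections,
                 shared_disease_cues = shared_disease_cues,
                 shared_nondisease_cues = shared_nondisease_cues,
                 filler_words = filler_words, cue_strength = cue_strength,
                 negation_rate = negation_rate,
                 icd_undercoding_rate = icd_undercoding_rate,
                 seed = as.integer(seed)),
            class = "corpus_config")
}

# Deterministic per-concept event quota: largest-remainder apportionment of
# the normalised frequency targets, so realised candidate frequencies track
# their targets without sampling drift across seeds.
concept_quota <- function(freq_target, n_events) {
  share <- freq_target / sum(freq_target)
  raw <- share * n_events
  base <- floor(raw)
  left <- n_events - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Synthetic ICD-9/ICD-10 codes per concept row.
concept_icd9 <- function(i) sprintf("7%02d.%d", i %/% 10, i %% 10)
concept_icd10 <- function(i) sprintf("E7%02d.%d", i %/% 10, i %% 10)

GROUP_TRAP_ORDO <- "Orphanet_900001"
GROUP_TRAP_UMLS <- "C0900001"
NTBT_TRAP_ORDO <- "Orphanet_900002"
NTBT_TRAP_UMLS <- "C0900002"

# Ontology tables consistent with the concept inventory, plus one
# group-of-disorders trap mapping and one NTBT trap relation.
build_ontology_tables <- function(concepts) {
  n <- nrow(concepts)
  xrefs <- crossref(
    source_id = c(concepts$ordo_id, concepts$ordo_id,
                  GROUP_TRAP_ORDO, NTBT_TRAP_ORDO),
    target_id = c(concepts$umls_id, concept_icd10(seq_len(n)),
                  GROUP_TRAP_UMLS, NTBT_TRAP_UMLS),
    target_system = c(rep("UMLS", n), rep("ICD10", n), "UMLS", "UMLS"),
    relation = c(rep("E", n), rep("E", n), "E", "NTBT"))
  meta <- ordo_meta(
    ordo_id = c(concepts$ordo_id, GROUP_TRAP_ORDO, NTBT_TRAP_ORDO),
    label = c(concepts$long_term, "synthetic group-of-disorders trap",
              "synthetic NTBT trap"),
    is_group_of_disorders = c(concepts$is_group, TRUE, FALSE))
  icd9_to_icd10 <- data.frame(source = concept_icd9(seq_len(n)),
                              target = concept_icd10(seq_len(n)),
                              stringsAsFactors = FALSE)
  icd9_to_umls <- data.frame(source = concept_icd9(seq_len(n)),
                             target = concepts$umls_id,
                             stringsAsFactors = FALSE)
  list(xrefs = xrefs, meta = meta, icd9_to_icd10 = icd9_to_icd10,
       icd9_to_umls = icd9_to_umls)
}

# One sentence around a mention. Returns the sentence string and the
# mention's character offset within it.
build_sentence <- function(mention, sense_cues, filler, cue_strength,
                           negated) {
  pick <- function(pool, k) pool[sample.int(length(pool), k, replace = TRUE)]
  cue_or_filler <- function() {
    if (stats::runif(1) < cue_strength) pick(sense_cues, 1) else pick(filler, 1)
  }
  left <- c(pick(filler, 2), cue_or_filler(), cue_or_filler())
  if (negated) left <- c(left, "no", "evidence", "of")
  right <- c(cue_or_filler(), pick(filler, 1))
  words <- c(left, mention, right)
  sent <- paste0(paste(words, collapse = " "), " .")
  prefix <- sum(nchar(left)) + length(left)   # words before mention + spaces
  list(text = sent, m_start = prefix, m_end = prefix + nchar(mention))
}

#' Generate a synthetic corpus
#'
#' Fully deterministic given `config$seed`. Mention events are apportioned
#' to concepts by their frequency targets (largest-remainder quotas), each
#' event samples a surface form (long term vs abbreviation) and — for
#' abbreviations — a sense (disease vs non-disease), and that sense's cue
#' words are injected into the surrounding window with probability
#' `cue_strength`. The gold label is "sense is the disease AND not negated".
#' Admission groupings, deliberately under-coded ICD-9 lists, ontology
#' tables and a gazetteer lexicon consistent with the concept inventory are
#' emitted alongside.
#'
#' @param config A [corpus_config()].
#' @return A `syn_corpus`: list with `documents` (doc_id, text),
#'   `gold_links` (candidate links plus `label`, `form`, `sense` columns),
#'   `admissions` (doc_id, admission_id), `icd_codes` (admission_id,
#'   icd9_code), `ontology` (xrefs, meta, icd9_to_icd10, icd9_to_umls),
#'   `lexicon`, and `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  with_preserved_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  concepts <- config$concepts
  ontology <- build_ontology_tables(concepts)
  lex <- lexicon(
    terms = c(concepts$long_term,
              concepts$abbreviation[!is.na(concepts$abbreviation)],
              "hyperlipidemia"),
    umls_ids = c(concepts$umls_id,
                 concepts$umls_id[!is.na(concepts$abbreviation)],
                 GROUP_TRAP_UMLS))
  n_docs <- config$n_docs
  if (n_docs == 0) {
    return(structure(list(
      documents = data.frame(doc_id = character(0), text = character(0),
                             stringsAsFactors = FALSE),
      gold_links = cbind(empty_links(),
                         data.frame(label = integer(0), form = character(0),
                                    sense = character(0))),
      admissions = data.frame(doc_id = character(0),
                              admission_id = character(0),
                              stringsAsFactors = FALSE),
      icd_codes = data.frame(admission_id = character(0),
                             icd9_code = character(0),
                             stringsAsFactors = FALSE),
      ontology = ontology, lexicon = lex, config = config),
      class = "syn_corpus"))
  }
  n_events <- n_docs * config$mentions_per_doc
  quota <- concept_quota(concepts$freq_target, n_events)
  ev_concept <- rep.int(seq_len(nrow(concepts)), quota)
  n_ev <- length(ev_concept)
  has_abbr <- !is.na(concepts$abbreviation[ev_concept])
  ev_abbrev <- has_abbr &
    stats::runif(n_ev) < concepts$abbrev_share[ev_concept]
  ev_disease <- ifelse(ev_abbrev,
                       stats::runif(n_ev) < concepts$disease_sense_rate[ev_concept],
                       TRUE)
  ev_negated <- ev_disease & stats::runif(n_ev) < config$negation_rate
  ev_doc <- sample.int(n_docs, n_ev, replace = TRUE)
  ev_section <- sample(config$sections, n_ev, replace = TRUE)

  # admissions: consecutive docs grouped into admissions of sampled size
  doc_ids <- sprintf("doc-%04d", seq_len(n_docs))
  adm_of_doc <- character(n_docs)
  i <- 1L; a <- 0L
  rng <- config$docs_per_admission
  while (i <= n_docs) {
    a <- a + 1L
    size <- sample(seq(rng[1], rng[2]), 1L)
    take <- i:min(n_docs, i + size - 1L)
    adm_of_doc[take] <- sprintf("adm-%04d", a)
    i <- i + size
  }

  sec_levels <- config$sections
  link_rows <- vector("list", n_ev)
  doc_texts <- character(n_docs)
  ev_order <- order(ev_doc, match(ev_section, sec_levels))
  by_doc <- split(ev_order, ev_doc[ev_order])
  for (d in seq_len(n_docs)) {
    evs <- by_doc[[as.character(d)]]
    cursor <- 0L
    parts <- character(0)
    if (is.null(evs)) {
      doc_texts[d] <- "GENERAL:\nno acute findings ."
      next
    }
    for (sec in unique(ev_section[evs])) {
      header <- paste0(sec, ":\n")
      parts <- c(parts, header)
      cursor <- cursor + nchar(header)
      for (e in evs[ev_section[evs] == sec]) {
        ci <- ev_concept[e]
        mention <- if (ev_abbrev[e]) concepts$abbreviation[ci] else
          concepts$long_term[ci]
        sense_cues <- if (ev_disease[e]) {
          c(config$shared_disease_cues, concepts$disease_cues[[ci]])
        } else {
          c(config$shared_nondisease_cues, concepts$nondisease_cues[[ci]])
        }
        sent <- build_sentence(mention, sense_cues, config$filler_words,
                               config$cue_strength, ev_negated[e])
        link_rows[[e]] <- list(doc = d, sec = sec,
                               m_start = cursor + sent$m_start,
                               m_end = cursor + sent$m_end,
                               mention = mention, ci = ci)
        piece <- paste0(sent$text, " ")
        parts <- c(parts, piece)
        cursor <- cursor + nchar(piece)
      }
      parts <- c(parts, "\n")
      cursor <- cursor + 1L
    }
    doc_texts[d] <- paste(parts, collapse = "")
  }

  rows <- lapply(seq_len(n_ev), function(e) {
    lr <- link_rows[[e]]
    ctx <- extract_context_window(doc_texts[lr$doc], lr$m_start, lr$m_end,
                                  w = 5L)
    data.frame(doc_id = doc_ids[lr$doc], admission_id = adm_of_doc[lr$doc],
               m_start = lr$m_start, m_end = lr$m_end,
               mention_text = lr$mention,
               umls_id = concepts$umls_id[lr$ci], context = ctx$context,
               context_offset = ctx$context_offset, section = lr$sec,
               hypo_neg_flag = ev_negated[e],
               label = as.integer(ev_disease[e] & !ev_negated[e]),
               form = if (ev_abbrev[e]) "abbreviation" else "long",
               sense = if (ev_disease[e]) "disease" else "other",
               stringsAsFactors = FALSE)
  })
  gold_links <- do.call(rbind, rows)
  gold_links <- gold_links[order(gold_links$doc_id, gold_links$m_start), ,
                           drop = FALSE]
  rownames(gold_links) <- NULL
  gold_links <- candidate_links(gold_links)

  # true admission phenotypes -> under-coded ICD-9 lists
  true_pairs <- unique(gold_links[gold_links$label == 1L,
                                  c("admission_id", "umls_id")])
  icd_rows <- NULL
  if (nrow(true_pairs) > 0) {
    keep <- stats::runif(nrow(true_pairs)) >= config$icd_undercoding_rate
    kept <- true_pairs[keep, , drop = FALSE]
    if (nrow(kept) > 0) {
      ci <- match(kept$umls_id, concepts$umls_id)
      icd_rows <- data.frame(admission_id = kept$admission_id,
                             icd9_code = concept_icd9(ci),
                             stringsAsFactors = FALSE)
      icd_rows <- icd_rows[order(icd_rows$admission_id, icd_rows$icd9_code), ,
                           drop = FALSE]
      rownames(icd_rows) <- NULL
    }
  }
  if (is.null(icd_rows)) {
    icd_rows <- data.frame(admission_id = character(0),
                           icd9_code = character(0), stringsAsFactors = FALSE)
  }

  structure(list(
    documents = data.frame(doc_id = doc_ids, text = doc_texts,
                           stringsAsFactors = FALSE),
    gold_links = gold_links,
    admissions = data.frame(doc_id = doc_ids, admission_id = adm_of_doc,
                            stringsAsFactors = FALSE),
    icd_codes = icd_rows, ontology = ontology, lexicon = lex,
    config = config), class = "syn_corpus")
}

#' @export
print.syn_corpus <- function(x, ...) {
  cat("<syn_corpus> ", nrow(x$documents), " document(s), ",
      nrow(x$gold_links), " candidate link(s) (",
      sum(x$gold_links$label == 1L), " true), ",
      length(unique(x$admissions$admission_id)), " admission(s)\n", sep = "")
  invisible(x)
}

# Default concept inventories ------------------------------------------------

syllables <- c("tra", "cheo", "bron", "malo", "dys", "tro", "phi", "neu",
               "ro", "myo", "path", "ia", "gen", "osis", "enia", "card")

make_rare_name <- function(i) {
  # deterministic pseudo-clinical polysyllabic term, unique per index
  b <- length(syllables)
  digits <- c(i %% b, (i %/% b) %% b, (i * 7) %% b)
  paste0(paste(syllables[digits + 1], collapse = ""), "osis")
}

make_abbrev <- function(i) {
  letters3 <- expand.grid(LETTERS[1:20], LETTERS[1:20])
  paste0("R", letters3[i, 1], letters3[i, 2])
}

default_concepts <- function(n_prevalent, n_rare_abbrev, n_rare_long,
                             prevalent_freq = 0.20, rare_freq = 0.002) {
  prevalent <- data.frame(
    umls_id = sprintf("C01000%02d", seq_len(n_prevalent)),
    ordo_id = sprintf("Orphanet_1000%02d", seq_len(n_prevalent)),
    long_term = c("huntington disease", "pompe disease", "marfan syndrome",
                  "gaucher disease")[seq_len(n_prevalent)],
    abbreviation = c("HD", "PD", "MS", "GD")[seq_len(n_prevalent)],
    freq_target = prevalent_freq, is_group = FALSE, abbrev_share = 0.98,
    disease_sense_rate = 0.01, stringsAsFactors = FALSE)
  prevalent$disease_cues <- replicate(n_prevalent, character(0), simplify = FALSE)
  prevalent$nondisease_cues <- list(
    c("dialysis", "line", "pulled"), c("hospital", "admitted", "transfer"),
    c("tablet", "mg", "dispensed"), c("scan", "ordered", "protocol")
  )[seq_len(n_prevalent)]
  n_rare <- n_rare_abbrev + n_rare_long
  rare <- data.frame(
    umls_id = sprintf("C02000%02d", seq_len(n_rare)),
    ordo_id = sprintf("Orphanet_2000%02d", seq_len(n_rare)),
    long_term = vapply(seq_len(n_rare), make_rare_name, character(1)),
    abbreviation = c(vapply(seq_len(n_rare_abbrev), make_abbrev, character(1)),
                     rep(NA_character_, n_rare_long)),
    freq_target = rare_freq, is_group = FALSE,
    abbrev_share = c(rep(0.4, n_rare_abbrev), rep(0, n_rare_long)),
    disease_sense_rate = 0.5, stringsAsFactors = FALSE)
  rare$disease_cues <- lapply(seq_len(n_rare), function(i) {
    paste0(c("marker", "variant"), i)
  })
  rare$nondisease_cues <- lapply(seq_len(n_rare), function(i) {
    paste0(c("proc", "sched"), i)
  })
  rbind(prevalent, rare)
}

#' Ready-made end-to-end fixtures
#'
#' Two scales of a complete synthetic study: `"tiny"` (20 documents — unit
#' tests) and `"standard"` (1,200 documents — the scale the package's
#' summary results are computed at). Both inventories contain ambiguous
#' prevalent abbreviations violating the prevalence rule at p = 0.005 and
#' many genuinely rare concepts below it, and the ontology tables include
#' one group-of-disorders trap mapping and one NTBT trap relation.
#'
#' @param scale `"tiny"` or `"standard"`.
#' @param seed Integer seed (default 42).
#' @param ... Overrides passed to [corpus_config()] (e.g. `negation_rate`).
#' @return A list: `corpus` (the generated [generate_corpus()] output),
#'   `umls_to_ordo`, `icd9_to_ordo` (maps built from the fixture ontology),
#'   `rare_set`, `params` (default [weak_rule_params()]), and `strategy`
#'   (default [encoding_strategy()]).
#' @export
make_end_to_end_fixture <- function(scale = c("tiny", "standard"),
                                    seed = 42L, ...) {
  scale <- match.arg(scale)
  concepts <- if (scale == "tiny") {
    default_concepts(n_prevalent = 1, n_rare_abbrev = 3, n_rare_long = 4,
                     prevalent_freq = 0.4, rare_freq = 0.08)
  } else {
    default_concepts(n_prevalent = 3, n_rare_abbrev = 20, n_rare_long = 40)
  }
  n_docs <- if (scale == "tiny") 20L else 1200L
  config <- corpus_config(n_docs = n_docs, concepts = concepts,
                          seed = seed, ...)
  corpus <- generate_corpus(config)
  map <- build_umls_to_ordo_map(corpus$ontology$xrefs, corpus$ontology$meta)
  icd9_map <- build_icd9_to_ordo_map(corpus$ontology$icd9_to_icd10,
                                     corpus$ontology$icd9_to_umls,
                                     corpus$ontology$xrefs,
                                     corpus$ontology$meta)
  list(corpus = corpus, umls_to_ordo = map, icd9_to_ordo = icd9_map,
       rare_set = rare_umls_set(map), params = weak_rule_params(),
       strategy = encoding_strategy())
}

#' Write a synthetic corpus to disk
#'
#' Plain-text layout: `documents/<doc_id>.txt`, `links.jsonl` (candidate
#' links without gold columns), `gold.jsonl` (with gold columns),
#' `admissions.tsv`, `icd.tsv`, `lexicon.tsv` and `ontology/*.tsv` — all
#' readable back through the package loaders.
#'
#' @param corpus A `syn_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "documents"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "ontology"), showWarnings = FALSE)
  for (i in seq_len(nrow(corpus$documents))) {
    writeLines(corpus$documents$text[i],
               file.path(dir, "documents",
                         paste0(corpus$documents$doc_id[i], ".txt")))
  }
  plain <- as.data.frame(corpus$gold_links)
  write_links(plain[, LINK_FIELDS], file.path(dir, "links.jsonl"))
  write_links(plain, file.path(dir, "gold.jsonl"))
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  tsv(corpus$admissions, "admissions.tsv")
  tsv(corpus$icd_codes, "icd.tsv")
  tsv(data.frame(term = corpus$lexicon$terms,
                 umls_id = corpus$lexicon$umls_ids), "lexicon.tsv")
  tsv(as.data.frame(corpus$ontology$xrefs), file.path("ontology", "xrefs.tsv"))
  meta_out <- corpus$ontology$meta
  meta_out$is_group_of_disorders <- tolower(as.character(meta_out$is_group_of_disorders))
  tsv(meta_out, file.path("ontology", "ordo_meta.tsv"))
  tsv(corpus$ontology$icd9_to_icd10, file.path("ontology", "icd9_to_icd10.tsv"))
  tsv(corpus$ontology$icd9_to_umls, file.path("ontology", "icd9_to_umls.tsv"))
  invisible(dir)
}
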