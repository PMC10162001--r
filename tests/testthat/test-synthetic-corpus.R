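test_that("corpus generation is deterministic given the seed", {
  fx1 <- make_end_to_end_fixture("tiny", seed = 42)
  fx2 <- make_end_to_end_fixture("tiny", seed = 42)
  expect_identical(fx1$corpus$documents, fx2$corpus$documents)
  expect_identical(as.data.frame(fx1$corpus$gold_links),
                   as.data.frame(fx2$corpus$gold_links))
  expect_identical(fx1$corpus$icd_codes, fx2$corpus$icd_codes)
  # a different seed changes the text
  fx3 <- make_end_to_end_fixture("tiny", seed = 43)
  expect_false(identical(fx1$corpus$documents, fx3$corpus$documents))
})

test_that("degenerate configurations are handled", {
  concepts <- default_concepts(1, 0, 2, prevalent_freq = 0.5, rare_freq = 0.1)
  empty <- generate_corpus(corpus_config(n_docs = 0, concepts = concepts))
  expect_equal(nrow(empty$documents), 0)
  expect_equal(nrow(empty$gold_links), 0)
  expect_error(corpus_config(n_docs = 5, concepts = concepts[0, ]),
               "no concepts")
  bad <- concepts; bad$freq_target[1] <- 0
  expect_error(corpus_config(n_docs = 5, concepts = bad),
               "frequency targets")
})

test_that("cue vocabularies must be disjoint across senses", {
  concepts <- default_concepts(1, 1, 1, prevalent_freq = 0.5, rare_freq = 0.2)
  concepts$disease_cues[[2]] <- c("dialysis")   # collides with non-disease
  expect_error(corpus_config(n_docs = 5, concepts = concepts), "disjoint")
})

test_that("realised candidate frequencies track their targets", {
  fx <- standard_fixture()
  corpus <- fx$corpus
  concepts <- corpus$config$concepts
  freqs <- concept_frequencies(corpus$gold_links)
  total <- nrow(corpus$gold_links)
  share <- concepts$freq_target / sum(concepts$freq_target)
  for (i in seq_len(nrow(concepts))) {
    realised <- unname(freqs[concepts$umls_id[i]]) / total
    expect_lt(abs(realised - share[i]) / share[i], 0.2)
  }
  # the skew the rules rely on: prevalent concepts far above the default
  # threshold, rare concepts below it
  expect_true(any(share > 0.005) && any(share < 0.005))
})

test_that("gold links satisfy the span invariants against their documents", {
  fx <- tiny_fixture()
  corpus <- fx$corpus
  gold <- as.data.frame(corpus$gold_links)
  docs <- stats::setNames(corpus$documents$text, corpus$documents$doc_id)
  expect_equal(unname(substring(docs[gold$doc_id], gold$m_start + 1,
                                gold$m_end)),
               gold$mention_text)
  # context windows are document substrings containing the mention
  expect_equal(unname(substring(docs[gold$doc_id], gold$context_offset + 1,
                                gold$context_offset + nchar(gold$context))),
               gold$context)
})

test_that("the gazetteer recovers every non-negated gold mention span", {
  fx <- tiny_fixture()
  corpus <- fx$corpus
  gold <- as.data.frame(corpus$gold_links)
  for (i in seq_len(nrow(corpus$documents))) {
    d <- corpus$documents$doc_id[i]
    found <- gazetteer_candidates(d, corpus$documents$text[i],
                                  corpus$lexicon, fx$rare_set)
    g <- gold[gold$doc_id == d & !gold$hypo_neg_flag, ]
    missing <- setdiff(paste(g$m_start, g$m_end),
                       paste(found$m_start, found$m_end))
    expect_length(missing, 0)
  }
})

test_that("ICD lists are an under-coded subset of the true phenotype cohort", {
  fx <- standard_fixture()
  corpus <- fx$corpus
  gold <- as.data.frame(corpus$gold_links)
  concepts <- corpus$config$concepts
  true_pairs <- unique(paste(gold$admission_id[gold$label == 1L],
                             gold$umls_id[gold$label == 1L]))
  icd <- corpus$icd_codes
  # every ICD code traces back to a truly present phenotype
  icd_concept <- concepts$umls_id[match(icd$icd9_code,
                                        sprintf("7%02d.%d",
                                                seq_len(nrow(concepts)) %/% 10,
                                                seq_len(nrow(concepts)) %% 10))]
  icd_pairs <- unique(paste(icd$admission_id, icd_concept))
  expect_true(all(icd_pairs %in% true_pairs))
  # and with under-coding rate 0.5 the subset is strict
  expect_lt(length(icd_pairs), length(true_pairs))
})

test_that("fixture scales and ontology traps are as constructed", {
  tiny <- tiny_fixture()
  expect_lte(nrow(tiny$corpus$documents), 20)

  fx <- standard_fixture()
  freqs <- concept_frequencies(fx$corpus$gold_links)
  total <- nrow(fx$corpus$gold_links)
  # at least one concept violates the prevalence rule at p = 0.005
  expect_true(any(freqs / total >= 0.005))

  # traps: a group-of-disorders mapping and an NTBT relation exist in the
  # raw tables but never reach the filtered map
  xrefs <- fx$corpus$ontology$xrefs
  meta <- fx$corpus$ontology$meta
  group_ids <- meta$ordo_id[meta$is_group_of_disorders]
  expect_gte(length(group_ids), 1)
  expect_true(any(xrefs$relation == "NTBT"))
  trap_umls <- xrefs$target_id[xrefs$source_id %in% group_ids |
                                 xrefs$relation == "NTBT"]
  expect_false(any(trap_umls %in% fx$rare_set))
})

test_that("a written corpus round-trips through the package loaders", {
  fx <- tiny_fixture()
  dir <- tempfile("corpus")
  write_corpus(fx$corpus, dir)

  xrefs <- load_crossref_table(file.path(dir, "ontology", "xrefs.tsv"))
  expect_identical(as.data.frame(xrefs),
                   as.data.frame(fx$corpus$ontology$xrefs))
  meta <- load_ordo_meta(file.path(dir, "ontology", "ordo_meta.tsv"))
  expect_identical(meta, fx$corpus$ontology$meta)
  map <- build_umls_to_ordo_map(xrefs, meta)
  expect_identical(map$entries, fx$umls_to_ordo$entries)

  links <- read_links(file.path(dir, "links.jsonl"))
  expect_equal(nrow(links), nrow(fx$corpus$gold_links))
  lex <- read_lexicon(file.path(dir, "lexicon.tsv"))
  expect_setequal(lex$terms, fx$corpus$lexicon$terms)

  pairs <- load_pair_table(file.path(dir, "ontology", "icd9_to_icd10.tsv"))
  expect_identical(pairs, fx$corpus$ontology$icd9_to_icd10)
})

test_that("negation templates are generated, flagged, and labelled negative", {
  concepts <- default_concepts(1, 2, 3, prevalent_freq = 0.3, rare_freq = 0.1)
  cfg <- corpus_config(n_docs = 30, concepts = concepts,
                       negation_rate = 0.5, seed = 9)
  corpus <- generate_corpus(cfg)
  gold <- as.data.frame(corpus$gold_links)
  flagged <- gold[gold$hypo_neg_flag, ]
  expect_gt(nrow(flagged), 0)
  expect_true(all(flagged$label == 0L))
  # the negation template precedes the mention in the text
  docs <- stats::setNames(corpus$documents$text, corpus$documents$doc_id)
  lead <- substring(docs[flagged$doc_id],
                    pmax(1, flagged$m_start - 15), flagged$m_start)
  expect_true(all(grepl("evidence of", lead)))
})
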