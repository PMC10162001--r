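# End-to-end inference and cohort comparison: candidate links are encoded,
# filtered by the confirmation model, mapped to ORDO per document, then
# aggregated to admissions; the text-derived (NLP) cohort is compared with
# the ICD-code-derived cohort per ORDO concept.

#' Run text-to-ORDO inference
#'
#' Composes the inference chain: (optionally) drop links flagged
#' hypothetical/negated upstream, encode each mention in context, keep the
#' links the confirmation model accepts, map each confirmed UMLS concept
#' through the UMLS-to-ORDO map, and union per document.
#'
#' @param links Candidate links, already restricted to the rare-disease UMLS
#'   vocabulary (see [restrict_to_rare()]).
#' @param backend Encoder backend (see [encode_links()]).
#' @param strategy An [encoding_strategy()].
#' @param model A `confirmation_model`.
#' @param umls_to_ordo A `umls_ordo_map`.
#' @param drop_flagged Drop `hypo_neg_flag` links before inference
#'   (default TRUE).
#' @return A `doc_ordo_results`: list with `by_doc` (named list, document ->
#'   character vector of ORDO ids) and `support` (data.frame of confirmed
#'   links with their probabilities and mapped ORDO ids).
#' @export
run_text_to_ordo <- function(links, backend, strategy, model, umls_to_ordo,
                             drop_flagged = TRUE) {
  stopifnot(inherits(umls_to_ordo, "umls_ordo_map"))
  all_docs <- unique(links$doc_id)
  if (drop_flagged) {
    links <- links[!links$hypo_neg_flag, , drop = FALSE]
  }
  confirmed <- tryCatch({
    vectors <- encode_links(links, backend, strategy)
    confirm_links(links, vectors, model)
  }, error = function(e) stop("text-to-ORDO inference failed at encoding/",
                              "confirmation stage: ", conditionMessage(e)))
  support <- NULL
  if (nrow(confirmed) > 0) {
    rows <- lapply(seq_len(nrow(confirmed)), function(i) {
      ordos <- map_umls_to_ordo(confirmed$umls_id[i], umls_to_ordo)
      if (length(ordos) == 0) return(NULL)
      data.frame(doc_id = confirmed$doc_id[i],
                 admission_id = confirmed$admission_id[i],
                 m_start = confirmed$m_start[i], m_end = confirmed$m_end[i],
                 mention_text = confirmed$mention_text[i],
                 umls_id = confirmed$umls_id[i],
                 probability = confirmed$probability[i],
                 ordo_id = ordos, stringsAsFactors = FALSE)
    })
    support <- do.call(rbind, rows)
  }
  if (is.null(support)) {
    support <- data.frame(doc_id = character(0), admission_id = character(0),
                          m_start = integer(0), m_end = integer(0),
                          mention_text = character(0), umls_id = character(0),
                          probability = numeric(0), ordo_id = character(0),
                          stringsAsFactors = FALSE)
  }
  by_doc <- stats::setNames(
    lapply(all_docs, function(d) sort(unique(support$ordo_id[support$doc_id == d]))),
    all_docs)
  structure(list(by_doc = by_doc, support = support),
            class = "doc_ordo_results")
}

#' @export
print.doc_ordo_results <- function(x, ...) {
  nonempty <- sum(lengths(x$by_doc) > 0)
  cat("<doc_ordo_results> ", length(x$by_doc), " document(s), ", nonempty,
      " with >= 1 rare-disease concept; ", nrow(x$support),
      " supporting link-concept pair(s)\n", sep = "")
  invisible(x)
}

#' Aggregate document results to admissions
#'
#' Unions the per-document ORDO sets over each admission's documents.
#' Documents absent from the table become singleton admissions keyed by
#' their own `doc_id`.
#'
#' @param results A `doc_ordo_results`.
#' @param doc_admissions data.frame(`doc_id`, `admission_id`).
#' @return Named list: admission id -> character vector of ORDO ids.
#' @export
aggregate_admissions <- function(results, doc_admissions) {
  by_doc <- results$by_doc
  docs <- names(by_doc)
  adm <- doc_admissions$admission_id[match(docs, doc_admissions$doc_id)]
  adm[is.na(adm) | !nzchar(adm)] <- docs[is.na(adm) | !nzchar(adm)]
  out <- lapply(split(docs, adm), function(ds) {
    sort(unique(unlist(by_doc[ds], use.names = FALSE)))
  })
  out
}

#' ICD-code-derived admission cohort
#'
#' @param admission_icd data.frame(`admission_id`, `icd9_code`).
#' @param icd9_map An `icd9_ordo_map`.
#' @return Named list: admission id -> character vector of ORDO ids (the
#'   union over the admission's codes; empty vectors for admissions none of
#'   whose codes map).
#' @export
icd_cohort <- function(admission_icd, icd9_map) {
  if (nrow(admission_icd) == 0) return(stats::setNames(list(), character(0)))
  lapply(split(admission_icd$icd9_code, admission_icd$admission_id),
         function(codes) {
           sort(unique(unlist(lapply(codes, map_icd9_to_ordo, map = icd9_map),
                              use.names = FALSE)))
         })
}

#' Compare NLP and ICD admission cohorts per concept
#'
#' For every ORDO concept appearing in either cohort, counts the admissions
#' identified only by ICD codes, only by the text pipeline, and by both.
#'
#' @param nlp Named list: admission -> ORDO ids (text-derived).
#' @param icd Named list: admission -> ORDO ids (code-derived).
#' @return data.frame(`ordo_id`, `icd_only`, `nlp_only`, `both`), one row
#'   per concept; per concept `icd_only + both` and `nlp_only + both` equal
#'   the concept's ICD and NLP cohort sizes.
#' @export
compare_cohorts <- function(nlp, icd) {
  pairs <- function(coh) {
    if (length(coh) == 0) return(character(0))
    unlist(lapply(names(coh), function(a) {
      if (length(coh[[a]]) == 0) return(character(0))
      paste(a, coh[[a]], sep = "\r")
    }), use.names = FALSE)
  }
  np <- pairs(nlp); ip <- pairs(icd)
  concepts <- sort(unique(c(sub("^.*\r", "", np), sub("^.*\r", "", ip))))
  if (length(concepts) == 0) {
    return(data.frame(ordo_id = character(0), icd_only = integer(0),
                      nlp_only = integer(0), both = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- lapply(concepts, function(cc) {
    n_adm <- sub("\r.*$", "", np[endsWith(np, paste0("\r", cc))])
    i_adm <- sub("\r.*$", "", ip[endsWith(ip, paste0("\r", cc))])
    data.frame(ordo_id = cc,
               icd_only = length(setdiff(i_adm, n_adm)),
               nlp_only = length(setdiff(n_adm, i_adm)),
               both = length(intersect(n_adm, i_adm)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
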