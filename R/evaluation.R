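# Evaluation machinery: mention-level precision/recall/F1, stratification by
# weak-supervision visibility (seen vs unseen), admission-level micro
# multi-label metrics, ontology-matching accuracy, and inter-annotator
# agreement (Cohen's and Fleiss' kappa).
#
# All metrics are kept at full precision internally; rounding (half-up, one
# decimal) happens only at the reporting boundary.

#' Build an evaluation report from counts
#' @param tp,fp,fn True-positive, false-positive, false-negative counts.
#' @param stratum Label for the evaluated stratum (e.g. "all", "seen").
#' @return A one-row data.frame of class `eval_report` with percentages at
#'   full precision; `print` rounds half-up to one decimal.
#' @export
eval_report <- function(tp, fp, fn, stratum = "all") {
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  out <- data.frame(stratum = stratum, tp = as.integer(tp),
                    fp = as.integer(fp), fn = as.integer(fn),
                    precision = precision, recall = recall, f1 = f1,
                    stringsAsFactors = FALSE)
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in c("precision", "recall", "f1")) {
    y[[col]] <- round_half_up(y[[col]], 1L)
  }
  print(y)
  invisible(x)
}

#' Mention-level precision/recall/F1
#'
#' Evaluates a set of predicted (confirmed) link keys against a labelled
#' gold standard. By default the evaluation is closed-world over the gold
#' key set (the annotation protocol labels candidate pairs, so predictions
#' outside it are ignored); with `closed_world = FALSE` extra predictions
#' count as false positives, supporting gold sets that extend beyond the
#' candidate pool.
#'
#' @param gold data.frame with key columns `doc_id`, `m_start`, `m_end`,
#'   `umls_id` and a 0/1 (or logical) `label` column; keys must be unique.
#' @param predicted Character vector of predicted keys (from [link_key_of()])
#'   or a data.frame with the key columns.
#' @param closed_world Restrict scoring to the gold key set (default TRUE).
#' @param stratum Stratum label for the report.
#' @return An [eval_report()].
#' @export
prf <- function(gold, predicted, closed_world = TRUE, stratum = "all") {
  gkeys <- link_key(gold)
  if (anyDuplicated(gkeys)) stop("duplicate gold keys")
  pkeys <- if (is.data.frame(predicted)) link_key(predicted) else predicted
  pkeys <- unique(pkeys)
  lab <- as.integer(gold$label)
  pos <- gkeys[lab == 1L]
  neg <- gkeys[lab == 0L]
  tp <- length(intersect(pkeys, pos))
  fp <- length(intersect(pkeys, neg))
  if (!closed_world) fp <- fp + length(setdiff(pkeys, gkeys))
  fn <- length(setdiff(pos, pkeys))
  eval_report(tp, fp, fn, stratum = stratum)
}

#' Key identifying a mention-UMLS link
#' @param df data.frame with `doc_id`, `m_start`, `m_end`, `umls_id`.
#' @return Character vector of keys, one per row.
#' @export
link_key_of <- function(df) link_key(df)

#' F1 from printed precision and recall
#'
#' Harmonic mean of two percentages, reported half-up to one decimal — the
#' arithmetic used to recompute published F1 cells from their P/R pairs.
#'
#' @param p,r Precision and recall in percent.
#' @return F1 in percent, rounded to one decimal (0 when `p + r == 0`).
#' @export
f1_from_pr <- function(p, r) {
  ifelse(p + r > 0, round_half_up(2 * p * r / (p + r), 1L), 0)
}

#' Split gold pairs by weak-supervision visibility
#'
#' "Seen" pairs are those on which the two weak rules agree (they would be
#' weakly labelled during training); "unseen" pairs satisfy exactly one
#' rule and were never labelled. Unseen pairs are split by which rule
#' fired: `unseen-lambda1` (only the mention-length rule) or
#' `unseen-lambda2` (only the prevalence rule).
#'
#' @param gold data.frame with the link key columns.
#' @param params A [weak_rule_params()].
#' @param corpus_links The corpus candidate links from which concept
#'   frequencies are computed.
#' @return Factor parallel to `gold` rows with levels `seen`,
#'   `unseen-lambda1`, `unseen-lambda2`.
#' @export
seen_unseen_split <- function(gold, params, corpus_links) {
  if (nrow(gold) == 0) {
    return(factor(character(0),
                  levels = c("seen", "unseen-lambda1", "unseen-lambda2")))
  }
  freqs <- concept_frequencies(corpus_links)
  lam1 <- rule_mention_length(gold, params$l)
  lam2 <- rule_prevalence(gold$umls_id, freqs, nrow(corpus_links), params$p)
  out <- ifelse(lam1 == lam2, "seen",
                ifelse(lam1, "unseen-lambda1", "unseen-lambda2"))
  factor(out, levels = c("seen", "unseen-lambda1", "unseen-lambda2"))
}

#' Admission-level micro multi-label metrics
#'
#' Treats each (admission, ORDO concept) pair as one instance and scores
#' predicted against gold pair sets.
#'
#' @param gold Named list: admission -> character vector of ORDO ids.
#' @param predicted Named list in the same form.
#' @return An [eval_report()] with stratum `"admission-micro"`.
#' @export
micro_admission_metrics <- function(gold, predicted) {
  flat <- function(coh) {
    unlist(lapply(names(coh), function(a) {
      if (length(coh[[a]]) == 0) return(character(0))
      paste(a, coh[[a]], sep = "\r")
    }), use.names = FALSE)
  }
  g <- unique(flat(gold)); p <- unique(flat(predicted))
  eval_report(tp = length(intersect(p, g)), fp = length(setdiff(p, g)),
              fn = length(setdiff(g, p)), stratum = "admission-micro")
}

#' Ontology-matching accuracy
#'
#' Accuracy of concept mappings judged correct/incorrect, both per unique
#' mapping and weighted by how many mentions each mapping covers.
#'
#' @param correct Logical vector, one element per unique mapping.
#' @param multiplicity Integer vector of mention counts per mapping
#'   (default 1, giving the unweighted view twice).
#' @return List with `unique_accuracy` and `weighted_accuracy`, both in
#'   percent at full precision.
#' @export
matching_accuracy <- function(correct, multiplicity = rep(1L, length(correct))) {
  if (length(correct) != length(multiplicity)) {
    stop("correct and multiplicity must have equal length")
  }
  if (length(correct) == 0) {
    return(list(unique_accuracy = 0, weighted_accuracy = 0))
  }
  list(unique_accuracy = 100 * sum(correct) / length(correct),
       weighted_accuracy = 100 * sum(multiplicity[correct]) / sum(multiplicity))
}

#' Cohen's kappa for two raters
#' @param r1,r2 Parallel vectors of category labels.
#' @return Kappa in [-1, 1].
#' @export
cohen_kappa <- function(r1, r2) {
  if (length(r1) != length(r2) || length(r1) == 0) {
    stop("two non-empty rating vectors of equal length are required")
  }
  r1 <- as.character(r1); r2 <- as.character(r2)
  cats <- sort(unique(c(r1, r2)))
  n <- length(r1)
  po <- mean(r1 == r2)
  pe <- sum(vapply(cats, function(cc) mean(r1 == cc) * mean(r2 == cc),
                   numeric(1)))
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Fleiss' kappa for k raters
#'
#' Observed-vs-chance agreement for a fixed panel of raters; for two raters
#' the statistic reduces to the usual pairwise agreement structure.
#'
#' @param ratings Matrix (or data.frame) of category labels, one row per
#'   subject, one column per rater.
#' @return Kappa in [-1, 1].
#' @export
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n == 0 || k < 2) stop("need >= 1 subject and >= 2 raters")
  cats <- sort(unique(as.character(ratings)))
  counts <- t(apply(ratings, 1, function(row) {
    vapply(cats, function(cc) sum(row == cc), integer(1))
  }))
  counts <- matrix(counts, nrow = n)   # guard the single-category case
  p_i <- (rowSums(counts^2) - k) / (k * (k - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / (n * k)
  pe <- sum(p_j^2)
  if (pe == 1) return(1)
  (p_bar - pe) / (1 - pe)
}
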