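# Weak supervision over candidate links: two labelling rules, XNOR data
# selection with AND labelling, and the grid search over rule parameters.
#
# Rule 1 (mention length): a candidate passes when the mention is longer than
# l characters — short surface forms are mostly ambiguous abbreviations.
# Rule 2 (prevalence): a candidate passes when its UMLS concept accounts for
# less than a fraction p of all candidate links — genuinely rare phenotypes
# are mentioned rarely in a consecutive sample of notes. Both inequalities
# are strict. A link enters the weak training set only when the rules agree
# (XNOR); its label is positive only when both hold (AND). Links where
# exactly one rule fires stay unlabelled.

#' Weak-rule parameters
#' @param l Mention character-length threshold (default 3): rule 1 requires
#'   strictly more than `l` characters.
#' @param p Prevalence threshold as a fraction of all candidate links
#'   (default 0.005): rule 2 requires Freq(c)/|L| strictly below `p`.
#' @return A `weak_rule_params` object.
#' @export
weak_rule_params <- function(l = 3L, p = 0.005) {
  l <- as.integer(l)
  if (is.na(l) || l < 0L) stop("l must be a non-negative integer")
  if (!is.finite(p) || p <= 0 || p > 1) stop("p must be in (0, 1]")
  structure(list(l = l, p = p), class = "weak_rule_params")
}

#' @export
print.weak_rule_params <- function(x, ...) {
  cat("<weak_rule_params> l = ", x$l, ", p = ", x$p, "\n", sep = "")
  invisible(x)
}

#' Mention character-length rule
#' @param links A `candidate_links` table (or any data.frame with
#'   `m_start`/`m_end`).
#' @param l Length threshold.
#' @return Logical vector: `(m_end - m_start) > l` per link.
#' @export
rule_mention_length <- function(links, l = 3L) {
  (links$m_end - links$m_start) > l
}

#' Per-concept candidate frequencies
#' @param links A `candidate_links` table.
#' @return Named integer vector of counts per UMLS id; counts sum to the
#'   number of links.
#' @export
concept_frequencies <- function(links) {
  if (nrow(links) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(links$umls_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Concept prevalence rule
#' @param umls_id UMLS id(s) to test.
#' @param freqs Named counts from [concept_frequencies()].
#' @param total Total number of candidate links |L|.
#' @param p Prevalence threshold.
#' @return Logical: `Freq(c)/total < p` (strict). Ids absent from `freqs`
#'   count as frequency zero.
#' @export
rule_prevalence <- function(umls_id, freqs, total, p = 0.005) {
  if (total <= 0) stop("prevalence undefined: total candidate count is zero")
  f <- freqs[umls_id]
  f[is.na(f)] <- 0L
  unname(f / total < p)
}

#' Weakly label a candidate-link list
#'
#' Evaluates both rules per link (frequencies computed once over the full
#' input list), selects links where the rules agree (XNOR) and labels them by
#' the conjunction (AND): positive when both hold, negative when neither
#' does. Links where exactly one rule fires are left unlabelled.
#'
#' @param links A `candidate_links` table.
#' @param params A [weak_rule_params()].
#' @return A `weak_dataset`: list with `positive`, `negative`, `unlabelled`
#'   link tables (labelled ones carry `y_weak`), `params`, and `total`.
#' @export
weak_label_dataset <- function(links, params = weak_rule_params()) {
  stopifnot(inherits(params, "weak_rule_params"))
  n <- nrow(links)
  if (n == 0) {
    empty <- links
    out <- list(positive = empty, negative = empty, unlabelled = empty,
                params = params, total = 0L)
    class(out) <- "weak_dataset"
    return(out)
  }
  freqs <- concept_frequencies(links)
  lam1 <- rule_mention_length(links, params$l)
  lam2 <- rule_prevalence(links$umls_id, freqs, n, params$p)
  selected <- lam1 == lam2
  label <- lam1 & lam2
  pos <- links[selected & label, , drop = FALSE]
  neg <- links[selected & !label, , drop = FALSE]
  unl <- links[!selected, , drop = FALSE]
  if (nrow(pos) > 0) pos$y_weak <- 1L
  if (nrow(neg) > 0) neg$y_weak <- 0L
  rownames(pos) <- rownames(neg) <- rownames(unl) <- NULL
  out <- list(positive = pos, negative = neg, unlabelled = unl,
              params = params, total = n)
  class(out) <- "weak_dataset"
  out
}

#' @export
print.weak_dataset <- function(x, ...) {
  cat("<weak_dataset> |L| = ", x$total, ": ", nrow(x$positive), " positive, ",
      nrow(x$negative), " negative, ", nrow(x$unlabelled), " unlabelled",
      " (l = ", x$params$l, ", p = ", x$params$p, ")\n", sep = "")
  invisible(x)
}

#' Rules-only confirmation baseline
#'
#' The disjunction of the two rules, used for reporting a rules-only
#' classifier (a recall-oriented OR, distinct from the XNOR/AND used to
#' create training data): a link is predicted a true phenotype when either
#' rule fires.
#'
#' @param links A `candidate_links` table.
#' @param params A [weak_rule_params()].
#' @param freqs,total Optional precomputed frequencies and total (defaults:
#'   computed from `links`).
#' @return Logical vector of per-link predictions.
#' @export
rules_only_predict <- function(links, params = weak_rule_params(),
                               freqs = NULL, total = NULL) {
  if (nrow(links) == 0) return(logical(0))
  if (is.null(freqs)) freqs <- concept_frequencies(links)
  if (is.null(total)) total <- nrow(links)
  rule_mention_length(links, params$l) |
    rule_prevalence(links$umls_id, freqs, total, params$p)
}

#' Grid search over weak-rule parameters
#'
#' Evaluates the rules-only (OR) classifier against a gold standard for every
#' grid cell and returns the best cell under the objective. Ties break
#' toward higher recall, then larger `p`, then smaller `l`, then first in
#' grid order — deterministic and recall-biased.
#'
#' @param links The corpus candidate links (used for concept frequencies).
#' @param gold A data.frame with key columns `doc_id`, `m_start`, `m_end`,
#'   `umls_id` and a 0/1 `label` column.
#' @param grid_l Integer vector of `l` values (default `c(3, 4)`).
#' @param grid_p Numeric vector of `p` values (default
#'   `c(0.0005, 0.005, 0.01)`).
#' @param objective `"f1"` or `"recall"`.
#' @return A list with `params` (the best [weak_rule_params()]) and `table`
#'   (per-cell precision/recall/F1).
#' @export
tune_rule_params <- function(links, gold, grid_l = c(3L, 4L),
                             grid_p = c(0.0005, 0.005, 0.01),
                             objective = c("f1", "recall")) {
  objective <- match.arg(objective)
  if (length(grid_l) == 0 || length(grid_p) == 0) stop("empty parameter grid")
  if (anyDuplicated(link_key(gold))) stop("duplicate gold keys")
  freqs <- concept_frequencies(links)
  total <- nrow(links)
  # evaluate rules on the gold items themselves (their mention lengths and
  # corpus-level concept frequencies)
  cells <- expand.grid(l = as.integer(grid_l), p = grid_p,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    prm <- weak_rule_params(cells$l[i], cells$p[i])
    pred <- rules_only_predict(gold, prm, freqs = freqs, total = total)
    rep <- prf(gold, link_key(gold)[pred],
               stratum = sprintf("l=%d,p=%g", prm$l, prm$p))
    cbind(cells[i, , drop = FALSE], rep[, c("precision", "recall", "f1")])
  })
  table <- do.call(rbind, res)
  rownames(table) <- NULL
  score <- if (objective == "f1") table$f1 else table$recall
  best <- which(score == max(score))
  if (length(best) > 1) {
    ord <- order(-table$recall[best], -table$p[best], table$l[best], best)
    best <- best[ord[1]]
  }
  list(params = weak_rule_params(table$l[best], table$p[best]), table = table)
}
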