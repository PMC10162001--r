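# Shared fixture builders. Everything is generated in code at test time;
# the larger fixtures are memoised so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  hit <- .fixture_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- builder()
  assign(key, val, envir = .fixture_cache)
  val
}

tiny_fixture <- function() cached("tiny", function() make_end_to_end_fixture("tiny"))

standard_fixture <- function() {
  cached("standard", function() make_end_to_end_fixture("standard"))
}

# Rare-restricted candidate links of the standard fixture plus their stub
# encodings (the expensive part, shared by several tests).
standard_encoded <- function() {
  cached("standard_encoded", function() {
    fx <- standard_fixture()
    links <- restrict_to_rare(fx$corpus$gold_links, fx$rare_set)
    list(fx = fx, links = links,
         vectors = encode_links(links, stub_encoder, fx$strategy))
  })
}

# Build one candidate link by locating `mention` inside `doc_text`.
link_from_doc <- function(doc_text, mention, umls_id, doc_id = "d1",
                          occurrence = 1L, w = 5L, section = "",
                          admission_id = "") {
  m <- gregexpr(mention, doc_text, fixed = TRUE)[[1]]
  stopifnot(m[1] != -1L, length(m) >= occurrence)
  m_start <- as.integer(m[occurrence]) - 1L
  m_end <- m_start + nchar(mention)
  ctx <- extract_context_window(doc_text, m_start, m_end, w = w)
  candidate_links(data.frame(
    doc_id = doc_id, admission_id = admission_id, m_start = m_start,
    m_end = m_end, mention_text = mention, umls_id = umls_id,
    context = ctx$context, context_offset = ctx$context_offset,
    section = section, hypo_neg_flag = FALSE, stringsAsFactors = FALSE))
}

# Random valid candidate links: mentions of mixed lengths over a skewed
# concept distribution (a few frequent ids, many rare ones).
random_links <- function(n, seed = 1L, n_docs = max(2L, n %/% 3L)) {
  set.seed(seed)
  mentions <- c("HD", "PD", "RX", "abcd", "widefield",
                "tracheobronchomalacia", "longmentionterm")
  ids <- c(rep("C0000001", 4), rep("C0000002", 2),
           paste0("C10000", sprintf("%02d", 1:20)))
  rows <- lapply(seq_len(n), function(i) {
    mention <- sample(mentions, 1)
    left <- paste(sample(letters, sample(0:4, 1), replace = TRUE), collapse = " ")
    right <- paste(sample(letters, sample(0:4, 1), replace = TRUE), collapse = " ")
    doc <- trimws(paste(left, mention, right))
    m_start <- if (nzchar(left)) nchar(left) + 1L else 0L
    data.frame(doc_id = sprintf("d%02d", sample.int(n_docs, 1)),
               admission_id = "", m_start = m_start,
               m_end = m_start + nchar(mention), mention_text = mention,
               umls_id = sample(ids, 1), context = doc, context_offset = 0L,
               section = sample(c("", "PMH", "HPI"), 1),
               hypo_neg_flag = FALSE, stringsAsFactors = FALSE)
  })
  candidate_links(do.call(rbind, rows))
}

# Independent brute-force evaluation of the two weak rules for one link.
oracle_rules <- function(links, i, l, p) {
  len_ok <- (links$m_end[i] - links$m_start[i]) > l
  freq <- sum(links$umls_id == links$umls_id[i])
  prev_ok <- freq / nrow(links) < p
  c(lambda1 = len_ok, lambda2 = prev_ok)
}

# A confirmation model with fixed weights/bias (bypasses training), for
# pipeline tests that need an accept-all or reject-all filter.
fixed_model <- function(d, bias, weights = rep(0, d), threshold = 0.5) {
  structure(list(weights = weights, bias = bias, threshold = threshold,
                 provenance = "weak",
                 train_meta = list(n = 0L, seed = 0L, reg_strength = 1,
                                   max_iter = 100L, tol = 1e-4,
                                   converged = TRUE)),
            class = "confirmation_model")
}
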