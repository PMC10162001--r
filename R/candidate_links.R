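# Candidate mention-UMLS link records: the 5-element tuples (mention span,
# UMLS concept, context window, document-structure name) that every
# downstream stage consumes, plus the toy gazetteer that stands in for an
# upstream NER+L tool.

LINK_FIELDS <- c("doc_id", "admission_id", "m_start", "m_end", "mention_text",
                 "umls_id", "context", "context_offset", "section",
                 "hypo_neg_flag")

#' Construct a candidate-link table
#'
#' A candidate link records one potential mention of a rare-disease concept:
#' the character span of the mention in its source document (0-based,
#' end-exclusive, code points), the UMLS concept a linker assigned, the
#' surrounding context window, and the document-structure (section) name.
#' `hypo_neg_flag` carries an upstream hypothetical/negation/experiencer
#' marker; it is never computed here.
#'
#' @param df A data.frame with columns `doc_id`, `admission_id`, `m_start`,
#'   `m_end`, `mention_text`, `umls_id`, `context`, `context_offset`,
#'   `section`, `hypo_neg_flag`. Missing `admission_id`/`section` may be
#'   empty strings.
#' @return The validated data.frame with class `candidate_links`.
#' @export
candidate_links <- function(df) {
  missing_cols <- setdiff(LINK_FIELDS, names(df))
  if (length(missing_cols) > 0) {
    stop("candidate link table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)[,
    c(LINK_FIELDS, setdiff(names(df), LINK_FIELDS)), drop = FALSE]
  df$m_start <- as.integer(df$m_start)
  df$m_end <- as.integer(df$m_end)
  df$context_offset <- as.integer(df$context_offset)
  df$hypo_neg_flag <- as.logical(df$hypo_neg_flag)
  bad <- validate_link_rows(df)
  if (length(bad) > 0) {
    stop("invalid candidate link row(s) ", paste(utils::head(bad, 10), collapse = ", "),
         " (doc_id ", paste(unique(df$doc_id[utils::head(bad, 10)]), collapse = ", "),
         "): span/context invariants violated")
  }
  class(df) <- c("candidate_links", "data.frame")
  df
}

# Returns row indices violating the span invariants:
#   0 <= m_start < m_end, mention inside the context window, and
#   mention_text equal to the context substring at the mention span.
validate_link_rows <- function(df) {
  n <- nrow(df)
  if (n == 0) return(integer(0))
  ok <- !is.na(df$m_start) & !is.na(df$m_end) &
    df$m_start >= 0L & df$m_start < df$m_end &
    df$context_offset >= 0L &
    df$m_start >= df$context_offset &
    df$m_end <= df$context_offset + nchar(df$context)
  rel_start <- df$m_start - df$context_offset
  rel_end <- df$m_end - df$context_offset
  sub <- substr0(df$context, pmax(rel_start, 0L), pmax(rel_end, 0L))
  which(!(ok & !is.na(sub) & sub == df$mention_text))
}

#' @export
print.candidate_links <- function(x, ...) {
  cat("<candidate_links> ", nrow(x), " link(s), ",
      length(unique(x$doc_id)), " document(s), ",
      length(unique(x$umls_id)), " UMLS concept(s)\n", sep = "")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x)[, c("doc_id", "m_start",
    "m_end", "mention_text", "umls_id", "section")], 6))
  invisible(x)
}

#' Read candidate links from a JSONL file
#'
#' One JSON object per line with the `candidate_links` field names. Records
#' violating the span invariants are rejected with their line numbers.
#'
#' @param path Path to a JSONL file.
#' @return A `candidate_links` table.
#' @export
read_links <- function(path) {
  if (!file.exists(path)) stop("link file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(candidate_links(empty_links()))
  }
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("malformed JSON on line ", i,
                                             " of ", path, ": ", conditionMessage(e)))
    for (f in setdiff(LINK_FIELDS, names(rec))) {
      rec[[f]] <- if (f %in% c("m_start", "m_end", "context_offset")) NA_integer_
                  else if (f == "hypo_neg_flag") FALSE else ""
    }
    recs[[i]] <- as.data.frame(rec[LINK_FIELDS], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, recs)
  df$m_start <- as.integer(df$m_start)
  df$m_end <- as.integer(df$m_end)
  df$context_offset <- as.integer(df$context_offset)
  bad <- validate_link_rows(df)
  if (length(bad) > 0) {
    stop("invalid candidate link record(s) at line(s) ",
         paste(bad, collapse = ", "), " of ", path,
         " (doc_id: ", paste(unique(df$doc_id[bad]), collapse = ", "), ")")
  }
  candidate_links(df)
}

#' Write candidate links to a JSONL file
#'
#' Inverse of [read_links()]: `read_links(write_links(x, p))` round-trips.
#' Any extra columns (e.g. `y_weak`, `probability`) are written too.
#'
#' @param links A `candidate_links` table (or plain data.frame with the fields).
#' @param path Output path.
#' @return Invisibly, the number of records written.
#' @export
write_links <- function(links, path) {
  df <- as.data.frame(links)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(df) > 0) {
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null"),
                 con, useBytes = TRUE)
    }
  }
  invisible(nrow(df))
}

empty_links <- function() {
  data.frame(doc_id = character(0), admission_id = character(0),
             m_start = integer(0), m_end = integer(0),
             mention_text = character(0), umls_id = character(0),
             context = character(0), context_offset = integer(0),
             section = character(0), hypo_neg_flag = logical(0),
             stringsAsFactors = FALSE)
}

#' Extract the context window around a mention
#'
#' The window spans `w` whitespace-delimited tokens to the left and right of
#' the mention (fewer at document edges) plus the mention itself. With
#' `w = 0` the context is exactly the mention text.
#'
#' @param doc_text Full document text.
#' @param m_start,m_end Mention span, 0-based end-exclusive code points.
#' @param w Number of context tokens on each side (default 5).
#' @return A list with `context` and `context_offset`.
#' @export
extract_context_window <- function(doc_text, m_start, m_end, w = 5L) {
  n <- nchar(doc_text)
  if (m_start < 0 || m_end > n || m_start >= m_end) {
    stop("mention span [", m_start, ", ", m_end, ") outside document of length ", n)
  }
  if (w == 0L) {
    return(list(context = substr0(doc_text, m_start, m_end),
                context_offset = as.integer(m_start)))
  }
  toks <- tokenize_ws(doc_text)
  left <- toks[toks$end <= m_start, , drop = FALSE]
  right <- toks[toks$start >= m_end, , drop = FALSE]
  lstart <- if (nrow(left) > 0) {
    left$start[max(1L, nrow(left) - w + 1L)]
  } else m_start
  rend <- if (nrow(right) > 0) {
    right$end[min(w, nrow(right))]
  } else m_end
  cstart <- min(lstart, m_start)
  cend <- max(rend, m_end)
  list(context = substr0(doc_text, cstart, cend),
       context_offset = as.integer(cstart))
}

#' Read a gazetteer lexicon from TSV
#'
#' Two tab-separated columns, `term` and `umls_id`, with a header row. Each
#' surface term maps to exactly one UMLS concept (a most-frequent-sense
#' prior, mimicking how fast string-matching linkers resolve ambiguity).
#'
#' @param path TSV path.
#' @param case_sensitive Whether matching should respect case (default FALSE).
#' @return A `lexicon` object.
#' @export
read_lexicon <- function(path, case_sensitive = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  if (!all(c("term", "umls_id") %in% names(df))) {
    stop("lexicon TSV must have columns 'term' and 'umls_id'")
  }
  lexicon(df$term, df$umls_id, case_sensitive = case_sensitive)
}

#' Construct a lexicon
#' @param terms Character vector of surface terms.
#' @param umls_ids Parallel vector of UMLS ids.
#' @param case_sensitive Whether matching respects case.
#' @return A `lexicon` object.
#' @export
lexicon <- function(terms, umls_ids, case_sensitive = FALSE) {
  terms <- trimws2(terms)
  umls_ids <- toupper(trimws2(umls_ids))
  if (any(!nzchar(terms))) stop("lexicon terms must be non-empty")
  if (anyDuplicated(if (case_sensitive) terms else tolower(terms))) {
    stop("each lexicon term must map to exactly one UMLS id")
  }
  structure(list(terms = terms, umls_ids = umls_ids,
                 case_sensitive = case_sensitive),
            class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon> ", length(x$terms), " term(s), case_",
      if (x$case_sensitive) "sensitive" else "insensitive", "\n", sep = "")
  invisible(x)
}

is_word_char <- function(ch) grepl("[[:alnum:]]", ch)

#' Find candidate links in a document with a gazetteer
#'
#' Longest-match-first, left-to-right, non-overlapping dictionary matching at
#' word boundaries (a transition between alphanumeric and non-alphanumeric
#' characters, so "HD" never fires inside "CHD"). Only terms whose UMLS id is
#' in `rare_set` are emitted; ambiguity between senses of a surface form is
#' deliberately NOT resolved here — that is the confirmation model's job.
#'
#' @param doc_id Document identifier.
#' @param doc_text Document text.
#' @param lex A [lexicon()].
#' @param rare_set Character vector of UMLS ids linked to rare-disease
#'   concepts (the key set of the UMLS-to-ORDO map).
#' @param admission_id Optional admission identifier (default "").
#' @param sections Optional data.frame(`section`, `start`, `end`) assigning
#'   document-structure names to character ranges.
#' @param w Context window size in tokens.
#' @return A `candidate_links` table with `hypo_neg_flag = FALSE`.
#' @export
gazetteer_candidates <- function(doc_id, doc_text, lex, rare_set,
                                 admission_id = "", sections = NULL, w = 5L) {
  stopifnot(inherits(lex, "lexicon"))
  keep <- lex$umls_ids %in% toupper(rare_set)
  terms <- lex$terms[keep]
  ids <- lex$umls_ids[keep]
  if (length(terms) == 0 || nchar(doc_text) == 0) {
    return(candidate_links(empty_links()))
  }
  ord <- order(-nchar(terms))
  terms <- terms[ord]; ids <- ids[ord]
  hay <- if (lex$case_sensitive) doc_text else tolower(doc_text)
  occupied <- logical(nchar(doc_text))
  hits <- list()
  for (k in seq_along(terms)) {
    needle <- if (lex$case_sensitive) terms[k] else tolower(terms[k])
    m <- gregexpr(needle, hay, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.integer(m) - 1L
    len <- nchar(needle)
    for (s in starts) {
      e <- s + len
      # word boundaries on both sides
      before <- if (s > 0) substr0(doc_text, s - 1L, s) else ""
      after <- if (e < nchar(doc_text)) substr0(doc_text, e, e + 1L) else ""
      if (nzchar(before) && is_word_char(before) &&
          is_word_char(substr0(doc_text, s, s + 1L))) next
      if (nzchar(after) && is_word_char(after) &&
          is_word_char(substr0(doc_text, e - 1L, e))) next
      if (any(occupied[(s + 1L):e])) next
      occupied[(s + 1L):e] <- TRUE
      hits[[length(hits) + 1L]] <- list(start = s, end = e, umls_id = ids[k])
    }
  }
  if (length(hits) == 0) return(candidate_links(empty_links()))
  hits <- hits[order(vapply(hits, `[[`, integer(1), "start"))]
  rows <- lapply(hits, function(h) {
    ctx <- extract_context_window(doc_text, h$start, h$end, w = w)
    sec <- ""
    if (!is.null(sections) && nrow(sections) > 0) {
      i <- which(sections$start <= h$start & h$end <= sections$end)
      if (length(i) > 0) sec <- sections$section[i[1]]
    }
    data.frame(doc_id = doc_id, admission_id = admission_id,
               m_start = h$start, m_end = h$end,
               mention_text = substr0(doc_text, h$start, h$end),
               umls_id = h$umls_id, context = ctx$context,
               context_offset = ctx$context_offset, section = sec,
               hypo_neg_flag = FALSE, stringsAsFactors = FALSE)
  })
  candidate_links(do.call(rbind, rows))
}

#' Keep only links to rare-disease concepts
#'
#' @param links A `candidate_links` table.
#' @param rare_set Character vector of UMLS ids (O^rare_UMLS).
#' @return The subset of `links` whose `umls_id` is in `rare_set`, order
#'   preserved.
#' @export
restrict_to_rare <- function(links, rare_set) {
  out <- links[links$umls_id %in% toupper(rare_set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
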