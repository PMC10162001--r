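# Contextual mention representation: encoder-input preparation (optional
# mention masking and section prepending), token-character alignment, layer
# selection, and mean pooling of the mention's token rows into one vector.
#
# The encoder itself is pluggable: any function from input text to an
# `encoder_output` (tokens with character offsets plus a stack of hidden
# layers) satisfies the backend contract. Production use would adapt a
# pretrained transformer; tests and the synthetic pipeline use the
# deterministic stub encoder shipped with the package.

SECTION_DELIM <- ": "   # joins the document-structure name to the context

#' Encoding strategy
#'
#' @param mask_mention Replace the mention surface by a mask symbol before
#'   encoding (default FALSE; non-masked encoding performs better when the
#'   mention identity is informative).
#' @param include_section Prepend the document-structure (section) name to
#'   the context (default TRUE).
#' @param layer_index Offset from the top of the layer stack for feature
#'   extraction: 0 is the top layer, 1 the second-last (default 1 — the
#'   second-last layer is less specialised toward the pre-training losses
#'   and carries better contextual features).
#' @param pooling Aggregation over the mention's token rows; only
#'   `"mean"` is provided.
#' @return An `encoding_strategy` object.
#' @export
encoding_strategy <- function(mask_mention = FALSE, include_section = TRUE,
                              layer_index = 1L, pooling = "mean") {
  if (!identical(pooling, "mean")) stop("only mean pooling is supported")
  structure(list(mask_mention = isTRUE(mask_mention),
                 include_section = isTRUE(include_section),
                 layer_index = as.integer(layer_index), pooling = pooling),
            class = "encoding_strategy")
}

#' Construct an encoder output
#' @param tokens data.frame(`text`, `start`, `end`) with 0-based,
#'   end-exclusive, non-overlapping, ordered character offsets into the
#'   encoder input text.
#' @param layers List of numeric matrices (one per layer, bottom first),
#'   each `nrow(tokens)` x `dim`.
#' @param dim Embedding dimensionality.
#' @return An `encoder_output` object.
#' @export
encoder_output <- function(tokens, layers, dim) {
  stopifnot(is.data.frame(tokens), is.list(layers), length(layers) >= 2)
  for (H in layers) {
    if (!is.matrix(H) || nrow(H) != nrow(tokens) || ncol(H) != dim) {
      stop("every layer must be a |tokens| x dim matrix")
    }
  }
  if (nrow(tokens) > 1) {
    if (any(diff(tokens$start) <= 0) || any(tokens$start[-1] < tokens$end[-nrow(tokens)])) {
      stop("token spans must be ordered and non-overlapping")
    }
  }
  structure(list(tokens = tokens, layers = layers, dim = dim),
            class = "encoder_output")
}

#' @export
print.encoder_output <- function(x, ...) {
  cat("<encoder_output> ", nrow(x$tokens), " token(s), ",
      length(x$layers), " layer(s), dim ", x$dim, "\n", sep = "")
  invisible(x)
}

#' Prepare the encoder input for one link
#'
#' Optionally prepends the section name (`section`, a colon and a space) and
#' optionally replaces the mention surface with `mask_symbol`. Returns the
#' input text together with the mention's character span inside it.
#'
#' @param link One-row `candidate_links` table (or list with the fields).
#' @param strategy An [encoding_strategy()].
#' @param mask_symbol Mask token text (default `"[MASK]"`).
#' @return List with `text` and `span` (0-based, end-exclusive c(start, end)).
#' @export
prepare_encoder_input <- function(link, strategy = encoding_strategy(),
                                  mask_symbol = "[MASK]") {
  ctx <- link$context
  rel_start <- link$m_start - link$context_offset
  rel_end <- link$m_end - link$context_offset
  if (isTRUE(strategy$mask_mention)) {
    ctx <- paste0(substr0(ctx, 0L, rel_start), mask_symbol,
                  substr0(ctx, rel_end, nchar(link$context)))
    rel_end <- rel_start + nchar(mask_symbol)
  }
  if (isTRUE(strategy$include_section) && nzchar(link$section)) {
    shift <- nchar(link$section) + nchar(SECTION_DELIM)
    ctx <- paste0(link$section, SECTION_DELIM, ctx)
    rel_start <- rel_start + shift
    rel_end <- rel_end + shift
  }
  list(text = ctx, span = c(as.integer(rel_start), as.integer(rel_end)))
}

#' Align a mention character span to token indices
#'
#' Returns the minimal contiguous token range covering every token that
#' overlaps the character span (overlap, not containment: subword tokenisers
#' may merge mention boundaries with neighbouring characters). Indices are
#' 1-based and inclusive.
#'
#' @param span `c(start, end)`, 0-based end-exclusive character offsets.
#' @param tokens data.frame(`text`, `start`, `end`).
#' @return `c(first, last)` token indices.
#' @export
align_mention_to_tokens <- function(span, tokens) {
  hit <- which(tokens$start < span[2] & tokens$end > span[1])
  if (length(hit) == 0) {
    stop("no token overlaps mention span [", span[1], ", ", span[2],
         "): tokenizer/offset mismatch")
  }
  c(min(hit), max(hit))
}

#' Pool a mention vector from an encoder output
#'
#' Takes the layer addressed by the strategy (`layer_index` below the top;
#' default the second-last) and averages its rows over the inclusive token
#' span — only tokens within the mention contribute.
#'
#' @param enc An [encoder_output()].
#' @param token_span `c(first, last)` 1-based inclusive token indices.
#' @param strategy An [encoding_strategy()].
#' @return Numeric vector of length `enc$dim`.
#' @export
pool_mention_vector <- function(enc, token_span, strategy = encoding_strategy()) {
  n_layers <- length(enc$layers)
  idx <- n_layers - strategy$layer_index
  if (idx < 1 || idx > n_layers) {
    stop("layer_index ", strategy$layer_index, " addresses no layer (stack of ",
         n_layers, ")")
  }
  H <- enc$layers[[idx]]
  rows <- token_span[1]:token_span[2]
  if (any(rows < 1 | rows > nrow(H))) stop("token span outside encoder output")
  colMeans(H[rows, , drop = FALSE])
}

# Symmetric truncation around the mention for backends with a token limit.
truncate_around_mention <- function(text, span, max_tokens) {
  toks <- tokenize_ws(text)
  if (nrow(toks) <= max_tokens) return(list(text = text, span = span))
  mspan <- align_mention_to_tokens(span, toks)
  halo <- max(0L, (max_tokens - (mspan[2] - mspan[1] + 1L)) %/% 2L)
  first <- max(1L, mspan[1] - halo)
  last <- min(nrow(toks), mspan[2] + halo)
  cstart <- toks$start[first]
  cend <- toks$end[last]
  list(text = substr0(text, cstart, cend),
       span = c(span[1] - cstart, span[2] - cstart))
}

#' Encode candidate links into mention vectors
#'
#' Runs prepare -> encode -> align -> pool for each link. The backend is any
#' deterministic function `function(text) -> encoder_output`; if it carries a
#' `max_tokens` attribute, inputs are truncated symmetrically around the
#' mention first. Its `mask_symbol` attribute, when present, overrides the
#' default mask token.
#'
#' @param links A `candidate_links` table.
#' @param backend Encoder backend function.
#' @param strategy An [encoding_strategy()].
#' @return A numeric matrix with one row per link (in input order) and an
#'   attached `link_key` attribute (data.frame `doc_id`, `m_start`, `m_end`,
#'   `umls_id`).
#' @export
encode_links <- function(links, backend, strategy = encoding_strategy()) {
  stopifnot(is.function(backend))
  mask_symbol <- attr(backend, "mask_symbol")
  if (is.null(mask_symbol)) mask_symbol <- "[MASK]"
  max_tokens <- attr(backend, "max_tokens")
  n <- nrow(links)
  out <- NULL
  for (i in seq_len(n)) {
    link <- links[i, , drop = FALSE]
    v <- tryCatch({
      prep <- prepare_encoder_input(link, strategy, mask_symbol = mask_symbol)
      if (!is.null(max_tokens)) {
        prep <- truncate_around_mention(prep$text, prep$span, max_tokens)
      }
      enc <- backend(prep$text)
      tspan <- align_mention_to_tokens(prep$span, enc$tokens)
      pool_mention_vector(enc, tspan, strategy)
    }, error = function(e) {
      stop("encoding failed for link (", link$doc_id, ", ", link$m_start, ", ",
           link$m_end, ", ", link$umls_id, "): ", conditionMessage(e))
    })
    if (is.null(out)) out <- matrix(0, nrow = n, ncol = length(v))
    out[i, ] <- v
  }
  if (is.null(out)) out <- matrix(0, nrow = 0, ncol = 0)
  attr(out, "link_key") <- as.data.frame(links)[, c("doc_id", "m_start",
                                                    "m_end", "umls_id"),
                                               drop = FALSE]
  out
}
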