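# Internal helpers shared across modules.

#' Run an expression under a temporary RNG state
#'
#' Evaluates `expr` with the random number generator seeded to `seed`, then
#' restores whatever global RNG state existed before the call. All package
#' randomness flows through this helper so no function pollutes the session
#' seed.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Tokenise a string into whitespace-delimited tokens with 0-based,
# end-exclusive code-point offsets. Returns a data.frame(text, start, end).
tokenize_ws <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || nchar(text) == 0L) {
    return(data.frame(text = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(text = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(m) - 1L                       # to 0-based
  lens <- attr(m, "match.length")
  data.frame(
    text = substring(text, starts + 1L, starts + lens),
    start = starts,
    end = starts + lens,
    stringsAsFactors = FALSE
  )
}

# Substring by 0-based, end-exclusive code-point offsets.
substr0 <- function(text, start, end) {
  substring(text, start + 1L, end)
}

# Round half-up to `digits` decimals; base round() is round-half-even, which
# does not match how results tables are conventionally printed.
round_half_up <- function(x, digits = 1L) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

trimws2 <- function(x) trimws(as.character(x))

# Stable key identifying one mention-UMLS link.
link_key <- function(df) {
  paste(df$doc_id, df$m_start, df$m_end, df$umls_id, sep = "\r")
}
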