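# Deterministic stub encoder.
#
# A tiny, fully deterministic drop-in for the encoder backend contract, with
# just enough structure to make the pipeline's behaviour observable in
# tests: token identity lives in the bottom layer, context sensitivity in
# the middle layer (each token row mixes in its neighbours, so cue words
# near a mention shift the mention's vector), and the top layer is a fixed
# rotation of the middle one so that layer selection is detectable.

STUB_DIM <- 64L
STUB_NEIGHBOUR_WINDOW <- 5L

.stub_cache <- new.env(parent = emptyenv())

# Deterministic polynomial hash of a token (31-base rolling hash mod 2^31-1).
token_hash <- function(token) {
  codes <- utf8ToInt(token)
  h <- 0
  for (cd in codes) h <- (h * 31 + cd) %% 2147483647
  as.integer(h)
}

# Unit vector derived from the token's hash; cached per token.
stub_token_vector <- function(token) {
  hit <- .stub_cache[[token]]
  if (!is.null(hit)) return(hit)
  v <- with_preserved_seed(token_hash(token) + 1L, stats::rnorm(STUB_DIM))
  v <- v / sqrt(sum(v^2))
  assign(token, v, envir = .stub_cache)
  v
}

# Fixed orthogonal rotation (QR of a seeded Gaussian matrix), computed once.
stub_rotation <- function() {
  hit <- .stub_cache[[".rotation"]]
  if (!is.null(hit)) return(hit)
  M <- with_preserved_seed(987654321L,
    matrix(stats::rnorm(STUB_DIM * STUB_DIM), STUB_DIM, STUB_DIM))
  Q <- qr.Q(qr(M))
  assign(".rotation", Q, envir = .stub_cache)
  Q
}

#' Deterministic stub encoder backend
#'
#' Tokenises on whitespace with exact character offsets and returns a
#' three-layer stack of 64-dimensional representations:
#' \itemize{
#'   \item H0 — per-token hash-derived unit vectors (pure token identity);
#'   \item H1 — for each token, the normalised sum of its own H0 row and
#'     0.5 times the mean of neighbouring H0 rows within 5 tokens
#'     (context-sensitive: the same token gets different rows in different
#'     contexts);
#'   \item H2 — H1 under a fixed orthogonal rotation (so selecting a
#'     different layer visibly changes downstream vectors).
#' }
#' Identical input text always yields identical output. Satisfies the
#' encoder backend contract of [encode_links()].
#'
#' @param text Input text.
#' @return An [encoder_output()] with 3 layers and dim 64.
#' @export
stub_encoder <- function(text) {
  toks <- tokenize_ws(text)
  n <- nrow(toks)
  if (n == 0) {
    Z <- matrix(0, nrow = 0, ncol = STUB_DIM)
    return(encoder_output(toks, list(Z, Z, Z), STUB_DIM))
  }
  H0 <- t(vapply(toks$text, stub_token_vector, numeric(STUB_DIM)))
  rownames(H0) <- NULL
  H1 <- matrix(0, n, STUB_DIM)
  for (i in seq_len(n)) {
    lo <- max(1L, i - STUB_NEIGHBOUR_WINDOW)
    hi <- min(n, i + STUB_NEIGHBOUR_WINDOW)
    nb <- setdiff(lo:hi, i)
    v <- H0[i, ]
    if (length(nb) > 0) {
      v <- v + 0.5 * colMeans(H0[nb, , drop = FALSE])
    }
    H1[i, ] <- v / sqrt(sum(v^2))
  }
  H2 <- H1 %*% stub_rotation()
  encoder_output(toks, list(H0, H1, H2), STUB_DIM)
}
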