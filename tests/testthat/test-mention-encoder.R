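test_that("encoder input preparation shifts spans for sections and masking", {
  link <- link_from_doc("a b c TARGET d e f", "TARGET", "C1", w = 1L,
                        section = "PMH")
  prep <- prepare_encoder_input(link, encoding_strategy())
  expect_equal(prep$text, "PMH: c TARGET d")
  # span shifted by len("PMH") + 2 and still covering the mention
  expect_equal(substr(prep$text, prep$span[1] + 1, prep$span[2]), "TARGET")

  prep2 <- prepare_encoder_input(link, encoding_strategy(include_section = FALSE))
  expect_equal(prep2$text, "c TARGET d")
  expect_equal(substr(prep2$text, prep2$span[1] + 1, prep2$span[2]), "TARGET")

  prep3 <- prepare_encoder_input(link,
                                 encoding_strategy(mask_mention = TRUE,
                                                   include_section = FALSE))
  expect_false(grepl("TARGET", prep3$text, fixed = TRUE))
  expect_equal(substr(prep3$text, prep3$span[1] + 1, prep3$span[2]), "[MASK]")
})

test_that("mention-to-token alignment uses the overlap rule", {
  tokens <- data.frame(text = c("a", "bb", "ccc", "dd", "ee", "ff", "g"),
                       start = c(0, 2, 5, 9, 12, 15, 18),
                       end = c(1, 4, 8, 11, 14, 17, 19))
  # mention exactly token 3
  expect_equal(align_mention_to_tokens(c(5, 8), tokens), c(3, 3))
  # mention split across tokens 4-6; brute-force overlap scan agrees
  span <- c(10, 16)
  expect_equal(align_mention_to_tokens(span, tokens), c(4, 6))
  brute <- which(vapply(seq_len(nrow(tokens)), function(i) {
    max(tokens$start[i], span[1]) < min(tokens$end[i], span[2])
  }, logical(1)))
  expect_equal(align_mention_to_tokens(span, tokens),
               c(min(brute), max(brute)))
  # sharing a single character with token 2 includes it
  expect_equal(align_mention_to_tokens(c(3, 6), tokens)[1], 2)
  expect_error(align_mention_to_tokens(c(100, 110), tokens), "mismatch")
})

test_that("pooling averages the selected layer over the mention tokens", {
  tokens <- data.frame(text = c("x", "y", "z"), start = c(0, 2, 4),
                       end = c(1, 3, 5))
  H_bottom <- matrix(1:6, nrow = 3, ncol = 2)
  H_mid <- rbind(c(0, 2), c(2, 0), c(5, 5))
  H_top <- matrix(9, nrow = 3, ncol = 2)
  enc <- encoder_output(tokens, list(H_bottom, H_mid, H_top), 2L)

  # default: the second-last layer of the stack
  expect_equal(pool_mention_vector(enc, c(1, 1)), H_mid[1, ])
  expect_equal(pool_mention_vector(enc, c(1, 2)), c(1, 1))
  # layer selection is live
  expect_equal(pool_mention_vector(enc, c(1, 1),
                                   encoding_strategy(layer_index = 0L)),
               H_top[1, ])
  expect_equal(pool_mention_vector(enc, c(1, 1),
                                   encoding_strategy(layer_index = 2L)),
               H_bottom[1, ])
  expect_error(pool_mention_vector(enc, c(1, 1),
                                   encoding_strategy(layer_index = 5L)),
               "layer")
  # mean equals sum/len exactly
  expect_identical(pool_mention_vector(enc, c(1, 3)),
                   colSums(H_mid) / 3)
})

test_that("random spans pool to the brute-force row average", {
  set.seed(4)
  tokens <- data.frame(text = letters[1:8], start = seq(0, 14, 2),
                       end = seq(1, 15, 2))
  H <- matrix(rnorm(8 * 5), 8, 5)
  enc <- encoder_output(tokens, list(H * 2, H, H + 1), 5L)
  for (rep in 1:10) {
    i <- sort(sample.int(8, 2))
    v <- pool_mention_vector(enc, i)
    expect_equal(v, colMeans(H[i[1]:i[2], , drop = FALSE]), tolerance = 1e-12)
  }
})

test_that("the stub encoder is deterministic and context-sensitive", {
  a <- stub_encoder("dialysis line HD pulled today")
  b <- stub_encoder("dialysis line HD pulled today")
  expect_identical(a$layers, b$layers)
  expect_equal(a$dim, 64L)
  expect_length(a$layers, 3)
  # exact character offsets
  expect_equal(a$tokens$text,
               c("dialysis", "line", "HD", "pulled", "today"))
  expect_equal(substring("dialysis line HD pulled today",
                         a$tokens$start + 1, a$tokens$end), a$tokens$text)

  # same token in two cue contexts: identical bottom row, different middle row
  c2 <- stub_encoder("diagnosed hereditary HD confirmed genetic")
  i1 <- which(a$tokens$text == "HD"); i2 <- which(c2$tokens$text == "HD")
  expect_equal(a$layers[[1]][i1, ], c2$layers[[1]][i2, ])
  expect_false(isTRUE(all.equal(a$layers[[2]][i1, ], c2$layers[[2]][i2, ])))
  # top layer is a rotation of the middle layer: norms preserved, rows differ
  expect_equal(sqrt(sum(a$layers[[3]][i1, ]^2)),
               sqrt(sum(a$layers[[2]][i1, ]^2)), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(a$layers[[3]][i1, ], a$layers[[2]][i1, ])))

  empty <- stub_encoder("")
  expect_equal(nrow(empty$tokens), 0)
  expect_equal(nrow(empty$layers[[1]]), 0)
})

test_that("encode_links runs prepare-encode-align-pool per link in order", {
  expect_equal(nrow(encode_links(random_links(3, 1)[0, ], stub_encoder,
                                 encoding_strategy())), 0)

  doc <- "followup diagnosed hereditary HD confirmed today"
  link <- link_from_doc(doc, "HD", "C0020179", section = "HPI")
  two <- candidate_links(rbind(as.data.frame(link), as.data.frame(link)))
  V <- encode_links(two, stub_encoder, encoding_strategy())
  expect_equal(dim(V), c(2, 64))
  expect_identical(V[1, ], V[2, ])   # identical links -> identical vectors

  # hand-derived oracle for one link: pool H1 over the mention token
  prep <- prepare_encoder_input(two[1, ], encoding_strategy())
  enc <- stub_encoder(prep$text)
  tspan <- align_mention_to_tokens(prep$span, enc$tokens)
  expect_equal(V[1, ], pool_mention_vector(enc, tspan, encoding_strategy()))

  # masked vs non-masked representations differ when context and mention
  # identity carry different information
  Vm <- encode_links(two, stub_encoder,
                     encoding_strategy(mask_mention = TRUE))
  expect_false(isTRUE(all.equal(V[1, ], Vm[1, ])))

  # alignment round-trip: the aligned token range covers the mention text
  joined <- paste(enc$tokens$text[tspan[1]:tspan[2]], collapse = "")
  expect_true(grepl("HD", joined, fixed = TRUE))
})

test_that("changing the selected layer changes encoded vectors", {
  link <- link_from_doc("a b TARGET c d", "TARGET", "C1")
  v1 <- encode_links(link, stub_encoder, encoding_strategy(layer_index = 1L))
  v0 <- encode_links(link, stub_encoder, encoding_strategy(layer_index = 0L))
  expect_false(isTRUE(all.equal(v1[1, ], v0[1, ])))
})

test_that("inputs longer than a backend token limit are truncated around the mention", {
  limited <- function(text) stub_encoder(text)
  attr(limited, "max_tokens") <- 7L
  doc <- paste(c(letters[1:15], "TARGET", letters[16:26]), collapse = " ")
  link <- link_from_doc(doc, "TARGET", "C1", w = 12L)
  V <- encode_links(link, limited, encoding_strategy(include_section = FALSE))
  expect_equal(dim(V), c(1, 64))
  # the vector equals encoding of the 7-token window centred on the mention
  prep <- prepare_encoder_input(link[1, ],
                                encoding_strategy(include_section = FALSE))
  toks <- strsplit(prep$text, " ")[[1]]
  mid <- which(toks == "TARGET")
  short <- paste(toks[(mid - 3):(mid + 3)], collapse = " ")
  enc <- stub_encoder(short)
  tspan <- align_mention_to_tokens(
    c(regexpr("TARGET", short) - 1L, regexpr("TARGET", short) + 5L),
    enc$tokens)
  expect_equal(V[1, ], pool_mention_vector(enc, tspan, encoding_strategy()))
})
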