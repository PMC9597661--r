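test_that("vocabulary size contract holds on a tiny corpus", {
  tok <- train_unigram(c("CCO", "CCC"), 10, seed = 1)
  expect_s3_class(tok, "unigram_tokenizer")
  expect_identical(tok$vocab_size, 10L)
  expect_length(tok$vocab, 10L)
  expect_identical(tok$vocab[1:5], c("[PAD]", "[CLS]", "[SEP]", "[UNK]", "[MASK]"))
  # specials at reserved ids, never overlapping content
  expect_identical(unname(tok$specials), 0:4)
  expect_false(any(duplicated(tok$vocab)))
})

test_that("vocab_size below character coverage errors", {
  expect_error(train_unigram(c("CCO", "CCC"), 6, seed = 1), "coverage")
})

test_that("every training line is encodable with zero [UNK]", {
  corpus <- desk_corpus()$smiles[1:300]
  tok <- desk_tokenizer()
  for (s in corpus[seq(1, 300, by = 7)]) {
    ids <- encode(tok, s)$ids
    expect_false(any(ids == 3L), info = s)
  }
})

test_that("encode/decode round-trips and wraps in [CLS]/[SEP]", {
  tok <- desk_tokenizer()
  for (s in desk_corpus()$smiles[c(1, 17, 33, 250, 999)]) {
    seq <- encode(tok, s)
    expect_identical(seq$ids[1], 1L)
    expect_identical(seq$ids[length(seq$ids)], 2L)
    expect_identical(decode(tok, seq), s)
  }
  # empty string
  e <- encode(tok, "")
  expect_identical(e$ids, c(1L, 2L))
  expect_identical(decode(tok, e), "")
})

test_that("token offsets tile the source string exactly", {
  tok <- desk_tokenizer()
  for (s in desk_corpus()$smiles[c(3, 44, 120)]) {
    seq <- encode(tok, s)
    n_tok <- length(seq$ids)
    offs <- seq$offsets[2:(n_tok - 1L), , drop = FALSE]  # content rows
    expect_identical(offs[1, 1], 0L)
    expect_identical(offs[nrow(offs), 2], nchar(s))
    if (nrow(offs) > 1) {
      expect_identical(offs[-1, 1], offs[-nrow(offs), 2])  # no gaps/overlap
    }
    # surfaces match their spans
    for (i in seq_len(nrow(offs))) {
      expect_identical(substr(s, offs[i, 1] + 1L, offs[i, 2]),
                       seq$tokens[i + 1L])
    }
  }
})

test_that("sequence length is bounded by 514 tokens", {
  tok <- desk_tokenizer()
  set.seed(8)
  long <- paste(sample(tok$char_set, 2000, replace = TRUE), collapse = "")
  seq <- encode(tok, long)
  expect_identical(length(seq$ids), 514L)
  expect_true(seq$truncated)
  # and always >= 2
  expect_gte(length(encode(tok, "C")$ids), 2L)
})

test_that("Viterbi segmentation equals exhaustive ML segmentation (<= 8 chars)", {
  tok <- train_unigram(desk_corpus()$smiles[1:200], 80, seed = 5)
  lp <- structure(tok$logprob, names = tok$vocab)
  seg_score <- function(pieces) {
    v <- lp[pieces]
    if (any(is.na(v))) -Inf else sum(v)
  }
  best_exhaustive <- function(s) {
    n <- nchar(s)
    best <- -Inf
    # enumerate all 2^(n-1) segmentations via cut masks
    for (mask in 0:(2^(n - 1) - 1)) {
      cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
      starts <- c(1L, cuts + 1L); ends <- c(cuts, n)
      sc <- seg_score(substring(s, starts, ends))
      if (sc > best) best <- sc
    }
    best
  }
  set.seed(42)
  cases <- c("CCO", "c1ccccc1", "CC(=O)O", "CCCCCCCC",
             substr(desk_corpus()$smiles[5], 1, 8),
             substr(desk_corpus()$smiles[71], 1, 7))
  for (s in cases) {
    seq <- encode(tok, s)
    got <- sum(lp[seq$tokens[2:(length(seq$ids) - 1L)]])
    expect_equal(got, best_exhaustive(s), tolerance = 1e-10, info = s)
  }
})

test_that("decode handles specials, single tokens, and bad ids", {
  tok <- desk_tokenizer()
  expect_identical(decode(tok, c(1L, 2L, 0L, 4L)), "")
  content_id <- 5L
  expect_identical(decode(tok, content_id), tok$vocab[content_id + 1L])
  set.seed(1)
  ids <- sample(5:(tok$vocab_size - 1L), 6)
  expect_identical(decode(tok, ids), paste(tok$vocab[ids + 1L], collapse = ""))
  expect_error(decode(tok, 99999L), "unknown")
})

test_that("regex tokenization follows the atom-level pattern", {
  expect_identical(regex_tokenize("CCO"), c("C", "C", "O"))
  expect_identical(regex_tokenize("C(=O)O"), c("C", "(", "=", "O", ")", "O"))
  expect_identical(regex_tokenize("[nH]1cccc1")[1], "[nH]")
  expect_identical(regex_tokenize("CCl"), c("C", "Cl"))
  expect_identical(regex_tokenize("CBr"), c("C", "Br"))
  # tiling guarantee: concatenation equals input on corpus strings
  for (s in desk_corpus()$smiles[1:20]) {
    expect_identical(paste(regex_tokenize(s), collapse = ""), s)
  }
  expect_error(regex_tokenize("C^C"), "unmatched span")
})

test_that("token-count comparison matches brute-force per-line sums", {
  tok <- desk_tokenizer()
  corpus <- desk_corpus()$smiles[1:100]
  res <- compare_token_counts(corpus, tok)
  want_uni <- sum(vapply(corpus, function(s) length(encode(tok, s)$ids) - 2L,
                         integer(1)))
  want_re <- sum(vapply(corpus, function(s) length(regex_tokenize(s)),
                        integer(1)))
  expect_identical(res$total_unigram, want_uni)
  expect_identical(res$total_regex, want_re)
  expect_equal(res$mean_diff_per_smiles, (want_re - want_uni) / 100)
  # subword merging means fewer unigram tokens than atom-level tokens
  expect_lt(res$total_unigram, res$total_regex)
})

test_that("a hand-built model segments by unigram likelihood", {
  # vocab where "CC"+"O" beats "C"+"C"+"O": total_unigram 2 vs regex 3
  tok <- structure(list(
    vocab = c("[PAD]", "[CLS]", "[SEP]", "[UNK]", "[MASK]", "C", "CC", "O"),
    logprob = c(NA, NA, NA, NA, NA, -2, -1, -1),
    specials = structure(0:4, names = c("[PAD]", "[CLS]", "[SEP]", "[UNK]", "[MASK]")),
    max_content_length = 512L, max_piece_len = 2L,
    char_set = c("C", "O"), vocab_size = 8L
  ), class = "unigram_tokenizer")
  res <- compare_token_counts("CCO", tok)
  expect_identical(res$total_unigram, 2L)
  expect_identical(res$total_regex, 3L)
  expect_equal(res$mean_diff_per_smiles, 1)
})

test_that("tokenizer serialization round-trips", {
  tok <- desk_tokenizer()
  path <- tempfile(fileext = ".json")
  save_tokenizer(tok, path)
  tok2 <- load_tokenizer(path)
  expect_identical(tok2$vocab, tok$vocab)
  expect_equal(tok2$logprob, tok$logprob)
  s <- desk_corpus()$smiles[10]
  expect_identical(encode(tok2, s)$ids, encode(tok, s)$ids)
})

test_that("full-scale vocabulary preset is attainable", {
  tok <- train_unigram(desk_corpus()$smiles[1:800], 2417, seed = 1,
                       em_iters = 1L)
  expect_identical(tok$vocab_size, 2417L)
})
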