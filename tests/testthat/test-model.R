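desk_cfg <- function() encoder_config(n_layers = 2L, n_heads = 2L,
                                      hidden = 64L, intermediate = 128L,
                                      max_positions = 64L, vocab_size = 100L,
                                      dropout = 0)

test_that("forward pass satisfies the shape contract", {
  set.seed(1)
  enc <- build_encoder(desk_cfg())
  ids <- list(c(1L, 10L, 20L, 30L, 2L))
  fwd <- encoder_forward(enc, ids, need_layers = TRUE, need_attention = TRUE)
  expect_identical(dim(fwd$hidden), c(5L, 64L))
  expect_length(fwd$layer_hidden, 2L)
  expect_identical(dim(fwd$layer_hidden[[1]]), c(5L, 64L))
  # per-layer, per-head L x L attention with rows summing to 1
  for (l in 1:2) for (h in 1:2) {
    A <- fwd$attention[[l]][[1]][[h]]
    expect_identical(dim(A), c(5L, 5L))
    expect_true(all(abs(rowSums(A) - 1) < 1e-5))
  }
  # eval-mode determinism
  fwd2 <- encoder_forward(enc, ids)
  expect_identical(fwd$hidden, fwd2$hidden)
  # length guard
  expect_error(encoder_forward(enc, list(rep(1L, 100))), "max_positions")
})

test_that("parameter count matches the closed form and marginal costs", {
  cfg <- desk_cfg()
  set.seed(1)
  enc <- build_encoder(cfg)
  expect_identical(count_parameters(enc), count_parameters(cfg))
  # vocab + 1 adds one tied embedding row plus one head bias entry
  cfg2 <- desk_cfg(); cfg2$vocab_size <- 101L
  expect_identical(count_parameters(cfg2) - count_parameters(cfg),
                   cfg$hidden + 1)
  # zero-layer degenerate config: embeddings + head only, by hand
  cfg0 <- encoder_config(n_layers = 0L, n_heads = 1L, hidden = 8L,
                         intermediate = 16L, max_positions = 10L,
                         vocab_size = 20L, dropout = 0)
  hand <- (20 * 8 + 10 * 8 + 2 * 8) +            # embeddings + LN
    (8 * 8 + 8 + 2 * 8 + 20)                     # MLM head, tied decoder
  expect_identical(count_parameters(cfg0), hand)
  expect_identical(count_parameters(build_encoder(cfg0)), hand)
})

test_that("full-scale preset lands at about 88 million parameters", {
  n <- count_parameters(base_preset())
  expect_equal(n / 1e6, 88, tolerance = 2 / 88)
})

test_that("masking respects specials and the corruption split", {
  tok_ids <- list(c(1L, rep(10L, 50), 2L), c(1L, rep(11L, 30), 2L))
  # mask_prob 0: nothing changes, no labels
  m0 <- mask_tokens(tok_ids, mlm_config(mask_prob = 0, seed = 1), 100L)
  expect_identical(m0$corrupted, tok_ids)
  expect_true(all(unlist(m0$labels) == -1L))
  # mask_prob 1 with pure-mask split: every content token becomes [MASK]
  m1 <- mask_tokens(tok_ids, mlm_config(1, c(1, 0, 0), seed = 1), 100L)
  for (i in 1:2) {
    ids <- m1$corrupted[[i]]
    expect_identical(ids[1], 1L)
    expect_identical(ids[length(ids)], 2L)
    expect_true(all(ids[2:(length(ids) - 1L)] == 4L))
    expect_true(all(m1$labels[[i]][2:(length(ids) - 1L)] ==
                      tok_ids[[i]][2:(length(ids) - 1L)]))
  }
  # empirical corruption fraction ~ 0.15 on ~100k content tokens
  big <- replicate(1000, c(1L, sample(5:99, 100, replace = TRUE), 2L),
                   simplify = FALSE)
  mb <- mask_tokens(big, mlm_config(0.15, seed = 99), 100L)
  frac <- mean(unlist(mb$labels) >= 0L) * 102 / 100  # specials never labeled
  expect_equal(frac, 0.15, tolerance = 0.005 / 0.15)
  # specials never corrupted
  expect_true(all(vapply(mb$corrupted, function(x) {
    x[1] == 1L && x[length(x)] == 2L
  }, logical(1))))
})

test_that("MLM loss matches closed forms and direct arithmetic", {
  V <- 7L
  expect_equal(as.numeric(mlm_loss(matrix(0, 1, V), 3L)), log(V))
  sharp <- matrix(-100, 1, V); sharp[1, 4] <- 100
  expect_lt(as.numeric(mlm_loss(sharp, 3L)), 1e-10)
  # random 3-position case against brute-force softmax arithmetic
  set.seed(2)
  lg <- matrix(rnorm(3 * V), 3, V)
  lab <- c(0L, 6L, 2L)
  want <- mean(vapply(1:3, function(i) {
    p <- exp(lg[i, ]) / sum(exp(lg[i, ]))
    -log(p[lab[i] + 1L])
  }, numeric(1)))
  expect_equal(as.numeric(mlm_loss(lg, lab)), want, tolerance = 1e-12)
  # no corrupted positions: defined 0 with a flag
  expect_warning(l0 <- mlm_loss(lg, c(-1L, -1L, -1L)), "no corrupted")
  expect_identical(as.numeric(l0), 0)
  expect_true(attr(l0, "no_positions"))
})

test_that("learning-rate schedule ramps, peaks at 6e-4 and decays", {
  s <- lr_schedule(peak_lr = 6e-4, warmup_steps = 100, total_steps = 1000,
                   power = 1, end_lr = 0)
  expect_identical(lr_at_step(s, 0), 0)
  expect_identical(lr_at_step(s, 100), 6e-4)
  expect_identical(lr_at_step(s, 1000), 0)
  expect_error(lr_at_step(s, 1001), "out of range")
  expect_error(lr_at_step(s, -1), "out of range")
  # continuity and piecewise monotonicity on a fine grid
  grid <- lr_at_step(s, 0:1000)
  expect_true(all(diff(grid[1:101]) >= 0))
  expect_true(all(diff(grid[101:1001]) <= 0))
  expect_lt(max(abs(diff(grid))), 6e-4 / 50)  # no jumps
  # polynomial power and end_lr respected
  s2 <- lr_schedule(6e-4, 0, 100, power = 2, end_lr = 1e-5)
  expect_equal(lr_at_step(s2, 100), 1e-5)
  expect_equal(lr_at_step(s2, 50), 1e-5 + (6e-4 - 1e-5) * 0.25)
})

test_that("effective batch size is the plan product", {
  expect_identical(effective_batch_size(batch_plan(8, 32, 16)), 4096L)
  expect_identical(effective_batch_size(batch_plan(1, 1, 1)), 1L)
  expect_identical(effective_batch_size(batch_plan(8, 32, 1)), 256L)
})

test_that("accumulated micro-batch gradients equal the large-batch gradient", {
  tok <- desk_tokenizer()
  set.seed(10)
  enc <- build_encoder(desk_preset(tok$vocab_size))
  ids <- lapply(desk_corpus()$smiles[1:32], function(s) encode(tok, s)$ids)
  mk <- mask_tokens(ids, mlm_config(seed = 5), tok$vocab_size)
  big <- mlm_grad(enc, mk$corrupted, mk$labels)
  acc <- NULL; n <- 0L
  for (b in split(1:32, rep(1:4, each = 8))) {
    r <- mlm_grad(enc, mk$corrupted[b], mk$labels[b])
    acc <- if (is.null(acc)) r$grads else smilesbert:::param_add(acc, r$grads)
    n <- n + r$n
  }
  v_big <- smilesbert:::param_flatten(smilesbert:::param_scale(big$grads, 1 / big$n))
  v_acc <- smilesbert:::param_flatten(smilesbert:::param_scale(acc, 1 / n))
  expect_lt(max(abs(v_big - v_acc)) / max(abs(v_big)), 1e-5)
})

test_that("pre-training is seeded-deterministic and learns on a tiny corpus", {
  corpus <- desk_corpus()$smiles[1:160]
  tok <- train_unigram(corpus, 60, seed = 2)
  cfg <- encoder_config(2L, 2L, 32L, 64L, 514L, tok$vocab_size, dropout = 0)
  m1 <- pretrain(corpus, tok, cfg, plan = batch_plan(8, 2), epochs = 3,
                 seed = 11)
  m2 <- pretrain(corpus, tok, cfg, plan = batch_plan(8, 2), epochs = 3,
                 seed = 11)
  expect_identical(m1$trace, m2$trace)
  k <- nrow(m1$trace)
  expect_lt(mean(m1$trace$loss[(k - 4):k]), mean(m1$trace$loss[1:5]))
})

test_that("checkpoint save/load round-trips the model", {
  m <- tiny_bundle()
  dir <- tempfile()
  m$trace <- data.frame(step = 1L, lr = 1e-4, loss = 2.5)
  save_model(m, dir)
  m2 <- load_model(dir)
  s <- desk_corpus()$smiles[2]
  expect_equal(fingerprint_batch(m2, s), fingerprint_batch(m, s))
  expect_equal(m2$trace$loss, 2.5)
})
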