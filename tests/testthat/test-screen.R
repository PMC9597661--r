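test_that("ranking puts a duplicated query first and fuses correctly", {
  set.seed(1)
  q <- matrix(rnorm(8), 1, 8)
  lib <- rbind(q, matrix(rnorm(8 * 5), 5, 8))
  r <- rank_library(q, lib)
  expect_identical(r$index[1], 1L)
  expect_equal(r$score[1], 1)
  # single query: max fusion equals mean fusion
  expect_equal(rank_library(q, lib, "max"), rank_library(q, lib, "mean"))
  expect_error(rank_library(q, matrix(numeric(0), 0, 8)), "empty library")
})

test_that("multi-query ranking matches brute-force enumeration", {
  set.seed(7)
  q <- matrix(rnorm(24), 3, 8)
  lib <- matrix(rnorm(80), 10, 8)
  for (fusion in c("max", "mean")) {
    got <- rank_library(q, lib, fusion)
    want_scores <- vapply(1:10, function(i) {
      sims <- vapply(1:3, function(j) cosine_similarity(lib[i, ], q[j, ]),
                     numeric(1))
      if (fusion == "max") max(sims) else mean(sims)
    }, numeric(1))
    expect_equal(got$score, sort(want_scores, decreasing = TRUE),
                 tolerance = 1e-12)
    expect_identical(got$index, order(-want_scores))
  }
})

test_that("AUCROC matches closed cases and exhaustive pair counting", {
  expect_equal(auc_roc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_roc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  expect_equal(auc_roc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_error(auc_roc(1:3, c(1, 1, 1)), "both classes")
  # exhaustive oracle on all random inputs of length <= 12, with ties
  pair_count_auc <- function(s, l) {
    a <- s[l == 1]; d <- s[l == 0]
    tot <- 0
    for (x in a) for (y in d) tot <- tot + (x > y) + 0.5 * (x == y)
    tot / (length(a) * length(d))
  }
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # forces ties
    l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auc_roc(s, l), pair_count_auc(s, l), tolerance = 1e-12)
  }
})

test_that("BEDROC hits its bounds and the hand-computed case", {
  expect_equal(bedroc(c(9, 8, 7, 3, 2, 1), c(1, 1, 1, 0, 0, 0)), 1)
  expect_lt(bedroc(c(9, 8, 7, 3, 2, 1), c(0, 0, 0, 1, 1, 1)), 0.01)
  # 2 actives among 10 at ranks 1 and 6, alpha = 20: independent arithmetic
  # of the exponential-sum definition
  scores <- 10:1
  labels <- c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0)
  S <- exp(-20 * 1 / 10) + exp(-20 * 6 / 10)
  Smax <- exp(-20 * 1 / 10) + exp(-20 * 2 / 10)
  Smin <- exp(-20 * 9 / 10) + exp(-20 * 10 / 10)
  expect_equal(bedroc(scores, labels, 20), (S - Smin) / (Smax - Smin),
               tolerance = 1e-12)
  expect_error(bedroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("BEDROC agrees with the reference cheminformatics implementation", {
  # independent oracle: rdkit.ML.Scoring.CalcBEDROC on the same ranking
  set.seed(21)
  n <- 40
  scores <- rnorm(n)
  labels <- as.integer(rank(-scores) <= 25) * 0L
  labels[sample(n, 8)] <- 1L
  ord <- order(-scores)
  rows <- paste(sprintf("[0,%d]", labels[ord]), collapse = ",")
  code <- sprintf(
    "from rdkit.ML.Scoring.Scoring import CalcBEDROC; print(CalcBEDROC([%s], 1, 20.0))",
    rows)
  out <- system2("python", c("-c", shQuote(code)), stdout = TRUE)
  expect_equal(bedroc(scores, labels, 20), as.numeric(out), tolerance = 1e-6)
})

test_that("BEDROC is monotone under promoting an active", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(8:20, 1)
    labels <- sample(c(1, 1, rep(0, n - 2)))
    scores <- seq(n, 1)  # rank = position
    b0 <- bedroc(scores, labels, 20)
    # promote one active by one rank position (swap with the decoy above)
    pos <- which(labels == 1)
    pos <- pos[pos > 1 & labels[pmax(pos - 1, 1)] == 0]
    if (!length(pos)) next
    i <- pos[1]
    l2 <- labels; l2[c(i - 1, i)] <- l2[c(i, i - 1)]
    expect_gte(bedroc(scores, l2, 20), b0)
  }
})

test_that("BEDROC flattens toward AUC as alpha approaches zero", {
  set.seed(6)
  scores <- rnorm(30)
  labels <- sample(c(rep(1, 6), rep(0, 24)))
  expect_equal(bedroc(scores, labels, 1e-3), auc_roc(scores, labels),
               tolerance = 1e-3)
})

test_that("benchmark metrics are seeded, decoy-order invariant, and null at 0.5", {
  tg <- desk_target()
  m <- tiny_bundle()
  b1 <- run_benchmark(m, tg, repetitions = 5, seed = 3)
  b2 <- run_benchmark(m, tg, repetitions = 5, seed = 3)
  expect_equal(b1$aggregate, b2$aggregate)
  # reordering the decoy list leaves the metrics unchanged
  tg2 <- tg; tg2$decoys <- rev(tg$decoys)
  b3 <- run_benchmark(m, tg2, repetitions = 5, seed = 3)
  expect_equal(b1$aggregate, b3$aggregate, tolerance = 1e-10)
  # random-vector fingerprints give chance-level AUCROC
  rand_fp <- function(model, smiles, pooling = "mean", ...) {
    t(vapply(smiles, function(s) {
      # per-string polynomial hash so distinct molecules decorrelate
      u <- utf8ToInt(s)
      set.seed(sum(u * (31^(seq_along(u) %% 5))) %% 100000L)
      rnorm(16)
    }, numeric(16)))
  }
  b_null <- run_benchmark(m, tg, repetitions = 30, seed = 9, fp_fun = rand_fp)
  expect_lt(abs(b_null$aggregate[["aucroc_mean"]] - 0.5), 0.1)
})

test_that("a target with too few actives is skipped with a warning", {
  tg <- desk_target()
  # built directly: the constructor itself refuses n_queries >= n_actives
  small <- structure(list(name = "tiny", actives = tg$actives[1:4],
                          decoys = tg$decoys[1:10], n_queries = 5L),
                     class = "screening_target")
  m <- tiny_bundle()
  expect_warning(expect_error(
    run_benchmark(m, list(small), repetitions = 2, seed = 1),
    "no usable targets"), "skipped")
})

test_that("cluster evaluation separates blobs and is permutation-null at 0.5", {
  set.seed(12)
  blob1 <- matrix(rnorm(40 * 5, mean = 0), 40, 5)
  blob2 <- matrix(rnorm(40 * 5, mean = 6), 40, 5)
  fp <- rbind(blob1, blob2)
  labels <- rep(c(0, 1), each = 40)
  ce <- cluster_eval(fp, labels, seed = 1)
  expect_equal(ce$aucroc, 1)
  expect_gt(ce$silhouette, 0.5)
  # shuffled labels: chance level (averaged over shuffles)
  aucs <- vapply(1:10, function(i) {
    set.seed(100 + i)
    cluster_eval(fp, sample(labels), seed = 1)$aucroc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
  # relabeling the classes does not change the scores
  ce_flip <- cluster_eval(fp, 1 - labels, seed = 1)
  expect_equal(ce_flip$aucroc, ce$aucroc)
  expect_equal(ce_flip$silhouette, ce$silhouette)
  expect_error(cluster_eval(matrix(1, 10, 4), rep(c(0, 1), 5)), "degenerate")
})
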