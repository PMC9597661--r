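test_that("canonicalization is idempotent and rejects invalid chemistry", {
  res <- sanitize_and_canonicalize(c("c1ccccc1", "C1CC", "CCO"))
  expect_true(res$ok[1])
  expect_identical(res$canonical[1], "c1ccccc1")
  expect_false(res$ok[2])
  expect_match(res$reason[2], "error")
  # idempotence: re-canonicalizing canonical output is a no-op
  again <- sanitize_and_canonicalize(res$canonical[res$ok])
  expect_identical(again$canonical, res$canonical[res$ok])
})

test_that("equivalent SMILES of one molecule share a canonical form", {
  # two aspirin writings; equality checked through the canonicalization
  # oracle itself, not a hard-coded string
  res <- sanitize_and_canonicalize(c("OC(=O)c1ccccc1OC(C)=O",
                                     "CC(=O)Oc1ccccc1C(=O)O"))
  expect_true(all(res$ok))
  expect_identical(res$canonical[1], res$canonical[2])
})

test_that("sanitization keeps the largest organic fragment", {
  res <- sanitize_and_canonicalize("[Na+].CC(=O)[O-]")
  expect_true(res$ok)
  expect_false(grepl("Na", res$canonical))
  expect_true(grepl("C", res$canonical))
})

test_that("reaction strings split into ordered dot-separated molecules", {
  expect_identical(extract_molecules_from_reaction("CCO.CC(=O)O>>CC(=O)OCC"),
                   c("CCO", "CC(=O)O", "CC(=O)OCC"))
  # duplicates preserved for frequency analysis
  expect_identical(extract_molecules_from_reaction("CCO>O>CCO"),
                   c("CCO", "O", "CCO"))
  expect_identical(extract_molecules_from_reaction(">>"), character(0))
  expect_error(extract_molecules_from_reaction("CCO>CCO"), "two '>'")
  expect_error(extract_molecules_from_reaction("a>b>c>d"), "two '>'")
})

test_that("frequency analysis counts duplicates and conserves totals", {
  expect_identical(frequency_analysis(c("A", "A", "B")),
                   structure(c(2L, 1L), names = c("A", "B")))
  expect_identical(frequency_analysis(character(0)),
                   structure(integer(0), names = character(0)))
  # planted Zipf fixture: counts recover the generator's multiplicities
  co <- gen_corpus(fixture_spec(n_molecules = 1000, seed = 33))
  canon <- sanitize_and_canonicalize(co$smiles)$canonical
  freq <- frequency_analysis(canon)
  expect_identical(sum(freq), length(co$smiles))
  planted <- tapply(co$manifest$count, co$manifest$canonical, unique)
  expect_identical(freq[names(planted)],
                   structure(as.integer(planted), names = names(planted)))
})

test_that("top-fraction selection takes the most frequent duplicates", {
  freq <- c(A = 5L, B = 3L, C = 1L, D = 1L)
  expect_identical(select_top_fraction(freq, 0.5), "A")
  expect_setequal(select_top_fraction(freq, 1.0), c("A", "B"))
  expect_identical(select_top_fraction(structure(integer(0), names = character(0)), 0.5),
                   character(0))
})

test_that("top-fraction tie-break is deterministic and matches brute force", {
  set.seed(9)
  keys <- sprintf("M%03d", 1:100)
  freq <- structure(sample(1:6, 100, replace = TRUE), names = keys)
  for (frac in c(0.2, 0.5, 0.77)) {
    got <- select_top_fraction(freq, frac)
    # independent brute-force: documented sort (count desc, name asc)
    dup <- freq[freq > 1L]
    df <- data.frame(k = names(dup), n = as.integer(dup))
    df <- df[order(-df$n, df$k), ]
    want <- df$k[seq_len(ceiling(frac * nrow(df)))]
    expect_identical(got, want)
    expect_identical(got, select_top_fraction(freq, frac))  # stable re-run
  }
})

test_that("augmentation round-trips through canonicalization", {
  canon <- sanitize_and_canonicalize("CCO")$canonical
  aug <- augment_smiles(canon, 3, seed = 7)
  expect_length(aug, 3)
  expect_true(all(sanitize_and_canonicalize(aug)$canonical == canon))
  # reproducibility under seed
  expect_identical(aug, augment_smiles(canon, 3, seed = 7))
  # single atom: repeats, never failure
  expect_identical(augment_smiles("C", 2, seed = 0), c("C", "C"))
  # a ring system admits several distinct traversals
  asp <- "CC(=O)Oc1ccccc1C(=O)O"
  aug10 <- augment_smiles(asp, 10, seed = 1)
  expect_gte(length(unique(aug10)), 2)
  expect_true(all(sanitize_and_canonicalize(aug10)$canonical ==
                    sanitize_and_canonicalize(asp)$canonical))
})

test_that("corpus building matches a brute-force application of the rules", {
  set.seed(5)
  uniq <- replicate(40, smilesbert:::gen_molecule())
  canon <- sanitize_and_canonicalize(uniq)$canonical
  uniq <- uniq[!duplicated(canon) & !is.na(canon)]
  canon <- unique(canon[!is.na(canon)])
  dup_idx <- seq_len(10)
  stream <- c(canon, rep(canon[dup_idx], times = rep(3L, 10)))
  cfg <- curation_config(top_fraction = 0.2, shuffle_seed = 42)
  out_file <- tempfile(fileext = ".smi")
  man <- build_pretraining_corpus(list(main = stream), cfg, out_file)

  lines <- readLines(out_file)
  got_freq <- frequency_analysis(sanitize_and_canonicalize(lines)$canonical)

  # brute force: each unique canonical once, except ceiling(0.2 * 10) top
  # duplicates which appear count-proportionally (rate 1 => count times)
  freq_in <- frequency_analysis(stream)
  top <- select_top_fraction(freq_in, 0.2)
  want_n <- length(canon) - length(top) + sum(freq_in[top])
  expect_identical(length(lines), want_n)
  for (k in top) expect_identical(got_freq[[k]], freq_in[[k]])
  for (k in setdiff(canon, top)) expect_identical(got_freq[[k]], 1L)
  # conservation: retained counts in the manifest cover all inputs
  expect_identical(man$sources$main$retained + man$sources$main$rejected_invalid,
                   length(stream))
  # determinism: same inputs, config and seed => byte-identical output
  out2 <- tempfile(fileext = ".smi")
  build_pretraining_corpus(list(main = stream), cfg, out2)
  expect_identical(readLines(out2), lines)
})

test_that("single-molecule source yields one output line", {
  out_file <- tempfile(fileext = ".smi")
  man <- build_pretraining_corpus(list(x = "CCO"), curation_config(), out_file)
  expect_identical(readLines(out_file), "CCO")
  expect_identical(man$output_lines, 1L)
})

test_that("over-length sequences are removed by the length filter", {
  long <- paste(rep("CC(O)", 300), collapse = "")  # >> 12 regex tokens
  out_file <- tempfile(fileext = ".smi")
  man <- build_pretraining_corpus(list(x = c("CCO", long)),
                                  curation_config(max_token_length = 12),
                                  out_file)
  expect_identical(man$removed_too_long, 1L)
  expect_identical(readLines(out_file), "CCO")
})

test_that("functional-group profile counts planted groups exactly", {
  expect_identical(functional_group_profile("CCO",
                                            c(hydroxyl = "[OX2H]"))[["hydroxyl"]], 1L)
  expect_true(all(functional_group_profile("CCC") == 0L))
  # planted fixture: nitro counts recovered from the generator's truth
  ds <- gen_labeled_dataset(50, "nitro", noise_rate = 0, seed = 13)
  truth <- attr(ds, "manifest")$truth
  prof <- functional_group_profile(ds$smiles)
  expect_identical(prof[["nitro"]], as.integer(sum(truth)))
  # invalid SMILES are skipped with a warning, not passed through
  expect_warning(p2 <- functional_group_profile(c("CCO", "C1CC")),
                 "invalid")
  expect_identical(attr(p2, "n_invalid"), 1L)
})

test_that("chunked shuffle is a seeded permutation", {
  lines <- sprintf("m%04d", 1:500)
  s1 <- smilesbert:::chunked_shuffle(lines, seed = 3, chunk_size = 64)
  s2 <- smilesbert:::chunked_shuffle(lines, seed = 3, chunk_size = 64)
  s3 <- smilesbert:::chunked_shuffle(lines, seed = 4, chunk_size = 64)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_setequal(s1, lines)
})
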