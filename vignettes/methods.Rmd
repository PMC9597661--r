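---
title: "Transformer fingerprints from SMILES: models, choices, and what the desk-scale experiments show"
author: "smilesbert"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transformer fingerprints from SMILES}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A molecular fingerprint is a fixed-length numeric vector summarizing a
molecule, used for similarity search, virtual screening and as features for
property prediction. Classical fingerprints (circular/ECFP-style,
descriptor-based) extract pre-defined features; data-driven fingerprints
learn their features from large unlabeled corpora of SMILES strings.
`smilesbert` implements the full data-driven pipeline at a scale that runs
on one CPU: corpus curation, raw-stream subword tokenization,
masked-language-model (MLM) pre-training of a transformer encoder,
fingerprint inference by pooling token embeddings, fine-tuning (single-head
and Siamese), and quantitative evaluation (retrieval metrics, clustering
separation, attention attribution).

## The model

The encoder is a RoBERTa-style stack: learned token embeddings plus learned
absolute position embeddings (514 positions: 512 content tokens bounded by
`[CLS]` and `[SEP]`), then `n_layers` post-layer-norm transformer blocks of
multi-head self-attention and a GELU feed-forward sublayer, and an MLM head
(dense + GELU + layer norm) whose decoder matrix is tied to the input
embedding table. At the full-scale preset — 12 layers, 12 heads, hidden 768,
intermediate 3072, vocabulary 2417 — the instantiated encoder has
87,901,553 trainable scalars, i.e. ~88 M; the count is only consistent with
a *tied* decoder, which is why tying is the default and not an option.
(A token-type embedding, one row in the reference architecture, is omitted:
SMILES have no sentence pairs; this changes the count by well under 0.1%.)

Pre-training corrupts 15% of content tokens per batch (80% to `[MASK]`, 10%
to a random content token, 10% kept) and minimizes cross-entropy over the
corrupted positions only. The optimizer is decoupled-weight-decay Adam
(betas 0.9/0.98, eps 1e-6, decay 0.01 on weight matrices only) under a
schedule that ramps linearly from 0 to the peak learning rate 6e-4 and then
decays polynomially (power 1 by default) to 0. The warmup length has no canonical
value for this family; the default is 6% of total optimizer steps, a
standard choice, and it is exposed in `lr_schedule()`.

### Batch semantics

The full-scale preset's batch semantics correspond to 16-way data-parallel
training with per-device batch 8 and 32 gradient-accumulation steps
(effective batch 4096). This package reproduces those semantics
single-process: micro-batch gradients are
accumulated as unnormalized sums together with the pooled count of
corrupted positions, and the update divides by the pooled count. This makes
an accumulated step mathematically identical to one large-batch step (the
mean-loss convention), which the test suite verifies to ~1e-12 relative
error in double precision. `world_size` survives only as a factor in
`effective_batch_size()`.

## Tokenization

The tokenizer is a raw-stream unigram subword model in the SentencePiece
style, authored in R because no R package provides one:

1. **Seed vocabulary**: all substrings up to 8 characters, the most
   frequent ~3x target-size kept, plus every observed character
   (guaranteeing 100% coverage — no training line can produce `[UNK]`).
2. **EM**: expected piece counts are computed by forward–backward over each
   line's segmentation lattice; the M-step renormalizes log-probabilities.
3. **Pruning**: the lowest-expected-count multi-character pieces (the
   pieces whose removal costs the least corpus likelihood) are dropped ~25%
   at a time, with EM re-runs between rounds, until exactly
   `vocab_size - 5` content pieces remain. Single characters are never
   pruned.

Encoding is Viterbi over the same lattice, which is exactly the
maximum-likelihood segmentation; the tests verify this against brute-force
enumeration of all segmentations for short strings. Ties are broken toward
the longer piece, then the smaller id, making encoding deterministic.
Special ids are fixed: `[PAD]`=0, `[CLS]`=1, `[SEP]`=2, `[UNK]`=3,
`[MASK]`=4. The atom-level regex tokenizer (`regex_tokenize()`) implements
the standard SMILES pattern (bracket atoms, two-letter elements,
two-digit ring closures as single tokens) and serves as the comparison
baseline and as the bootstrap length filter before a tokenizer exists. No
single canonical SMILES regex exists, so the pattern is configurable and
only the comparison harness (`compare_token_counts()`) — not any specific
token-count total — is a tested quantity.

## Chemistry backend

Canonicalization, validity checking, randomized-traversal SMILES,
SMARTS substructure matching and Murcko scaffolds are delegated to RDKit
through a bundled Python helper called in batches over stdin/stdout, with
per-session memoisation. Sanitization keeps the largest organic fragment
(preferring carbon-containing fragments) and strips explicit hydrogens;
syntax and valence failures are rejected with reason codes. Randomized
SMILES are produced by renumbering atoms with a seeded permutation and
writing non-canonically — the same traversal-randomization primitive as the
reference toolkit's `doRandom`, but reproducible under a seed.

## Corpus curation

`build_pretraining_corpus()` canonicalizes and pools all sources, counts
duplicate canonical forms, and keeps each unique molecule once — except the
top fraction (default 20%) of *duplicated* molecules ranked by count, which
are emitted count-proportionally, half canonical and half randomized
traversals. Decisions this procedure leaves genuinely open, fixed here:

- **Tie-break** at the top-fraction boundary: count descending, then
  canonical string ascending — deterministic selection.
- **Proportionality constant**: a molecule with count `c` is emitted
  `ceiling(c * r)` times with `r = 1` by default (`augment_rate`).
- **Length filter**: "longer than 512 tokens" is measured with the trained
  unigram tokenizer when one is supplied, else with the atom-level regex —
  the bootstrap phase, before any tokenizer exists.
- **Shuffle**: a seeded chunked merge-shuffle (shuffle within chunks, drain
  chunks by size-proportional sampling) replaces the external-memory
  shuffler; linear time, bounded per-chunk working set, byte-identical
  under a fixed seed.
- A single uniform frequency-augmentation rule is applied to all sources.

## Fingerprints

A fingerprint is a pooled row of the final hidden states: `pool_mean()`
averages all token embeddings — including `[CLS]`/`[SEP]`, since the
description "mean of all token embeddings" does not exclude them; a
`content_only` flag provides the interior-only variant, and both are
tested — and `pool_cls()` returns the `[CLS]` row. Fingerprints are stored
unnormalized; `cosine_similarity()` normalizes internally. Retrieval ranks
a library by fused cosine similarity to the query set; the default fusion
is the maximum over queries (the multi-query convention of the reference
benchmarking platform), with mean fusion behind a flag.

## Evaluation metrics

- `auc_roc()` is the normalized Mann-Whitney statistic from midranks (ties
  count one half), verified against exhaustive pair counting.
- `bedroc()` implements the Boltzmann-enhanced discrimination of ROC as the
  explicit min–max normalization of the exponential rank sum
  `S = sum(exp(-alpha * r_i / N))`, with `S_max`/`S_min` the all-top /
  all-bottom placements. This is algebraically the (RIE-scaled) closed form
  of the defining publication; the tests cross-check against the reference
  cheminformatics implementation. Alpha defaults to 20.
- `run_benchmark()` resamples `n_queries = 5` actives per repetition
  (default 50 repetitions, enough for a stable mean ± sd) and reports both
  metrics per target and aggregated.
- `cluster_eval()` projects fingerprints to two principal components, runs
  K-means with k = number of classes, maps clusters to classes by the
  agreement-maximizing label permutation, and reports the AUCROC of the
  mapped hard assignments plus the silhouette coefficient. Turning hard
  cluster assignments into an AUCROC admits several conventions; the
  permutation-mapped one is what the package documents and tests. Silhouette is computed in the
  2-D PCA space by default (`silhouette_space = "full"` for the raw space).

## Fine-tuning

`finetune_single()` feeds the 20%-dropout-regularized mean embedding
through one linear layer (sigmoid + binary cross-entropy for
classification, identity + MSE for regression) and, by default, lets
gradients flow into the whole encoder; `freeze_encoder` trains the head
alone (the cheap option when compute matters). Splits are 80/10/10,
random or Murcko-scaffold grouped (greedy largest-first packing). The
fine-tuning learning rate is unstated originally; the default is a constant
1e-3 AdamW step at desk scale, config-exposed. Multi-label tasks use one
sigmoid per label with mean BCE.

The Siamese variants share one parameter set between branches (identity,
not copies — an update through either branch moves both):
`siamese_classify()` pairs each molecule with a seeded random traversal of
itself and classifies `[fp1, fp2, |fp2 - fp1|]`; both gradient paths are
supported, and encoder training is the default, matching the single-head
default.
`siamese_latent_train()` minimizes `(cos(fp1, fp2) - 1)^2`, pulling a
molecule's SMILES permutations together in cosine space, and reports the
held-out mean pair cosine before and after training.

## Attention attribution

`extract_attention()` returns the full (layer, head, from, to) attention
tensor with token offsets. `match_groups_to_tokens()` maps SMARTS matches
to tokens through the atom-order correspondence: the k-th atom-denoting
regex token of a SMILES string is the k-th atom of the parsed molecule, so
matched atom indices become character spans and then the set of tokenizer
tokens overlapping them. `attention_proportion()` reduces the share of
attention *received* by a token set (column mass / L), averaged over all
layers and heads by default; per-layer/per-head and emitted-attention
variants sit behind flags since no one reduction is canonical.
The rank test (`mann_whitney_u()`) enumerates the exact null for group
sizes up to 8 and otherwise uses the tie-corrected normal approximation;
the pairing unit of such a comparison is a genuine choice;
`attention_report()` compares per-group frequency against per-group mean
attention proportion across a molecule sample, which is the package's
documented convention.

## Synthetic data and what passing tests show

All tests run on generator output; no chemical database is downloaded.
`gen_corpus()` assembles molecules from a closed grammar — alkyl, benzene
and cyclohexane backbones decorated with 15 monovalent functional-group
fragments — so every string is valid by construction, and draws duplicate
multiplicities from a Zipf law (exponent 1.2), emitting repeats half in
randomized form: the statistical structure (duplicates in canonical and
non-canonical form with a skewed frequency profile) of the real
pre-training aggregate. `gen_labeled_dataset()` plants a structural rule
(nitro-group presence, or heavy-atom count for regression) with optional
label noise, recording ground truth in a manifest.

`gen_screening_target()` plants a benzamide scaffold in diverse contexts
(decorated alkyl prefixes on the amide nitrogen, varied ring substituents)
and generates *fragment-matched* decoys: amide and phenyl fragments from
the same prefix grammar, never composed into the scaffold. This follows the
property-matched-decoy convention of real screening benchmarks and is what
makes the fixture informative — with naive decoys, raw token composition
separates actives from decoys and every representation saturates the
metrics, so the comparisons between pretrained/random and mean/[CLS]
fingerprints would measure nothing.

The desk-scale study conditions, fixed once: a 5,000-line corpus, a
200-token tokenizer, a 2-layer / 4-head / hidden-64 / intermediate-256
encoder (dropout 0) pre-trained 1 epoch at effective batch 32, a 500-sample
labeled fixture fine-tuned 10 epochs, a 25-active / 150-decoy target
evaluated over 20 query resamplings, and 500 molecules / 2 epochs for the
Siamese latent run. Under these conditions the suite reproduces the
qualitative findings: pre-training reduces MLM loss; pre-trained
mean-pooled fingerprints beat random initialization at retrieval
(BEDROC20 ~0.95 vs ~0.87 on the planted target); mean pooling beats
`[CLS]` pooling (~0.95 vs ~0.3); fine-tuning massively enhances cluster
separation (silhouette ~0.4 to ~1.0, cluster AUCROC ~0.7 to ~1.0); and
Siamese latent training raises the held-out canonical-vs-permuted cosine.

What passing these tests does *not* show: the grammar molecules are far
simpler than drug-like chemistry (no stereochemistry, no fused rings, no
charged species beyond nitro); the desk encoder is ~3 orders of magnitude
smaller than the full-scale preset; and absolute screening scores on real
ChEMBL-style targets or billion-molecule corpus statistics are out of reach
of a single-CPU run and are deliberately not claimed. The enumerated-database ablation is supported as
named presets only (`gdb13_subset_presets()`).

## Numerical choices and degenerate inputs

Double precision throughout; layer-norm epsilon 1e-5; exact GELU
(`x * pnorm(x)`); softmax with row-max subtraction. Molecules with a single
atom admit no distinct traversal — augmentation returns repeats. An
all-masked pooling request, a zero-norm cosine, a one-class metric input, a
single-class training split, and degenerate (zero-variance) fingerprints
all raise errors rather than returning silent values; a batch with no
corrupted positions contributes loss 0 with a flag. Non-finite training
loss aborts and restores the last good parameters.
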