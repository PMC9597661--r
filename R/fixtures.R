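# Seeded synthetic SMILES generation. Molecules are assembled from a closed
# grammar (alkyl/alicyclic/aromatic backbones plus monovalent functional-
# group decorations), so every emitted string is valid by construction and
# no chemical database is needed. Ground truth (duplicate counts, planted
# labels) is recorded in manifests so downstream directional tests can be
# verified against the generator, not against the model under test.

fg_fragments <- function() {
  c(hydroxyl = "O", amine = "N", methyl = "C", ethyl = "CC",
    chloro = "Cl", fluoro = "F", bromo = "Br",
    nitrile = "C#N", nitro = "[N+](=O)[O-]",
    carboxyl = "C(=O)O", amide = "C(=O)N", methoxy = "OC",
    vinyl = "C=C", thiol = "S", phenyl = "c2ccccc2")
}

# one random molecule from the grammar; uses the ambient RNG
gen_molecule <- function(decorations = names(fg_fragments()),
                         force_group = NULL) {
  frags <- fg_fragments()
  backbone <- sample(c("alkyl", "benzene", "cyclohexane"), 1L,
                     prob = c(0.5, 0.3, 0.2))
  pick <- function() unname(frags[sample(decorations, 1L)])
  if (backbone == "alkyl") {
    len <- sample(3:8, 1L)
    atoms <- rep("C", len)
    n_dec <- sample(0:2, 1L)
    pos <- if (n_dec > 0) sample(seq_len(len), n_dec) else integer(0)
    for (p in pos) atoms[p] <- paste0("C(", pick(), ")")
    if (!is.null(force_group)) {
      p <- sample(seq_len(len), 1L)
      atoms[p] <- paste0("C(", unname(frags[force_group]), ")")
    }
    paste(atoms, collapse = "")
  } else {
    a <- if (backbone == "benzene") "c" else "C"
    atoms <- rep(a, 4L)  # decorable ring positions 2..5
    n_dec <- sample(0:2, 1L)
    pos <- if (n_dec > 0) sample(1:4, n_dec) else integer(0)
    for (p in pos) atoms[p] <- paste0(a, "(", pick(), ")")
    if (!is.null(force_group)) {
      p <- sample(1:4, 1L)
      atoms[p] <- paste0(a, "(", unname(frags[force_group]), ")")
    }
    paste0(a, "1", paste(atoms, collapse = ""), a, "1")
  }
}

#' Fixture specification
#'
#' Parameters of the synthetic corpus generator.
#'
#' @param n_molecules Number of output lines.
#' @param zipf_exponent Skew of the duplicate-frequency distribution
#'   (duplicate multiplicities follow a Zipf law with this exponent).
#' @param scaffold SMILES of the substructure planted in screening actives.
#' @param label_rule `"nitro"` (classification: nitro group present) or
#'   `"heavy_atoms"` (regression: heavy-atom count).
#' @param noise_rate Label-flip probability (classification) or noise SD as
#'   a fraction of the target SD (regression), in `[0, 1)`.
#' @param seed Integer seed.
#' @export
fixture_spec <- function(n_molecules = 100L, zipf_exponent = 1.2,
                         scaffold = "NC(=O)c1ccccc1",
                         label_rule = c("nitro", "heavy_atoms"),
                         noise_rate = 0, seed = 1L) {
  label_rule <- match.arg(label_rule)
  stopifnot(n_molecules >= 1, zipf_exponent > 0, noise_rate >= 0,
            noise_rate < 1)
  structure(list(n_molecules = as.integer(n_molecules),
                 zipf_exponent = zipf_exponent, scaffold = scaffold,
                 label_rule = label_rule, noise_rate = noise_rate,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic SMILES corpus with planted duplicate frequencies
#'
#' Draws `n_molecules` lines from a pool of grammar-generated molecules
#' whose sampling probabilities follow a Zipf law, so the stream contains
#' duplicates with a skewed frequency distribution. Repeat occurrences are
#' emitted in randomized (non-canonical) form with probability one half.
#' The manifest records the generating canonical form and planted count of
#' every line.
#'
#' @param spec A [fixture_spec()].
#' @return List with `smiles` (the stream), `manifest` (data.frame
#'   `canonical`, `count` of planted multiplicities).
#' @export
gen_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_molecules
  pool_n <- max(2L, ceiling(n / 2))
  pool_raw <- character(0)
  canon_seen <- character(0)
  while (length(pool_raw) < pool_n) {
    cand <- replicate(pool_n, gen_molecule())
    cc <- chem_canonicalize(cand)
    keep <- cc$ok & !(cc$canonical %in% canon_seen) & !duplicated(cc$canonical)
    pool_raw <- c(pool_raw, cand[keep])
    canon_seen <- c(canon_seen, cc$canonical[keep])
  }
  pool_raw <- pool_raw[seq_len(pool_n)]
  canon <- canon_seen[seq_len(pool_n)]

  probs <- (1 / seq_len(pool_n)^spec$zipf_exponent)
  draws <- sample.int(pool_n, n, replace = TRUE, prob = probs / sum(probs))
  counts <- tabulate(draws, nbins = pool_n)

  lines <- character(0); which_mol <- integer(0)
  for (i in which(counts > 0L)) {
    k <- counts[i]
    forms <- rep(pool_raw[i], k)
    if (k > 1L) {
      rand_pick <- which(stats::runif(k - 1L) < 0.5) + 1L
      if (length(rand_pick)) {
        rand <- augment_smiles(canon[i], length(rand_pick),
                               seed = spec$seed + i)
        forms[rand_pick] <- rand
      }
    }
    lines <- c(lines, forms)
    which_mol <- c(which_mol, rep(i, k))
  }
  ord <- sample(length(lines))
  list(smiles = lines[ord],
       manifest = data.frame(canonical = canon[which_mol[ord]],
                             count = counts[which_mol[ord]],
                             stringsAsFactors = FALSE))
}
#' Generate a screening target with a planted scaffold
#'
#' Actives carry the scaffold embedded in varied contexts: a decorated
#' alkyl prefix on the amide nitrogen and a varied ring substituent, so the
#' active pool is structurally diverse rather than a family of
#' near-duplicates. Decoys are scaffold-free; by default they are
#' *fragment-matched* (the convention of property-matched decoy sets):
#' each decoy carries the scaffold's component fragments — an amide-like
#' group and a phenyl ring — assembled from the same prefix grammar but
#' never bonded into the planted scaffold, so separating actives from
#' decoys requires recognizing the composed substructure rather than raw
#' fragment content. `decoy_style = "random"` draws plain grammar
#' molecules instead. Both pools are deduplicated and verified: every
#' active contains the scaffold as a substructure, no decoy does, and the
#' pools are disjoint by canonical form.
#'
#' @param n_actives,n_decoys Pool sizes.
#' @param scaffold Scaffold SMILES (default benzamide). The varied-context
#'   active grammar is specific to the benzamide default; other scaffolds
#'   are decorated with a prefix only.
#' @param seed Integer seed.
#' @param n_queries Stored on the returned target (default 5).
#' @param decoy_style `"matched"` (default) or `"random"`.
#' @return A [screening_target()].
#' @export
gen_screening_target <- function(n_actives, n_decoys,
                                 scaffold = "NC(=O)c1ccccc1", seed = 1L,
                                 n_queries = 5L,
                                 decoy_style = c("matched", "random")) {
  decoy_style <- match.arg(decoy_style)
  set.seed(seed)
  pre_decs <- c("O", "N", "C", "Cl", "F", "OC", "C(C)")
  ring_subs <- c("", "C", "Cl", "F", "OC", "CC", "O")

  mk_prefix <- function() {
    len <- sample(1:5, 1L)
    atoms <- rep("C", len)
    nd <- sample(0:2, 1L)
    if (nd > 0) {
      for (p in sample(seq_len(len), min(nd, len))) {
        atoms[p] <- paste0("C(", sample(pre_decs, 1L), ")")
      }
    }
    paste(atoms, collapse = "")
  }
  benzamide_like <- identical(scaffold, "NC(=O)c1ccccc1")
  mk_active <- function() {
    if (benzamide_like) {
      sub <- sample(ring_subs, 1L)
      core <- if (nzchar(sub)) paste0("NC(=O)c1ccc(", sub, ")cc1") else scaffold
      paste0(mk_prefix(), core)
    } else {
      paste0(mk_prefix(), scaffold)
    }
  }
  # fragment-matched decoy: amide and phenyl present, scaffold absent
  mk_decoy <- function() {
    if (decoy_style == "random") return(gen_molecule())
    if (stats::runif(1) < 0.6) {
      mid <- paste(rep("C", sample(1:3, 1L)), collapse = "")
      paste0(mk_prefix(), "NC(=O)C", mid, "C(c1ccccc1)",
             sample(c("", "C", "CC"), 1L))
    } else {
      paste0(mk_prefix(), "C(N)C(=O)OC(c1ccccc1)")
    }
  }

  # batched generate-validate-filter loop
  gen_pool <- function(n, fn, avoid, want_scaffold) {
    out <- character(0); seen <- avoid
    rounds <- 0L
    while (length(out) < n && rounds < 60L) {
      rounds <- rounds + 1L
      cand <- unique(replicate(max(2L * (n - length(out)), 20L), fn()))
      cc <- chem_canonicalize(cand)
      keep <- cc$ok & !(cc$canonical %in% seen) & !duplicated(cc$canonical)
      cand <- cand[keep]
      if (!length(cand)) next
      has <- chem_has_substructure(cand, scaffold)
      cand <- cand[!is.na(has) & has == want_scaffold]
      canon <- chem_canonicalize(cand)$canonical
      out <- c(out, cand); seen <- c(seen, canon)
    }
    if (length(out) < n) {
      stop("could not generate ", n, " distinct molecules for scaffold ",
           scaffold, call. = FALSE)
    }
    list(smiles = out[seq_len(n)], canonical = seen)
  }

  act <- gen_pool(n_actives, mk_active, character(0), TRUE)
  dec <- gen_pool(n_decoys, mk_decoy, act$canonical, FALSE)
  screening_target(paste0("planted-", scaffold), act$smiles, dec$smiles,
                   n_queries = n_queries, check_disjoint = FALSE)
}

#' Generate a labeled dataset with a planted structural rule
#'
#' Classification (`label_rule = "nitro"`): roughly half the molecules are
#' forced to carry a nitro group; the label is the *measured* presence of
#' the group (SMARTS match, not the generator's intent) XOR a Bernoulli
#' noise flip. Regression (`"heavy_atoms"`): the label is the heavy-atom
#' count plus Gaussian noise with SD `noise_rate` times the target SD.
#'
#' @param n Number of molecules.
#' @param label_rule `"nitro"` or `"heavy_atoms"`.
#' @param noise_rate In `[0, 1)`.
#' @param seed Integer seed.
#' @return Data.frame `(smiles, label)`; attribute `manifest` holds the
#'   noiseless ground truth.
#' @export
gen_labeled_dataset <- function(n, label_rule = c("nitro", "heavy_atoms"),
                                noise_rate = 0, seed = 1L) {
  label_rule <- match.arg(label_rule)
  set.seed(seed)
  n_pos <- sum(stats::runif(n) < 0.5)
  gen_side <- function(k, positive) {
    out <- character(0); seen <- character(0); rounds <- 0L
    while (length(out) < k && rounds < 60L) {
      rounds <- rounds + 1L
      cand <- unique(replicate(max(2L * (k - length(out)), 20L), {
        # molecules not forced to carry the group must not contain it by chance
        if (positive) gen_molecule(force_group = "nitro")
        else gen_molecule(decorations = setdiff(names(fg_fragments()), "nitro"))
      }))
      cc <- chem_canonicalize(cand)
      keep <- cc$ok & !(cc$canonical %in% seen) & !duplicated(cc$canonical)
      out <- c(out, cand[keep]); seen <- c(seen, cc$canonical[keep])
    }
    if (length(out) < k) stop("could not generate ", k, " molecules", call. = FALSE)
    out[seq_len(k)]
  }
  smiles <- sample(c(gen_side(n_pos, TRUE), gen_side(n - n_pos, FALSE)))

  if (label_rule == "nitro") {
    truth <- as.integer(chem_has_substructure(smiles, "[N+](=O)[O-]",
                                              smarts = TRUE))
    flips <- stats::runif(n) < noise_rate
    label <- as.integer(xor(truth == 1L, flips))
  } else {
    truth <- vapply(smiles, function(s) nrow(atom_char_spans(s)), numeric(1))
    label <- truth + stats::rnorm(n, sd = noise_rate * stats::sd(truth))
  }
  out <- data.frame(smiles = smiles, label = label, stringsAsFactors = FALSE)
  attr(out, "manifest") <- data.frame(smiles = smiles, truth = truth,
                                      stringsAsFactors = FALSE)
  out
}
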