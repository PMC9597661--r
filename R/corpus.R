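# Corpus curation: canonicalization, frequency-driven augmentation, seeded
# shuffling of SMILES pre-training corpora.

#' Curation configuration
#'
#' Bundles the knobs of [build_pretraining_corpus()]: which share of the
#' duplicated molecules is kept for augmentation, the maximum tokenized
#' length, the augmentation multiplier, and the shuffle seed.
#'
#' @param top_fraction Fraction in (0, 1] of the *duplicated* canonical
#'   molecules (highest duplicate count first) retained for augmentation.
#'   Default 0.2, i.e. the top 20\% most frequent duplicates.
#' @param max_token_length Sequences longer than this many content tokens are
#'   dropped. Default 512.
#' @param augment_rate Multiplier `r`: a molecule with duplicate count `c` in
#'   the top set is emitted `ceiling(c * r)` times, split evenly between its
#'   canonical form and randomized traversals. Default 1 (count-proportional).
#' @param shuffle_seed Integer seed controlling the output shuffle and the
#'   randomized-SMILES draws.
#' @param chunk_size Chunk size of the external-memory style merge shuffle.
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(top_fraction = 0.2, max_token_length = 512L,
                            augment_rate = 1, shuffle_seed = 1L,
                            chunk_size = 10000L) {
  stopifnot(top_fraction > 0, top_fraction <= 1,
            max_token_length >= 3, augment_rate >= 0, chunk_size >= 1)
  structure(list(top_fraction = top_fraction,
                 max_token_length = as.integer(max_token_length),
                 augment_rate = augment_rate,
                 shuffle_seed = as.integer(shuffle_seed),
                 chunk_size = as.integer(chunk_size)),
            class = "curation_config")
}

#' Sanitize and canonicalize SMILES
#'
#' Validates each string with RDKit, keeps the largest organic fragment,
#' strips explicit hydrogens and returns the canonical form. Invalid
#' chemistry (syntax errors, valence violations) is rejected with a reason
#' code, never silently passed through. Canonicalization is idempotent:
#' canonical strings map to themselves.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A data.frame with columns `smiles`, `ok`, `canonical` (NA for
#'   rejected records) and `reason` (`"parse_error"` or `"sanitize_error"`,
#'   NA for accepted records).
#' @export
sanitize_and_canonicalize <- function(smiles) {
  stopifnot(is.character(smiles))
  chem_canonicalize(smiles)
}

#' Extract molecules from a reaction SMILES
#'
#' Splits a `reactants>agents>products` string into its dot-separated
#' molecule components, preserving order and duplicates (duplicates carry the
#' frequency signal used downstream).
#'
#' @param rxn A single reaction SMILES/SMARTS string with exactly two `>`
#'   separators.
#' @return Character vector of component SMILES (possibly empty).
#' @export
extract_molecules_from_reaction <- function(rxn) {
  stopifnot(is.character(rxn), length(rxn) == 1L)
  seps <- gregexpr(">", rxn, fixed = TRUE)[[1]]
  n_sep <- if (seps[1] == -1L) 0L else length(seps)
  if (n_sep != 2L) {
    stop("malformed reaction string: expected exactly two '>' separators, found ",
         n_sep, call. = FALSE)
  }
  fields <- c(substr(rxn, 1L, seps[1] - 1L),
              substr(rxn, seps[1] + 1L, seps[2] - 1L),
              substr(rxn, seps[2] + 1L, nchar(rxn)))
  out <- unlist(lapply(fields, function(f) strsplit(f, ".", fixed = TRUE)[[1]]))
  out[nzchar(out)]
}

#' Duplicate-frequency analysis
#'
#' Counts occurrences of each canonical SMILES in a stream of canonicalized
#' records. Counts sum to the number of input records.
#'
#' @param canonical Character vector of canonical SMILES.
#' @return Named integer vector, names are the unique canonical forms.
#' @export
frequency_analysis <- function(canonical) {
  stopifnot(is.character(canonical))
  if (length(canonical) == 0L) return(structure(integer(0), names = character(0)))
  tab <- table(canonical)
  structure(as.integer(tab), names = names(tab))
}

#' Select the top fraction of duplicated molecules
#'
#' Among molecules with duplicate count > 1, returns the
#' `ceiling(fraction * n_duplicated)` most frequent canonical forms. Ties at
#' the boundary are broken deterministically by (count descending, canonical
#' string ascending).
#'
#' @param freq Named integer vector from [frequency_analysis()].
#' @param fraction Fraction in (0, 1].
#' @return Character vector of selected canonical forms.
#' @export
select_top_fraction <- function(freq, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  dup <- freq[freq > 1L]
  if (length(dup) == 0L) return(character(0))
  ord <- order(-dup, names(dup), method = "radix")
  k <- ceiling(fraction * length(dup))
  names(dup)[ord][seq_len(k)]
}

#' Randomized SMILES augmentation
#'
#' Emits `n` alternative SMILES for a molecule by randomizing the atom
#' traversal order (RDKit atom renumbering followed by non-canonical
#' writing). Every returned string canonicalizes back to the input; results
#' are reproducible under `seed`. Molecules admitting no distinct traversal
#' (e.g. single atoms) yield repeats.
#'
#' @param canonical A valid canonical SMILES string.
#' @param n Number of strings to emit (>= 0).
#' @param seed Integer seed.
#' @return Character vector of length `n`.
#' @export
augment_smiles <- function(canonical, n, seed) {
  stopifnot(n >= 0)
  if (n == 0L) return(character(0))
  chem_random_smiles(canonical, as.integer(n), as.integer(seed))
}

# Seeded chunked merge-shuffle: shuffle within fixed-size chunks, then drain
# the chunks by size-proportional sampling. Linear time, bounded working set
# per chunk; in-memory stand-in for an external-memory shuffler with
# identical output distribution.
chunked_shuffle <- function(lines, seed, chunk_size = 10000L) {
  n <- length(lines)
  if (n <= 1L) return(lines)
  rng <- local({ set.seed(seed); NULL })
  set.seed(seed)
  starts <- seq.int(1L, n, by = chunk_size)
  chunks <- lapply(starts, function(s) {
    idx <- s:min(s + chunk_size - 1L, n)
    lines[sample(idx)]
  })
  remaining <- vapply(chunks, length, integer(1))
  pos <- rep(1L, length(chunks))
  out <- character(n)
  for (i in seq_len(n)) {
    j <- sample.int(length(chunks), 1L, prob = remaining)
    out[i] <- chunks[[j]][pos[j]]
    pos[j] <- pos[j] + 1L
    remaining[j] <- remaining[j] - 1L
  }
  out
}

#' Build a deduplicated, frequency-augmented pre-training corpus
#'
#' Applies the full curation pipeline to one or more SMILES sources:
#' sanitize/canonicalize every record, pool duplicate counts, keep each
#' unique canonical form once — except the top-fraction most frequent
#' duplicates, which are emitted count-proportionally in canonical and
#' randomized forms — drop sequences longer than `max_token_length` tokens,
#' and write a seeded shuffle of the result.
#'
#' @param sources Named list of character vectors of raw SMILES (one element
#'   per source dataset).
#' @param config A [curation_config()].
#' @param out_file Output path; one SMILES per line. The manifest is written
#'   next to it as `<out_file>.manifest.json`.
#' @param tokenizer Optional trained [train_unigram()] model used for the
#'   length filter; when absent the atom-level regex tokenizer measures
#'   length (bootstrap phase).
#' @return Invisibly, the manifest as a list.
#' @export
build_pretraining_corpus <- function(sources, config = curation_config(),
                                     out_file, tokenizer = NULL) {
  stopifnot(is.list(sources), length(sources) > 0)
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    names(sources) <- paste0("source", seq_along(sources))
  }

  per_source <- list()
  canon_all <- character(0)
  for (nm in names(sources)) {
    res <- sanitize_and_canonicalize(sources[[nm]])
    per_source[[nm]] <- list(input = nrow(res),
                             rejected_invalid = sum(!res$ok),
                             retained = sum(res$ok))
    canon_all <- c(canon_all, res$canonical[res$ok])
  }

  freq <- frequency_analysis(canon_all)
  top <- select_top_fraction(freq, config$top_fraction)

  token_len <- function(s) {
    if (!is.null(tokenizer)) {
      vapply(s, function(x) length(encode(tokenizer, x)$ids) - 2L, integer(1))
    } else {
      vapply(s, function(x) length(regex_tokenize(x)), integer(1))
    }
  }
  keys <- names(freq)
  lens <- token_len(keys)
  too_long <- lens > config$max_token_length
  n_too_long <- sum(too_long)
  keys <- keys[!too_long]
  freq <- freq[!too_long]
  top <- setdiff(top, names(which(too_long)))
  if (length(keys) == 0L) stop("zero retained records after filtering", call. = FALSE)

  lines <- character(0)
  n_aug_lines <- 0L
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (k %in% top) {
      m <- max(1L, ceiling(freq[[k]] * config$augment_rate))
      n_canon <- ceiling(m / 2)
      n_rand <- m - n_canon
      aug <- if (n_rand > 0L) {
        augment_smiles(k, n_rand, seed = config$shuffle_seed + i)
      } else character(0)
      lines <- c(lines, rep(k, n_canon), aug)
      n_aug_lines <- n_aug_lines + m
    } else {
      lines <- c(lines, k)
    }
  }

  lines <- chunked_shuffle(lines, seed = config$shuffle_seed,
                           chunk_size = config$chunk_size)
  writeLines(lines, out_file)

  manifest <- list(
    sources = per_source,
    unique_molecules = length(keys),
    removed_too_long = n_too_long,
    top_set_size = length(top),
    augmented_lines = n_aug_lines,
    output_lines = length(lines),
    seed = config$shuffle_seed,
    config = unclass(config)
  )
  jsonlite::write_json(manifest, paste0(out_file, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Functional-group profile of a SMILES sample
#'
#' Counts, for each named substructure pattern in the catalog, how many
#' molecules of the sample match it. A molecule may count toward several
#' groups. Invalid SMILES are skipped; their number is attached as the
#' `n_invalid` attribute and reported with a warning.
#'
#' @param smiles Character vector of SMILES.
#' @param catalog Named character vector of SMARTS patterns; defaults to the
#'   built-in 15-group catalog ([default_fg_catalog()]).
#' @return Named integer vector of molecule counts per group.
#' @export
functional_group_profile <- function(smiles, catalog = default_fg_catalog()) {
  ok <- sanitize_and_canonicalize(smiles)$ok
  if (any(!ok)) warning(sum(!ok), " invalid SMILES skipped", call. = FALSE)
  valid <- smiles[ok]
  counts <- vapply(catalog, function(p) {
    if (length(valid) == 0L) return(0L)
    sum(chem_has_substructure(valid, p, smarts = TRUE), na.rm = TRUE)
  }, integer(1))
  structure(counts, names = names(catalog), n_invalid = sum(!ok))
}

#' Read / write .smi files
#'
#' `read_smi()` reads one SMILES per line; an optional tab-separated second
#' column (record ID) is dropped. `write_smi()` writes one SMILES per line.
#'
#' @param path File path.
#' @return `read_smi()`: character vector of SMILES.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' @rdname read_smi
#' @param smiles Character vector to write.
#' @export
write_smi <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}
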