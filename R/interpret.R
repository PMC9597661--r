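# Attention extraction, functional-group-to-token attribution and the
# attention-proportion rank test.

#' Built-in functional-group catalog
#'
#' Fifteen named SMARTS patterns covering the common organic functional
#' groups. Deliberately self-contained so no external fragment-catalog
#' version is a dependency; pass any named SMARTS vector to override.
#'
#' @return Named character vector of SMARTS.
#' @export
default_fg_catalog <- function() {
  c(hydroxyl        = "[OX2H]",
    carboxylic_acid = "C(=O)[OX2H1]",
    ester           = "C(=O)O[#6]",
    amide           = "C(=O)[NX3]",
    primary_amine   = "[NX3;H2;!$(NC=O)]",
    nitro           = "[N+](=O)[O-]",
    nitrile         = "C#N",
    ketone          = "[#6][CX3](=O)[#6]",
    aldehyde        = "[CX3H1]=O",
    ether           = "[OD2]([#6])[#6]",
    thiol           = "[SX2H]",
    halogen         = "[F,Cl,Br,I]",
    alkene          = "C=C",
    alkyne          = "C#C",
    benzene_ring    = "c1ccccc1")
}

#' Extract the full attention tensor for a molecule
#'
#' Runs the encoder in eval mode and returns every attention matrix,
#' indexed (layer, head, from-token, to-token), with the token surfaces and
#' character offsets of the encoded sequence. Each row of every matrix sums
#' to 1 (softmax normalization). Over-length inputs are truncated with a
#' warning.
#'
#' @param model A `smilesbert_model`.
#' @param smiles A single SMILES string.
#' @return List of class `attention_map`: `attention` (nested list
#'   `[[layer]][[head]]` of L x L matrices), `tokens`, `offsets`,
#'   `n_layers`, `n_heads`.
#' @export
extract_attention <- function(model, smiles) {
  seq <- encode(model$tokenizer, smiles)
  if (isTRUE(seq$truncated)) {
    warning("input truncated to ", model$tokenizer$max_content_length,
            " content tokens", call. = FALSE)
  }
  fwd <- encoder_forward(model$encoder, list(seq$ids), training = FALSE,
                         need_attention = TRUE)
  att <- lapply(fwd$attention, function(layer) layer[[1]])
  structure(list(attention = att, tokens = seq$tokens, offsets = seq$offsets,
                 n_layers = model$encoder$config$n_layers,
                 n_heads = model$encoder$config$n_heads),
            class = "attention_map")
}

# Character span (0-based, half-open) of each atom in a SMILES string: the
# k-th atom-level regex token that denotes an atom corresponds to atom k-1
# in the molecular graph (atom order in the parsed molecule follows
# appearance order in the string).
atom_char_spans <- function(smiles) {
  toks <- regex_tokenize(smiles)
  starts <- cumsum(c(0L, nchar(toks)))[seq_along(toks)]
  is_atom <- grepl("^(\\[.*\\]|Br|Cl|B|C|N|O|S|P|F|I|b|c|n|o|s|p)$", toks)
  data.frame(start = starts[is_atom],
             end = starts[is_atom] + nchar(toks[is_atom]))
}

#' Map catalog functional groups to tokenizer tokens
#'
#' For each catalog pattern matched in the molecule, maps the matched atom
#' indices to their character spans in the SMILES string and thence to the
#' (1-based) indices of the encoded tokens overlapping those spans.
#'
#' @param smiles A single valid SMILES string.
#' @param offsets Token offsets from [encode()] (n x 2, 0-based half-open).
#' @param catalog Named SMARTS vector (default [default_fg_catalog()]).
#' @return Named list: for each matched group, the sorted integer vector of
#'   token indices. Groups without a match are omitted.
#' @export
match_groups_to_tokens <- function(smiles, offsets,
                                   catalog = default_fg_catalog()) {
  spans <- atom_char_spans(smiles)
  matches <- chem_substruct_matches(smiles, as.list(catalog))
  out <- list()
  for (g in names(matches)) {
    hits <- matches[[g]]
    if (length(hits) == 0L) next
    atom_idx <- unique(unlist(hits))  # 0-based atom indices
    if (any(atom_idx + 1L > nrow(spans))) {
      warning("atom-to-character mapping failed for group '", g, "'; skipped",
              call. = FALSE)
      next
    }
    a_start <- spans$start[atom_idx + 1L]
    a_end <- spans$end[atom_idx + 1L]
    tok_idx <- which(vapply(seq_len(nrow(offsets)), function(t) {
      any(offsets[t, 1] < a_end & offsets[t, 2] > a_start)
    }, logical(1)))
    if (length(tok_idx)) out[[g]] <- sort(tok_idx)
  }
  out
}

#' Attention proportion received by a token set
#'
#' The share of total attention received by the given tokens: for each
#' (layer, head), the column sums over the index set divided by the total
#' attention mass (= L by row normalization), then reduced over layers and
#' heads. The default reduction is the mean over all layers and heads;
#' `"per_layer"`/`"per_head"` return the un-collapsed values, and
#' `direction = "emitted"` uses row sums (attention paid by the set)
#' instead.
#'
#' @param map An `attention_map`.
#' @param token_idx Integer token indices (1-based). Empty set returns 0.
#' @param reduction `"mean"`, `"per_layer"` or `"per_head"`.
#' @param direction `"received"` (column mass, default) or `"emitted"`.
#' @return A proportion in `[0, 1]` (or a vector/matrix for un-collapsed
#'   reductions).
#' @export
attention_proportion <- function(map, token_idx,
                                 reduction = c("mean", "per_layer", "per_head"),
                                 direction = c("received", "emitted")) {
  reduction <- match.arg(reduction)
  direction <- match.arg(direction)
  L <- length(map$tokens)
  if (length(token_idx) == 0L) return(0)
  stopifnot(all(token_idx >= 1L), all(token_idx <= L))
  per <- matrix(NA_real_, map$n_layers, map$n_heads)
  for (l in seq_len(map$n_layers)) {
    for (h in seq_len(map$n_heads)) {
      A <- map$attention[[l]][[h]]
      mass <- if (direction == "received") {
        sum(A[, token_idx, drop = FALSE])
      } else {
        sum(A[token_idx, , drop = FALSE])
      }
      per[l, h] <- mass / L
    }
  }
  switch(reduction,
         mean = mean(per),
         per_layer = rowMeans(per),
         per_head = per)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For small samples (both sizes <= 8) the exact
#' null distribution is enumerated over all rank arrangements (midranks
#' under ties); larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List with `U` (statistic of the first sample), `p` (two-sided),
#'   `method`, and `all_tied` (flag: degenerate all-equal input, p = 1).
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  n <- length(sample_a); m <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled, ties.method = "average")
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (length(unique(pooled)) == 1L) {
    return(list(U = U, p = 1, method = "degenerate", all_tied = TRUE))
  }
  if (n <= 8L && m <= 8L) {
    combs <- utils::combn(n + m, n)
    Us <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
    mid <- n * m / 2
    p <- mean(abs(Us - mid) >= abs(U - mid) - 1e-9)
    return(list(U = U, p = p, method = "exact", all_tied = FALSE))
  }
  mu <- n * m / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / ((n + m) * (n + m - 1))
  sigma2 <- n * m / 12 * ((n + m + 1) - tie_term)
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-max(z, 0))),
       method = "normal_approx", all_tied = FALSE)
}

#' Attention attribution report for a molecule sample
#'
#' Convenience wrapper producing, per molecule, the matched groups, their
#' token spans and attention proportions, plus the rank test between the
#' functional-group frequency distribution and the attention-proportion
#' distribution across the sample.
#'
#' @param model A `smilesbert_model`.
#' @param smiles Character vector of molecules.
#' @param catalog Named SMARTS vector.
#' @return List with `per_molecule` (list of group -> proportion), `test`
#'   (the [mann_whitney_u()] result comparing the per-group frequency
#'   distribution with the per-group mean attention proportions).
#' @export
attention_report <- function(model, smiles, catalog = default_fg_catalog()) {
  per_mol <- vector("list", length(smiles))
  names(per_mol) <- smiles
  for (i in seq_along(smiles)) {
    map <- extract_attention(model, smiles[i])
    grp <- match_groups_to_tokens(smiles[i], map$offsets, catalog)
    per_mol[[i]] <- vapply(grp, function(idx) {
      attention_proportion(map, idx)
    }, numeric(1))
  }
  groups <- names(catalog)
  freq <- vapply(groups, function(g) {
    mean(vapply(per_mol, function(pm) g %in% names(pm), logical(1)))
  }, numeric(1))
  att <- vapply(groups, function(g) {
    v <- unlist(lapply(per_mol, function(pm) {
      if (g %in% names(pm)) pm[[g]] else NULL
    }))
    if (is.null(v) || !length(v)) NA_real_ else mean(v)
  }, numeric(1))
  present <- !is.na(att)
  test <- if (sum(present) >= 2) {
    mann_whitney_u(freq[present], att[present])
  } else NULL
  list(per_molecule = per_mol,
       group_frequency = freq, group_attention = att, test = test)
}
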