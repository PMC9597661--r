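# Raw-stream unigram subword tokenizer for SMILES.
#
# Training follows the SentencePiece unigram recipe at desk scale: a seed
# vocabulary of frequent substrings is reduced by EM-estimated likelihood
# contribution until the requested size is reached. No whitespace
# pre-tokenization: the line is the unit.

SPECIAL_TOKENS <- c("[PAD]", "[CLS]", "[SEP]", "[UNK]", "[MASK]")
PAD_ID <- 0L; CLS_ID <- 1L; SEP_ID <- 2L; UNK_ID <- 3L; MASK_ID <- 4L

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# All substrings of `line` with length 1..max_len, as a data.frame of
# (start, len, piece). Vectorized.
line_substrings <- function(line, max_len) {
  n <- nchar(line)
  if (n == 0L) return(NULL)
  starts <- rep(seq_len(n), each = max_len)
  lens <- rep(seq_len(max_len), times = n)
  keep <- starts + lens - 1L <= n
  starts <- starts[keep]; lens <- lens[keep]
  list(start = starts, len = lens,
       piece = substring(line, starts, starts + lens - 1L))
}

# Precompute the segmentation lattice of one line against a fixed piece
# pool: for each lattice edge, its start, end and pool index, plus index
# lists grouped by end (forward pass) and by start (backward pass).
line_lattice <- function(line, pool, max_len) {
  n <- nchar(line)
  sub <- line_substrings(line, max_len)
  pidx <- match(sub$piece, pool)
  keep <- !is.na(pidx)
  start <- sub$start[keep]; len <- sub$len[keep]; pidx <- pidx[keep]
  end <- start + len - 1L
  list(n = n, start = start, end = end, pidx = pidx,
       by_end = split(seq_along(start), factor(end, levels = seq_len(n))),
       by_start = split(seq_along(start), factor(start, levels = seq_len(n))))
}

# One EM pass (forward-backward expected counts) over precomputed lattices.
# `pool_lp` is the log-probability per pool piece (-Inf = inactive piece).
# Returns updated log-probabilities (over active pieces only), expected
# counts and the corpus log-likelihood.
em_pass <- function(lattices, pool_lp) {
  P <- length(pool_lp)
  total <- numeric(P)
  ll_sum <- 0
  for (lat in lattices) {
    n <- lat$n
    lp <- pool_lp[lat$pidx]
    alpha <- c(0, rep(-Inf, n))
    for (j in seq_len(n)) {
      idx <- lat$by_end[[j]]
      if (length(idx)) {
        v <- alpha[lat$start[idx]] + lp[idx]
        m <- max(v)
        if (is.finite(m)) alpha[j + 1L] <- m + log(sum(exp(v - m)))
      }
    }
    ll <- alpha[n + 1L]
    if (!is.finite(ll)) next
    ll_sum <- ll_sum + ll
    beta <- c(rep(-Inf, n), 0)
    for (j in rev(seq_len(n))) {
      idx <- lat$by_start[[j]]
      if (length(idx)) {
        v <- lp[idx] + beta[lat$end[idx] + 1L]
        m <- max(v)
        if (is.finite(m)) beta[j] <- m + log(sum(exp(v - m)))
      }
    }
    post <- exp(alpha[lat$start] + lp + beta[lat$end + 1L] - ll)
    ok <- is.finite(post) & post > 0
    if (any(ok)) {
      agg <- rowsum(post[ok], lat$pidx[ok])
      ridx <- as.integer(rownames(agg))
      total[ridx] <- total[ridx] + agg[, 1]
    }
  }
  active <- is.finite(pool_lp)
  new_lp <- rep(-Inf, P)
  new_lp[active] <- log(total[active] + 1e-12) -
    log(sum(total[active]) + 1e-12 * sum(active))
  list(logprob = new_lp, counts = total, ll = ll_sum)
}

#' Train a unigram tokenizer on a SMILES corpus
#'
#' Treats each line as a raw character stream (no whitespace
#' pre-tokenization), seeds a vocabulary from frequent substrings, estimates
#' unigram log-probabilities by EM over all segmentations
#' (forward–backward), and prunes the lowest-contribution multi-character
#' pieces until exactly `vocab_size` entries remain (five auxiliary tokens
#' `[PAD] [CLS] [SEP] [UNK] [MASK]` plus content pieces). Every character
#' seen in training is kept as a single-character piece, so training lines
#' are always encodable with zero `[UNK]`.
#'
#' @param corpus Character vector of SMILES lines (or a file path).
#' @param vocab_size Total vocabulary size including the five specials. Must
#'   be at least the training character-set size + 5.
#' @param seed Integer seed (controls corpus subsampling when the corpus is
#'   large).
#' @param max_piece_len Maximum piece length in characters. Default 8.
#' @param em_iters EM passes per pruning round. Default 2.
#' @param max_train_lines Subsample cap on training lines. Default 20000.
#' @return An object of class `unigram_tokenizer` with fields `vocab`
#'   (token surfaces, index = id + 1), `logprob`, `specials`,
#'   `max_content_length` (512) and `char_set`.
#' @export
train_unigram <- function(corpus, vocab_size, seed = 1L, max_piece_len = 8L,
                          em_iters = 2L, max_train_lines = 20000L) {
  if (length(corpus) == 1L && file.exists(corpus)) corpus <- read_smi(corpus)
  corpus <- corpus[nzchar(corpus)]
  stopifnot(length(corpus) > 0)
  set.seed(seed)
  if (length(corpus) > max_train_lines) {
    corpus <- corpus[sample.int(length(corpus), max_train_lines)]
  }

  chars <- sort(unique(unlist(strsplit(corpus, "", fixed = TRUE))))
  n_content <- vocab_size - length(SPECIAL_TOKENS)
  if (n_content < length(chars)) {
    stop("vocab_size ", vocab_size, " is below character coverage (",
         length(chars), " characters + 5 specials)", call. = FALSE)
  }

  all_pieces <- unlist(lapply(corpus, function(l) line_substrings(l, max_piece_len)$piece))
  counts <- sort(table(all_pieces), decreasing = TRUE)
  pool_size <- min(length(counts), max(n_content * 3L, n_content + 50L))
  pool <- union(chars, names(counts)[seq_len(pool_size)])
  if (length(pool) < n_content) {
    stop("corpus admits only ", length(pool), " distinct pieces; ",
         "vocab_size ", vocab_size, " is unattainable", call. = FALSE)
  }
  pool_nchar <- nchar(pool)
  lattices <- lapply(corpus, line_lattice, pool = pool, max_len = max_piece_len)

  cnt0 <- as.numeric(counts[pool]); cnt0[is.na(cnt0)] <- 1
  pool_lp <- log(cnt0) - log(sum(cnt0))

  repeat {
    for (it in seq_len(em_iters)) {
      em <- em_pass(lattices, pool_lp)
      pool_lp <- em$logprob
    }
    n_active <- sum(is.finite(pool_lp))
    if (n_active <= n_content) break
    # prune lowest expected-count multi-character pieces (likelihood-loss
    # proxy: a rarely used piece contributes least to the corpus likelihood)
    cand <- which(is.finite(pool_lp) & pool_nchar > 1L)
    n_drop <- min(length(cand), max(1L, ceiling(n_active * 0.25)),
                  n_active - n_content)
    if (n_drop == 0L) break
    ord <- order(em$counts[cand], pool[cand], method = "radix")
    pool_lp[cand[ord][seq_len(n_drop)]] <- -Inf
  }

  # top up to the exact size if single-character coverage left us short
  n_active <- sum(is.finite(pool_lp))
  if (n_active < n_content) {
    inactive <- which(!is.finite(pool_lp))
    ord <- order(-cnt0[inactive], pool[inactive], method = "radix")
    revive <- inactive[ord][seq_len(n_content - n_active)]
    pool_lp[revive] <- min(pool_lp[is.finite(pool_lp)]) - 1
  }
  em <- em_pass(lattices, pool_lp)
  pool_lp <- em$logprob

  active <- which(is.finite(pool_lp))
  o <- order(pool[active], method = "radix")
  content <- pool[active][o]
  content_lp <- pool_lp[active][o]
  model <- structure(list(
    vocab = c(SPECIAL_TOKENS, content),
    logprob = c(rep(NA_real_, length(SPECIAL_TOKENS)), content_lp),
    specials = structure(c(PAD_ID, CLS_ID, SEP_ID, UNK_ID, MASK_ID),
                         names = SPECIAL_TOKENS),
    max_content_length = 512L,
    max_piece_len = as.integer(max_piece_len),
    char_set = chars,
    vocab_size = length(SPECIAL_TOKENS) + length(content)
  ), class = "unigram_tokenizer")
  model
}

#' @export
print.unigram_tokenizer <- function(x, ...) {
  cat("Unigram SMILES tokenizer\n")
  cat("  vocabulary:", x$vocab_size, "tokens (5 specials +",
      x$vocab_size - 5L, "content pieces)\n")
  cat("  character set:", length(x$char_set), "characters\n")
  cat("  max content length:", x$max_content_length, "tokens\n")
  invisible(x)
}

#' Encode a SMILES string
#'
#' Segments the string into the maximum-likelihood token sequence under the
#' unigram model (Viterbi over the segmentation lattice), truncates the
#' content to 512 tokens, and wraps it in `[CLS]` ... `[SEP]`. Characters
#' outside the training set map to `[UNK]`.
#'
#' @param model A trained [train_unigram()] model.
#' @param smiles A single SMILES string.
#' @return A list of class `token_sequence`: `ids` (integer, 0-based),
#'   `tokens` (surfaces), `offsets` (n x 2 integer matrix of 0-based
#'   half-open character spans; specials span zero characters), and
#'   `truncated` (logical).
#' @export
encode <- function(model, smiles) {
  stopifnot(inherits(model, "unigram_tokenizer"), length(smiles) == 1L)
  n <- nchar(smiles)
  if (n == 0L) {
    return(structure(list(ids = c(CLS_ID, SEP_ID),
                          tokens = c("[CLS]", "[SEP]"),
                          offsets = matrix(0L, 2, 2), truncated = FALSE),
                     class = "token_sequence"))
  }
  sub <- line_substrings(smiles, model$max_piece_len)
  id <- match(sub$piece, model$vocab) - 1L
  lp <- model$logprob[id + 1L]
  # unknown single characters fall back to [UNK] at a heavily penalized score
  unk <- is.na(id) & sub$len == 1L
  lp_floor <- min(model$logprob, na.rm = TRUE) - 100
  id[unk] <- UNK_ID
  lp[unk] <- lp_floor
  usable <- !is.na(id) & !is.na(lp)

  best <- c(0, rep(-Inf, n))
  back_len <- integer(n); back_id <- integer(n)
  ends <- sub$start + sub$len - 1L
  for (j in seq_len(n)) {
    idx <- which(ends == j & usable)
    if (!length(idx)) next
    cand <- best[sub$start[idx]] + lp[idx]
    # deterministic tie-break: prefer the longer piece, then the smaller id
    o <- order(-cand, -sub$len[idx], id[idx], method = "radix")[1]
    best[j + 1L] <- cand[o]
    back_len[j] <- sub$len[idx][o]
    back_id[j] <- id[idx][o]
  }
  if (!is.finite(best[n + 1L])) stop("unencodable input", call. = FALSE)

  ids <- integer(0); offs <- NULL
  j <- n
  while (j > 0L) {
    l <- back_len[j]
    ids <- c(back_id[j], ids)
    offs <- rbind(c(j - l, j), offs)
    j <- j - l
  }
  truncated <- length(ids) > model$max_content_length
  if (truncated) {
    keep <- seq_len(model$max_content_length)
    ids <- ids[keep]; offs <- offs[keep, , drop = FALSE]
  }
  surfaces <- ifelse(ids == UNK_ID, "[UNK]", model$vocab[ids + 1L])
  structure(list(
    ids = c(CLS_ID, ids, SEP_ID),
    tokens = c("[CLS]", surfaces, "[SEP]"),
    offsets = rbind(c(0L, 0L), offs, c(n, n)),
    truncated = truncated
  ), class = "token_sequence")
}

#' Decode a token sequence
#'
#' Concatenates the surfaces of the content tokens; auxiliary tokens
#' (`[PAD] [CLS] [SEP] [MASK]`) are dropped. `[UNK]` has no surface and
#' decodes to the empty string.
#'
#' @param model A trained [train_unigram()] model.
#' @param seq A `token_sequence` or a bare integer id vector.
#' @return The decoded string.
#' @export
decode <- function(model, seq) {
  ids <- if (inherits(seq, "token_sequence")) seq$ids else as.integer(seq)
  if (any(ids < 0L | ids >= model$vocab_size)) {
    stop("unknown token id: ", paste(ids[ids < 0L | ids >= model$vocab_size],
                                     collapse = ", "), call. = FALSE)
  }
  content <- ids[!(ids %in% c(PAD_ID, CLS_ID, SEP_ID, MASK_ID, UNK_ID))]
  paste(model$vocab[content + 1L], collapse = "")
}

#' Atom-level regex tokenization
#'
#' Tokenizes a SMILES string with the widely used atom-level pattern
#' (bracket atoms, two-letter elements, ring-closure digits and stereo marks
#' as single tokens). The matches must tile the input exactly; any
#' unmatched span raises an error naming it.
#'
#' @param smiles A single SMILES string.
#' @param pattern Regex whose matches tile SMILES strings. The default is
#'   the standard atom-level SMILES pattern.
#' @return Character vector of tokens whose concatenation equals the input.
#' @export
regex_tokenize <- function(smiles, pattern = smiles_atom_regex()) {
  stopifnot(length(smiles) == 1L)
  if (!nzchar(smiles)) return(character(0))
  m <- gregexpr(pattern, smiles, perl = TRUE)[[1]]
  toks <- regmatches(smiles, gregexpr(pattern, smiles, perl = TRUE))[[1]]
  if (paste(toks, collapse = "") != smiles) {
    covered <- rep(FALSE, nchar(smiles))
    if (m[1] != -1L) {
      for (k in seq_along(m)) {
        covered[m[k]:(m[k] + attr(m, "match.length")[k] - 1L)] <- TRUE
      }
    }
    bad <- which(!covered)
    stop("regex does not tile input; unmatched span at characters ",
         bad[1], "-", bad[length(bad)], ": '",
         substr(smiles, bad[1], bad[length(bad)]), "'", call. = FALSE)
  }
  toks
}

#' @rdname regex_tokenize
#' @export
smiles_atom_regex <- function() {
  paste0("(\\[[^\\]]+\\]|Br?|Cl?|N|O|S|P|F|I|b|c|n|o|s|p|\\(|\\)|\\.|=|#|",
         "-|\\+|\\\\|/|:|~|@|\\?|>|\\*|\\$|%[0-9]{2}|[0-9])")
}

#' Compare unigram and regex token counts over a corpus
#'
#' Totals exclude padding and auxiliary tokens; the mean difference is
#' `(total_regex - total_unigram) / n_smiles`, i.e. how many extra tokens
#' per molecule the regex tokenizer feeds through the model.
#'
#' @param corpus Character vector of SMILES.
#' @param model A trained [train_unigram()] model.
#' @param pattern Regex for the baseline (default [smiles_atom_regex()]).
#' @return List with `total_unigram`, `total_regex`, `mean_diff_per_smiles`.
#' @export
compare_token_counts <- function(corpus, model, pattern = smiles_atom_regex()) {
  n_uni <- vapply(corpus, function(s) length(encode(model, s)$ids) - 2L,
                  integer(1))
  n_re <- vapply(corpus, function(s) length(regex_tokenize(s, pattern)),
                 integer(1))
  list(total_unigram = sum(n_uni), total_regex = sum(n_re),
       mean_diff_per_smiles = (sum(n_re) - sum(n_uni)) / length(corpus))
}

#' Save / load a tokenizer model
#'
#' Serializes the model as a single JSON file (vocabulary surfaces,
#' log-probabilities, specials, configuration).
#'
#' @param model A `unigram_tokenizer`.
#' @param path File path.
#' @export
save_tokenizer <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_tokenizer
#' @export
load_tokenizer <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$specials <- structure(as.integer(x$specials), names = SPECIAL_TOKENS)
  x$max_content_length <- as.integer(x$max_content_length)
  x$max_piece_len <- as.integer(x$max_piece_len)
  x$vocab_size <- as.integer(x$vocab_size)
  structure(x, class = "unigram_tokenizer")
}
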