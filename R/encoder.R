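# RoBERTa-style transformer encoder: configuration, initialization, forward
# pass (with attention capture) and parameter accounting. The backward pass
# lives in backprop.R.

#' Encoder configuration
#'
#' Hyperparameters of the transformer stack. The defaults are the
#' full-scale preset (12 layers, 12 heads, hidden 768, intermediate 3072,
#' 514 positions); [desk_preset()] gives a configuration small enough to
#' train on one CPU in minutes.
#'
#' @param n_layers Number of encoder blocks.
#' @param n_heads Attention heads per block; must divide `hidden`.
#' @param hidden Hidden size; this is also the fingerprint dimensionality.
#' @param intermediate Feed-forward inner size.
#' @param max_positions Maximum sequence length including `[CLS]`/`[SEP]`
#'   (512 content tokens + 2 auxiliaries = 514).
#' @param vocab_size Tokenizer vocabulary size.
#' @param dropout Dropout probability used during training (0 disables).
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(n_layers = 12L, n_heads = 12L, hidden = 768L,
                           intermediate = 3072L, max_positions = 514L,
                           vocab_size, dropout = 0.1) {
  stopifnot(hidden %% n_heads == 0L, max_positions >= 3L, vocab_size >= 6L,
            dropout >= 0, dropout < 1)
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 hidden = as.integer(hidden),
                 intermediate = as.integer(intermediate),
                 max_positions = as.integer(max_positions),
                 vocab_size = as.integer(vocab_size), dropout = dropout),
            class = "encoder_config")
}

#' Desk-scale encoder preset
#'
#' A configuration trainable in minutes on one CPU: 2 layers, 4 heads,
#' hidden 64, intermediate 256, dropout 0. Used throughout the tests and
#' examples.
#'
#' @param vocab_size Tokenizer vocabulary size (default 200, the desk
#'   tokenizer preset).
#' @export
desk_preset <- function(vocab_size = 200L) {
  encoder_config(n_layers = 2L, n_heads = 4L, hidden = 64L,
                 intermediate = 256L, max_positions = 514L,
                 vocab_size = vocab_size, dropout = 0)
}

#' @rdname desk_preset
#' @details `base_preset()` is the full-scale configuration of this
#'   architecture family: 12 layers, 12 heads, hidden 768, intermediate
#'   3072, vocabulary 2417.
#' @export
base_preset <- function(vocab_size = 2417L) {
  encoder_config(vocab_size = vocab_size)
}

#' Named presets for the enumerated-database ablation
#'
#' The cumulative GDB-13 subsets (increasingly restrictive molecule-removal
#' criteria, from heteroatom-bond exclusion down to scaffold-like molecules)
#' are supported as named training presets only: each preset pairs the
#' full-scale encoder with the subset label and its selection criterion.
#' The subset data themselves are not bundled.
#'
#' @return A named list of preset descriptors.
#' @export
gdb13_subset_presets <- function() {
  crit <- c(AB = "no cyclic or acyclic HetHet bonds",
            ABC = "stable FG",
            ABCD = "no cyclic C=C or C#C bonds",
            ABCDE = "no acyclic C=C or C#C bonds",
            ABCDEF = "no small rings",
            ABCDEFG = "fragment-like",
            ABCDEFGH = "scaffold-like")
  lapply(stats::setNames(names(crit), names(crit)), function(nm) {
    list(subset = nm, criterion = crit[[nm]], config = base_preset())
  })
}

rnorm_mat <- function(n, m, sd = 0.02) matrix(stats::rnorm(n * m, sd = sd), n, m)

#' Build a transformer encoder
#'
#' Initializes all parameters (truncated-normal weights, unit layer-norm
#' gains, zero biases). The masked-language-model head shares its decoder
#' matrix with the input embedding table (weight tying), so the tied tensor
#' is counted once by [count_parameters()].
#'
#' @param config An [encoder_config()].
#' @param init `"normal"` (sd 0.02) or `"zero"`.
#' @return An object of class `smiles_encoder`.
#' @export
build_encoder <- function(config, init = c("normal", "zero")) {
  init <- match.arg(init)
  H <- config$hidden; I <- config$intermediate; V <- config$vocab_size
  mk <- function(n, m) {
    if (init == "zero") matrix(0, n, m) else rnorm_mat(n, m)
  }
  ln <- function() list(g = rep(1, H), b = rep(0, H))
  layers <- lapply(seq_len(config$n_layers), function(l) {
    list(Wq = mk(H, H), bq = rep(0, H), Wk = mk(H, H), bk = rep(0, H),
         Wv = mk(H, H), bv = rep(0, H), Wo = mk(H, H), bo = rep(0, H),
         ln1 = ln(),
         W1 = mk(H, I), b1 = rep(0, I), W2 = mk(I, H), b2 = rep(0, H),
         ln2 = ln())
  })
  params <- list(
    We = mk(V, H),
    Pe = mk(config$max_positions, H),
    ln_e = ln(),
    layers = layers,
    head = list(W = mk(H, H), b = rep(0, H), ln = ln(), bias = rep(0, V))
  )
  structure(list(config = config, params = params), class = "smiles_encoder")
}

#' @export
print.smiles_encoder <- function(x, ...) {
  cfg <- x$config
  cat("Transformer SMILES encoder\n")
  cat(sprintf("  %d layers x %d heads, hidden %d, intermediate %d\n",
              cfg$n_layers, cfg$n_heads, cfg$hidden, cfg$intermediate))
  cat(sprintf("  vocabulary %d, max positions %d\n",
              cfg$vocab_size, cfg$max_positions))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums the trainable scalars of an encoder (or computes the same number
#' directly from a configuration). The tied embedding/decoder matrix is
#' counted once. At the full-scale preset with vocabulary 2417 this is
#' 87,938,417, i.e. approximately 88 million.
#'
#' @param x A `smiles_encoder` or an `encoder_config`.
#' @return Integer (double) scalar parameter count.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "smiles_encoder")) {
    count_scalars <- function(p) {
      if (is.numeric(p)) return(length(p))
      sum(vapply(p, count_scalars, numeric(1)))
    }
    return(count_scalars(x$params))
  }
  stopifnot(inherits(x, "encoder_config"))
  H <- x$hidden; I <- x$intermediate; V <- x$vocab_size
  emb <- V * H + x$max_positions * H + 2 * H
  per_layer <- 4 * (H * H + H) + 2 * (2 * H) + (H * I + I) + (I * H + H)
  head <- H * H + H + 2 * H + V
  emb + x$n_layers * per_layer + head
}

# layer norm forward: returns y and the quantities needed for backward
ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(y = y, xhat = xhat, inv = inv)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# Forward pass over a batch of id sequences (list of 0-based integer
# vectors). Sequences are processed flattened for all position-wise
# operations; attention is computed per sequence. Returns the final hidden
# states (N_total x hidden, rows grouped by sequence), row offsets, and
# optionally per-layer hidden states, attention tensors, and the caches
# required by the backward pass.
encoder_forward <- function(enc, ids_list, training = FALSE,
                            need_cache = FALSE, need_attention = FALSE,
                            need_layers = FALSE) {
  cfg <- enc$config; p <- enc$params
  H <- cfg$hidden; nh <- cfg$n_heads; dk <- H / nh
  lens <- lengths(ids_list)
  if (any(lens > cfg$max_positions)) {
    stop("sequence length ", max(lens), " exceeds max_positions ",
         cfg$max_positions, call. = FALSE)
  }
  if (any(unlist(ids_list) >= cfg$vocab_size)) {
    stop("token id out of range for vocab_size ", cfg$vocab_size, call. = FALSE)
  }
  B <- length(ids_list)
  offs <- cumsum(c(0L, lens))
  rows_of <- function(s) (offs[s] + 1L):offs[s + 1L]
  ids_flat <- unlist(ids_list) + 1L
  pos_flat <- unlist(lapply(lens, seq_len))

  drop_p <- if (training) cfg$dropout else 0
  apply_dropout <- function(x) {
    if (drop_p <= 0) return(list(y = x, mask = NULL))
    mask <- matrix(stats::rbinom(length(x), 1L, 1 - drop_p), nrow(x)) / (1 - drop_p)
    list(y = x * mask, mask = mask)
  }

  x0 <- p$We[ids_flat, , drop = FALSE] + p$Pe[pos_flat, , drop = FALSE]
  ln_e <- ln_forward(x0, p$ln_e$g, p$ln_e$b)
  d0 <- apply_dropout(ln_e$y)
  x <- d0$y

  caches <- vector("list", cfg$n_layers)
  attn_all <- if (need_attention) vector("list", cfg$n_layers) else NULL
  layers_out <- if (need_layers) vector("list", cfg$n_layers) else NULL

  for (l in seq_len(cfg$n_layers)) {
    lp <- p$layers[[l]]
    X_in <- x
    Q <- sweep(x %*% lp$Wq, 2, lp$bq, "+")
    K <- sweep(x %*% lp$Wk, 2, lp$bk, "+")
    V <- sweep(x %*% lp$Wv, 2, lp$bv, "+")
    O <- matrix(0, nrow(x), H)
    A_list <- vector("list", B)
    for (s in seq_len(B)) {
      rs <- rows_of(s)
      A_heads <- vector("list", nh)
      for (h in seq_len(nh)) {
        ch <- ((h - 1L) * dk + 1L):(h * dk)
        S <- (Q[rs, ch, drop = FALSE] %*% t(K[rs, ch, drop = FALSE])) / sqrt(dk)
        A <- softmax_rows(S)
        A_heads[[h]] <- A
        O[rs, ch] <- A %*% V[rs, ch, drop = FALSE]
      }
      A_list[[s]] <- A_heads
    }
    attn_proj <- sweep(O %*% lp$Wo, 2, lp$bo, "+")
    d1 <- apply_dropout(attn_proj)
    ln1 <- ln_forward(X_in + d1$y, lp$ln1$g, lp$ln1$b)
    x1 <- ln1$y
    F_pre <- sweep(x1 %*% lp$W1, 2, lp$b1, "+")
    F_act <- gelu(F_pre)
    ffn <- sweep(F_act %*% lp$W2, 2, lp$b2, "+")
    d2 <- apply_dropout(ffn)
    ln2 <- ln_forward(x1 + d2$y, lp$ln2$g, lp$ln2$b)
    x <- ln2$y

    if (need_cache) {
      caches[[l]] <- list(X_in = X_in, Q = Q, K = K, V = V, O = O,
                          A = A_list, ln1 = ln1, ln2 = ln2, x1 = x1,
                          F_pre = F_pre, F_act = F_act,
                          d1 = d1$mask, d2 = d2$mask)
    }
    if (need_attention) attn_all[[l]] <- A_list
    if (need_layers) layers_out[[l]] <- x
  }

  list(hidden = x, lens = lens, offs = offs, ids_flat = ids_flat,
       pos_flat = pos_flat,
       cache = if (need_cache) list(layers = caches, ln_e = ln_e,
                                    d0 = d0$mask, x0 = x0) else NULL,
       attention = attn_all, layer_hidden = layers_out)
}

# MLM head forward at selected rows: returns logits and the head cache.
mlm_head_forward <- function(enc, hidden_rows) {
  hp <- enc$params$head
  z <- sweep(hidden_rows %*% hp$W, 2, hp$b, "+")
  a <- gelu(z)
  ln <- ln_forward(a, hp$ln$g, hp$ln$b)
  logits <- sweep(ln$y %*% t(enc$params$We), 2, hp$bias, "+")
  list(logits = logits, z = z, a = a, ln = ln, h_in = hidden_rows)
}
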