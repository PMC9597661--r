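# Hand-written backward pass through the encoder, parameter-structure
# helpers, and the AdamW optimizer. Everything is double precision; the
# gradient of k accumulated micro-batches therefore equals the large-batch
# gradient to floating-point rounding.

param_zero <- function(p) {
  if (is.numeric(p)) {
    z <- p; z[] <- 0; return(z)
  }
  lapply(p, param_zero)
}

param_map2 <- function(a, b, f) {
  if (is.numeric(a)) return(f(a, b))
  out <- mapply(param_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
  out
}

param_add <- function(a, b) param_map2(a, b, `+`)
param_scale <- function(a, s) {
  if (is.numeric(a)) return(a * s)
  lapply(a, param_scale, s = s)
}

param_flatten <- function(p) {
  if (is.numeric(p)) return(as.numeric(p))
  unlist(lapply(p, param_flatten), use.names = FALSE)
}

ln_backward <- function(dy, ln, g) {
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * ln$xhat)
  dx <- (dxhat - m1 - ln$xhat * m2) * ln$inv
  list(dx = dx, dg = colSums(dy * ln$xhat), db = colSums(dy))
}

# Backward through the encoder given the gradient at the final hidden
# states. `fwd` must come from encoder_forward(need_cache = TRUE).
# Returns gradients in the same nested structure as enc$params (the head is
# left zeroed; callers that use the MLM head add its gradients themselves).
encoder_backward <- function(enc, fwd, d_hidden) {
  cfg <- enc$config; p <- enc$params
  H <- cfg$hidden; nh <- cfg$n_heads; dk <- H / nh
  B <- length(fwd$lens)
  offs <- fwd$offs
  rows_of <- function(s) (offs[s] + 1L):offs[s + 1L]
  g <- param_zero(p)
  dx <- d_hidden

  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- p$layers[[l]]
    c <- fwd$cache$layers[[l]]
    gl <- g$layers[[l]]

    ln2b <- ln_backward(dx, c$ln2, lp$ln2$g)
    gl$ln2$g <- ln2b$dg; gl$ln2$b <- ln2b$db
    dsum2 <- ln2b$dx
    dffn <- if (is.null(c$d2)) dsum2 else dsum2 * c$d2
    gl$W2 <- t(c$F_act) %*% dffn
    gl$b2 <- colSums(dffn)
    dF_act <- dffn %*% t(lp$W2)
    dF_pre <- dF_act * gelu_grad(c$F_pre)
    gl$W1 <- t(c$x1) %*% dF_pre
    gl$b1 <- colSums(dF_pre)
    dx1 <- dsum2 + dF_pre %*% t(lp$W1)

    ln1b <- ln_backward(dx1, c$ln1, lp$ln1$g)
    gl$ln1$g <- ln1b$dg; gl$ln1$b <- ln1b$db
    dsum1 <- ln1b$dx
    dattn <- if (is.null(c$d1)) dsum1 else dsum1 * c$d1
    gl$Wo <- t(c$O) %*% dattn
    gl$bo <- colSums(dattn)
    dO <- dattn %*% t(lp$Wo)

    dQ <- matrix(0, nrow(dx), H); dK <- dQ; dV <- dQ
    for (s in seq_len(B)) {
      rs <- rows_of(s)
      for (h in seq_len(nh)) {
        ch <- ((h - 1L) * dk + 1L):(h * dk)
        A <- c$A[[s]][[h]]
        dOh <- dO[rs, ch, drop = FALSE]
        Vh <- c$V[rs, ch, drop = FALSE]
        dA <- dOh %*% t(Vh)
        dV[rs, ch] <- t(A) %*% dOh
        dS <- A * (dA - rowSums(dA * A))
        dQ[rs, ch] <- (dS %*% c$K[rs, ch, drop = FALSE]) / sqrt(dk)
        dK[rs, ch] <- (t(dS) %*% c$Q[rs, ch, drop = FALSE]) / sqrt(dk)
      }
    }
    X_in <- c$X_in
    gl$Wq <- t(X_in) %*% dQ; gl$bq <- colSums(dQ)
    gl$Wk <- t(X_in) %*% dK; gl$bk <- colSums(dK)
    gl$Wv <- t(X_in) %*% dV; gl$bv <- colSums(dV)
    dx <- dsum1 + dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
    g$layers[[l]] <- gl
  }

  if (!is.null(fwd$cache$d0)) dx <- dx * fwd$cache$d0
  lneb <- ln_backward(dx, fwd$cache$ln_e, p$ln_e$g)
  g$ln_e$g <- lneb$dg; g$ln_e$b <- lneb$db
  dx0 <- lneb$dx

  agg <- rowsum(dx0, fwd$ids_flat)
  ridx <- as.integer(rownames(agg))
  g$We[ridx, ] <- g$We[ridx, , drop = FALSE] + agg
  agg_p <- rowsum(dx0, fwd$pos_flat)
  pidx <- as.integer(rownames(agg_p))
  g$Pe[pidx, ] <- g$Pe[pidx, , drop = FALSE] + agg_p
  g
}

# Forward + backward for one masked micro-batch. Returns the summed
# cross-entropy over corrupted positions, their count, and the gradient of
# that *sum* (so accumulated micro-batches divide by the pooled count,
# reproducing the large-batch mean gradient exactly).
mlm_grad <- function(enc, corrupted_ids, labels, training = TRUE) {
  fwd <- encoder_forward(enc, corrupted_ids, training = training,
                         need_cache = TRUE)
  lab_flat <- unlist(labels)
  corr <- which(lab_flat >= 0L)
  if (length(corr) == 0L) {
    return(list(loss_sum = 0, n = 0L, grads = param_zero(enc$params)))
  }
  hf <- mlm_head_forward(enc, fwd$hidden[corr, , drop = FALSE])
  lab <- lab_flat[corr]
  lse <- apply(hf$logits, 1, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
  picked <- hf$logits[cbind(seq_along(lab), lab + 1L)]
  loss_sum <- sum(lse - picked)

  P <- exp(hf$logits - lse)
  P[cbind(seq_along(lab), lab + 1L)] <- P[cbind(seq_along(lab), lab + 1L)] - 1
  dlogits <- P

  hp <- enc$params$head
  g_head <- list(W = NULL, b = NULL, ln = NULL, bias = colSums(dlogits))
  dWe_head <- t(dlogits) %*% hf$ln$y
  dy <- dlogits %*% enc$params$We
  lnb <- ln_backward(dy, hf$ln, hp$ln$g)
  g_head$ln <- list(g = lnb$dg, b = lnb$db)
  dz <- lnb$dx * gelu_grad(hf$z)
  g_head$W <- t(hf$h_in) %*% dz
  g_head$b <- colSums(dz)
  dh_rows <- dz %*% t(hp$W)

  d_hidden <- matrix(0, nrow(fwd$hidden), ncol(fwd$hidden))
  d_hidden[corr, ] <- dh_rows
  grads <- encoder_backward(enc, fwd, d_hidden)
  grads$We <- grads$We + dWe_head
  grads$head <- g_head
  list(loss_sum = loss_sum, n = length(corr), grads = grads)
}

adam_init <- function(params) {
  list(m = param_zero(params), v = param_zero(params), t = 0L)
}

# Decoupled-weight-decay Adam; decay applies to weight matrices only
# (embeddings, projections), never to biases or layer-norm vectors.
adamw_update <- function(params, grads, state, lr, betas = c(0.9, 0.98),
                         eps = 1e-6, weight_decay = 0.01) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  step_tensor <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    if (is.matrix(p) && weight_decay > 0) upd <- upd + weight_decay * p
    list(p = p - lr * upd, m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (is.numeric(p)) return(step_tensor(p, g, m, v))
    out <- mapply(rec, p, g, m, v, SIMPLIFY = FALSE)
    list(p = lapply(out, `[[`, "p"),
         m = lapply(out, `[[`, "m"),
         v = lapply(out, `[[`, "v"))
  }
  res <- rec(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}
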