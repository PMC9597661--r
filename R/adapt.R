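# Fine-tuning: single feed-forward head on mean-pooled embeddings, Siamese
# classification and Siamese latent (cosine) training, classical heads on
# frozen fingerprints, and scaffold splitting.

#' Fine-tuning configuration
#'
#' @param dropout Dropout on the pooled embedding fed to the head
#'   (default 0.2).
#' @param epochs Training epochs (default 10).
#' @param split Train/valid/test fractions summing to 1 (default 80/10/10).
#' @param loss `"bce"` (classification, sigmoid head) or `"mse"`
#'   (regression, linear head).
#' @param lr Constant AdamW learning rate (default 1e-3).
#' @param batch_size Sequences per gradient step (default 8).
#' @param seed Integer seed (splitting, dropout, pairing augmentation).
#' @param split_strategy `"random"` or `"scaffold"` (Murcko-scaffold
#'   grouping with greedy packing).
#' @param freeze_encoder Train the head only, leaving the encoder fixed.
#' @export
finetune_config <- function(dropout = 0.2, epochs = 10L,
                            split = c(0.8, 0.1, 0.1),
                            loss = c("bce", "mse"), lr = 1e-3,
                            batch_size = 8L, seed = 1L,
                            split_strategy = c("random", "scaffold"),
                            freeze_encoder = FALSE) {
  loss <- match.arg(loss)
  split_strategy <- match.arg(split_strategy)
  stopifnot(dropout >= 0, dropout < 1, abs(sum(split) - 1) < 1e-8,
            all(split >= 0), epochs >= 0, lr >= 0)
  structure(list(dropout = dropout, epochs = as.integer(epochs),
                 split = split, loss = loss, lr = lr,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), split_strategy = split_strategy,
                 freeze_encoder = isTRUE(freeze_encoder)),
            class = "finetune_config")
}

#' Scaffold split
#'
#' Groups molecules by Murcko scaffold and packs whole groups (largest
#' first) into train/valid/test so each partition approaches the requested
#' fraction; train and test then contain disjoint chemotypes.
#'
#' @param smiles Character vector.
#' @param split Length-3 fractions summing to 1.
#' @param seed Seed breaking ties among equal-size groups.
#' @return List of integer index vectors `train`, `valid`, `test`.
#' @export
scaffold_split <- function(smiles, split = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(abs(sum(split) - 1) < 1e-8)
  scaf <- chem_murcko_scaffold(smiles)
  scaf[is.na(scaf)] <- ""
  groups <- split(seq_along(smiles), scaf)
  set.seed(seed)
  groups <- groups[order(-lengths(groups), stats::runif(length(groups)))]
  target <- split * length(smiles)
  sizes <- c(0, 0, 0)
  out <- list(train = integer(0), valid = integer(0), test = integer(0))
  for (g in groups) {
    k <- which.max(target - sizes)
    out[[k]] <- c(out[[k]], g)
    sizes[k] <- sizes[k] + length(g)
  }
  out
}

random_split <- function(n, split, seed) {
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- round(split[1] * n)
  n_valid <- round(split[2] * n)
  list(train = idx[seq_len(n_train)],
       valid = idx[seq_len(n_valid) + n_train],
       test = idx[seq.int(n_train + n_valid + 1L, n)])
}

# pooled-mean forward for a batch: returns pooled matrix (B x H), the
# forward cache, and row offsets for the backward distribution
pooled_forward <- function(enc, ids_list, need_cache) {
  fwd <- encoder_forward(enc, ids_list, training = FALSE,
                         need_cache = need_cache)
  B <- length(ids_list)
  pooled <- matrix(0, B, enc$config$hidden)
  for (s in seq_len(B)) {
    rs <- (fwd$offs[s] + 1L):fwd$offs[s + 1L]
    pooled[s, ] <- colMeans(fwd$hidden[rs, , drop = FALSE])
  }
  list(pooled = pooled, fwd = fwd)
}

pooled_backward_dhidden <- function(fwd, dpooled) {
  d_hidden <- matrix(0, nrow(fwd$hidden), ncol(dpooled))
  for (s in seq_along(fwd$lens)) {
    rs <- (fwd$offs[s] + 1L):fwd$offs[s + 1L]
    d_hidden[rs, ] <- matrix(dpooled[s, ] / fwd$lens[s], length(rs),
                             ncol(dpooled), byrow = TRUE)
  }
  d_hidden
}

head_forward <- function(feat, head, task) {
  z <- sweep(feat %*% head$W, 2, head$b, "+")
  if (task == "bce") list(z = z, p = 1 / (1 + exp(-z))) else list(z = z, p = z)
}

eval_metric <- function(p, y, task) {
  if (task == "bce") {
    mean((p > 0.5) == (y > 0.5))  # accuracy
  } else {
    sqrt(mean((p - y)^2))  # rmse
  }
}

#' Fine-tune the encoder with a single feed-forward head
#'
#' The head consumes the dropout-regularized mean of the token embeddings:
#' a single linear layer to `l` outputs (one per label column), sigmoid +
#' binary cross-entropy for classification or identity + MSE for
#' regression. By default gradients flow into the full encoder;
#' `freeze_encoder` trains the head alone.
#'
#' @param model A `smilesbert_model`.
#' @param dataset Data.frame with a `smiles` column and one or more label
#'   columns.
#' @param cfg A [finetune_config()].
#' @param verbose Print a line per epoch.
#' @return Object of class `smilesbert_finetuned`: updated model, head,
#'   per-epoch metric trace and the split indices.
#' @export
finetune_single <- function(model, dataset, cfg = finetune_config(),
                            verbose = FALSE) {
  stopifnot("smiles" %in% names(dataset))
  task <- cfg$loss
  Y <- as.matrix(dataset[setdiff(names(dataset), "smiles")])
  storage.mode(Y) <- "double"
  l <- ncol(Y)
  idx <- if (cfg$split_strategy == "scaffold") {
    scaffold_split(dataset$smiles, cfg$split, cfg$seed)
  } else {
    random_split(nrow(dataset), cfg$split, cfg$seed)
  }
  if (task == "bce" && length(unique(Y[idx$train, 1])) < 2L) {
    stop("single-class training set; cannot fit a classifier", call. = FALSE)
  }

  enc <- model$encoder
  H <- enc$config$hidden
  tokenizer <- model$tokenizer
  ids_all <- lapply(dataset$smiles, function(s) encode(tokenizer, s)$ids)

  set.seed(cfg$seed)
  head <- list(W = rnorm_mat(H, l), b = rep(0, l))
  params <- if (cfg$freeze_encoder) list(head = head) else
    list(encoder = enc$params, head = head)
  opt <- adam_init(params)

  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      valid_metric = numeric(0))
  valid_idx <- if (length(idx$valid)) idx$valid else idx$train

  for (ep in seq_len(cfg$epochs)) {
    perm <- sample(idx$train)
    ep_loss <- 0; ep_n <- 0L
    for (bs in split(perm, ceiling(seq_along(perm) / cfg$batch_size))) {
      pf <- pooled_forward(enc, ids_all[bs], need_cache = !cfg$freeze_encoder)
      drop_mask <- if (cfg$dropout > 0) {
        matrix(stats::rbinom(length(bs) * H, 1L, 1 - cfg$dropout),
               length(bs), H) / (1 - cfg$dropout)
      } else NULL
      feat <- if (is.null(drop_mask)) pf$pooled else pf$pooled * drop_mask
      hf <- head_forward(feat, head, task)
      yb <- Y[bs, , drop = FALSE]
      if (task == "bce") {
        p <- pmin(pmax(hf$p, 1e-12), 1 - 1e-12)
        loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
        dz <- (hf$p - yb) / length(yb)
      } else {
        loss <- mean((hf$z - yb)^2)
        dz <- 2 * (hf$z - yb) / length(yb)
      }
      ep_loss <- ep_loss + loss * length(bs); ep_n <- ep_n + length(bs)

      gW <- t(feat) %*% dz
      gb <- colSums(dz)
      grads <- list(head = list(W = gW, b = gb))
      if (!cfg$freeze_encoder) {
        dfeat <- dz %*% t(head$W)
        if (!is.null(drop_mask)) dfeat <- dfeat * drop_mask
        d_hidden <- pooled_backward_dhidden(pf$fwd, dfeat)
        grads <- list(encoder = encoder_backward(enc, pf$fwd, d_hidden),
                      head = grads$head)
      }
      upd <- adamw_update(params, grads, opt, cfg$lr)
      params <- upd$params; opt <- upd$state
      head <- params$head
      if (!cfg$freeze_encoder) enc$params <- params$encoder
    }
    pv <- pooled_forward(enc, ids_all[valid_idx], need_cache = FALSE)
    hv <- head_forward(pv$pooled, head, task)
    vm <- eval_metric(hv$p, Y[valid_idx, , drop = FALSE], task)
    trace <- rbind(trace, data.frame(epoch = ep, train_loss = ep_loss / max(ep_n, 1),
                                     valid_metric = vm))
    if (verbose) message(sprintf("epoch %d  loss %.4f  valid %.4f",
                                 ep, ep_loss / max(ep_n, 1), vm))
  }

  model$encoder <- enc
  structure(list(model = model, head = head, cfg = cfg, task = task,
                 trace = trace, split = idx, dataset = dataset),
            class = "smilesbert_finetuned")
}

#' @export
print.smilesbert_finetuned <- function(x, ...) {
  cat("Fine-tuned SMILES model (", x$task, " head, ",
      ncol(x$head$W), " label(s))\n", sep = "")
  if (nrow(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  %d epochs; final train loss %.4f, valid metric %.4f\n",
                nrow(x$trace), last$train_loss, last$valid_metric))
  }
  invisible(x)
}

#' @export
predict.smilesbert_finetuned <- function(object, smiles, ...) {
  fp <- fingerprint_batch(object$model, smiles)
  head_forward(fp, object$head, object$task)$p
}

#' Remove the head, exposing the specialized fingerprint model
#'
#' Returns the (fine-tuned) encoder + tokenizer bundle usable with
#' [fingerprint_batch()]. Idempotent: a bare model passes through.
#'
#' @param finetuned A `smilesbert_finetuned` (or already-stripped model).
#' @export
strip_head <- function(finetuned) {
  if (inherits(finetuned, "smilesbert_model")) return(finetuned)
  stopifnot(inherits(finetuned, c("smilesbert_finetuned", "siamese_finetuned")))
  finetuned$model
}

#' Siamese feature vector
#'
#' Concatenation `[fp1, fp2, |fp2 - fp1|]` of the two branch fingerprints
#' and their element-wise absolute difference.
#'
#' @param fp1,fp2 Equal-length numeric vectors.
#' @return Numeric vector of length `3 * length(fp1)`.
#' @export
siamese_features <- function(fp1, fp2) {
  if (length(fp1) != length(fp2)) stop("fingerprint length mismatch", call. = FALSE)
  c(fp1, fp2, abs(fp2 - fp1))
}

#' Siamese latent loss
#'
#' Squared deviation of the pair's cosine similarity from the target
#' similarity 1: `(cos(fp1, fp2) - 1)^2`.
#'
#' @param fp1,fp2 Nonzero fingerprints.
#' @export
siamese_latent_loss <- function(fp1, fp2) {
  (cosine_similarity(fp1, fp2) - 1)^2
}

# gradient of cos(a,b) wrt a: b/(|a||b|) - cos * a/|a|^2
dcos_da <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  cs <- sum(a * b) / (na * nb)
  b / (na * nb) - cs * a / (na * na)
}

# seeded augmented partner for every SMILES; falls back to the original
# string when randomization fails (sample then skipped from pairing stats)
augment_partners <- function(smiles, seed) {
  vapply(seq_along(smiles), function(i) {
    tryCatch(chem_random_smiles(smiles[i], 1L, seed + i),
             error = function(e) NA_character_)
  }, character(1))
}

#' Siamese classification fine-tuning
#'
#' Each sample is paired with a seeded random SMILES permutation of itself;
#' both strings pass through the *same* encoder (shared weights by
#' identity), and the head consumes [siamese_features()] of the two
#' mean-pooled fingerprints (input width `3 * hidden`). Sigmoid + BCE.
#' Samples whose SMILES cannot be parsed are skipped with a log entry.
#'
#' @inheritParams finetune_single
#' @return Object of class `siamese_finetuned`.
#' @export
siamese_classify <- function(model, dataset, cfg = finetune_config(),
                             verbose = FALSE) {
  stopifnot("smiles" %in% names(dataset), cfg$loss == "bce")
  partners <- augment_partners(dataset$smiles, cfg$seed)
  bad <- which(is.na(partners))
  if (length(bad)) {
    message(length(bad), " samples skipped (unparseable SMILES)")
    dataset <- dataset[-bad, , drop = FALSE]
    partners <- partners[-bad]
  }
  Y <- as.matrix(dataset[setdiff(names(dataset), "smiles")])
  storage.mode(Y) <- "double"
  l <- ncol(Y)
  idx <- random_split(nrow(dataset), cfg$split, cfg$seed)

  enc <- model$encoder; H <- enc$config$hidden
  tokenizer <- model$tokenizer
  ids1 <- lapply(dataset$smiles, function(s) encode(tokenizer, s)$ids)
  ids2 <- lapply(partners, function(s) encode(tokenizer, s)$ids)

  set.seed(cfg$seed)
  head <- list(W = rnorm_mat(3L * H, l), b = rep(0, l))
  params <- if (cfg$freeze_encoder) list(head = head) else
    list(encoder = enc$params, head = head)
  opt <- adam_init(params)
  trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      valid_metric = numeric(0))
  valid_idx <- if (length(idx$valid)) idx$valid else idx$train

  feat_of <- function(p1, p2) cbind(p1, p2, abs(p2 - p1))

  for (ep in seq_len(cfg$epochs)) {
    perm <- sample(idx$train)
    ep_loss <- 0; ep_n <- 0L
    for (bs in split(perm, ceiling(seq_along(perm) / cfg$batch_size))) {
      pf1 <- pooled_forward(enc, ids1[bs], need_cache = !cfg$freeze_encoder)
      pf2 <- pooled_forward(enc, ids2[bs], need_cache = !cfg$freeze_encoder)
      drop_mask <- if (cfg$dropout > 0) {
        matrix(stats::rbinom(length(bs) * 3L * H, 1L, 1 - cfg$dropout),
               length(bs), 3L * H) / (1 - cfg$dropout)
      } else NULL
      feat0 <- feat_of(pf1$pooled, pf2$pooled)
      feat <- if (is.null(drop_mask)) feat0 else feat0 * drop_mask
      hf <- head_forward(feat, head, "bce")
      yb <- Y[bs, , drop = FALSE]
      p <- pmin(pmax(hf$p, 1e-12), 1 - 1e-12)
      loss <- -mean(yb * log(p) + (1 - yb) * log(1 - p))
      dz <- (hf$p - yb) / length(yb)
      ep_loss <- ep_loss + loss * length(bs); ep_n <- ep_n + length(bs)

      grads <- list(head = list(W = t(feat) %*% dz, b = colSums(dz)))
      if (!cfg$freeze_encoder) {
        dfeat <- dz %*% t(head$W)
        if (!is.null(drop_mask)) dfeat <- dfeat * drop_mask
        sgn <- sign(pf2$pooled - pf1$pooled)
        dp1 <- dfeat[, 1:H, drop = FALSE] -
          dfeat[, (2 * H + 1):(3 * H), drop = FALSE] * sgn
        dp2 <- dfeat[, (H + 1):(2 * H), drop = FALSE] +
          dfeat[, (2 * H + 1):(3 * H), drop = FALSE] * sgn
        g1 <- encoder_backward(enc, pf1$fwd, pooled_backward_dhidden(pf1$fwd, dp1))
        g2 <- encoder_backward(enc, pf2$fwd, pooled_backward_dhidden(pf2$fwd, dp2))
        grads <- list(encoder = param_add(g1, g2), head = grads$head)
      }
      upd <- adamw_update(params, grads, opt, cfg$lr)
      params <- upd$params; opt <- upd$state
      head <- params$head
      if (!cfg$freeze_encoder) enc$params <- params$encoder
    }
    pv1 <- pooled_forward(enc, ids1[valid_idx], need_cache = FALSE)
    pv2 <- pooled_forward(enc, ids2[valid_idx], need_cache = FALSE)
    hv <- head_forward(feat_of(pv1$pooled, pv2$pooled), head, "bce")
    vm <- eval_metric(hv$p, Y[valid_idx, , drop = FALSE], "bce")
    trace <- rbind(trace, data.frame(epoch = ep,
                                     train_loss = ep_loss / max(ep_n, 1),
                                     valid_metric = vm))
    if (verbose) message(sprintf("epoch %d  loss %.4f  valid %.4f",
                                 ep, ep_loss / max(ep_n, 1), vm))
  }
  model$encoder <- enc
  structure(list(model = model, head = head, cfg = cfg, task = "bce",
                 trace = trace, split = idx, dataset = dataset,
                 partners = partners),
            class = c("siamese_finetuned", "smilesbert_finetuned"))
}

#' Siamese latent (augmented-representation) training
#'
#' Pulls each molecule's canonical and randomized SMILES together in cosine
#' space: the training loss per pair is `(cos(fp1, fp2) - 1)^2` through the
#' shared encoder. Reports the mean pair cosine on a held-out set before
#' and after training.
#'
#' @param model A `smilesbert_model`.
#' @param corpus Character vector of SMILES (unlabeled).
#' @param cfg A [finetune_config()] (`epochs`, `lr`, `batch_size`, `seed`
#'   are used; `epochs = 0` returns the model unchanged).
#' @param holdout_frac Fraction of molecules held out for the before/after
#'   measurement (default 0.2).
#' @return List of class `siamese_latent`: updated `model`, `cosine_before`,
#'   `cosine_after`, per-epoch loss trace.
#' @export
siamese_latent_train <- function(model, corpus, cfg = finetune_config(epochs = 3L),
                                 holdout_frac = 0.2, verbose = FALSE) {
  corpus <- corpus[nzchar(corpus)]
  partners <- augment_partners(corpus, cfg$seed)
  ok <- !is.na(partners)
  corpus <- corpus[ok]; partners <- partners[ok]
  n <- length(corpus)
  stopifnot(n >= 5)
  set.seed(cfg$seed)
  hold <- sample.int(n, max(2L, round(holdout_frac * n)))
  train <- setdiff(seq_len(n), hold)

  enc <- model$encoder
  tokenizer <- model$tokenizer
  ids1 <- lapply(corpus, function(s) encode(tokenizer, s)$ids)
  ids2 <- lapply(partners, function(s) encode(tokenizer, s)$ids)

  mean_pair_cosine <- function() {
    p1 <- pooled_forward(enc, ids1[hold], need_cache = FALSE)$pooled
    p2 <- pooled_forward(enc, ids2[hold], need_cache = FALSE)$pooled
    mean(vapply(seq_along(hold), function(i) {
      cosine_similarity(p1[i, ], p2[i, ])
    }, numeric(1)))
  }
  cos_before <- mean_pair_cosine()

  params <- list(encoder = enc$params)
  opt <- adam_init(params)
  trace <- data.frame(epoch = integer(0), loss = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample(train)
    ep_loss <- 0; ep_n <- 0L
    for (bs in split(perm, ceiling(seq_along(perm) / cfg$batch_size))) {
      pf1 <- pooled_forward(enc, ids1[bs], need_cache = TRUE)
      pf2 <- pooled_forward(enc, ids2[bs], need_cache = TRUE)
      B <- length(bs)
      dp1 <- matrix(0, B, ncol(pf1$pooled)); dp2 <- dp1
      loss <- 0
      for (i in seq_len(B)) {
        a <- pf1$pooled[i, ]; b <- pf2$pooled[i, ]
        cs <- cosine_similarity(a, b)
        loss <- loss + (cs - 1)^2
        dcs <- 2 * (cs - 1) / B
        dp1[i, ] <- dcs * dcos_da(a, b)
        dp2[i, ] <- dcs * dcos_da(b, a)
      }
      loss <- loss / B
      if (!is.finite(loss)) stop("latent training diverged", call. = FALSE)
      g1 <- encoder_backward(enc, pf1$fwd, pooled_backward_dhidden(pf1$fwd, dp1))
      g2 <- encoder_backward(enc, pf2$fwd, pooled_backward_dhidden(pf2$fwd, dp2))
      upd <- adamw_update(params, list(encoder = param_add(g1, g2)), opt, cfg$lr)
      params <- upd$params; opt <- upd$state
      enc$params <- params$encoder
      ep_loss <- ep_loss + loss * B; ep_n <- ep_n + B
    }
    trace <- rbind(trace, data.frame(epoch = ep, loss = ep_loss / max(ep_n, 1)))
    if (verbose) message(sprintf("epoch %d  latent loss %.5f", ep,
                                 ep_loss / max(ep_n, 1)))
  }
  model$encoder <- enc
  structure(list(model = model, cosine_before = cos_before,
                 cosine_after = mean_pair_cosine(), trace = trace),
            class = "siamese_latent")
}

#' Classical heads on frozen fingerprints
#'
#' Fits an off-the-shelf model — support vector machine (`e1071`), random
#' forest (`randomForest`) or a single-hidden-layer feed-forward network
#' (`nnet`) — on a train split of the fingerprint matrix and reports AUCROC
#' (classification) or RMSE (regression) on the test split.
#'
#' @param fingerprints n x d numeric matrix.
#' @param labels Numeric vector aligned with the rows (0/1 for
#'   classification).
#' @param head `"svm"`, `"rf"` or `"ffnn"`.
#' @param task `"classification"` or `"regression"`.
#' @param train_frac Fraction used for training (default 0.8).
#' @param seed Integer seed.
#' @return List with `metric` (named `aucroc` or `rmse`), `scores` and
#'   `test_idx`.
#' @export
classical_head_eval <- function(fingerprints, labels,
                                head = c("svm", "rf", "ffnn"),
                                task = c("classification", "regression"),
                                train_frac = 0.8, seed = 1L) {
  head <- match.arg(head); task <- match.arg(task)
  stopifnot(nrow(fingerprints) == length(labels))
  if (length(unique(labels)) < 2L) stop("degenerate labels", call. = FALSE)
  set.seed(seed)
  n <- length(labels)
  tr <- sample.int(n, round(train_frac * n))
  te <- setdiff(seq_len(n), tr)
  if (task == "classification" &&
      (length(unique(labels[tr])) < 2L || length(unique(labels[te])) < 2L)) {
    stop("a split ended up single-class; use a larger dataset", call. = FALSE)
  }
  Xtr <- fingerprints[tr, , drop = FALSE]; Xte <- fingerprints[te, , drop = FALSE]
  ytr <- labels[tr]; yte <- labels[te]

  scores <- switch(head,
    svm = {
      if (task == "classification") {
        yf <- factor(ytr)
        fit <- e1071::svm(Xtr, yf, kernel = "radial", decision.values = TRUE)
        dv <- attr(stats::predict(fit, Xte, decision.values = TRUE),
                   "decision.values")
        s <- as.numeric(dv)
        # positive decision value favors the class named first in the
        # column label; orient so that higher score = higher class level
        if (startsWith(colnames(dv)[1], paste0(levels(yf)[1], "/"))) s <- -s
        s
      } else {
        fit <- e1071::svm(Xtr, ytr, kernel = "radial")
        as.numeric(stats::predict(fit, Xte))
      }
    },
    rf = {
      if (task == "classification") {
        fit <- randomForest::randomForest(Xtr, factor(ytr))
        stats::predict(fit, Xte, type = "prob")[, 2]
      } else {
        fit <- randomForest::randomForest(Xtr, ytr)
        as.numeric(stats::predict(fit, Xte))
      }
    },
    ffnn = {
      fit <- nnet::nnet(Xtr, matrix(ytr), size = 16L, decay = 1e-3,
                        maxit = 200L, linout = (task == "regression"),
                        trace = FALSE)
      as.numeric(stats::predict(fit, Xte))
    })

  if (task == "classification") {
    list(metric = c(aucroc = auc_roc(scores, yte)), scores = scores,
         test_idx = te)
  } else {
    list(metric = c(rmse = sqrt(mean((scores - yte)^2))), scores = scores,
         test_idx = te)
  }
}
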