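# Masked-language-model pre-training: masking, loss, learning-rate
# schedule, batch-semantics contract, and the training loop.

#' MLM masking configuration
#'
#' Fifteen percent of content tokens are corrupted by default; of the
#' corrupted positions 80\% become `[MASK]`, 10\% a random content token and
#' 10\% keep their identity (the model still must predict them).
#'
#' @param mask_prob Probability a content token is selected for corruption.
#' @param split Length-3 vector (mask, random, keep) summing to 1.
#' @param seed Optional integer; when non-NULL, [mask_tokens()] seeds the
#'   RNG with it on entry (the training loop leaves it NULL and manages the
#'   RNG stream itself).
#' @export
mlm_config <- function(mask_prob = 0.15, split = c(0.8, 0.1, 0.1), seed = NULL) {
  stopifnot(mask_prob >= 0, mask_prob <= 1, length(split) == 3,
            abs(sum(split) - 1) < 1e-8, all(split >= 0))
  structure(list(mask_prob = mask_prob, split = split, seed = seed),
            class = "mlm_config")
}

#' Corrupt a batch of token sequences for MLM training
#'
#' Selects content positions (never `[CLS]`, `[SEP]` or `[PAD]`) with
#' probability `mask_prob` and corrupts them per the 80/10/10 split. Labels
#' hold the original id at corrupted positions and -1 elsewhere.
#'
#' @param ids_list List of 0-based id vectors (from [encode()]).
#' @param cfg An [mlm_config()].
#' @param vocab_size Vocabulary size (random replacements are drawn
#'   uniformly from the content ids `5 .. vocab_size - 1`).
#' @return List with `corrupted` (list of id vectors) and `labels` (list of
#'   integer vectors, -1 = ignore).
#' @export
mask_tokens <- function(ids_list, cfg, vocab_size) {
  stopifnot(inherits(cfg, "mlm_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_content_ids <- vocab_size - 5L
  corrupted <- vector("list", length(ids_list))
  labels <- vector("list", length(ids_list))
  for (i in seq_along(ids_list)) {
    ids <- ids_list[[i]]
    lab <- rep(-1L, length(ids))
    content <- which(!(ids %in% c(PAD_ID, CLS_ID, SEP_ID)))
    if (length(content)) {
      pick <- content[stats::runif(length(content)) < cfg$mask_prob]
      if (length(pick)) {
        lab[pick] <- ids[pick]
        u <- stats::runif(length(pick))
        to_mask <- pick[u < cfg$split[1]]
        to_rand <- pick[u >= cfg$split[1] & u < cfg$split[1] + cfg$split[2]]
        ids[to_mask] <- MASK_ID
        if (length(to_rand)) {
          ids[to_rand] <- 4L + sample.int(n_content_ids, length(to_rand),
                                          replace = TRUE)
        }
      }
    }
    corrupted[[i]] <- ids
    labels[[i]] <- lab
  }
  list(corrupted = corrupted, labels = labels)
}

#' Masked-language-model cross-entropy loss
#'
#' Mean cross-entropy over the corrupted positions only. With no corrupted
#' position the loss is defined as 0 and flagged (`attr(, "no_positions")`).
#'
#' @param logits n x vocab matrix of unnormalized scores (one row per
#'   position considered).
#' @param labels Integer vector of 0-based target ids, -1 = ignore.
#' @return Scalar loss; attribute `n_positions` carries the count.
#' @export
mlm_loss <- function(logits, labels) {
  stopifnot(nrow(logits) == length(labels))
  keep <- which(labels >= 0L)
  if (length(keep) == 0L) {
    warning("no corrupted positions; loss defined as 0", call. = FALSE)
    return(structure(0, n_positions = 0L, no_positions = TRUE))
  }
  lg <- logits[keep, , drop = FALSE]
  lab <- labels[keep]
  lse <- apply(lg, 1, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
  picked <- lg[cbind(seq_along(lab), lab + 1L)]
  structure(mean(lse - picked), n_positions = length(keep))
}

#' Learning-rate schedule
#'
#' Linear warmup from 0 to `peak_lr` over `warmup_steps`, then polynomial
#' decay `peak * (1 - (step - warmup)/(total - warmup))^power` down to
#' `end_lr`. Continuous at the warmup boundary, non-decreasing before it
#' and non-increasing after.
#'
#' @param peak_lr Peak learning rate (default 6e-4).
#' @param warmup_steps,total_steps Warmup and total optimizer steps.
#' @param power Decay exponent (1 = linear decay).
#' @param end_lr Final learning rate.
#' @export
lr_schedule <- function(peak_lr = 6e-4, warmup_steps, total_steps,
                        power = 1, end_lr = 0) {
  stopifnot(warmup_steps >= 0, warmup_steps <= total_steps, power > 0,
            end_lr >= 0, end_lr <= peak_lr)
  structure(list(peak_lr = peak_lr, warmup_steps = warmup_steps,
                 total_steps = total_steps, power = power, end_lr = end_lr),
            class = "lr_schedule")
}

#' @rdname lr_schedule
#' @param s An `lr_schedule`.
#' @param step Optimizer step in `[0, total_steps]` (vectorized).
#' @export
lr_at_step <- function(s, step) {
  stopifnot(inherits(s, "lr_schedule"))
  if (any(step < 0 | step > s$total_steps)) {
    stop("step out of range [0, ", s$total_steps, "]", call. = FALSE)
  }
  vapply(step, function(st) {
    if (st < s$warmup_steps) {
      s$peak_lr * st / s$warmup_steps
    } else if (s$total_steps == s$warmup_steps) {
      s$peak_lr
    } else {
      frac <- (st - s$warmup_steps) / (s$total_steps - s$warmup_steps)
      s$end_lr + (s$peak_lr - s$end_lr) * (1 - frac)^s$power
    }
  }, numeric(1))
}

#' Batch plan
#'
#' Single-process gradient accumulation reproducing the batch semantics of
#' synchronous data-parallel training: the effective batch is
#' `per_device * accum_steps * world_size`. Only the product matters here;
#' `world_size` survives as a bookkeeping factor.
#'
#' @param per_device Sequences per micro-batch (default 8).
#' @param accum_steps Micro-batches accumulated per optimizer step
#'   (default 32).
#' @param world_size Notional number of data-parallel workers (default 1).
#' @export
batch_plan <- function(per_device = 8L, accum_steps = 32L, world_size = 1L) {
  stopifnot(per_device >= 1, accum_steps >= 1, world_size >= 1)
  structure(list(per_device = as.integer(per_device),
                 accum_steps = as.integer(accum_steps),
                 world_size = as.integer(world_size)),
            class = "batch_plan")
}

#' @rdname batch_plan
#' @param plan A `batch_plan`.
#' @export
effective_batch_size <- function(plan) {
  stopifnot(inherits(plan, "batch_plan"))
  plan$per_device * plan$accum_steps * plan$world_size
}

#' Pre-train an encoder with masked language modeling
#'
#' Tokenizes the corpus, then optimizes the encoder with AdamW under the
#' given schedule, corrupting 15\% of content tokens per batch by default.
#' Micro-batch gradients are accumulated and normalized by the pooled count
#' of corrupted positions, so an accumulated step equals the mathematical
#' large-batch step. Training aborts on a non-finite loss, restoring the
#' last good parameters.
#'
#' @param corpus Character vector of SMILES (or a corpus file path).
#' @param tokenizer A trained [train_unigram()] model.
#' @param config An [encoder_config()]; its `vocab_size` must match the
#'   tokenizer. Default: [desk_preset()] at the tokenizer's vocabulary.
#' @param mlm An [mlm_config()].
#' @param schedule An [lr_schedule()]; by default peak 6e-4 with warmup
#'   over 6\% of total steps, linear decay to 0.
#' @param plan A [batch_plan()]; desk default accumulates 4 micro-batches
#'   of 8.
#' @param epochs Number of passes over the corpus (default 1).
#' @param seed Integer seed for initialization, shuffling and masking.
#' @param verbose Print a progress line per optimizer step.
#' @return An object of class `smilesbert_model` bundling the trained
#'   encoder, the tokenizer and the per-step loss trace.
#' @export
pretrain <- function(corpus, tokenizer, config = NULL, mlm = mlm_config(),
                     schedule = NULL, plan = batch_plan(8L, 4L), epochs = 1L,
                     seed = 1L, verbose = FALSE) {
  if (length(corpus) == 1L && file.exists(corpus)) corpus <- read_smi(corpus)
  corpus <- corpus[nzchar(corpus)]
  stopifnot(length(corpus) > 0, inherits(tokenizer, "unigram_tokenizer"))
  if (is.null(config)) config <- desk_preset(vocab_size = tokenizer$vocab_size)
  stopifnot(config$vocab_size == tokenizer$vocab_size)

  ids_all <- lapply(corpus, function(s) encode(tokenizer, s)$ids)

  n <- length(ids_all)
  micro_per_epoch <- ceiling(n / plan$per_device)
  steps_per_epoch <- max(1L, ceiling(micro_per_epoch / plan$accum_steps))
  total_steps <- steps_per_epoch * epochs
  if (is.null(schedule)) {
    schedule <- lr_schedule(warmup_steps = max(1L, ceiling(0.06 * total_steps)),
                            total_steps = total_steps)
  }

  set.seed(seed)
  enc <- build_encoder(config)
  opt <- adam_init(enc$params)
  trace <- data.frame(step = integer(0), lr = numeric(0), loss = numeric(0))
  last_good <- enc$params
  step <- 0L

  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    micro_starts <- seq.int(1L, n, by = plan$per_device)
    i <- 1L
    while (i <= length(micro_starts)) {
      take <- seq.int(i, min(i + plan$accum_steps - 1L, length(micro_starts)))
      acc <- NULL; loss_sum <- 0; n_corr <- 0L
      for (mi in take) {
        sel <- perm[micro_starts[mi]:min(micro_starts[mi] + plan$per_device - 1L, n)]
        masked <- mask_tokens(ids_all[sel], mlm, config$vocab_size)
        res <- mlm_grad(enc, masked$corrupted, masked$labels, training = TRUE)
        loss_sum <- loss_sum + res$loss_sum
        n_corr <- n_corr + res$n
        acc <- if (is.null(acc)) res$grads else param_add(acc, res$grads)
      }
      i <- i + length(take)
      if (n_corr == 0L) next
      step <- step + 1L
      grads <- param_scale(acc, 1 / n_corr)
      loss <- loss_sum / n_corr
      if (!is.finite(loss)) {
        warning("non-finite loss at step ", step,
                "; aborting and restoring last good parameters", call. = FALSE)
        enc$params <- last_good
        break
      }
      lr <- lr_at_step(schedule, min(step, schedule$total_steps))
      upd <- adamw_update(enc$params, grads, opt, lr)
      enc$params <- upd$params
      opt <- upd$state
      last_good <- enc$params
      trace <- rbind(trace, data.frame(step = step, lr = lr, loss = loss))
      if (verbose) {
        message(sprintf("step %d  lr %.2e  loss %.4f", step, lr, loss))
      }
    }
  }

  structure(list(encoder = enc, tokenizer = tokenizer, trace = trace,
                 schedule = schedule, plan = plan, mlm = mlm, seed = seed,
                 model_id = sprintf("pretrain-seed%d-steps%d", seed, step)),
            class = "smilesbert_model")
}

#' @export
print.smilesbert_model <- function(x, ...) {
  cat("Pre-trained SMILES masked-language model\n")
  print(x$encoder)
  if (nrow(x$trace)) {
    cat(sprintf("  %d optimizer steps; MLM loss %.4f -> %.4f\n",
                nrow(x$trace), x$trace$loss[1], x$trace$loss[nrow(x$trace)]))
  }
  invisible(x)
}

#' @export
summary.smilesbert_model <- function(object, ...) {
  cat("Model:", object$model_id, "\n")
  print(object)
  cat("Effective batch size:", effective_batch_size(object$plan), "\n")
  cat("Mask probability:", object$mlm$mask_prob, "\n")
  invisible(object)
}

#' @export
plot.smilesbert_model <- function(x, ...) {
  plot(x$trace$step, x$trace$loss, type = "l", xlab = "optimizer step",
       ylab = "MLM loss", main = "Pre-training loss trace", ...)
  invisible(x)
}

#' Save / load a trained model
#'
#' Writes a checkpoint directory containing `config.json`, the weights
#' (`weights.rds`), the tokenizer (`tokenizer.json`) and the loss trace
#' (`trace.csv`).
#'
#' @param model A `smilesbert_model`.
#' @param dir Checkpoint directory.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(model$encoder$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  saveRDS(model$encoder$params, file.path(dir, "weights.rds"))
  save_tokenizer(model$tokenizer, file.path(dir, "tokenizer.json"))
  utils::write.csv(model$trace, file.path(dir, "trace.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"))
  config <- encoder_config(cfg$n_layers, cfg$n_heads, cfg$hidden,
                           cfg$intermediate, cfg$max_positions,
                           cfg$vocab_size, cfg$dropout)
  enc <- structure(list(config = config,
                        params = readRDS(file.path(dir, "weights.rds"))),
                   class = "smiles_encoder")
  trace_path <- file.path(dir, "trace.csv")
  structure(list(encoder = enc,
                 tokenizer = load_tokenizer(file.path(dir, "tokenizer.json")),
                 trace = if (file.exists(trace_path)) utils::read.csv(trace_path)
                         else data.frame(),
                 model_id = basename(dir)),
            class = "smilesbert_model")
}
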