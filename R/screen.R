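# Virtual-screening retrieval harness and clustering-based fingerprint
# quality evaluation.

#' Screening target
#'
#' One retrieval experiment: a pool of active molecules sharing the target
#' and many decoys. Queries are drawn from the actives at benchmark time.
#' Actives and decoys must be disjoint by canonical form.
#'
#' @param name Target label.
#' @param actives,decoys Character vectors of SMILES.
#' @param n_queries Queries sampled per repetition (default 5); must be
#'   smaller than the number of actives.
#' @param check_disjoint Canonicalize both pools and verify disjointness
#'   (default TRUE; requires the chemistry backend).
#' @export
screening_target <- function(name, actives, decoys, n_queries = 5L,
                             check_disjoint = TRUE) {
  stopifnot(n_queries >= 1, n_queries < length(actives), length(decoys) > 0)
  if (check_disjoint) {
    ca <- sanitize_and_canonicalize(actives)
    cd <- sanitize_and_canonicalize(decoys)
    stopifnot(all(ca$ok), all(cd$ok))
    overlap <- intersect(ca$canonical, cd$canonical)
    if (length(overlap)) {
      stop("actives and decoys overlap by canonical form: ",
           paste(utils::head(overlap, 3), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(name = name, actives = actives, decoys = decoys,
                 n_queries = as.integer(n_queries)),
            class = "screening_target")
}

#' Rank a library against query fingerprints
#'
#' Scores each library compound by its fused cosine similarity to the
#' queries — by default the maximum over queries, the usual convention for
#' multi-query retrieval; `fusion = "mean"` averages instead — and sorts
#' descending. Ties are broken deterministically by input index.
#'
#' @param query_fps q x d matrix of query fingerprints.
#' @param library_fps n x d matrix of library fingerprints (queries must
#'   not be in the library).
#' @param fusion `"max"` or `"mean"`.
#' @return Data.frame with columns `index` (into the library) and `score`,
#'   in rank order.
#' @export
rank_library <- function(query_fps, library_fps, fusion = c("max", "mean")) {
  fusion <- match.arg(fusion)
  if (is.null(dim(query_fps))) query_fps <- matrix(query_fps, nrow = 1)
  if (is.null(dim(library_fps)) || nrow(library_fps) == 0L) {
    stop("empty library", call. = FALSE)
  }
  qn <- query_fps / sqrt(rowSums(query_fps^2))
  ln <- library_fps / sqrt(rowSums(library_fps^2))
  sims <- ln %*% t(qn)  # n x q cosine similarities
  score <- if (fusion == "max") apply(sims, 1, max) else rowMeans(sims)
  ord <- order(-score, seq_along(score), method = "radix")
  data.frame(index = ord, score = score[ord])
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen active outranks a randomly chosen
#' decoy, with ties counting one half — the normalized Mann-Whitney U
#' statistic computed from midranks.
#'
#' @param scores Numeric scores (higher = better).
#' @param labels Binary labels (1 = active).
#' @return AUCROC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Boltzmann-enhanced discrimination of ROC
#'
#' Early-recognition retrieval metric: the exponentially weighted sum over
#' the active ranks, min-max normalized to `[0, 1]`. With N compounds, n of
#' them active at ranks r_i (1 = best),
#' \deqn{S = \sum_i e^{-\alpha r_i / N}} and
#' \deqn{BEDROC = (S - S_{min}) / (S_{max} - S_{min})}
#' where S_max and S_min place the actives at the very top and very bottom.
#' Alpha sets the weighting sharpness (20 emphasizes roughly the top 8\%).
#' Ranks are assigned by descending score with ties broken by input order.
#'
#' @param scores Numeric scores (higher = better).
#' @param labels Binary labels (1 = active).
#' @param alpha Weighting sharpness, > 0 (default 20).
#' @return BEDROC in `[0, 1]`; 1 iff all actives are ranked first.
#' @export
bedroc <- function(scores, labels, alpha = 20) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)),
            alpha > 0)
  N <- length(scores)
  n <- sum(labels == 1L)
  if (n == 0L || n == N) stop("both classes must be present", call. = FALSE)
  ord <- order(-scores, seq_along(scores), method = "radix")
  ranks <- which(labels[ord] == 1L)
  S <- sum(exp(-alpha * ranks / N))
  Smax <- sum(exp(-alpha * seq_len(n) / N))
  Smin <- sum(exp(-alpha * seq.int(N - n + 1L, N) / N))
  (S - Smin) / (Smax - Smin)
}

#' Run the virtual-screening benchmark
#'
#' For each target and repetition: sample `n_queries` actives (seeded),
#' rank the remaining actives plus all decoys by fused cosine similarity,
#' and score the ranking with AUCROC and BEDROC. Fingerprints are computed
#' once per target.
#'
#' @param model A `smilesbert_model`.
#' @param targets A `screening_target` or list of them.
#' @param repetitions Query resamplings per target (default 50).
#' @param seed Integer seed.
#' @param pooling Fingerprint pooling mode.
#' @param fusion Query-score fusion, `"max"` (default) or `"mean"`.
#' @param alpha BEDROC alpha (default 20).
#' @param fp_fun Fingerprinting function `(model, smiles, pooling)`;
#'   defaults to [fingerprint_batch()]. Override to benchmark alternative
#'   representations (e.g. a null model) with the same harness.
#' @return List of class `screen_metrics`: per-target data.frame of
#'   repetition metrics, per-target mean/sd, and the across-target
#'   aggregate.
#' @export
run_benchmark <- function(model, targets, repetitions = 50L, seed = 1L,
                          pooling = "mean", fusion = "max", alpha = 20,
                          fp_fun = fingerprint_batch) {
  if (inherits(targets, "screening_target")) targets <- list(targets)
  set.seed(seed)
  per_target <- list()
  for (tg in targets) {
    if (length(tg$actives) < tg$n_queries + 1L) {
      warning("target '", tg$name, "' has fewer than n_queries + 1 actives; skipped",
              call. = FALSE)
      next
    }
    fpa <- fp_fun(model, tg$actives, pooling = pooling)
    fpd <- fp_fun(model, tg$decoys, pooling = pooling)
    reps <- data.frame(repetition = seq_len(repetitions),
                       aucroc = NA_real_, bedroc = NA_real_)
    for (r in seq_len(repetitions)) {
      q <- sample.int(nrow(fpa), tg$n_queries)
      lib_fp <- rbind(fpa[-q, , drop = FALSE], fpd)
      lib_lab <- c(rep(1L, nrow(fpa) - tg$n_queries), rep(0L, nrow(fpd)))
      ranking <- rank_library(fpa[q, , drop = FALSE], lib_fp, fusion = fusion)
      scores <- ranking$score[order(ranking$index)]
      reps$aucroc[r] <- auc_roc(scores, lib_lab)
      reps$bedroc[r] <- bedroc(scores, lib_lab, alpha = alpha)
    }
    per_target[[tg$name]] <- reps
  }
  if (length(per_target) == 0L) stop("no usable targets", call. = FALSE)
  summarize <- function(df) {
    c(aucroc_mean = mean(df$aucroc), aucroc_sd = stats::sd(df$aucroc),
      bedroc_mean = mean(df$bedroc), bedroc_sd = stats::sd(df$bedroc))
  }
  per_summary <- t(vapply(per_target, summarize, numeric(4)))
  structure(list(per_repetition = per_target,
                 per_target = per_summary,
                 aggregate = colMeans(per_summary),
                 alpha = alpha, repetitions = repetitions),
            class = "screen_metrics")
}

#' @export
print.screen_metrics <- function(x, ...) {
  cat("Virtual-screening benchmark (", x$repetitions, " repetitions, alpha ",
      x$alpha, ")\n", sep = "")
  print(round(x$per_target, 4))
  agg <- x$aggregate
  cat(sprintf("aggregate: AUCROC %.3f +/- %.3f, BEDROC %.3f +/- %.3f\n",
              agg["aucroc_mean"], agg["aucroc_sd"],
              agg["bedroc_mean"], agg["bedroc_sd"]))
  invisible(x)
}

#' Clustering-based fingerprint quality
#'
#' Projects fingerprints to two principal components, clusters them with
#' K-means (k = number of classes), maps clusters to classes by the label
#' permutation maximizing agreement, and reports the AUCROC of the mapped
#' hard assignments together with the silhouette coefficient of the
#' clustering.
#'
#' @param fingerprints n x d numeric matrix.
#' @param labels Class labels (>= 2 samples per class).
#' @param seed Integer seed for K-means restarts.
#' @param silhouette_space `"pca"` (default: the 2-D projection) or
#'   `"full"` (the original fingerprint space).
#' @return List with `aucroc`, `silhouette`, `assignments` and `projection`.
#' @export
cluster_eval <- function(fingerprints, labels, seed = 1L,
                         silhouette_space = c("pca", "full")) {
  silhouette_space <- match.arg(silhouette_space)
  labels <- as.factor(labels)
  stopifnot(nrow(fingerprints) == length(labels), nlevels(labels) >= 2,
            all(table(labels) >= 2))
  if (all(apply(fingerprints, 2, stats::var) < 1e-12)) {
    stop("degenerate fingerprints: no variance to cluster", call. = FALSE)
  }
  pc <- stats::prcomp(fingerprints, rank. = 2L)
  proj <- pc$x[, 1:2, drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(proj, centers = nlevels(labels), nstart = 10L)

  k <- nlevels(labels)
  perms <- perms_of(k)
  best_map <- NULL; best_agree <- -1L
  lab_int <- as.integer(labels)
  for (p in perms) {
    agree <- sum(p[km$cluster] == lab_int)
    if (agree > best_agree) { best_agree <- agree; best_map <- p }
  }
  assigned <- best_map[km$cluster]
  pos <- nlevels(labels)  # last level treated as the positive class
  auc <- auc_roc(as.numeric(assigned == pos), as.integer(lab_int == pos))

  sil_x <- if (silhouette_space == "pca") proj else fingerprints
  sil <- cluster::silhouette(km$cluster, stats::dist(sil_x))
  list(aucroc = auc, silhouette = mean(sil[, "sil_width"]),
       assignments = assigned, projection = proj)
}

# all permutations of 1..k (k is the number of classes, tiny)
perms_of <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in perms_of(k - 1L)) {
      rest <- setdiff(seq_len(k), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
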