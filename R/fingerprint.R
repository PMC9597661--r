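# Fixed-length molecular fingerprints from token embeddings.

#' Mean-pool token embeddings into a fingerprint
#'
#' Arithmetic mean over the unmasked (non-padding) rows of an embedding
#' matrix. By default the auxiliary `[CLS]`/`[SEP]` rows are included,
#' since the fingerprint is the mean of *all* token embeddings; set
#' `content_only = TRUE` upstream masks to exclude them.
#'
#' @param embeddings L x hidden matrix of token embeddings.
#' @param mask Logical length-L vector, TRUE = include the row. Default all.
#' @return Numeric fingerprint of length `hidden`.
#' @export
pool_mean <- function(embeddings, mask = rep(TRUE, nrow(embeddings))) {
  stopifnot(is.matrix(embeddings), length(mask) == nrow(embeddings))
  if (!any(mask)) stop("all positions masked; mean undefined", call. = FALSE)
  colMeans(embeddings[mask, , drop = FALSE])
}

#' Extract the `[CLS]` embedding as the fingerprint
#'
#' Returns row 1 (the `[CLS]` position) of the embedding matrix.
#'
#' @param embeddings L x hidden matrix whose first row is the `[CLS]` token.
#' @export
pool_cls <- function(embeddings) {
  stopifnot(is.matrix(embeddings))
  if (nrow(embeddings) == 0L) stop("empty embedding matrix", call. = FALSE)
  embeddings[1L, ]
}

#' Cosine similarity between two fingerprints
#'
#' @param a,b Numeric vectors of equal length with nonzero norm.
#' @return `a.b / (|a||b|)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("zero-norm fingerprint", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Fingerprint a batch of molecules
#'
#' Encodes each SMILES, runs the encoder in eval mode and pools the final
#' hidden states. Invalid or unencodable inputs yield a row of `NA` and are
#' flagged in the `failed` attribute rather than silently dropped.
#'
#' @param model A `smilesbert_model` (or a list with `$encoder` and
#'   `$tokenizer`).
#' @param smiles Character vector of SMILES.
#' @param pooling `"mean"` or `"cls"`.
#' @param content_only For mean pooling, exclude the `[CLS]`/`[SEP]` rows.
#' @param validate Check each SMILES chemically before fingerprinting
#'   (default TRUE); invalid records yield `NA` rows.
#' @return n x hidden numeric matrix, rows in input order; attribute
#'   `failed` lists the indices of failed rows (if any).
#' @export
fingerprint_batch <- function(model, smiles, pooling = c("mean", "cls"),
                              content_only = FALSE, validate = TRUE) {
  pooling <- match.arg(pooling)
  enc <- model$encoder; tok <- model$tokenizer
  H <- enc$config$hidden
  out <- matrix(NA_real_, length(smiles), H)
  failed <- if (validate) which(!sanitize_and_canonicalize(smiles)$ok) else integer(0)
  ids_list <- vector("list", length(smiles))
  for (i in setdiff(seq_along(smiles), failed)) {
    ids_list[[i]] <- tryCatch(encode(tok, smiles[i])$ids, error = function(e) NULL)
    if (is.null(ids_list[[i]])) failed <- c(failed, i)
  }
  ok <- setdiff(seq_along(smiles), failed)
  if (length(ok)) {
    fwd <- encoder_forward(enc, ids_list[ok], training = FALSE)
    for (j in seq_along(ok)) {
      rs <- (fwd$offs[j] + 1L):fwd$offs[j + 1L]
      emb <- fwd$hidden[rs, , drop = FALSE]
      out[ok[j], ] <- if (pooling == "cls") {
        pool_cls(emb)
      } else if (content_only && nrow(emb) > 2L) {
        pool_mean(emb, mask = c(FALSE, rep(TRUE, nrow(emb) - 2L), FALSE))
      } else {
        pool_mean(emb)
      }
    }
  }
  if (length(failed)) {
    warning(length(failed), " SMILES could not be fingerprinted", call. = FALSE)
    attr(out, "failed") <- failed
  }
  out
}

#' @export
#' @rdname fingerprint_batch
#' @param object,... Method arguments (`predict` dispatches to
#'   `fingerprint_batch`).
predict.smilesbert_model <- function(object, smiles, pooling = "mean", ...) {
  fingerprint_batch(object, smiles, pooling = pooling, ...)
}

#' Write / read fingerprint matrices
#'
#' CSV matrix plus a JSON sidecar recording the model id, pooling mode and
#' SMILES order.
#'
#' @param fp Fingerprint matrix from [fingerprint_batch()].
#' @param smiles The SMILES the rows correspond to.
#' @param path Output CSV path (sidecar written as `<path>.meta.json`).
#' @param model_id,pooling Provenance recorded in the sidecar.
#' @export
write_fingerprints <- function(fp, smiles, path, model_id = "", pooling = "mean") {
  utils::write.table(fp, path, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(model_id = model_id, pooling = pooling,
                            smiles = smiles),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  fp <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(fp) <- NULL
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  attr(fp, "meta") <- meta
  fp
}
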