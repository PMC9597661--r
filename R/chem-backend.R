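#' @keywords internal
"_PACKAGE"

# RDKit bridge -----------------------------------------------------------
#
# All chemistry primitives (canonicalization, randomized traversal,
# substructure matching, Murcko scaffolds) are delegated to RDKit through a
# bundled Python helper, called in batch over stdin/stdout. Results are
# memoised per session so repeated queries (common in tests and corpus
# curation) cost one subprocess call.

.chem_cache <- new.env(parent = emptyenv())

chem_python <- function() {
  py <- Sys.getenv("SMILESBERT_PYTHON", unset = Sys.which("python"))
  if (!nzchar(py)) stop("No 'python' executable found on PATH", call. = FALSE)
  py
}

chem_script <- function() {
  p <- system.file("python", "chem_tool.py", package = "smilesbert")
  if (!nzchar(p)) {
    # during devtools::load_all() the package root is inst/'s parent
    p <- file.path("inst", "python", "chem_tool.py")
  }
  if (!file.exists(p)) stop("chem_tool.py helper not found", call. = FALSE)
  p
}

# Run one batch op: `requests` is a list of R lists, one JSON object per line.
chem_call <- function(op, requests) {
  if (length(requests) == 0L) return(list())
  lines <- vapply(requests, function(r) {
    jsonlite::toJSON(r, auto_unbox = TRUE)
  }, character(1))
  out <- suppressWarnings(system2(
    chem_python(), c(shQuote(chem_script()), op),
    input = lines, stdout = TRUE, stderr = FALSE
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("chemistry helper exited with status ", status, call. = FALSE)
  }
  if (length(out) != length(requests)) {
    stop("chemistry helper returned ", length(out), " replies for ",
         length(requests), " requests", call. = FALSE)
  }
  lapply(out, jsonlite::fromJSON, simplifyVector = FALSE)
}

# Memoised vectorized canonicalization. Returns a data.frame with columns
# smiles, ok, canonical (NA on rejection), reason (NA on success).
chem_canonicalize <- function(smiles) {
  key <- paste0("canon\x1f", smiles)
  miss <- !vapply(key, exists, logical(1), envir = .chem_cache)
  if (any(miss)) {
    todo <- unique(smiles[miss])
    replies <- chem_call("canon", lapply(todo, function(s) list(s = s)))
    for (i in seq_along(todo)) {
      assign(paste0("canon\x1f", todo[i]), replies[[i]], envir = .chem_cache)
    }
  }
  replies <- lapply(key, get, envir = .chem_cache)
  data.frame(
    smiles = smiles,
    ok = vapply(replies, function(r) isTRUE(r$ok), logical(1)),
    canonical = vapply(replies, function(r) {
      if (isTRUE(r$ok)) r$canonical else NA_character_
    }, character(1)),
    reason = vapply(replies, function(r) {
      if (isTRUE(r$ok)) NA_character_ else r$reason
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

chem_random_smiles <- function(smiles, n, seed) {
  reply <- chem_call("random", list(list(s = smiles, n = n, seed = seed)))[[1]]
  if (!isTRUE(reply$ok)) {
    stop("cannot randomize '", smiles, "': ", reply$reason, call. = FALSE)
  }
  unlist(reply$out)
}

# Substructure matches: named list of SMARTS -> list of integer vectors of
# 0-based atom indices (one vector per match).
chem_substruct_matches <- function(smiles, patterns) {
  reply <- chem_call("match", list(list(s = smiles, patterns = patterns)))[[1]]
  if (!isTRUE(reply$ok)) {
    stop("cannot match '", smiles, "': ", reply$reason, call. = FALSE)
  }
  lapply(reply$matches, function(m) lapply(m, function(v) unlist(v)))
}

chem_has_substructure <- function(smiles, query, smarts = FALSE) {
  key <- paste0("hassub\x1f", smarts, "\x1f", query, "\x1f", smiles)
  miss <- !vapply(key, exists, logical(1), envir = .chem_cache)
  if (any(miss)) {
    todo <- smiles[miss]
    replies <- chem_call("hassub", lapply(todo, function(s) {
      list(s = s, q = query, smarts = smarts)
    }))
    for (i in seq_along(todo)) assign(key[miss][i], replies[[i]], envir = .chem_cache)
  }
  vapply(lapply(key, get, envir = .chem_cache), function(r) {
    if (!isTRUE(r$ok)) NA else isTRUE(r$has)
  }, logical(1))
}

chem_murcko_scaffold <- function(smiles) {
  replies <- chem_call("scaffold", lapply(smiles, function(s) list(s = s)))
  vapply(replies, function(r) {
    if (isTRUE(r$ok)) r$scaffold else NA_character_
  }, character(1))
}
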