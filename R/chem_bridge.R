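# Subprocess bridge to the RDKit cheminformatics engine.
#
# All chemistry (SMILES parsing, MACCS keys, 2D descriptors) is delegated to
# RDKit, reached through the `python` interpreter on the PATH.  Calls are
# batched (one process per request, arbitrarily many molecules) and memoised
# per task+SMILES in a package-local cache, so repeated featurization of the
# same molecules costs one subprocess.

.chem_cache <- new.env(parent = emptyenv())

chem_bridge_script <- function() {
  path <- system.file("python", "chem_bridge.py", package = "mvsynergy")
  if (!nzchar(path)) {
    stop("chem_bridge.py not found; is the package installed correctly?")
  }
  path
}

#' Is the RDKit chemistry bridge available?
#'
#' The drug featurizers shell out to RDKit through the `python` interpreter.
#' This checks that `python` is on the PATH and can import rdkit.
#'
#' @return `TRUE` or `FALSE`.
#' @export
rdkit_available <- function() {
  if (!is.null(.chem_cache$rdkit_ok)) {
    return(.chem_cache$rdkit_ok)
  }
  ok <- nzchar(Sys.which("python")) &&
    suppressWarnings(system2("python", c("-c", shQuote("import rdkit")),
                             stdout = FALSE, stderr = FALSE)) == 0L
  .chem_cache$rdkit_ok <- ok
  ok
}

chem_call <- function(task, smiles) {
  stopifnot(is.character(smiles))
  if (!rdkit_available()) {
    stop("the RDKit chemistry bridge is unavailable: `python` with rdkit ",
         "must be on the PATH (see SystemRequirements)")
  }
  req <- tempfile(fileext = ".json")
  on.exit(unlink(req), add = TRUE)
  jsonlite::write_json(list(task = task, smiles = I(smiles)), req,
                       auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(system2(
    "python", shQuote(chem_bridge_script()),
    stdout = TRUE, stderr = FALSE, stdin = req
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("chemistry bridge failed (exit status ", status, ")")
  }
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

# Memoised batch call: returns a list parallel to `smiles`, each element the
# per-molecule result object from the bridge ({ok: ...}).
chem_batch <- function(task, smiles) {
  keys <- paste0(task, "\r", smiles)
  res <- vector("list", length(smiles))
  hit <- vapply(keys, function(k) !is.null(.chem_cache[[k]]), logical(1))
  for (i in which(hit)) res[[i]] <- .chem_cache[[keys[i]]]
  miss <- which(!hit)
  if (length(miss)) {
    uniq <- !duplicated(smiles[miss])
    ask <- smiles[miss][uniq]
    ans <- chem_call(task, ask)
    if (task == "descriptors") {
      names_vec <- vapply(ans$names, identity, character(1))
      results <- ans$results
      for (j in seq_along(ask)) results[[j]]$descriptor_names <- names_vec
    } else {
      results <- ans$results
    }
    names(results) <- ask
    for (i in miss) {
      r <- results[[smiles[i]]]
      .chem_cache[[keys[i]]] <- r
      res[[i]] <- r
    }
  }
  res
}

chem_stop_on_failure <- function(results, smiles, ids = NULL) {
  bad <- which(vapply(results, function(r) !isTRUE(r$ok), logical(1)))
  if (length(bad)) {
    who <- if (is.null(ids)) smiles[bad[1]] else ids[bad[1]]
    stop("chemistry engine failed for ", sQuote(who), ": ",
         results[[bad[1]]]$error, call. = FALSE)
  }
  invisible(results)
}
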