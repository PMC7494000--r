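# Chemistry backends.
#
# Two external engines stand behind the package, both long-lived:
#  * OpenBabel (in-process via ChemmineOB) for SMILES parsing, kekulisation
#    and the canonical aromatic SMILES used as molecular identity;
#  * RDKit (persistent python subprocess, inst/python/rdkit_service.py) for
#    the published property definitions: QED, Crippen logP, the
#    fragment-contribution synthetic-accessibility score, ring statistics.
# Everything above these primitives (graph model, actions, search, score
# assembly) is native R in this package.

.molevolve <- new.env(parent = emptyenv())

#' Low-level molecular property computation
#'
#' Computes standard published molecular descriptors for one molecule through
#' the persistent RDKit service. Accepts a [molgraph], a SMILES string, or an
#' MDL molblock string (identified by embedded newlines).
#'
#' @param x A `molgraph`, SMILES character scalar, or molblock string.
#' @param props Character vector of property names: any of `"canonical"`,
#'   `"qed"`, `"logp"`, `"sa"`, `"largest_ring"`, `"n_rings"`, `"formula"`.
#' @return Named list of property values.
#' @examples
#' \dontrun{
#' mol_properties("c1ccccc1", c("qed", "logp"))
#' }
#' @export
mol_properties <- function(x, props) {
  props <- as.list(props)   # keep a JSON array even for one property
  if (inherits(x, "molgraph")) {
    req <- list(molblock = mol_to_molblock(x), props = props)
  } else if (length(x) == 1L && is.character(x)) {
    if (grepl("\n", x, fixed = TRUE)) {
      req <- list(molblock = x, props = props)
    } else {
      req <- list(smiles = x, props = props)
    }
  } else {
    stop("`x` must be a molgraph, a SMILES string, or a molblock string")
  }
  # properties are pure in the molecule: memoise across calls and runs
  cache_key <- paste(c(unlist(props), req$molblock %||% req$smiles),
                     collapse = "\r")
  cache <- prop_cache()
  hit <- cache[[cache_key]]
  if (!is.null(hit)) return(hit)
  ans <- rdkit_request(req)
  if (!isTRUE(ans$ok)) {
    stop("property backend failed: ", ans$error %||% "unknown error")
  }
  ans$ok <- NULL
  if (length(cache) > 60000L) rm(list = ls(cache), envir = cache)
  cache[[cache_key]] <- ans
  ans
}

prop_cache <- function() {
  if (is.null(.molevolve$prop_cache)) {
    .molevolve$prop_cache <- new.env(parent = emptyenv())
  }
  .molevolve$prop_cache
}

# process-wide molblock -> canonical-SMILES memo (canonicalisation is pure;
# candidate molecules repeat heavily within and across runs)
shared_key_cache <- function() {
  if (is.null(.molevolve$key_cache)) {
    .molevolve$key_cache <- new.env(parent = emptyenv())
  }
  .molevolve$key_cache
}

#' Is the RDKit property service available?
#'
#' @return `TRUE` if the python RDKit worker can be started (or already runs).
#' @export
rdkit_available <- function() {
  ok <- tryCatch({
    rdkit_request(list(smiles = "C", props = list("logp")))$ok
  }, error = function(e) FALSE)
  isTRUE(ok)
}

rdkit_request <- function(req) {
  p <- rdkit_process()
  p$write_input(paste0(jsonlite::toJSON(req, auto_unbox = TRUE), "\n"))
  line <- character(0)
  deadline <- Sys.time() + 120
  while (length(line) == 0L) {
    p$poll_io(1000)
    line <- p$read_output_lines(1)
    if (length(line) == 0L && (!p$is_alive() || Sys.time() > deadline)) {
      err <- paste(p$read_error_lines(), collapse = "\n")
      rdkit_stop()
      stop("RDKit service died or timed out: ", err)
    }
  }
  jsonlite::fromJSON(line, simplifyVector = TRUE)
}

rdkit_process <- function() {
  p <- .molevolve$rdkit
  if (!is.null(p) && p$is_alive()) {
    return(p)
  }
  script <- system.file("python", "rdkit_service.py", package = "molevolve")
  if (script == "") {
    # during pkgload::load_all() the inst/ prefix is still present
    script <- system.file("inst", "python", "rdkit_service.py",
                          package = "molevolve")
  }
  python <- Sys.which("python")
  if (python == "") stop("no `python` interpreter on PATH")
  p <- processx::process$new(python, c("-u", script),
                             stdin = "|", stdout = "|", stderr = "|")
  # fail fast if rdkit is missing from the interpreter
  p$poll_io(200)
  if (!p$is_alive()) {
    stop("could not start RDKit service: ",
         paste(p$read_error_lines(), collapse = "\n"))
  }
  .molevolve$rdkit <- p
  p
}

rdkit_stop <- function() {
  p <- .molevolve$rdkit
  if (!is.null(p)) {
    try(p$kill(), silent = TRUE)
    .molevolve$rdkit <- NULL
  }
}

.onUnload <- function(libpath) {
  rdkit_stop()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ob_convert <- function(from, to, source) {
  out <- ChemmineOB::convertFormat(from, to, source)
  trimws(out)
}
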