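# Objective functions and combinators.
#
# An objective is a pure score of a molecular graph, wrapped with an
# evaluation counter and a cache keyed by canonical SMILES: scoring the same
# molecule twice is free and counts once. Rejection (by a hard constraint or
# a failed external evaluation) is distinguishable from a low score and does
# not consume an evaluation.

#' Wrap a scoring function as a counted, cached objective
#'
#' @param fn `function(graph, key)` returning a numeric score, or a list with
#'   elements `score` (numeric), optional `sub` (named numeric sub-scores)
#'   and optional `reject` (logical).
#' @param name Objective name used in logs and outputs.
#' @param predicate Optional hard constraint `function(graph)`; candidates
#'   failing it are rejected *before* scoring and never hit the evaluation
#'   counter.
#' @return An `objective_fn` object.
#' @examples
#' const <- objective_custom(function(g, key) 0.5, "constant")
#' @export
objective_custom <- function(fn, name = "custom", predicate = NULL) {
  structure(
    list(name = name, fn = fn, predicate = predicate,
         state = new.env(parent = emptyenv())),
    class = "objective_fn"
  ) -> obj
  objective_reset(obj)
  obj
}

#' Reset an objective's cache and counters
#' @param obj An `objective_fn`.
#' @return The objective, invisibly.
#' @export
objective_reset <- function(obj) {
  obj$state$cache <- new.env(parent = emptyenv())
  obj$state$count <- 0L   # unique molecules scored (cache misses)
  obj$state$calls <- 0L   # all evaluation requests, cache hits included
  invisible(obj)
}

#' Evaluate an objective on a molecule
#'
#' @param obj An `objective_fn`.
#' @param g A `molgraph`.
#' @param key The molecule's canonical key; computed when missing.
#' @return List with `score`, `sub`, `reject`, `cached`.
#' @export
evaluate_objective <- function(obj, g, key = canonical_key(g)) {
  obj$state$calls <- obj$state$calls + 1L
  hit <- obj$state$cache[[key]]
  if (!is.null(hit)) {
    hit$cached <- TRUE
    return(hit)
  }
  if (!is.null(obj$predicate) && !isTRUE(obj$predicate(g))) {
    res <- list(score = NA_real_, sub = NULL, reject = TRUE, cached = FALSE)
    obj$state$cache[[key]] <- res
    return(res)
  }
  raw <- obj$fn(g, key)
  if (!is.list(raw)) raw <- list(score = raw)
  res <- list(score = as.numeric(raw$score), sub = raw$sub,
              reject = isTRUE(raw$reject), cached = FALSE)
  if (!res$reject && !is.finite(res$score)) {
    stop("objective '", obj$name, "' returned a non-finite score for ", key)
  }
  if (!res$reject) obj$state$count <- obj$state$count + 1L
  obj$state$cache[[key]] <- res
  res
}

#' Evaluation counters of an objective
#'
#' @param obj An `objective_fn`.
#' @return Integer count of unique molecules scored; the attribute `"calls"`
#'   carries the total number of requests including cache hits.
#' @export
objective_evaluations <- function(obj) {
  structure(obj$state$count, calls = obj$state$calls)
}

obj_calls <- function(obj) obj$state$calls

#' @export
print.objective_fn <- function(x, ...) {
  cat("<objective_fn> ", x$name, " (", x$state$count, " evaluations)\n",
      sep = "")
  invisible(x)
}

# ---- standard drug-likeness / synthesizability scores -----------------------

#' Quantitative estimate of drug-likeness (QED)
#'
#' Standard QED in `[0, 1]` (1 best), delegated to the published definition
#' in the property backend.
#'
#' @return An `objective_fn`.
#' @export
objective_qed <- function() {
  objective_custom(function(g, key) {
    mol_properties(g, "qed")$qed
  }, name = "qed")
}

#' Synthetic-accessibility score
#'
#' Raw fragment-contribution SAscore lies in `[1, 10]` with 1 the most
#' accessible. The normalised variant maps it to `[0, 1]` with 1 best:
#' `(10 - raw) / 9`.
#'
#' @param normalised Return the normalised score (default) or the raw one.
#' @return An `objective_fn`.
#' @export
objective_sascore <- function(normalised = TRUE) {
  objective_custom(function(g, key) {
    raw <- mol_properties(g, "sa")$sa
    if (normalised) {
      list(score = sascore_normalise(raw), sub = c(sa_raw = raw))
    } else {
      raw
    }
  }, name = if (normalised) "sascore_normalised" else "sascore")
}

#' @rdname objective_sascore
#' @param raw Raw SAscore value(s).
#' @export
sascore_normalise <- function(raw) (10 - raw) / 9

#' z-score constants for normalised penalised logP
#'
#' Means and standard deviations of the three plogP components (Crippen
#' logP, SAscore, large-ring penalty) over the ZINC250k subset, as used by
#' the graph-generation literature this score comes from. All values are
#' configuration, not constants of nature: pass your own to
#' [objective_plogp()].
#'
#' @return Named list of means/standard deviations.
#' @export
plogp_normalisation <- function() {
  list(
    logp_mean = 2.4570953396190123, logp_sd = 1.434324401111988,
    sa_mean = 3.0525811293166134, sa_sd = 0.8335207024513095,
    ring_mean = 0.0485696876403053, ring_sd = 0.2860212110245455
  )
}

#' Penalised logP
#'
#' The octanol-water partition coefficient (Crippen logP) penalised by the
#' synthetic-accessibility score and by large rings:
#' `logP - SA - max(0, largest_ring - 6)`, the largest ring being taken over
#' the smallest set of smallest rings. With `normalised = TRUE` each
#' component is z-scored by the ZINC250k constants first (the "plogP-dagger"
#' variant used for cross-method comparison).
#'
#' @param normalised Z-score the three components before combining.
#' @param constants Normalisation constants, see [plogp_normalisation()].
#' @return An `objective_fn`; sub-scores carry the raw components.
#' @export
objective_plogp <- function(normalised = FALSE,
                            constants = plogp_normalisation()) {
  if (normalised) {
    sds <- unlist(constants[c("logp_sd", "sa_sd", "ring_sd")])
    stopifnot(all(sds > 0))
  }
  objective_custom(function(g, key) {
    p <- mol_properties(g, c("logp", "sa", "largest_ring"))
    ring_pen <- max(0L, p$largest_ring - 6L)
    score <- if (normalised) {
      (p$logp - constants$logp_mean) / constants$logp_sd -
        (p$sa - constants$sa_mean) / constants$sa_sd -
        (ring_pen - constants$ring_mean) / constants$ring_sd
    } else {
      p$logp - p$sa - ring_pen
    }
    list(score = score,
         sub = c(logp = p$logp, sa = p$sa, ring_penalty = ring_pen))
  }, name = if (normalised) "plogp_normalised" else "plogp")
}

# ---- CLscore ----------------------------------------------------------------

#' Shingle weight tables
#'
#' A shingle is a circular molecular substructure: the subgraph induced by
#' all atoms within graph distance `r` (r = 1..`radius_max`) of a heavy
#' atom, serialised as canonical SMILES. A weight table maps shingles to
#' weights; unknown shingles weigh 0.
#'
#' @param weights Named numeric vector (names are shingle SMILES).
#' @param radius_max Largest neighbourhood radius, default 3.
#' @return A `shingle_table` object.
#' @export
shingle_table <- function(weights, radius_max = 3L) {
  stopifnot(is.numeric(weights), !is.null(names(weights)),
            all(is.finite(weights)), radius_max >= 1L)
  structure(list(weights = weights, radius_max = as.integer(radius_max)),
            class = "shingle_table")
}

#' @rdname shingle_table
#' @param path File to read/write. Two-column TSV (shingle, weight; no
#'   header needed, one is tolerated) or JSON
#'   (`{"radius_max": n, "weights": {...}}`, or a flat shingle-to-weight
#'   map).
#' @export
read_shingle_table <- function(path, radius_max = 3L) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    if (!is.null(obj$weights)) {
      return(shingle_table(unlist(obj$weights),
                           obj$radius_max %||% radius_max))
    }
    return(shingle_table(unlist(obj), radius_max))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (nrow(df) > 0L && is.na(suppressWarnings(as.numeric(df[1L, 2L])))) {
    df <- df[-1L, , drop = FALSE]   # tolerate a header line
  }
  shingle_table(stats::setNames(as.numeric(df[[2L]]), df[[1L]]), radius_max)
}

#' @rdname shingle_table
#' @param table A `shingle_table`.
#' @export
write_shingle_table <- function(table, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(radius_max = table$radius_max, weights = as.list(table$weights)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(
      data.frame(shingle = names(table$weights), weight = table$weights),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Circular-substructure shingles of a molecule
#'
#' @param g A `molgraph`.
#' @param radius_max Largest neighbourhood radius.
#' @return Character vector of distinct shingle SMILES. Neighbourhoods
#'   containing no bond (an isolated atom) yield no shingle, so single-atom
#'   molecules return none.
#' @export
molecule_shingles <- function(g, radius_max = 3L) {
  alive <- mg_alive(g)
  if (length(alive) < 2L) return(character(0))
  ig <- mg_igraph(g)
  d <- igraph::distances(ig)
  out <- character(0)
  for (ci in seq_along(alive)) {
    for (r in seq_len(radius_max)) {
      sel <- alive[d[ci, ] <= r]
      if (length(sel) < 2L) next
      sub <- new_molgraph(
        replace(rep(NA_character_, length(g$elements)), sel,
                g$elements[sel]),
        g$charge, g$mutable,
        {a <- matrix(0L, nrow(g$adj), ncol(g$adj))
         a[sel, sel] <- g$adj[sel, sel]; a},
        g$valences)
      out <- c(out, canonical_key(sub))
    }
  }
  unique(out)
}

#' ChEMBL-likeness score over a shingle weight table
#'
#' Mean weight of the molecule's distinct shingles; shingles absent from the
#' table weigh 0, and a molecule with no shingles scores 0. The score is a
#' pure function of the canonical molecular identity.
#'
#' @param table A [shingle_table()].
#' @return An `objective_fn`.
#' @export
objective_clscore <- function(table) {
  stopifnot(inherits(table, "shingle_table"))
  objective_custom(function(g, key) {
    sh <- molecule_shingles(g, table$radius_max)
    if (length(sh) == 0L) return(0)
    w <- table$weights[sh]
    w[is.na(w)] <- 0
    mean(w)
  }, name = "clscore")
}

# ---- sigmoid composition (multi-objective products) -------------------------

#' Sigmoid transfer specification
#'
#' Evaluates `1 / (1 + exp(sign * steepness * (x - center)))`; strictly
#' inside (0, 1), equal to 0.5 at the center, increasing in `x` when
#' `sign = -1` and decreasing when `sign = +1`.
#'
#' @param steepness Positive slope parameter.
#' @param center Value at which the sigmoid crosses 0.5.
#' @param sign `+1` or `-1`, the orientation.
#' @return A `sigmoid_spec` object.
#' @examples
#' eval_sigmoid(1.5, sigmoid_chembl_likeness())  # 0.5
#' @export
sigmoid_spec <- function(steepness = 1, center = 0, sign = 1) {
  stopifnot(steepness > 0, sign %in% c(-1, 1))
  structure(list(steepness = steepness, center = center, sign = sign),
            class = "sigmoid_spec")
}

#' @rdname sigmoid_spec
#' @param x Numeric value(s) to transform.
#' @param spec A `sigmoid_spec`.
#' @export
eval_sigmoid <- function(x, spec) {
  stopifnot(inherits(spec, "sigmoid_spec"))
  1 / (1 + exp(spec$sign * spec$steepness * (x - spec$center)))
}

#' Reference sigmoid shapes for composite objectives
#'
#' Ready-made transfer functions: a ChEMBL-likeness gate rising steeply
#' around CLscore 1.5 (blocks below 1, penalises 1-2), a LUMO-energy shape
#' rewarding low energies (0.5 at 0 eV), and a HOMO-energy shape rewarding
#' high energies (0.5 at -7 eV).
#'
#' @return A `sigmoid_spec`.
#' @export
sigmoid_chembl_likeness <- function() sigmoid_spec(10, 1.5, -1)

#' @rdname sigmoid_chembl_likeness
#' @export
sigmoid_lumo <- function() sigmoid_spec(1, 0, 1)

#' @rdname sigmoid_chembl_likeness
#' @export
sigmoid_homo <- function() sigmoid_spec(1, -7, -1)

#' Product-of-sigmoids composite objective
#'
#' Each factor extracts a molecular property and squashes it through a
#' sigmoid; the composite score is the product of the factor values, hence
#' strictly inside (0, 1) and monotone in every property.
#'
#' @param factors List of `list(objective = , sigmoid = )` pairs, where
#'   `objective` is an `objective_fn` (or plain `function(graph, key)`) and
#'   `sigmoid` a [sigmoid_spec()]. Named entries label the sub-scores.
#' @param name Composite name.
#' @return An `objective_fn`. If any factor rejects (e.g. a failed external
#'   evaluation) the composite rejects.
#' @export
objective_composite <- function(factors, name = "composite") {
  stopifnot(length(factors) >= 1L)
  labels <- names(factors) %||% rep("", length(factors))
  labels[labels == ""] <- vapply(seq_along(factors), function(i) {
    f <- factors[[i]]$objective
    if (inherits(f, "objective_fn")) f$name else paste0("factor", i)
  }, character(1))
  objective_custom(function(g, key) {
    vals <- numeric(length(factors))
    subs <- numeric(0)
    for (i in seq_along(factors)) {
      f <- factors[[i]]
      raw <- if (inherits(f$objective, "objective_fn")) {
        f$objective$fn(g, key)
      } else {
        f$objective(g, key)
      }
      if (!is.list(raw)) raw <- list(score = raw)
      if (isTRUE(raw$reject)) return(list(score = NA_real_, reject = TRUE))
      vals[i] <- eval_sigmoid(raw$score, f$sigmoid)
      subs <- c(subs, stats::setNames(c(raw$score, vals[i]),
                                      paste0(labels[i], c("", "_sigmoid"))))
    }
    list(score = prod(vals), sub = subs)
  }, name = name)
}

#' Hard-constraint wrapper
#'
#' Candidates failing the predicate are rejected before scoring (a rejected
#' candidate counts as a failed mutation try and never reaches the
#' evaluation counter), so every molecule inserted in a run passes the
#' predicate -- filtering during generation rather than after.
#'
#' @param objective The wrapped `objective_fn`.
#' @param predicate `function(graph)` returning TRUE for admissible
#'   molecules (e.g. a compound-quality rule set).
#' @param name Optional name; defaults to `<objective>+constraint`.
#' @return An `objective_fn`.
#' @export
objective_constrained <- function(objective, predicate,
                                  name = paste0(objective$name,
                                                "+constraint")) {
  stopifnot(inherits(objective, "objective_fn"), is.function(predicate))
  objective_custom(objective$fn, name = name, predicate = predicate)
}

# ---- external evaluators ----------------------------------------------------

#' External property evaluator contract
#'
#' Adapts a one-molecule-in / one-number-out evaluator (for instance a DFT
#' driver computing a HOMO or LUMO energy in eV) to the objective contract.
#' The evaluator receives the canonical SMILES and returns a number; `NA` (or
#' an error) signals failure, which rejects the candidate -- failures are
#' never conflated with low scores. Results are cached by canonical key so a
#' costly evaluator runs once per molecule.
#'
#' @param evaluator `function(smiles)` returning a numeric scalar or `NA`.
#' @param name Objective name.
#' @return An `objective_fn`.
#' @export
objective_external <- function(evaluator, name = "external") {
  objective_custom(function(g, key) {
    v <- tryCatch(evaluator(key), error = function(e) NA_real_)
    if (length(v) != 1L || is.na(v)) {
      list(score = NA_real_, reject = TRUE)
    } else {
      as.numeric(v)
    }
  }, name = name)
}

#' Deterministic toy electronic-property surrogate
#'
#' A stand-in for a quantum-chemistry evaluator, used to exercise the
#' external-evaluator and composite wiring without any QM code: returns
#' `-(heteroatom count) + 0.5 * (double/triple bond count)` for the molecule,
#' a cheap, deterministic number that moves when the structure moves. It is
#' a synthetic surrogate and has no physical meaning.
#'
#' @return `function(smiles)` suitable for [objective_external()].
#' @export
toy_electronic_evaluator <- function() {
  function(smiles) {
    g <- mol_from_smiles(smiles)
    alive <- mg_alive(g)
    hetero <- sum(!(g$elements[alive] %in% "C"))
    multi <- sum(g$adj[upper.tri(g$adj)] >= 2L)
    -hetero + 0.5 * multi
  }
}
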