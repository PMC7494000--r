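# The evolution loop: a fixed-capacity population of unique molecules,
# grown from one or more seeds, stepped by mutating the best-scoring
# individuals to replace the worst-scoring ones under a first-improver
# policy. With capacity 1 this collapses to a hill climber.

#' Configuration of an evolutionary run
#'
#' @param capacity Maximum population size (1 gives a hill climber).
#' @param n_replaced Number of individuals replaced (or, while the
#'   population is still growing, added) per step.
#' @param max_steps Step budget.
#' @param max_evaluations Optional evaluation budget; the run stops as soon
#'   as it is reached.
#' @param budget_counting What `max_evaluations` counts: `"unique"` (default;
#'   distinct molecules scored, cache hits free) or `"calls"` (every scoring
#'   request on a non-duplicate candidate, the raw-call convention used when
#'   comparing evaluation budgets across generation methods).
#' @param max_actions Maximum number of successive actions per mutation.
#' @param max_tries Improver-search budget per mutated individual.
#' @param allowed_elements,max_heavy_atoms,frozen_atoms,extra_filters Search
#'   space definition, see [action_context()].
#' @param valences Maximum-valence table, see [default_valences()].
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @param stop_score Optional early-stop: the run ends once the best score
#'   reaches this value.
#' @param record_tree Record the exploration tree (default TRUE).
#' @return An `evo_config` object.
#' @export
evo_config <- function(capacity = 1000L, n_replaced = 10L,
                       max_steps = 1500L, max_evaluations = NULL,
                       budget_counting = c("unique", "calls"),
                       max_actions = 2L, max_tries = 50L,
                       allowed_elements = names(default_valences()),
                       max_heavy_atoms = 38L,
                       frozen_atoms = integer(0),
                       extra_filters = list(),
                       valences = default_valences(),
                       seed = NULL, stop_score = NULL,
                       record_tree = TRUE) {
  stopifnot(capacity >= 1L, n_replaced >= 1L, n_replaced <= capacity,
            max_steps >= 0L, max_actions >= 1L, max_tries >= 1L,
            is.null(max_evaluations) || max_evaluations >= 1L)
  structure(
    list(capacity = as.integer(capacity),
         n_replaced = as.integer(n_replaced),
         max_steps = as.integer(max_steps),
         max_evaluations = if (!is.null(max_evaluations)) {
           as.integer(max_evaluations)
         },
         budget_counting = match.arg(budget_counting),
         max_actions = as.integer(max_actions),
         max_tries = as.integer(max_tries),
         allowed_elements = allowed_elements,
         max_heavy_atoms = as.integer(max_heavy_atoms),
         frozen_atoms = as.integer(frozen_atoms),
         extra_filters = extra_filters,
         valences = valences,
         seed = seed, stop_score = stop_score,
         record_tree = isTRUE(record_tree)),
    class = "evo_config"
  )
}

#' Initialise an evolution state from seed molecules
#'
#' Seeds are validated (parseable, valid, mutually distinct by canonical
#' key), scored, and become both the initial population and the roots of the
#' exploration tree. When more seeds than `capacity` are given, the surplus
#' is rejected rather than silently dropped.
#'
#' @param seeds Character vector of SMILES, a single `molgraph`, or a list
#'   of `molgraph`s.
#' @param objective An `objective_fn` (its counters are NOT reset here; see
#'   [evo_run()]).
#' @param config An [evo_config()].
#' @return An `evo_state` environment.
#' @export
evo_init <- function(seeds, objective, config) {
  stopifnot(inherits(config, "evo_config"),
            inherits(objective, "objective_fn"))
  if (inherits(seeds, "molgraph")) seeds <- list(seeds)
  if (is.character(seeds)) {
    seeds <- lapply(seeds, mol_from_smiles, valences = config$valences)
  }
  stopifnot(length(seeds) >= 1L)
  if (length(seeds) > config$capacity) {
    stop("more seeds (", length(seeds), ") than population capacity (",
         config$capacity, ")")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$objective <- objective
  st$ctx <- action_context(config$allowed_elements, config$max_heavy_atoms,
                           config$frozen_atoms, config$extra_filters)
  st$members <- list()
  st$keys <- new.env(parent = emptyenv())
  st$tree <- exploration_tree()
  st$step_idx <- 0L
  st$log <- list()
  st$enum_cache <- new.env(parent = emptyenv())
  st$key_cache <- shared_key_cache()
  st$stopped <- FALSE
  st$best_trace <- list()
  st$best_score <- NULL
  for (g in seeds) {
    ok <- mol_is_valid(g)
    if (!ok) {
      stop("invalid seed molecule: ",
           paste(attr(ok, "violations"), collapse = "; "))
    }
    key <- canonical_key(g)
    if (!is.null(st$keys[[key]])) stop("duplicate seed molecule: ", key)
    res <- evaluate_objective(objective, g, key)
    if (res$reject) stop("seed molecule rejected by the objective: ", key)
    ind <- list(graph = g, key = key, score = res$score, sub = res$sub,
                birth_step = 0L)
    st$members[[length(st$members) + 1L]] <- ind
    st$keys[[key]] <- TRUE
    if (is.null(st$best_score) || res$score > st$best_score) {
      st$best_score <- res$score
      st$best_trace[[length(st$best_trace) + 1L]] <- list(
        step = 0L, smiles = key, score = res$score,
        evaluations = objective$state$count,
        evaluation_calls = objective$state$calls)
    }
    if (config$record_tree) {
      tree_add_root(st$tree, key, res$score, res$sub, 0L)
    }
  }
  class(st) <- c("evo_state", "environment")
  st
}

st_budget_used <- function(st) {
  if (identical(st$config$budget_counting, "calls")) {
    st$objective$state$calls
  } else {
    st$objective$state$count
  }
}

# sorted indices: score descending, ties broken by birth step (older first)
member_order <- function(members) {
  scores <- vapply(members, `[[`, numeric(1), "score")
  births <- vapply(members, `[[`, integer(1), "birth_step")
  order(-scores, births)
}

cached_enum <- function(st, ind) {
  # Actions are slot-indexed, and a rediscovered molecule (same canonical
  # key, different edit history) can lay its atoms out on different slots:
  # a cache entry is only valid for the exact graph instance it was built
  # from, so the stored graph is compared before reuse.
  e <- st$enum_cache[[ind$key]]
  if (!is.null(e) &&
      identical(e$graph[c("elements", "adj", "charge", "mutable")],
                ind$graph[c("elements", "adj", "charge", "mutable")])) {
    return(e$tables)
  }
  tables <- if (length(st$ctx$extra_filters) > 0L) {
    enumerate_all_actions(ind$graph, st$ctx)
  } else {
    action_tables(ind$graph, st$ctx)
  }
  if (length(st$enum_cache) > 4096L) {
    rm(list = ls(st$enum_cache), envir = st$enum_cache)  # crude bound
  }
  st$enum_cache[[ind$key]] <- list(graph = ind$graph, tables = tables)
  tables
}

insert_member <- function(st, ind, parent, actions, replaced_at = NULL) {
  stopifnot(mol_is_valid(ind$graph))   # by-construction guarantee, enforced
  if (is.null(st$best_score) || ind$score > st$best_score) {
    # exact moment the global best first improves, with both counters
    st$best_score <- ind$score
    st$best_trace[[length(st$best_trace) + 1L]] <- list(
      step = ind$birth_step, smiles = ind$key, score = ind$score,
      evaluations = st$objective$state$count,
      evaluation_calls = st$objective$state$calls)
  }
  if (!is.null(replaced_at)) {
    old <- st$members[[replaced_at]]
    rm(list = old$key, envir = st$keys)
    st$members[[replaced_at]] <- ind
  } else {
    st$members[[length(st$members) + 1L]] <- ind
  }
  st$keys[[ind$key]] <- TRUE
  if (st$config$record_tree && !tree_has_node(st$tree, ind$key)) {
    # a molecule removed from the population earlier can be re-discovered
    # and re-inserted; the tree keeps its first lineage only (one node and
    # one incoming edge per canonical key)
    labels <- vapply(actions, action_label, character(1), short = TRUE)
    tree_record(st$tree, parent$key, ind$key, labels,
                score = ind$score, sub = ind$sub, step = ind$birth_step)
  }
}

#' Advance an evolution state by one step
#'
#' While the population is below capacity, up to `n_replaced` improvers of
#' the current best individuals are added (floor score `-Inf`), the number
#' of additions being bounded by the number of individuals available to be
#' mutated. At capacity, the i-th best individual is mutated to replace the
#' i-th worst, each replacement requiring a score at least equal to the
#' replaced individual's (first-improver with plateau insertion); when a
#' search fails, the next-best individual is tried for the same slot until
#' the expected number of replacements is reached or no candidate is left.
#'
#' @param st An `evo_state`.
#' @return The step report (named list), invisibly; also appended to the
#'   state's log.
#' @export
evo_step <- function(st) {
  cfg <- st$config
  st$step_idx <- st$step_idx + 1L
  ord <- member_order(st$members)
  snapshot <- st$members[ord]      # best first, frozen for this step
  m <- length(snapshot)
  inserted <- 0L
  growth <- m < cfg$capacity
  n_target <- if (growth) min(cfg$n_replaced, m, cfg$capacity - m) else {
    min(cfg$n_replaced, m)
  }
  parent_pos <- 1L
  while (inserted < n_target && parent_pos <= m && !st$stopped) {
    parent <- snapshot[[parent_pos]]
    if (growth) {
      floor_score <- -Inf
      replaced_at <- NULL
    } else {
      slot_ind <- snapshot[[m - inserted]]
      floor_score <- slot_ind$score
      replaced_at <- which(vapply(st$members, `[[`, character(1), "key") ==
                             slot_ind$key)[1L]
    }
    out <- find_improver(parent, floor_score, st$objective, st$ctx,
                         max_actions = cfg$max_actions,
                         max_tries = cfg$max_tries,
                         population_keys = st$keys,
                         max_evaluations = cfg$max_evaluations,
                         budget_counting = cfg$budget_counting,
                         first_enum = cached_enum(st, parent),
                         key_cache = st$key_cache)
    if (out$status == "budget_exhausted") {
      st$stopped <- TRUE
      break
    }
    if (out$status == "improver_found") {
      ind <- out$individual
      ind$birth_step <- st$step_idx
      insert_member(st, ind, parent, out$actions, replaced_at)
      inserted <- inserted + 1L
    }
    parent_pos <- parent_pos + 1L
    if (!is.null(cfg$max_evaluations) &&
        st_budget_used(st) >= cfg$max_evaluations) {
      st$stopped <- TRUE
    }
  }
  scores <- vapply(st$members, `[[`, numeric(1), "score")
  evals <- objective_evaluations(st$objective)
  report <- list(step = st$step_idx,
                 best_score = max(scores),
                 mean_score = mean(scores),
                 pop_size = length(st$members),
                 evaluations = as.integer(evals),
                 evaluation_calls = as.integer(attr(evals, "calls")),
                 inserted = inserted)
  st$log[[length(st$log) + 1L]] <- report
  if (!is.null(cfg$stop_score) && report$best_score >= cfg$stop_score) {
    st$stopped <- TRUE
  }
  invisible(report)
}

#' Run an evolutionary molecular optimisation
#'
#' Initialises a population from the seeds and steps it until the step
#' budget, the evaluation budget, or the optional target score is reached.
#'
#' @param objective An `objective_fn`; its cache and counters are reset at
#'   the start of the run unless `reset_objective = FALSE`.
#' @param seeds Seed molecules (SMILES character vector, `molgraph`, or list
#'   of `molgraph`s). Default: methane.
#' @param config An [evo_config()].
#' @param reset_objective Reset objective counters/cache first.
#' @return An `evomol_run` object: final population (tibble, best first),
#'   per-step log (tibble), exploration tree, evaluation counters and the
#'   resolved configuration.
#' @examples
#' \dontrun{
#' run <- evo_run(objective_qed(), "C",
#'                evo_config(capacity = 1, n_replaced = 1,
#'                           max_steps = 20, seed = 1))
#' run$population
#' }
#' @export
evo_run <- function(objective, seeds = "C", config = evo_config(),
                    reset_objective = TRUE) {
  if (reset_objective) objective_reset(objective)
  st <- evo_init(seeds, objective, config)
  while (st$step_idx < config$max_steps && !st$stopped) {
    evo_step(st)
    if (!is.null(config$max_evaluations) &&
        st_budget_used(st) >= config$max_evaluations) {
      st$stopped <- TRUE
    }
  }
  evo_result(st)
}

#' Extract the result object from an evolution state
#' @param st An `evo_state`.
#' @return An `evomol_run`.
#' @export
evo_result <- function(st) {
  ord <- member_order(st$members)
  members <- st$members[ord]
  sub_names <- unique(unlist(lapply(members, function(m) names(m$sub))))
  pop <- tibble::tibble(
    smiles = vapply(members, `[[`, character(1), "key"),
    score = vapply(members, `[[`, numeric(1), "score"),
    birth_step = vapply(members, `[[`, integer(1), "birth_step")
  )
  for (sn in sub_names) {
    pop[[sn]] <- vapply(members, function(m) {
      if (is.null(m$sub) || !(sn %in% names(m$sub))) NA_real_
      else as.numeric(m$sub[[sn]])
    }, numeric(1))
  }
  log <- if (length(st$log) > 0L) {
    tibble::as_tibble(do.call(rbind, lapply(st$log, function(r) {
      as.data.frame(r)
    })))
  } else {
    tibble::tibble(step = integer(0), best_score = numeric(0),
                   mean_score = numeric(0), pop_size = integer(0),
                   evaluations = integer(0), evaluation_calls = integer(0),
                   inserted = integer(0))
  }
  evals <- objective_evaluations(st$objective)
  best_trace <- tibble::tibble(
    step = vapply(st$best_trace, function(r) as.integer(r$step), integer(1)),
    smiles = vapply(st$best_trace, `[[`, character(1), "smiles"),
    score = vapply(st$best_trace, `[[`, numeric(1), "score"),
    evaluations = vapply(st$best_trace, function(r) {
      as.integer(r$evaluations)
    }, integer(1)),
    evaluation_calls = vapply(st$best_trace, function(r) {
      as.integer(r$evaluation_calls)
    }, integer(1))
  )
  structure(
    list(population = pop, log = log, tree = st$tree,
         best_trace = best_trace,
         evaluations = as.integer(evals),
         evaluation_calls = attr(evals, "calls"),
         steps = st$step_idx,
         objective_name = st$objective$name,
         config = st$config,
         members = members),
    class = "evomol_run"
  )
}

#' @export
print.evomol_run <- function(x, ...) {
  cat("<evomol_run> objective: ", x$objective_name,
      " | steps: ", x$steps,
      " | evaluations: ", x$evaluations,
      " | population: ", nrow(x$population), "\n", sep = "")
  if (nrow(x$population) > 0L) {
    cat("best: ", x$population$smiles[1L], "  score = ",
        format(x$population$score[1L], digits = 6), "\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the final population of a run
#' @param x An `evomol_run`.
#' @param ... Unused.
#' @return The population tibble (one row per molecule, best first).
#' @export
tidy.evomol_run <- function(x, ...) x$population

#' One-row summary of a run
#' @param x An `evomol_run`.
#' @param ... Unused.
#' @return A one-row tibble: best/mean score, population size, steps,
#'   unique evaluations, total evaluation calls.
#' @export
glance.evomol_run <- function(x, ...) {
  tibble::tibble(
    objective = x$objective_name,
    best_score = if (nrow(x$population)) x$population$score[1L] else NA_real_,
    mean_score = mean(x$population$score),
    pop_size = nrow(x$population),
    steps = x$steps,
    evaluations = x$evaluations,
    evaluation_calls = x$evaluation_calls
  )
}

#' Progress plot of a run
#'
#' Best and mean population score against the optimisation step.
#'
#' @param run An `evomol_run`.
#' @return A ggplot object.
#' @export
plot_progress <- function(run) {
  stopifnot(inherits(run, "evomol_run"))
  log <- run$log
  df <- rbind(
    data.frame(step = log$step, score = log$best_score, which = "best"),
    data.frame(step = log$step, score = log$mean_score, which = "mean")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$score,
                                   colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = run$objective_name, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
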