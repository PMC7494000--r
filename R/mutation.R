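# Mutation = a short random sequence of graph actions, plus the bounded
# first-improver search built on it. Randomness is drawn from R's RNG so a
# seeded run is bit-reproducible: first the number of actions k is uniform
# on {1..max_actions}, then at every sub-step the action type is uniform
# over the types that currently have at least one legal action, then the
# action is uniform within the type.

#' Draw a random mutation
#'
#' @param g A valid `molgraph`.
#' @param ctx An [action_context()].
#' @param max_actions Maximum number of successive actions (k is drawn
#'   uniformly from `1:max_actions`).
#' @param first_enum Optional precomputed [enumerate_all_actions()] result
#'   for `g` (speed-up when many draws start from the same parent).
#' @return `list(graph, actions)` where `actions` is the list of applied
#'   `mol_action`s, or `NULL` when some sub-step had no legal action of any
#'   type.
#' @export
draw_mutation <- function(g, ctx, max_actions = 2L, first_enum = NULL) {
  k <- sample.int(max_actions, 1L)
  cur <- g
  actions <- vector("list", k)
  use_lists <- length(ctx$extra_filters) > 0L ||
    (!is.null(first_enum) && !inherits(first_enum, "action_tables"))
  for (step in seq_len(k)) {
    if (use_lists) {
      # extra filters are predicates on materialised actions: take the
      # (slower) full-materialisation route
      by_type <- if (step == 1L && !is.null(first_enum)) {
        first_enum
      } else {
        enumerate_all_actions(cur, ctx)
      }
      counts <- lengths(by_type)
      nonempty <- which(counts > 0L)
      if (length(nonempty) == 0L) return(NULL)
      type <- nonempty[[sample.int(length(nonempty), 1L)]]
      acts <- by_type[[type]]
      a <- acts[[sample.int(length(acts), 1L)]]
    } else {
      tabs <- if (step == 1L && !is.null(first_enum)) {
        first_enum
      } else {
        action_tables(cur, ctx)
      }
      counts <- vapply(tabs, table_n, integer(1))
      nonempty <- which(counts > 0L)
      if (length(nonempty) == 0L) return(NULL)
      type_i <- nonempty[[sample.int(length(nonempty), 1L)]]
      tab <- tabs[[type_i]]
      a <- materialise_action(names(tabs)[type_i], tab,
                              sample.int(tab$n, 1L))
    }
    cur <- apply_action(cur, a, check = FALSE)
    actions[[step]] <- a
  }
  list(graph = cur, actions = actions)
}

#' Search for a first improver of an individual
#'
#' Repeats [draw_mutation()] from `parent` until a candidate scores at least
#' `floor_score` (plateau-equal candidates are accepted so flat fitness
#' regions remain traversable), is not already in the population, is not the
#' parent itself, and passes any hard constraint -- or until `max_tries`
#' draws have been spent. Objective evaluations are cached by canonical key;
#' cache hits and rejected candidates do not consume the evaluation budget.
#'
#' @param parent List with at least `graph` and `key` (an individual).
#' @param floor_score Score of the individual the improver would replace;
#'   use `-Inf` during population growth.
#' @param objective An `objective_fn`.
#' @param ctx An [action_context()].
#' @param max_actions,max_tries Mutation parameters (defaults 2 and 50).
#' @param population_keys Environment (or character vector) holding the
#'   canonical keys currently in the population.
#' @param max_evaluations Optional evaluation cap; the search stops before
#'   any evaluation that would exceed it.
#' @param budget_counting What the cap counts: `"unique"` molecules scored
#'   or raw `"calls"` (see [evo_config()]).
#' @param first_enum Optional cached enumeration for the parent graph.
#' @param key_cache Optional environment memoising molblock-to-canonical-key
#'   conversions across tries (candidates repeat heavily near fitness
#'   plateaus).
#' @return List with `status` (`"improver_found"`, `"no_improver"`,
#'   `"no_legal_action"` or `"budget_exhausted"`), `individual` (graph, key,
#'   score, sub -- only when found), `actions`, `evaluations_spent`, `tries`.
#' @export
find_improver <- function(parent, floor_score, objective, ctx,
                          max_actions = 2L, max_tries = 50L,
                          population_keys = character(0),
                          max_evaluations = NULL,
                          budget_counting = "unique",
                          first_enum = NULL, key_cache = NULL) {
  budget_used <- function() {
    if (identical(budget_counting, "calls")) obj_calls(objective)
    else objective$state$count
  }
  has_key <- if (is.environment(population_keys)) {
    function(k) !is.null(population_keys[[k]])
  } else {
    function(k) k %in% population_keys
  }
  if (is.null(first_enum)) {
    first_enum <- if (length(ctx$extra_filters) > 0L) {
      enumerate_all_actions(parent$graph, ctx)
    } else {
      action_tables(parent$graph, ctx)
    }
  }
  n_first <- if (inherits(first_enum, "action_tables")) {
    sum(vapply(first_enum, table_n, integer(1)))
  } else {
    sum(lengths(first_enum))
  }
  evals0 <- objective$state$count
  spent <- function() objective$state$count - evals0
  status <- "no_improver"
  for (try in seq_len(max_tries)) {
    if (!is.null(max_evaluations) && budget_used() >= max_evaluations) {
      return(list(status = "budget_exhausted", individual = NULL,
                  actions = NULL, evaluations_spent = spent(), tries = try - 1L))
    }
    mut <- draw_mutation(parent$graph, ctx, max_actions, first_enum)
    if (is.null(mut)) {
      # no legal action at sub-step 1 means no try can ever succeed
      if (n_first == 0L) {
        return(list(status = "no_legal_action", individual = NULL,
                    actions = NULL, evaluations_spent = spent(), tries = try))
      }
      next
    }
    key <- if (is.null(key_cache)) {
      canonical_key(mut$graph)
    } else {
      mb <- mol_to_molblock(mut$graph)
      k <- key_cache[[mb]]
      if (is.null(k)) {
        k <- ob_convert("MOL", "CAN", mb)
        if (length(key_cache) > 32768L) {
          rm(list = ls(key_cache), envir = key_cache)
        }
        key_cache[[mb]] <- k
      }
      k
    }
    if (identical(key, parent$key) || has_key(key)) next
    res <- evaluate_objective(objective, mut$graph, key)
    if (res$reject) next
    if (res$score >= floor_score) {
      return(list(
        status = "improver_found",
        individual = list(graph = mut$graph, key = key,
                          score = res$score, sub = res$sub),
        actions = mut$actions,
        evaluations_spent = spent(), tries = try))
    }
  }
  list(status = status, individual = NULL, actions = NULL,
       evaluations_spent = spent(), tries = max_tries)
}
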