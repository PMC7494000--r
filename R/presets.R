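# Ready-made configuration profiles. Presets fix the parameter profile of a
# run (search space, budgets); the objective is chosen separately.

#' Named configuration presets
#'
#' * `"hill-climber"`: capacity 1, one replacement per step, atoms
#'   C/N/O/F/P/S/Cl/Br, at most 38 heavy atoms, mutations of up to 2
#'   actions, 50 improver tries, 1500 steps. With a budget on evaluations
#'   this is the single-molecule baseline profile.
#' * `"population-1000"`: as `"hill-climber"` but capacity 1000 and 10
#'   replacements per step.
#' * `"large-molecules"`: capacity 1000, 10 replacements, up to 50 heavy
#'   atoms, mutations of up to 3 actions, 3000 steps -- the profile for
#'   goal-directed benchmark-style tasks on bigger molecules.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [evo_config()] (e.g. `seed`,
#'   `max_evaluations`, `allowed_elements`).
#' @return An `evo_config`.
#' @examples
#' evo_preset("hill-climber", seed = 1, max_evaluations = 1000)
#' @export
evo_preset <- function(name = c("hill-climber", "population-1000",
                                "large-molecules"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "hill-climber" = list(capacity = 1L, n_replaced = 1L, max_steps = 1500L,
                          max_actions = 2L, max_tries = 50L,
                          max_heavy_atoms = 38L),
    "population-1000" = list(capacity = 1000L, n_replaced = 10L,
                             max_steps = 1500L, max_actions = 2L,
                             max_tries = 50L, max_heavy_atoms = 38L),
    "large-molecules" = list(capacity = 1000L, n_replaced = 10L,
                             max_steps = 3000L, max_actions = 3L,
                             max_tries = 50L, max_heavy_atoms = 50L)
  )
  overrides <- list(...)
  do.call(evo_config, utils::modifyList(base, overrides))
}

#' Resolve an objective by name
#'
#' Used by the command-line interface: `"qed"`, `"sascore"` (normalised),
#' `"sascore-raw"`, `"plogp"`, `"plogp-norm"`, or `"clscore"` (requires
#' `shingle_table`).
#'
#' @param name Objective name.
#' @param shingle_table Path to a shingle weight table (for `"clscore"`).
#' @return An `objective_fn`.
#' @export
objective_by_name <- function(name, shingle_table = NULL) {
  switch(name,
    qed = objective_qed(),
    sascore = objective_sascore(normalised = TRUE),
    `sascore-raw` = objective_sascore(normalised = FALSE),
    plogp = objective_plogp(normalised = FALSE),
    `plogp-norm` = objective_plogp(normalised = TRUE),
    clscore = {
      if (is.null(shingle_table)) {
        stop("objective 'clscore' needs a shingle weight table file")
      }
      objective_clscore(read_shingle_table(shingle_table))
    },
    stop("unknown objective: ", name)
  )
}

#' Write the artifacts of a run to a directory
#'
#' Step log and final population as CSV, exploration tree as DOT and JSON,
#' and the resolved configuration as JSON -- enough, together with the seed,
#' to reproduce the run.
#'
#' @param run An `evomol_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_artifacts <- function(run, dir) {
  stopifnot(inherits(run, "evomol_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$log, file.path(dir, "steps.csv"), row.names = FALSE)
  utils::write.csv(run$population, file.path(dir, "population.csv"),
                   row.names = FALSE)
  if (length(ls(run$tree$nodes)) > 0L) {
    export_tree(run$tree, "dot", file.path(dir, "tree.dot"))
    export_tree(run$tree, "json", file.path(dir, "tree.json"))
  }
  cfg <- run$config
  cfg$extra_filters <- NULL                    # functions do not serialise
  jsonlite::write_json(
    c(cfg, list(objective = run$objective_name,
                steps_executed = run$steps,
                evaluations = run$evaluations)),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' Read seed molecules from a SMILES list file
#'
#' One SMILES per line; optional further tab-separated columns (scores,
#' names) are ignored. Blank lines and `#` comments are skipped.
#'
#' @param path File path.
#' @return Character vector of SMILES.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}
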