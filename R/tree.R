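# The exploration tree records every improver ever inserted during a run:
# one node per canonical key (with its score and insertion step), one edge
# per insertion labelled with the applied action sequence. It is history,
# not current population membership -- nodes persist after their molecule is
# replaced out of the population.

#' Create an empty exploration tree
#'
#' @return An `exploration_tree` object (environment-backed).
#' @export
exploration_tree <- function() {
  tr <- new.env(parent = emptyenv())
  tr$nodes <- new.env(parent = emptyenv())
  tr$edges <- list()
  tr$roots <- character(0)
  class(tr) <- c("exploration_tree", "environment")
  tr
}

tree_has_node <- function(tree, key) !is.null(tree$nodes[[key]])

tree_add_root <- function(tree, key, score, sub = NULL, step = 0L) {
  if (tree_has_node(tree, key)) stop("root already present: ", key)
  tree$nodes[[key]] <- list(score = score, sub = sub, step = step)
  tree$roots <- c(tree$roots, key)
  invisible(tree)
}

#' Record an inserted improver
#'
#' @param tree An `exploration_tree`.
#' @param parent_key Canonical key of the mutated parent; must already be a
#'   tree node (roots are the initial population).
#' @param child_key Canonical key of the inserted improver; must be new.
#' @param labels Character vector of short action labels (Ad, Rm, Ch, Sub,
#'   In, Ct, Mv) in application order.
#' @param score,sub,step Node annotations for the child.
#' @return The tree, invisibly.
#' @export
tree_record <- function(tree, parent_key, child_key, labels,
                        score, sub = NULL, step = NA_integer_) {
  if (!tree_has_node(tree, parent_key)) {
    stop("parent is not in the exploration tree: ", parent_key)
  }
  if (tree_has_node(tree, child_key)) {
    stop("child already in the exploration tree: ", child_key)
  }
  stopifnot(length(labels) >= 1L, all(labels %in% ACTION_TYPES))
  tree$nodes[[child_key]] <- list(score = score, sub = sub,
                                  step = as.integer(step))
  tree$edges[[length(tree$edges) + 1L]] <-
    list(parent = parent_key, child = child_key, labels = labels)
  invisible(tree)
}

#' Tabular views of an exploration tree
#'
#' @param tree An `exploration_tree`.
#' @return `tree_nodes()`: tibble with smiles, score, step, is_root;
#'   `tree_edges()`: tibble with from, to, labels (comma-joined) in
#'   insertion order.
#' @export
tree_nodes <- function(tree) {
  keys <- ls(tree$nodes)
  tibble::tibble(
    smiles = keys,
    score = vapply(keys, function(k) as.numeric(tree$nodes[[k]]$score),
                   numeric(1)),
    step = vapply(keys, function(k) {
      s <- tree$nodes[[k]]$step
      if (is.null(s)) NA_integer_ else as.integer(s)
    }, integer(1)),
    is_root = keys %in% tree$roots
  )
}

#' @rdname tree_nodes
#' @export
tree_edges <- function(tree) {
  tibble::tibble(
    from = vapply(tree$edges, `[[`, character(1), "parent"),
    to = vapply(tree$edges, `[[`, character(1), "child"),
    labels = vapply(tree$edges, function(e) paste(e$labels, collapse = ","),
                    character(1))
  )
}

#' @export
print.exploration_tree <- function(x, ...) {
  cat("<exploration_tree> ", length(ls(x$nodes)), " nodes, ",
      length(x$edges), " edges, ", length(x$roots), " root(s)\n", sep = "")
  invisible(x)
}

#' Export an exploration tree
#'
#' Writes (or returns) a DOT (Graphviz) or JSON rendering. DOT nodes carry
#' the score for colouring; edges carry their action labels. The JSON form
#' round-trips losslessly through [tree_from_json()].
#'
#' @param tree An `exploration_tree` with at least one node.
#' @param format `"dot"` or `"json"`.
#' @param file Optional path; when omitted the rendering is returned as a
#'   character scalar.
#' @return The rendering (invisibly when written to a file).
#' @export
export_tree <- function(tree, format = c("dot", "json"), file = NULL) {
  format <- match.arg(format)
  if (length(ls(tree$nodes)) == 0L) stop("empty exploration tree")
  text <- if (format == "dot") tree_to_dot(tree) else tree_to_json(tree)
  if (!is.null(file)) {
    writeLines(text, file)
    return(invisible(text))
  }
  text
}

tree_to_dot <- function(tree) {
  nodes <- tree_nodes(tree)
  edges <- tree_edges(tree)
  q <- function(s) paste0("\"", gsub("\"", "\\\\\"", s), "\"")
  lines <- c(
    "digraph exploration {",
    "  node [shape=circle, style=filled];",
    sprintf("  %s [score=%s, label=%s%s];",
            vapply(nodes$smiles, q, character(1)),
            format(nodes$score, digits = 6, trim = TRUE),
            vapply(paste0(nodes$smiles, "\\n",
                          format(nodes$score, digits = 4, trim = TRUE)),
                   q, character(1)),
            ifelse(nodes$is_root, ", penwidth=3", "")),
    sprintf("  %s -> %s [label=%s];",
            vapply(edges$from, q, character(1)),
            vapply(edges$to, q, character(1)),
            vapply(edges$labels, q, character(1))),
    "}"
  )
  paste(lines, collapse = "\n")
}

tree_to_json <- function(tree) {
  nodes <- tree_nodes(tree)
  jsonlite::toJSON(
    list(
      nodes = lapply(seq_len(nrow(nodes)), function(i) {
        list(smiles = nodes$smiles[i], score = nodes$score[i],
             step = nodes$step[i])
      }),
      edges = lapply(tree$edges, function(e) {
        list(from = e$parent, to = e$child, labels = as.list(e$labels))
      }),
      roots = as.list(tree$roots)
    ),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
}

#' Rebuild an exploration tree from its JSON export
#'
#' @param x JSON string or path to a JSON file produced by [export_tree()].
#' @return An `exploration_tree`.
#' @export
tree_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  tr <- exploration_tree()
  for (r in obj$roots) {
    node <- Filter(function(n) identical(n$smiles, r), obj$nodes)[[1L]]
    tree_add_root(tr, r, node$score, step = node$step %||% NA_integer_)
  }
  remaining <- Filter(function(n) !(n$smiles %in% tr$roots), obj$nodes)
  by_key <- stats::setNames(remaining,
                            vapply(remaining, `[[`, character(1), "smiles"))
  edges <- obj$edges
  while (length(edges) > 0L) {
    progressed <- FALSE
    keep <- list()
    for (e in edges) {
      if (tree_has_node(tr, e$from)) {
        node <- by_key[[e$to]]
        tree_record(tr, e$from, e$to, unlist(e$labels),
                    score = node$score, step = node$step %||% NA_integer_)
        progressed <- TRUE
      } else {
        keep[[length(keep) + 1L]] <- e
      }
    }
    if (!progressed) stop("edge list does not form a rooted tree")
    edges <- keep
  }
  tr
}
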