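# The seven atom-level actions on molecular graphs and their a priori
# filters. Actions are enumerated without being applied: every filter
# (dislocation, hypervalence, charged-atom protection, frozen-atom rules,
# size limit) is decided from graph analysis, so that each enumerated action
# is guaranteed to yield a valid graph.
#
# Primary actions: append atom, remove atom, change bond.
# Secondary actions (shortcuts that do not extend the reachable space):
# substitute atom type, insert carbon, cut atom, move group.

ACTION_TYPES <- c(
  append_atom = "Ad", remove_atom = "Rm", change_bond = "Ch",
  substitute_atom_type = "Sub", insert_carbon = "In",
  cut_atom = "Ct", move_group = "Mv"
)

#' The seven action types
#'
#' @return Named character vector mapping action-type name to the short label
#'   used on exploration-tree edges (Ad, Rm, Ch, Sub, In, Ct, Mv).
#' @export
action_types <- function() ACTION_TYPES

#' Action enumeration context
#'
#' Defines the chemical subspace an optimisation run explores: the element
#' set, the heavy-atom size limit, additional frozen atoms, and optional
#' extra action filters.
#'
#' @param allowed_elements Character vector of element symbols actions may
#'   introduce or substitute to.
#' @param max_heavy_atoms Maximum number of heavy atoms a molecule may reach.
#' @param frozen_atoms Integer atom indices frozen in addition to atoms whose
#'   own `mutable` flag is FALSE.
#' @param extra_filters List of predicates `function(graph, action)`; an
#'   action is kept only if every predicate returns TRUE.
#' @return An `action_context` object.
#' @examples
#' action_context(c("C", "N", "O", "F"), max_heavy_atoms = 9)
#' @export
action_context <- function(allowed_elements = names(default_valences()),
                           max_heavy_atoms = 38L,
                           frozen_atoms = integer(0),
                           extra_filters = list()) {
  stopifnot(max_heavy_atoms >= 1L, is.character(allowed_elements),
            length(allowed_elements) >= 1L)
  structure(
    list(allowed_elements = allowed_elements,
         max_heavy_atoms = as.integer(max_heavy_atoms),
         frozen_atoms = as.integer(frozen_atoms),
         extra_filters = extra_filters),
    class = "action_context"
  )
}

act <- function(type, ...) {
  structure(list(type = type, ...), class = "mol_action")
}

#' Serialise an action for logs and tree edges
#'
#' @param action A `mol_action`.
#' @param short If TRUE return only the type label (Ad, Rm, ...).
#' @return Character scalar, e.g. `"Ad(3,N)"` or `"Ch(2,5,1->2)"`.
#' @export
action_label <- function(action, short = FALSE) {
  lab <- ACTION_TYPES[[action$type]]
  if (short) return(lab)
  params <- switch(action$type,
    append_atom = paste0(action$a, ",", action$element),
    remove_atom = as.character(action$a),
    change_bond = paste0(action$a, ",", action$b, ",",
                         action$from, "->", action$order),
    substitute_atom_type = paste0(action$a, ",", action$element),
    insert_carbon = paste0(action$a, ",", action$b),
    cut_atom = as.character(action$a),
    move_group = paste0(action$g, "-", action$old, ",dest ", action$new)
  )
  paste0(lab, "(", params, ")")
}

#' @export
print.mol_action <- function(x, ...) {
  cat("<mol_action> ", action_label(x), "\n", sep = "")
  invisible(x)
}

# One-shot structural analysis reused by all per-type enumerators: valences,
# charges, mutability, plus articulation points, bridge edges and bridge side
# partitions from a single iterative depth-first search (Tarjan lowlinks;
# for a bridge, one side is exactly the DFS subtree of its child endpoint,
# a contiguous range of entry times).
mg_analysis <- function(g, ctx) {
  alive <- mg_alive(g)
  n <- length(alive)
  bsum <- mg_bond_sum(g, alive)
  freeval <- mg_max_valence(g, alive) - bsum
  charged <- g$charge[alive] != 0L
  mutable <- g$mutable[alive] & !(alive %in% ctx$frozen_atoms)
  arti <- integer(0)
  bridges <- list()
  if (n >= 2L) {
    tj <- tarjan_dfs(g, alive)
    arti <- tj$articulation
    bridges <- tj$bridges
  }
  list(alive = alive, n = n, bsum = bsum, freeval = freeval,
       charged = charged, mutable = mutable, arti = arti, bridges = bridges)
}

# Iterative Tarjan DFS over the live atoms of a connected graph.
# Returns articulation points (slot ids) and bridges, each bridge with the
# two slot-id sides it separates.
tarjan_dfs <- function(g, alive) {
  n <- length(alive)
  pos <- match(seq_along(g$elements), alive)     # slot -> position
  adj <- lapply(alive, function(s) pos[which(g$adj[s, ] > 0L)])
  disc <- integer(n); low <- integer(n); parent <- integer(n)
  sub_hi <- integer(n)                           # max entry time in subtree
  state <- integer(n)                            # next neighbour index
  counter <- 0L
  stack <- integer(n); top <- 0L
  is_arti <- logical(n)
  bridge_child <- integer(0)
  root <- 1L
  root_children <- 0L
  counter <- counter + 1L
  disc[root] <- low[root] <- counter
  top <- 1L; stack[1L] <- root; state[root] <- 1L
  while (top > 0L) {
    u <- stack[top]
    nb <- adj[[u]]
    if (state[u] <= length(nb)) {
      w <- nb[state[u]]
      state[u] <- state[u] + 1L
      if (disc[w] == 0L) {
        parent[w] <- u
        if (u == root) root_children <- root_children + 1L
        counter <- counter + 1L
        disc[w] <- low[w] <- counter
        state[w] <- 1L
        top <- top + 1L; stack[top] <- w
      } else if (w != parent[u]) {
        low[u] <- min(low[u], disc[w])
      }
    } else {
      sub_hi[u] <- counter
      top <- top - 1L
      if (top > 0L) {
        p <- stack[top]
        low[p] <- min(low[p], low[u])
        if (low[u] > disc[p]) bridge_child <- c(bridge_child, u)
        if (p != root && low[u] >= disc[p]) is_arti[p] <- TRUE
      }
    }
  }
  if (root_children >= 2L) is_arti[root] <- TRUE
  bridges <- lapply(bridge_child, function(w) {
    u <- parent[w]
    in_sub <- disc >= disc[w] & disc <= sub_hi[w]
    list(u = alive[u], v = alive[w], order = g$adj[alive[u], alive[w]],
         side_u = alive[!in_sub], side_v = alive[in_sub])
  })
  list(articulation = alive[is_arti], bridges = bridges)
}

# Compact enumeration: each action type is represented as parallel vectors
# (one row per legal action) so that counting and uniform drawing never
# allocate per-action objects; a row is materialised to a mol_action only
# when actually chosen or when the list API is used.
action_tables <- function(g, ctx, analysis = NULL) {
  an <- analysis %||% mg_analysis(g, ctx)
  tabs <- list(
    append_atom = enum_append(g, ctx, an),
    remove_atom = enum_remove(g, ctx, an),
    change_bond = enum_change_bond(g, ctx, an),
    substitute_atom_type = enum_substitute(g, ctx, an),
    insert_carbon = enum_insert_carbon(g, ctx, an),
    cut_atom = enum_cut(g, ctx, an),
    move_group = enum_move_group(g, ctx, an)
  )
  structure(tabs, class = "action_tables", analysis = an)
}

table_n <- function(tab) tab$n %||% 0L

materialise_action <- function(type, tab, i) {
  switch(type,
    append_atom = act("append_atom", a = tab$a[i], element = tab$element[i]),
    remove_atom = act("remove_atom", a = tab$a[i]),
    change_bond = act("change_bond", a = tab$a[i], b = tab$b[i],
                      order = tab$order[i], from = tab$from[i]),
    substitute_atom_type = act("substitute_atom_type", a = tab$a[i],
                               element = tab$element[i]),
    insert_carbon = act("insert_carbon", a = tab$a[i], b = tab$b[i]),
    cut_atom = act("cut_atom", a = tab$a[i]),
    move_group = act("move_group", g = tab$g[i], old = tab$old[i],
                     new = tab$new[i], order = tab$order[i])
  )
}

materialise_all <- function(type, tab) {
  lapply(seq_len(table_n(tab)), materialise_action, type = type, tab = tab)
}

#' Enumerate the legal actions of one type
#'
#' Every returned action is guaranteed, without being applied, to produce a
#' valid molecular graph: connected, not hypervalent, within the size limit,
#' and respecting the charged-atom and frozen-atom filters.
#'
#' @param g A valid `molgraph`.
#' @param type One of `names(action_types())`.
#' @param ctx An [action_context()].
#' @param analysis Optional precomputed `mg_analysis()` result (internal
#'   speed-up when several types are enumerated on the same graph).
#' @return List of `mol_action` objects (possibly empty).
#' @examples
#' enumerate_actions(mol_from_smiles("C"), "append_atom",
#'                   action_context(c("C", "N", "O", "F")))
#' @export
enumerate_actions <- function(g, type, ctx, analysis = NULL) {
  type <- match.arg(type, names(ACTION_TYPES))
  an <- analysis %||% mg_analysis(g, ctx)
  tab <- switch(type,
    append_atom = enum_append(g, ctx, an),
    remove_atom = enum_remove(g, ctx, an),
    change_bond = enum_change_bond(g, ctx, an),
    substitute_atom_type = enum_substitute(g, ctx, an),
    insert_carbon = enum_insert_carbon(g, ctx, an),
    cut_atom = enum_cut(g, ctx, an),
    move_group = enum_move_group(g, ctx, an)
  )
  out <- materialise_all(type, tab)
  for (f in ctx$extra_filters) {
    if (length(out) == 0L) break
    keep <- vapply(out, function(a) isTRUE(f(g, a)), logical(1))
    out <- out[keep]
  }
  out
}

#' Enumerate legal actions of every type
#'
#' @inheritParams enumerate_actions
#' @return Named list (one entry per action type) of action lists.
#' @export
enumerate_all_actions <- function(g, ctx) {
  an <- mg_analysis(g, ctx)
  stats::setNames(
    lapply(names(ACTION_TYPES), enumerate_actions, g = g, ctx = ctx,
           analysis = an),
    names(ACTION_TYPES))
}

no_actions <- list(n = 0L)

enum_append <- function(g, ctx, an) {
  if (an$n >= ctx$max_heavy_atoms) return(no_actions)
  els <- intersect(ctx$allowed_elements, names(g$valences))
  anchors <- an$alive[an$freeval >= 1L & !an$charged]
  na <- length(anchors); ne <- length(els)
  if (na == 0L || ne == 0L) return(no_actions)
  list(n = na * ne, a = rep(anchors, ne), element = rep(els, each = na))
}

enum_remove <- function(g, ctx, an) {
  if (an$n < 2L) return(no_actions)
  # removing an atom deletes every bond it carries: its neighbours must all
  # be uncharged (the atom itself may be charged -- the removal exception);
  # non-articulation guarantees the rest stays connected
  cand <- an$alive[an$mutable & !(an$alive %in% an$arti)]
  if (any(an$charged)) {
    charged_slots <- an$alive[an$charged]
    near_charged <- which(rowSums(
      g$adj[, charged_slots, drop = FALSE] > 0L) > 0L)
    cand <- setdiff(cand, near_charged)
  }
  if (length(cand) == 0L) return(no_actions)
  list(n = length(cand), a = cand)
}

enum_change_bond <- function(g, ctx, an) {
  if (an$n < 2L) return(no_actions)
  atoms <- an$alive
  pairs <- which(upper.tri(diag(an$n)), arr.ind = TRUE)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  keep <- !an$charged[i] & !an$charged[j] & (an$mutable[i] | an$mutable[j])
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0L) return(no_actions)
  cur <- g$adj[cbind(atoms[i], atoms[j])]
  bridge_key <- vapply(an$bridges, function(b) {
    paste(sort(c(b$u, b$v)), collapse = "-")
  }, character(1))
  pair_key <- paste(atoms[i], atoms[j], sep = "-")   # i < j, slots ascending
  is_bridge <- pair_key %in% bridge_key
  A <- integer(0); B <- integer(0); O <- integer(0); FR <- integer(0)
  for (k in 0:3) {
    sel <- cur != k
    if (k == 0L) {
      sel <- sel & cur > 0L & !is_bridge      # dislocation filter
    } else {
      inc <- k - cur
      sel <- sel & (inc <= 0L | (an$freeval[i] >= inc & an$freeval[j] >= inc))
    }
    if (any(sel)) {
      A <- c(A, atoms[i[sel]]); B <- c(B, atoms[j[sel]])
      O <- c(O, rep(k, sum(sel))); FR <- c(FR, cur[sel])
    }
  }
  if (length(A) == 0L) return(no_actions)
  list(n = length(A), a = A, b = B, order = O, from = FR)
}

enum_substitute <- function(g, ctx, an) {
  els <- intersect(ctx$allowed_elements, names(g$valences))
  sel <- an$mutable & !an$charged
  if (!any(sel) || length(els) == 0L) return(no_actions)
  cand <- an$alive[sel]; cb <- an$bsum[sel]
  na <- length(cand); ne <- length(els)
  a <- rep(cand, ne); el <- rep(els, each = na)
  keep <- g$elements[a] != el & rep(cb, ne) <= unname(g$valences[el])
  if (!any(keep)) return(no_actions)
  list(n = sum(keep), a = a[keep], element = el[keep])
}

enum_insert_carbon <- function(g, ctx, an) {
  if (an$n >= ctx$max_heavy_atoms || !("C" %in% ctx$allowed_elements)) {
    return(no_actions)
  }
  bonds <- which(upper.tri(g$adj) & g$adj > 0L, arr.ind = TRUE)
  if (nrow(bonds) == 0L) return(no_actions)
  ia <- match(bonds[, 1L], an$alive); ib <- match(bonds[, 2L], an$alive)
  # both endpoints trade a bond of order >= 1 for a single bond: their
  # bond-order sums cannot increase, so no valence check is needed
  keep <- !an$charged[ia] & !an$charged[ib] & (an$mutable[ia] | an$mutable[ib])
  if (!any(keep)) return(no_actions)
  list(n = sum(keep), a = bonds[keep, 1L], b = bonds[keep, 2L])
}

enum_cut <- function(g, ctx, an) {
  deg <- integer(length(an$alive))
  adj_pos <- g$adj[an$alive, an$alive, drop = FALSE] > 0L
  deg <- rowSums(adj_pos)
  cand_pos <- which(deg == 2L & an$mutable & !an$charged)
  keep <- vapply(cand_pos, function(p) {
    nb <- which(adj_pos[p, ])
    adj_pos[nb[1L], nb[2L]] == 0L &&        # neighbours not already bonded
      !an$charged[nb[1L]] && !an$charged[nb[2L]]
  }, logical(1))
  cand <- an$alive[cand_pos[keep]]
  if (length(cand) == 0L) return(no_actions)
  list(n = length(cand), a = cand)
}

enum_move_group <- function(g, ctx, an) {
  G <- integer(0); OLD <- integer(0); NEW <- integer(0); K <- integer(0)
  for (b in an$bridges) {
    for (dir in 1:2) {
      grp <- if (dir == 1L) b$v else b$u        # attachment atom, moved side
      old <- if (dir == 1L) b$u else b$v        # atom losing the bond
      static_side <- if (dir == 1L) b$side_u else b$side_v
      ig <- match(grp, an$alive); io <- match(old, an$alive)
      if (an$charged[ig] || an$charged[io]) next
      if (!(an$mutable[ig] || an$mutable[io])) next
      dests <- setdiff(static_side, old)
      if (length(dests) == 0L) next
      id <- match(dests, an$alive)
      ok <- !an$charged[id] & an$freeval[id] >= b$order &
        (an$mutable[ig] | an$mutable[id])
      if (!any(ok)) next
      d <- dests[ok]
      G <- c(G, rep(grp, length(d))); OLD <- c(OLD, rep(old, length(d)))
      NEW <- c(NEW, d); K <- c(K, rep(b$order, length(d)))
    }
  }
  if (length(G) == 0L) return(no_actions)
  list(n = length(G), g = G, old = OLD, new = NEW, order = K)
}

#' Bridge bonds and the functional groups they delimit
#'
#' A functional group (in the move-group sense) is a subgraph linked to the
#' rest of the molecule by exactly one edge -- a bridge. Every bridge bond is
#' returned with the two atom sets it separates.
#'
#' @param g A valid `molgraph` with at least 2 atoms.
#' @return List of `list(bond = c(u, v), order, side_u, side_v)`; empty when
#'   every edge lies on a ring.
#' @export
bridge_groups <- function(g) {
  an <- mg_analysis(g, action_context(max_heavy_atoms = n_atoms(g) + 1L))
  lapply(an$bridges, function(b) {
    list(bond = c(b$u, b$v), order = b$order,
         side_u = b$side_u, side_v = b$side_v)
  })
}

#' Check a prospective valence change
#'
#' @param g A `molgraph`.
#' @param atom Atom index.
#' @param delta Proposed change to the atom's bond-order sum.
#' @return `TRUE` iff the atom stays within its maximum valence.
#' @export
max_valence_check <- function(g, atom, delta) {
  stopifnot(atom %in% mg_alive(g))
  mg_bond_sum(g, atom) + delta <= mg_max_valence(g, atom)
}

#' Apply an action to a molecular graph
#'
#' The input graph is never modified. `apply_action()` re-checks the
#' structural preconditions the enumerator guarantees (existence, valence,
#' connectivity, size when a context is supplied) and errors on a violation,
#' so applying an action that [enumerate_actions()] would not have produced
#' is a contract violation, not silent corruption.
#'
#' @param g A valid `molgraph`.
#' @param action A `mol_action`.
#' @param ctx Optional [action_context()]; when given, the size limit and
#'   charge/frozen filters are also re-checked.
#' @param check Set to FALSE to skip all re-checks (internal fast path for
#'   actions freshly enumerated on `g`).
#' @return The edited `molgraph`.
#' @examples
#' ethane <- mol_from_smiles("CC")
#' propane <- apply_action(ethane, enumerate_actions(
#'   ethane, "insert_carbon", action_context())[[1]])
#' @export
apply_action <- function(g, action, ctx = NULL, check = TRUE) {
  stopifnot(inherits(action, "mol_action"))
  if (check) check_action(g, action, ctx)
  switch(action$type,
    append_atom = {
      n <- length(g$elements)
      g$elements <- c(g$elements, action$element)
      g$charge <- c(g$charge, 0L)
      g$mutable <- c(g$mutable, TRUE)
      g$adj <- rbind(cbind(g$adj, 0L), 0L)
      g$adj[action$a, n + 1L] <- g$adj[n + 1L, action$a] <- 1L
      g
    },
    remove_atom = {
      g$elements[action$a] <- NA_character_
      g$charge[action$a] <- 0L
      g$mutable[action$a] <- TRUE
      g$adj[action$a, ] <- g$adj[, action$a] <- 0L
      g
    },
    change_bond = {
      g$adj[action$a, action$b] <- g$adj[action$b, action$a] <-
        as.integer(action$order)
      g
    },
    substitute_atom_type = {
      g$elements[action$a] <- action$element
      g
    },
    insert_carbon = {
      n <- length(g$elements)
      g$elements <- c(g$elements, "C")
      g$charge <- c(g$charge, 0L)
      g$mutable <- c(g$mutable, TRUE)
      g$adj <- rbind(cbind(g$adj, 0L), 0L)
      g$adj[action$a, action$b] <- g$adj[action$b, action$a] <- 0L
      g$adj[action$a, n + 1L] <- g$adj[n + 1L, action$a] <- 1L
      g$adj[action$b, n + 1L] <- g$adj[n + 1L, action$b] <- 1L
      g
    },
    cut_atom = {
      nb <- which(g$adj[action$a, ] > 0L)
      g$elements[action$a] <- NA_character_
      g$charge[action$a] <- 0L
      g$mutable[action$a] <- TRUE
      g$adj[action$a, ] <- g$adj[, action$a] <- 0L
      g$adj[nb[1L], nb[2L]] <- g$adj[nb[2L], nb[1L]] <- 1L
      g
    },
    move_group = {
      g$adj[action$g, action$old] <- g$adj[action$old, action$g] <- 0L
      g$adj[action$g, action$new] <- g$adj[action$new, action$g] <-
        as.integer(action$order)
      g
    }
  )
}

check_action <- function(g, action, ctx) {
  alive <- mg_alive(g)
  need_alive <- switch(action$type,
    append_atom = action$a,
    remove_atom = action$a,
    change_bond = c(action$a, action$b),
    substitute_atom_type = action$a,
    insert_carbon = c(action$a, action$b),
    cut_atom = action$a,
    move_group = c(action$g, action$old, action$new)
  )
  if (!all(need_alive %in% alive)) {
    stop("action references unknown atom(s): ", action_label(action))
  }
  fail <- function(why) {
    stop("illegal action ", action_label(action), ": ", why)
  }
  charged <- function(i) g$charge[i] != 0L
  mut <- function(i) {
    g$mutable[i] & !(i %in% (ctx$frozen_atoms %||% integer(0)))
  }
  switch(action$type,
    append_atom = {
      if (free_valence(g, action$a) < 1L) fail("anchor has no free valence")
      if (!(action$element %in% names(g$valences))) fail("unknown element")
      if (charged(action$a)) fail("anchor is charged")
      if (!is.null(ctx)) {
        if (length(alive) >= ctx$max_heavy_atoms) fail("size limit")
        if (!(action$element %in% ctx$allowed_elements)) {
          fail("element not allowed")
        }
      }
    },
    remove_atom = {
      if (length(alive) < 2L) fail("cannot remove the last atom")
      if (would_disconnect(g, atom = action$a)) fail("would disconnect")
      nb <- which(g$adj[action$a, ] > 0L)
      if (any(charged(nb))) fail("neighbouring charged atom")
      if (!is.null(ctx) && !mut(action$a)) fail("atom is frozen")
    },
    change_bond = {
      cur <- g$adj[action$a, action$b]
      if (action$order == cur) fail("bond already has this order")
      if (action$order == 0L) {
        if (cur == 0L) fail("no bond to delete")
        if (would_disconnect(g, bond = c(action$a, action$b))) {
          fail("would disconnect")
        }
      } else if (action$order > cur) {
        inc <- action$order - cur
        if (free_valence(g, action$a) < inc ||
            free_valence(g, action$b) < inc) fail("hypervalence")
      }
      if (any(charged(c(action$a, action$b)))) fail("charged endpoint")
      if (!is.null(ctx) && !any(mut(c(action$a, action$b)))) {
        fail("both endpoints frozen")
      }
    },
    substitute_atom_type = {
      if (identical(g$elements[action$a], action$element)) {
        fail("same element")
      }
      if (!(action$element %in% names(g$valences))) fail("unknown element")
      if (mg_bond_sum(g, action$a) > g$valences[[action$element]]) {
        fail("hypervalence")
      }
      if (charged(action$a)) fail("charged atom")
      if (!is.null(ctx)) {
        if (!(action$element %in% ctx$allowed_elements)) {
          fail("element not allowed")
        }
        if (!mut(action$a)) fail("atom is frozen")
      }
    },
    insert_carbon = {
      if (g$adj[action$a, action$b] < 1L) fail("no bond to insert into")
      if (any(charged(c(action$a, action$b)))) fail("charged endpoint")
      if (!is.null(ctx)) {
        if (length(alive) >= ctx$max_heavy_atoms) fail("size limit")
        if (!("C" %in% ctx$allowed_elements)) fail("carbon not allowed")
        if (!any(mut(c(action$a, action$b)))) fail("both endpoints frozen")
      }
    },
    cut_atom = {
      nb <- which(g$adj[action$a, ] > 0L)
      if (length(nb) != 2L) fail("atom does not have exactly two neighbours")
      if (g$adj[nb[1L], nb[2L]] > 0L) fail("neighbours already bonded")
      if (any(charged(c(action$a, nb)))) fail("charged atom involved")
      if (!is.null(ctx) && !mut(action$a)) fail("atom is frozen")
    },
    move_group = {
      k <- g$adj[action$g, action$old]
      if (k < 1L) fail("no bond to move")
      if (!identical(as.integer(action$order), k)) {
        fail("recorded bond order does not match the graph")
      }
      if (!would_disconnect(g, bond = c(action$g, action$old))) {
        fail("bond is not a bridge")
      }
      # destination must lie on the static side and differ from old anchor
      sides <- bridge_side(g, action$g, action$old)
      if (!(action$new %in% setdiff(sides$static, action$old))) {
        fail("destination not on the static side")
      }
      if (free_valence(g, action$new) < k) fail("hypervalence at destination")
      if (any(charged(c(action$g, action$old, action$new)))) {
        fail("charged atom involved")
      }
      if (!is.null(ctx)) {
        if (!(any(mut(c(action$g, action$old))) &&
              any(mut(c(action$g, action$new))))) fail("frozen atom pair")
      }
    }
  )
  invisible(TRUE)
}

bridge_side <- function(g, grp, old) {
  # atoms reachable from grp without crossing the grp--old bridge
  alive <- mg_alive(g)
  seen <- grp
  frontier <- setdiff(which(g$adj[grp, ] > 0L), old)
  while (length(frontier) > 0L) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(lapply(frontier, function(s) {
      which(g$adj[s, ] > 0L)
    })))
    frontier <- setdiff(nxt, c(seen, old))
  }
  list(moved = sort(seen), static = setdiff(alive, sort(seen)))
}
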