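# Shared fixtures and independent oracles. Everything here is built in code;
# the only file fixture is the synthetic shingle table under inst/extdata.

ctx_default <- function(...) action_context(names(default_valences()), 38L, ...)
ctx_cnof <- function(max_heavy = 38L) {
  action_context(c("C", "N", "O", "F"), max_heavy)
}

# Independent canonicaliser (RDKit) used to cross-check the OpenBabel
# canonical-key route on molecule identity questions.
rdkit_canonical <- function(smiles) {
  mol_properties(smiles, "canonical")$canonical
}

# Random molecule fixture: a seeded random walk of legal actions from
# methane. Used where a *sample* of valid molecules is needed; oracle
# comparisons below re-derive legality independently.
random_molecule <- function(n_actions = 6L, elements = c("C", "N", "O", "F"),
                            max_heavy = 12L) {
  ctx <- action_context(elements, max_heavy)
  g <- mol_from_smiles("C")
  for (i in seq_len(n_actions)) {
    mut <- draw_mutation(g, ctx, max_actions = 1L)
    if (is.null(mut)) break
    g <- mut$graph
  }
  g
}

# ---- brute-force action oracle ---------------------------------------------
# Re-implements "apply every syntactically possible action, keep the valid
# results" with plain adjacency-matrix edits and its own validity test.
# Only meant for uncharged, fully mutable molecules (the charge and frozen
# filters are exercised by dedicated tests).

oracle_valid <- function(elements, adj, valences, max_heavy) {
  alive <- which(!is.na(elements))
  if (length(alive) < 1L || length(alive) > max_heavy) return(FALSE)
  a <- adj[alive, alive, drop = FALSE]
  if (length(alive) > 1L) {
    comps <- igraph::components(igraph::graph_from_adjacency_matrix(
      a > 0, mode = "undirected"))
    if (comps$no != 1L) return(FALSE)
  }
  all(rowSums(a) <= valences[elements[alive]])
}

# every syntactically possible action of one type, as canonical SMILES of
# the (valid) results plus a parameter signature
oracle_enumerate <- function(g, type, ctx) {
  elements <- g$elements
  adj <- g$adj
  val <- g$valences
  alive <- which(!is.na(elements))
  out <- character(0)
  try_result <- function(elements2, adj2, sig) {
    if (oracle_valid(elements2, adj2, val, ctx$max_heavy_atoms)) {
      out[[length(out) + 1L]] <<- sig
    }
  }
  if (type == "append_atom") {
    for (a in alive) for (e in ctx$allowed_elements) {
      n <- length(elements)
      el2 <- c(elements, e)
      adj2 <- rbind(cbind(adj, 0L), 0L)
      adj2[a, n + 1L] <- adj2[n + 1L, a] <- 1L
      try_result(el2, adj2, paste("Ad", a, e))
    }
  } else if (type == "remove_atom") {
    for (a in alive) {
      el2 <- elements; el2[a] <- NA
      adj2 <- adj; adj2[a, ] <- adj2[, a] <- 0L
      try_result(el2, adj2, paste("Rm", a))
    }
  } else if (type == "change_bond") {
    for (a in alive) for (b in alive) {
      if (b <= a) next
      for (k in 0:3) {
        if (k == adj[a, b]) next
        adj2 <- adj; adj2[a, b] <- adj2[b, a] <- k
        try_result(elements, adj2, paste("Ch", a, b, k))
      }
    }
  } else if (type == "substitute_atom_type") {
    for (a in alive) for (e in setdiff(ctx$allowed_elements, elements[a])) {
      el2 <- elements; el2[a] <- e
      try_result(el2, adj, paste("Sub", a, e))
    }
  } else if (type == "insert_carbon") {
    if ("C" %in% ctx$allowed_elements) {
      for (a in alive) for (b in alive) {
        if (b <= a || adj[a, b] == 0L) next
        n <- length(elements)
        el2 <- c(elements, "C")
        adj2 <- rbind(cbind(adj, 0L), 0L)
        adj2[a, b] <- adj2[b, a] <- 0L
        adj2[a, n + 1L] <- adj2[n + 1L, a] <- 1L
        adj2[b, n + 1L] <- adj2[n + 1L, b] <- 1L
        try_result(el2, adj2, paste("In", a, b))
      }
    }
  } else if (type == "cut_atom") {
    for (a in alive) {
      nb <- which(adj[a, ] > 0L)
      if (length(nb) != 2L || adj[nb[1L], nb[2L]] > 0L) next
      el2 <- elements; el2[a] <- NA
      adj2 <- adj; adj2[a, ] <- adj2[, a] <- 0L
      adj2[nb[1L], nb[2L]] <- adj2[nb[2L], nb[1L]] <- 1L
      try_result(el2, adj2, paste("Ct", a))
    }
  } else if (type == "move_group") {
    for (a in alive) for (b in alive) {
      k <- adj[a, b]
      if (b == a || k == 0L) next
      # the moved bond must be a bridge: removing it must split the graph
      adj0 <- adj; adj0[a, b] <- adj0[b, a] <- 0L
      comps <- igraph::components(igraph::graph_from_adjacency_matrix(
        adj0[alive, alive, drop = FALSE] > 0, mode = "undirected"))
      if (comps$no != 2L) next
      side_of <- comps$membership[match(c(a, b), alive)]
      # move the side attached at `a`: destination on b's side, not b itself
      dests <- alive[comps$membership == side_of[2L]]
      for (d in setdiff(dests, b)) {
        adj2 <- adj0
        adj2[a, d] <- adj2[d, a] <- k
        try_result(elements, adj2, paste("Mv", a, b, d))
      }
    }
  }
  sort(out)
}

# signature of an enumerated package action, matching oracle_enumerate
action_signature <- function(a) {
  switch(a$type,
    append_atom = paste("Ad", a$a, a$element),
    remove_atom = paste("Rm", a$a),
    change_bond = paste("Ch", min(a$a, a$b), max(a$a, a$b), a$order),
    substitute_atom_type = paste("Sub", a$a, a$element),
    insert_carbon = paste("In", min(a$a, a$b), max(a$a, a$b)),
    cut_atom = paste("Ct", a$a),
    move_group = paste("Mv", a$g, a$old, a$new)
  )
}

# fast deterministic objective for loop tests: no chemistry backend needed
objective_size_parity <- function() {
  objective_custom(function(g, key) {
    n <- n_atoms(g)
    b <- sum(g$adj[upper.tri(g$adj)])
    n + 0.1 * b + 0.01 * sin(n * 7 + b * 3)
  }, name = "size_parity")
}
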