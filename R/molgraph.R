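# Molecular-graph data model.
#
# Molecules are undirected graphs over heavy atoms only; hydrogens are
# implicit, i.e. every atom is assumed saturated with hydrogens up to its
# maximum valence. Bonds carry integer orders 1-3 (0 = no bond, never
# stored). Atom indices are stable for the lifetime of a molecule: removing
# an atom leaves a hole (NA element slot) rather than re-indexing, so that
# recorded actions stay interpretable after later edits.

#' Default maximum-valence table
#'
#' One maximum valence per element: the sum of explicit bond orders an atom
#' may carry (implicit hydrogens fill the remainder). Hypervalent states of S
#' and P are deliberately excluded so that action filtering is unambiguous;
#' pass your own table to [mol_from_smiles()] / [molgraph()] to change this.
#'
#' @return Named integer vector mapping element symbol to maximum valence.
#' @examples
#' default_valences()
#' @export
default_valences <- function() {
  c(C = 4L, N = 3L, O = 2L, F = 1L, P = 3L, S = 2L, Cl = 1L, Br = 1L)
}

new_molgraph <- function(elements, charge, mutable, adj, valences) {
  structure(
    list(elements = elements, charge = charge, mutable = mutable,
         adj = adj, valences = valences),
    class = "molgraph"
  )
}

#' Construct a molecular graph from atoms and bonds
#'
#' @param elements Character vector of element symbols, one per atom.
#' @param bonds Integer matrix (or data frame) with columns atom1, atom2,
#'   order; may have zero rows.
#' @param charge Integer vector of formal charges (recycled; default 0).
#' @param mutable Logical vector of per-atom mutability flags (recycled).
#' @param valences Maximum-valence table; see [default_valences()].
#' @return A `molgraph` object.
#' @examples
#' propane <- molgraph(c("C", "C", "C"), rbind(c(1, 2, 1), c(2, 3, 1)))
#' @export
molgraph <- function(elements, bonds = NULL, charge = 0L, mutable = TRUE,
                     valences = default_valences()) {
  n <- length(elements)
  stopifnot(n >= 1L)
  unknown <- setdiff(unique(elements), names(valences))
  if (length(unknown) > 0L) {
    stop("element(s) without a valence-table entry: ",
         paste(unknown, collapse = ", "))
  }
  adj <- matrix(0L, n, n)
  if (!is.null(bonds) && NROW(bonds) > 0L) {
    bonds <- as.matrix(bonds)
    storage.mode(bonds) <- "integer"
    stopifnot(ncol(bonds) == 3L, all(bonds[, 3L] %in% 1:3),
              all(bonds[, 1L] != bonds[, 2L]))
    adj[bonds[, 1:2, drop = FALSE]] <- bonds[, 3L]
    adj[bonds[, 2:1, drop = FALSE]] <- bonds[, 3L]
  }
  g <- new_molgraph(as.character(elements),
                    as.integer(rep_len(charge, n)),
                    rep_len(as.logical(mutable), n),
                    adj, valences)
  ok <- mol_is_valid(g)
  if (!ok) {
    stop("invalid molecular graph: ",
         paste(attr(ok, "violations"), collapse = "; "))
  }
  g
}

# indices of live atom slots (holes are NA elements)
mg_alive <- function(g) which(!is.na(g$elements))

#' Number of (heavy) atoms in a molecular graph
#' @param g A `molgraph`.
#' @return Integer atom count.
#' @export
n_atoms <- function(g) length(mg_alive(g))

# effective maximum valence per live slot: table valence adjusted by formal
# charge (isoelectronic rule: N+ binds like C, O- binds like F), floored at 0.
mg_max_valence <- function(g, idx = mg_alive(g)) {
  pmax(0L, unname(g$valences[g$elements[idx]]) + g$charge[idx])
}

# sum of explicit bond orders per slot
mg_bond_sum <- function(g, idx = mg_alive(g)) {
  if (length(idx) == 1L) sum(g$adj[idx, ]) else rowSums(g$adj[idx, , drop = FALSE])
}

#' Free valence of atoms
#'
#' Maximum valence minus the sum of incident explicit bond orders; for a
#' neutral atom this equals its implicit hydrogen count.
#'
#' @param g A `molgraph`.
#' @param idx Atom indices (default: all atoms).
#' @return Integer vector of free valences.
#' @examples
#' free_valence(mol_from_smiles("C"))      # 4
#' free_valence(mol_from_smiles("C=O"), 2) # 0
#' @export
free_valence <- function(g, idx = mg_alive(g)) {
  if (any(is.na(g$elements[idx]))) stop("unknown atom index")
  mg_max_valence(g, idx) - mg_bond_sum(g, idx)
}

mg_igraph <- function(g) {
  alive <- mg_alive(g)
  a <- g$adj[alive, alive, drop = FALSE] > 0L
  ig <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  igraph::set_vertex_attr(ig, "slot", value = alive)
}

mg_connected <- function(g) {
  alive <- mg_alive(g)
  if (length(alive) <= 1L) return(length(alive) == 1L)
  igraph::is_connected(mg_igraph(g))
}

#' Validity of a molecular graph
#'
#' A graph is valid iff it has at least one atom, is connected, and no atom
#' exceeds its maximum valence (the only valence inconsistency possible with
#' implicit hydrogens is hypervalence).
#'
#' @param g A `molgraph`.
#' @return Logical scalar; on `FALSE` the attribute `"violations"` lists the
#'   problems found.
#' @export
mol_is_valid <- function(g) {
  violations <- character(0)
  alive <- mg_alive(g)
  if (length(alive) == 0L) {
    violations <- "empty graph"
  } else {
    if (!mg_connected(g)) violations <- c(violations, "disconnected graph")
    over <- alive[mg_bond_sum(g) > mg_max_valence(g)]
    if (length(over) > 0L) {
      violations <- c(violations, paste0(
        "hypervalent atom(s): ",
        paste0(g$elements[over], over, collapse = ", ")))
    }
  }
  structure(length(violations) == 0L, violations = violations)
}

#' Would removing an atom or a bond disconnect the graph?
#'
#' Answers by brute force: performs the deletion on a copy and recounts
#' connected components. Used by the dislocation filter's reference semantics
#' (the action enumerator itself uses articulation points / bridge edges).
#'
#' @param g A `molgraph`.
#' @param atom Atom index to delete (with its bonds), or `NULL`.
#' @param bond Length-2 atom index vector whose bond is set to order 0, or
#'   `NULL`. Exactly one of `atom`/`bond` must be given.
#' @return `TRUE` iff the edit leaves more than one connected component, or
#'   no atoms at all.
#' @export
would_disconnect <- function(g, atom = NULL, bond = NULL) {
  stopifnot(xor(is.null(atom), is.null(bond)))
  adj <- g$adj
  alive <- mg_alive(g)
  if (!is.null(atom)) {
    stopifnot(atom %in% alive)
    alive <- setdiff(alive, atom)
    if (length(alive) == 0L) return(TRUE)
  } else {
    stopifnot(length(bond) == 2L, all(bond %in% alive),
              adj[bond[1L], bond[2L]] > 0L)
    adj[bond[1L], bond[2L]] <- 0L
    adj[bond[2L], bond[1L]] <- 0L
  }
  a <- adj[alive, alive, drop = FALSE] > 0L
  comps <- igraph::components(
    igraph::graph_from_adjacency_matrix(a, mode = "undirected"))
  comps$no > 1L
}

#' Freeze atoms against mutation
#'
#' Marks atoms as immutable so the frozen-core action filter applies to them
#' (used e.g. to grow substituents around a fixed aromatic core).
#'
#' @param g A `molgraph`.
#' @param idx Atom indices to freeze.
#' @return The modified `molgraph`.
#' @export
freeze_atoms <- function(g, idx) {
  stopifnot(all(idx %in% mg_alive(g)))
  g$mutable[idx] <- FALSE
  g
}

#' Parse a SMILES string into a molecular graph
#'
#' Parsing, kekulisation and charge perception are delegated to OpenBabel.
#' Implicit hydrogens are dropped; aromatic systems are stored in a Kekule
#' form (aromaticity only reappears at the canonical-key boundary). Ions and
#' zwitterions are accepted; multi-fragment or hypervalent input is rejected.
#'
#' @param smiles SMILES character scalar.
#' @param valences Maximum-valence table; every element of the molecule must
#'   have an entry.
#' @param mutable Logical: initial mutability flag for all atoms.
#' @return A `molgraph`.
#' @examples
#' mol_from_smiles("CCO")
#' @export
mol_from_smiles <- function(smiles, valences = default_valences(),
                            mutable = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  mb <- tryCatch(ChemmineOB::convertFormat("SMI", "MOL", smiles),
                 error = function(e) "")
  parsed <- parse_molblock(mb)
  if (is.null(parsed)) stop("could not parse SMILES: ", smiles)
  elements <- parsed$elements
  charge <- parsed$charge
  n <- length(elements)
  unknown <- setdiff(unique(elements), names(valences))
  if (length(unknown) > 0L) {
    stop("SMILES \"", smiles, "\" contains element(s) without a ",
         "valence-table entry: ", paste(unknown, collapse = ", "))
  }
  adj <- matrix(0L, n, n)
  if (NROW(parsed$bonds) > 0L) {
    bm <- parsed$bonds
    adj[bm[, 1:2, drop = FALSE]] <- bm[, 3L]
    adj[bm[, 2:1, drop = FALSE]] <- bm[, 3L]
  }
  g <- new_molgraph(elements, charge, rep_len(as.logical(mutable), n),
                    adj, valences)
  if (n > 1L && !mg_connected(g)) {
    stop("multi-fragment SMILES rejected: ", smiles)
  }
  over <- mg_alive(g)[mg_bond_sum(g) > mg_max_valence(g)]
  if (length(over) > 0L) {
    stop("hypervalent input rejected (", smiles, "): atom(s) ",
         paste0(elements[over], over, collapse = ", "),
         " exceed the valence table")
  }
  g
}

# Minimal V2000 molblock reader for OpenBabel output. (The ChemmineR SDF
# container refuses bond-less records, which rules out single-atom molecules
# such as methane -- the canonical seed -- hence this direct read.)
# Returns NULL when the text is not a molblock.
parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 4L || !grepl("V2000", lines[4L], fixed = TRUE)) {
    return(NULL)
  }
  n <- as.integer(substr(lines[4L], 1L, 3L))
  m <- as.integer(substr(lines[4L], 4L, 6L))
  if (is.na(n) || n < 1L) return(NULL)
  atom_lines <- lines[4L + seq_len(n)]
  elements <- trimws(substr(atom_lines, 32L, 34L))
  # old-style per-atom charge codes (superseded by M CHG when present)
  code <- suppressWarnings(as.integer(substr(atom_lines, 37L, 39L)))
  code_map <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L,
                `7` = -3L)
  charge <- integer(n)
  hit <- which(code %in% as.integer(names(code_map)))
  charge[hit] <- code_map[as.character(code[hit])]
  bonds <- matrix(integer(0), 0L, 3L)
  if (!is.na(m) && m > 0L) {
    bond_lines <- lines[4L + n + seq_len(m)]
    bonds <- cbind(as.integer(substr(bond_lines, 1L, 3L)),
                   as.integer(substr(bond_lines, 4L, 6L)),
                   as.integer(substr(bond_lines, 7L, 9L)))
  }
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines) > 0L) {
    charge <- integer(n)   # M CHG supersedes all atom-block codes
    for (cl in chg_lines) {
      k <- as.integer(substr(cl, 7L, 9L))
      for (i in seq_len(k)) {
        off <- 10L + (i - 1L) * 8L
        at <- as.integer(substr(cl, off, off + 3L))
        charge[at] <- as.integer(substr(cl, off + 4L, off + 7L))
      }
    }
  }
  list(elements = elements, charge = charge, bonds = bonds)
}

#' Serialise a molecular graph to an MDL molblock
#'
#' @param g A `molgraph`.
#' @return Character scalar holding a V2000 molblock (coordinates all zero;
#'   formal charges carried on `M  CHG` lines).
#' @export
mol_to_molblock <- function(g) {
  alive <- mg_alive(g)
  pos <- match(seq_along(g$elements), alive)   # slot -> molblock index
  n <- length(alive)
  ut <- which(upper.tri(g$adj) & g$adj > 0L, arr.ind = TRUE)
  ut <- ut[ut[, 1L] %in% alive & ut[, 2L] %in% alive, , drop = FALSE]
  lines <- c(
    "", " molevolve", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(ut)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, g$elements[alive])
  )
  if (nrow(ut) > 0L) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              pos[ut[, 1L]], pos[ut[, 2L]],
                              g$adj[ut]))
  }
  chg <- which(g$charge != 0L & !is.na(g$elements))
  while (length(chg) > 0L) {
    take <- chg[seq_len(min(8L, length(chg)))]
    chg <- chg[-seq_along(take)]
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(take)),
                             paste0(sprintf("%4d%4d", pos[take],
                                            g$charge[take]), collapse = "")))
  }
  paste(c(lines, "M  END", ""), collapse = "\n")
}

#' Canonical key (canonical aromatic SMILES) of a molecule
#'
#' The canonical aromatic SMILES is the molecular identity used everywhere:
#' population uniqueness, objective caches and exploration-tree nodes. Kekule
#' variants of the same aromatic system collapse to the same key.
#'
#' @param g A `molgraph`.
#' @return Character scalar.
#' @examples
#' canonical_key(mol_from_smiles("OCC")) == canonical_key(mol_from_smiles("CCO"))
#' @export
canonical_key <- function(g) {
  ob_convert("MOL", "CAN", mol_to_molblock(g))
}

#' @rdname canonical_key
#' @export
mol_to_smiles <- canonical_key

#' Tabular views of a molecular graph
#'
#' @param g A `molgraph`.
#' @return `mol_atoms()`: a tibble with one row per atom (index, element,
#'   charge, mutable, free_valence); `mol_bonds()`: a tibble with one row per
#'   bond (atom1, atom2, order).
#' @export
mol_atoms <- function(g) {
  alive <- mg_alive(g)
  tibble::tibble(
    index = alive,
    element = g$elements[alive],
    charge = g$charge[alive],
    mutable = g$mutable[alive],
    free_valence = free_valence(g, alive)
  )
}

#' @rdname mol_atoms
#' @export
mol_bonds <- function(g) {
  ut <- which(upper.tri(g$adj) & g$adj > 0L, arr.ind = TRUE)
  tibble::tibble(
    atom1 = as.integer(ut[, 1L]),
    atom2 = as.integer(ut[, 2L]),
    order = g$adj[ut]
  )
}

#' @export
print.molgraph <- function(x, ...) {
  alive <- mg_alive(x)
  cat("<molgraph> ", length(alive), " atoms, ",
      sum(x$adj[alive, alive, drop = FALSE] > 0L) / 2L, " bonds: ",
      canonical_key(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.molgraph <- function(x, ...) canonical_key(x)
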