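test_that("hand-checked enumerations on small molecules", {
  ctx <- ctx_cnof()
  methane <- mol_from_smiles("C")
  expect_length(enumerate_actions(methane, "append_atom", ctx), 4L)
  expect_length(enumerate_actions(methane, "change_bond", ctx), 0L)
  expect_length(enumerate_actions(methane, "remove_atom", ctx), 0L)

  ethane <- mol_from_smiles("CC")
  ch <- enumerate_actions(ethane, "change_bond", ctx)
  # single -> double and single -> triple; single -> none would disconnect
  expect_setequal(vapply(ch, `[[`, numeric(1), "order"), c(2, 3))
})

test_that("applying actions yields the documented products", {
  ctx <- ctx_cnof()
  ethane <- mol_from_smiles("CC")
  ins <- enumerate_actions(ethane, "insert_carbon", ctx)
  expect_length(ins, 1L)
  expect_identical(canonical_key(apply_action(ethane, ins[[1]])), "CCC")

  methane <- mol_from_smiles("C")
  sub_n <- Filter(function(a) a$element == "N",
                  enumerate_actions(methane, "substitute_atom_type", ctx))
  expect_identical(canonical_key(apply_action(methane, sub_n[[1]])), "N")

  butane <- mol_from_smiles("CCCC")
  closing <- Filter(function(a) a$order == 1L && a$from == 0L &&
                      abs(a$a - a$b) == 3L,
                    enumerate_actions(butane, "change_bond", ctx))
  expect_length(closing, 1L)
  expect_identical(canonical_key(apply_action(butane, closing[[1]])),
                   "C1CCC1")
})

test_that("apply_action refuses actions the enumerator would not produce", {
  ctx <- ctx_cnof()
  propane <- mol_from_smiles("CCC")
  # removing the articulation atom dislocates the graph
  bad_rm <- structure(list(type = "remove_atom", a = 2L),
                      class = "mol_action")
  expect_error(apply_action(propane, bad_rm), "disconnect")
  # pushing a saturated O into hypervalence
  formaldehyde <- mol_from_smiles("C=O")
  bad_ch <- structure(list(type = "change_bond", a = 1L, b = 2L,
                           order = 3L, from = 2L), class = "mol_action")
  expect_error(apply_action(formaldehyde, bad_ch), "hypervalence")
  # unknown atom
  bad_ap <- structure(list(type = "append_atom", a = 9L, element = "C"),
                      class = "mol_action")
  expect_error(apply_action(propane, bad_ap), "unknown atom")
})

test_that("bridge detection matches the functional-group definition", {
  propanol <- mol_from_smiles("CCCO")
  at <- mol_atoms(propanol)
  o <- at$index[at$element == "O"]
  br <- bridge_groups(propanol)
  co <- Filter(function(b) o %in% b$bond, br)[[1]]
  sides <- list(co$side_u, co$side_v)
  lens <- sort(lengths(sides))
  expect_equal(lens, c(1L, 3L))
  expect_true(any(vapply(sides, function(s) identical(s, o), logical(1))))

  expect_length(bridge_groups(mol_from_smiles("C1CCCCC1")), 0L)

  toluene <- mol_from_smiles("Cc1ccccc1")
  br <- bridge_groups(toluene)
  expect_length(br, 1L)
  expect_equal(sort(unname(lengths(br[[1]][c("side_u", "side_v")]))),
               c(1L, 6L))
})

test_that("max_valence_check reflects free valence", {
  expect_true(max_valence_check(mol_from_smiles("C"), 1L, 1L))
  formaldehyde <- mol_from_smiles("C=O")
  o <- mol_atoms(formaldehyde)$index[
    mol_atoms(formaldehyde)$element == "O"]
  expect_false(max_valence_check(formaldehyde, o, 1L))
  expect_true(max_valence_check(mol_from_smiles("N"), 1L, 3L))
})

test_that("every enumerated action yields a valid graph within the limit", {
  set.seed(101)
  ctx <- action_context(c("C", "N", "O", "F"), max_heavy_atoms = 12L)
  for (rep in 1:8) {
    g <- random_molecule(n_actions = sample(2:8, 1))
    for (type in names(action_types())) {
      for (a in enumerate_actions(g, type, ctx)) {
        res <- apply_action(g, a, ctx = ctx)
        expect_true(mol_is_valid(res), info = action_label(a))
        expect_lte(n_atoms(res), ctx$max_heavy_atoms)
      }
    }
  }
})

test_that("enumeration equals the brute-force apply-and-check oracle", {
  set.seed(202)
  ctx <- action_context(c("C", "N", "O", "F"), max_heavy_atoms = 7L)
  samples <- c(
    list(mol_from_smiles("C"), mol_from_smiles("CC"),
         mol_from_smiles("C1CC1"),          # ring
         mol_from_smiles("C=O"),            # saturated oxygen
         mol_from_smiles("C#N"),            # triple bond
         mol_from_smiles("C1OC1C")),        # heteroring + substituent
    lapply(1:10, function(i) random_molecule(n_actions = sample(2:5, 1),
                                             max_heavy = 6L))
  )
  for (g in samples) {
    for (type in names(action_types())) {
      enumerated <- sort(vapply(enumerate_actions(g, type, ctx),
                                action_signature, character(1)))
      expect_identical(enumerated, oracle_enumerate(g, type, ctx),
                       info = paste(canonical_key(g), type))
    }
  }
})

test_that("primary actions are reversible and counts shift as defined", {
  set.seed(303)
  ctx <- action_context(c("C", "N", "O", "F"), max_heavy_atoms = 13L)
  for (rep in 1:6) {
    g <- random_molecule(n_actions = sample(3:7, 1))
    key <- canonical_key(g)
    an_count <- n_atoms(g)
    for (a in enumerate_actions(g, "append_atom", ctx)) {
      res <- apply_action(g, a)
      expect_equal(n_atoms(res), an_count + 1L)
      new_slot <- setdiff(mol_atoms(res)$index, mol_atoms(g)$index)
      rm_back <- Filter(function(r) r$a == new_slot,
                        enumerate_actions(res, "remove_atom", ctx))
      expect_length(rm_back, 1L)
      expect_identical(canonical_key(apply_action(res, rm_back[[1]])), key)
    }
    for (a in enumerate_actions(g, "insert_carbon", ctx)) {
      res <- apply_action(g, a)
      expect_equal(n_atoms(res), n_atoms(g) + 1L)
      new_slot <- setdiff(mol_atoms(res)$index, mol_atoms(g)$index)
      ct_back <- Filter(function(r) r$a == new_slot,
                        enumerate_actions(res, "cut_atom", ctx))
      if (length(ct_back) == 1L) {
        expect_identical(canonical_key(apply_action(res, ct_back[[1]])), key)
      }
    }
    for (a in enumerate_actions(g, "change_bond", ctx)) {
      res <- apply_action(g, a)
      back <- Filter(function(r) r$a == a$a && r$b == a$b &&
                       r$order == a$from,
                     enumerate_actions(res, "change_bond", ctx))
      expect_length(back, 1L)
      expect_identical(canonical_key(apply_action(res, back[[1]])), key)
    }
    for (a in enumerate_actions(g, "cut_atom", ctx)) {
      expect_equal(n_atoms(apply_action(g, a)), n_atoms(g) - 1L)
    }
    for (a in enumerate_actions(g, "move_group", ctx)) {
      res <- apply_action(g, a)
      expect_equal(n_atoms(res), n_atoms(g))
      expect_identical(sort(mol_atoms(res)$element),
                       sort(mol_atoms(g)$element))
      expect_identical(res$adj[a$g, a$new], g$adj[a$g, a$old])
    }
  }
})

test_that("charged-atom filter protects ionic bonds, removal excepted", {
  ctx <- ctx_default()
  zw <- mol_from_smiles("[O-]C(=O)C[NH3+]")
  at <- mol_atoms(zw)
  charged <- at$index[at$charge != 0L]
  neighbours_of <- function(g, i) which(g$adj[i, ] > 0L)
  for (type in names(action_types())) {
    for (a in enumerate_actions(zw, type, ctx)) {
      touched <- switch(a$type,
        append_atom = a$a,
        remove_atom = setdiff(c(a$a, neighbours_of(zw, a$a)), a$a),
        change_bond = c(a$a, a$b),
        substitute_atom_type = a$a,
        insert_carbon = c(a$a, a$b),
        cut_atom = c(a$a, neighbours_of(zw, a$a)),
        move_group = c(a$g, a$old, a$new)
      )
      expect_length(intersect(touched, charged), 0L)
    }
  }
  # the charged atoms themselves can be removed (ionic subgraph removal) --
  # here the N+ is a leaf whose removal is legal, its neighbour is uncharged
  rm_targets <- vapply(enumerate_actions(zw, "remove_atom", ctx),
                       `[[`, integer(1), "a")
  expect_true(at$index[at$element == "N"] %in% rm_targets)
})

test_that("frozen-atom rules restrict the action space as specified", {
  ctx <- ctx_cnof()
  furane <- mol_from_smiles("c1ccoc1")
  frozen <- freeze_atoms(furane, mol_atoms(furane)$index)
  # substitute and cut need a mutable atom: none left
  expect_length(enumerate_actions(frozen, "substitute_atom_type", ctx), 0L)
  expect_length(enumerate_actions(frozen, "cut_atom", ctx), 0L)
  expect_length(enumerate_actions(frozen, "remove_atom", ctx), 0L)
  # pairs need at least one mutable member: none within the frozen core
  expect_length(enumerate_actions(frozen, "change_bond", ctx), 0L)
  expect_length(enumerate_actions(frozen, "insert_carbon", ctx), 0L)
  # appending to a frozen core is allowed (that is how cores are decorated)
  expect_gt(length(enumerate_actions(frozen, "append_atom", ctx)), 0L)

  # grow a substituent: actions pairing it with the core become legal again
  ap <- enumerate_actions(frozen, "append_atom", ctx)[[1]]
  grown <- apply_action(frozen, ap)
  expect_gt(length(enumerate_actions(grown, "change_bond", ctx)), 0L)
  for (a in enumerate_actions(grown, "substitute_atom_type", ctx)) {
    expect_true(grown$mutable[a$a])
  }
})

test_that("context frozen_atoms behaves like per-atom immutability", {
  base <- mol_from_smiles("CCO")
  ctx_frozen <- action_context(c("C", "N", "O", "F"), 38L,
                               frozen_atoms = mol_atoms(base)$index)
  expect_length(enumerate_actions(base, "substitute_atom_type", ctx_frozen),
                0L)
  via_flags <- freeze_atoms(base, mol_atoms(base)$index)
  expect_identical(
    length(enumerate_actions(base, "change_bond", ctx_frozen)),
    length(enumerate_actions(via_flags, "change_bond", ctx_cnof())))
})

test_that("extra filters drop matching actions", {
  ctx <- action_context(c("C", "N", "O", "F"), 38L,
                        extra_filters = list(function(g, a) {
                          !(a$type == "append_atom" && a$element == "F")
                        }))
  methane <- mol_from_smiles("C")
  els <- vapply(enumerate_actions(methane, "append_atom", ctx),
                `[[`, character(1), "element")
  expect_setequal(els, c("C", "N", "O"))
})

test_that("action labels follow the short-code convention", {
  expect_equal(unname(action_types()),
               c("Ad", "Rm", "Ch", "Sub", "In", "Ct", "Mv"))
  ctx <- ctx_cnof()
  eth <- mol_from_smiles("CC")
  a <- enumerate_actions(eth, "change_bond", ctx)[[1]]
  expect_match(action_label(a), "^Ch\\(1,2,1->[23]\\)$")
  expect_identical(action_label(a, short = TRUE), "Ch")
})
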