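test_that("evaluation counter counts distinct molecules only", {
  obj <- objective_qed()
  g <- mol_from_smiles("c1ccccc1")
  r1 <- evaluate_objective(obj, g)
  r2 <- evaluate_objective(obj, g)
  expect_identical(r1$score, r2$score)
  expect_true(r2$cached)
  evals <- objective_evaluations(obj)
  expect_identical(as.integer(evals), 1L)
  expect_identical(attr(evals, "calls"), 2L)
  # a second, distinct molecule
  evaluate_objective(obj, mol_from_smiles("CCO"))
  expect_identical(as.integer(objective_evaluations(obj)), 2L)
})

test_that("qed delegates to the published definition", {
  g <- mol_from_smiles("c1ccccc1")
  ours <- evaluate_objective(objective_qed(), g)$score
  expect_gt(ours, 0); expect_lt(ours, 1)
  # independent route: straight SMILES into the backend
  ref <- mol_properties("c1ccccc1", "qed")$qed
  expect_equal(ours, ref, tolerance = 1e-6)
  m <- evaluate_objective(objective_qed(), mol_from_smiles("C"))$score
  expect_gt(m, 0); expect_lt(m, 1)
})

test_that("sascore normalisation maps [1,10] onto [1,0]", {
  expect_equal(sascore_normalise(1), 1)
  expect_equal(sascore_normalise(10), 0)
  expect_equal(sascore_normalise(5.5), 0.5)
  g <- mol_from_smiles("CCO")
  raw <- evaluate_objective(objective_sascore(normalised = FALSE), g)$score
  norm <- evaluate_objective(objective_sascore(normalised = TRUE), g)$score
  expect_equal(norm, (10 - raw) / 9, tolerance = 1e-9)
})

test_that("penalised logP assembles its components as defined", {
  # no ring penalty up to 6-membered rings
  hexane_ring <- mol_from_smiles("C1CCCCC1")
  r <- evaluate_objective(objective_plogp(), hexane_ring)
  expect_equal(unname(r$sub["ring_penalty"]), 0)
  # cyclodecane: 10-ring costs 4
  r10 <- evaluate_objective(objective_plogp(), mol_from_smiles("C1CCCCCCCCC1"))
  expect_equal(unname(r10$sub["ring_penalty"]), 4)
  # methane: logP - SA, matching the component oracles
  p <- mol_properties("C", c("logp", "sa"))
  m <- evaluate_objective(objective_plogp(), mol_from_smiles("C"))
  expect_equal(m$score, p$logp - p$sa, tolerance = 1e-6)
})

test_that("degenerate normalisation constants reproduce the raw plogP", {
  flat <- list(logp_mean = 0, logp_sd = 1, sa_mean = 0, sa_sd = 1,
               ring_mean = 0, ring_sd = 1)
  for (s in c("C", "CCO", "C1CCCCCCCCC1", "FC(F)F")) {
    g <- mol_from_smiles(s)
    raw <- evaluate_objective(objective_plogp(normalised = FALSE), g)$score
    z <- evaluate_objective(objective_plogp(normalised = TRUE,
                                            constants = flat), g)$score
    expect_equal(z, raw, tolerance = 1e-9)
  }
})

test_that("shingles of a small molecule match a hand enumeration", {
  # CCO: radius-1 neighbourhoods are C-C, C-C-O, C-O; radius 2 and 3 all
  # cover the whole molecule -> distinct shingles {CC, CCO, CO}
  sh <- molecule_shingles(mol_from_smiles("CCO"), 3)
  expect_setequal(sh, c("CC", "CCO", "CO"))
  # methane has no bond, hence no shingle
  expect_length(molecule_shingles(mol_from_smiles("C"), 3), 0L)
})

test_that("clscore is the mean shingle weight, zero for unknowns", {
  tab <- shingle_table(c(CC = 1, CO = 2, CCO = 3), radius_max = 3)
  g <- mol_from_smiles("CCO")
  expect_equal(evaluate_objective(objective_clscore(tab), g)$score, 2)
  # constant weights: mean equals the constant
  tab_w <- shingle_table(c(CC = 0.7, CO = 0.7, CCO = 0.7), radius_max = 3)
  expect_equal(evaluate_objective(objective_clscore(tab_w), g)$score, 0.7)
  # molecule sharing no shingle with the table scores 0
  tab_other <- shingle_table(c(NN = 5), radius_max = 3)
  expect_equal(evaluate_objective(objective_clscore(tab_other), g)$score, 0)
  # no shingles at all scores 0
  expect_equal(evaluate_objective(objective_clscore(tab),
                                  mol_from_smiles("C"))$score, 0)
})

test_that("clscore is invariant under SMILES rewriting", {
  tab <- read_shingle_table(system.file("extdata",
                                        "shingle_weights_synthetic.tsv",
                                        package = "molevolve"))
  a <- evaluate_objective(objective_clscore(tab), mol_from_smiles("CCO"))
  b <- evaluate_objective(objective_clscore(tab), mol_from_smiles("OCC"))
  expect_identical(a$score, b$score)
  expect_gt(a$score, 0)
})

test_that("shingle tables round-trip through TSV and JSON", {
  tab <- shingle_table(c(CC = 1.25, `c1ccccc1` = 2.5), radius_max = 2)
  tsv <- tempfile(fileext = ".tsv"); json <- tempfile(fileext = ".json")
  write_shingle_table(tab, tsv)
  write_shingle_table(tab, json)
  back_tsv <- read_shingle_table(tsv, radius_max = 2)
  back_json <- read_shingle_table(json)
  expect_equal(back_tsv$weights[names(tab$weights)], tab$weights)
  expect_equal(back_json$weights[names(tab$weights)], tab$weights)
  expect_identical(back_json$radius_max, 2L)
})

test_that("sigmoid shapes evaluate to 0.5 at their centers", {
  expect_identical(eval_sigmoid(1.5, sigmoid_chembl_likeness()), 0.5)
  expect_identical(eval_sigmoid(0, sigmoid_lumo()), 0.5)
  expect_identical(eval_sigmoid(-7, sigmoid_homo()), 0.5)
  # orientation: the likeness gate rises, the LUMO shape falls
  expect_gt(eval_sigmoid(3, sigmoid_chembl_likeness()), 0.99)
  expect_lt(eval_sigmoid(0, sigmoid_chembl_likeness()), 0.01)
  expect_lt(eval_sigmoid(5, sigmoid_lumo()), 0.01)
  # outputs strictly inside (0, 1) over the representable range
  for (x in c(-8, 0, 8)) {
    v <- eval_sigmoid(x, sigmoid_spec(2, 1, -1))
    expect_gt(v, 0); expect_lt(v, 1)
  }
})

test_that("composite objectives multiply their factor sigmoids", {
  half_a <- objective_custom(function(g, key) 1.5, "a")
  half_b <- objective_custom(function(g, key) 0, "b")
  comp <- objective_composite(list(
    likeness = list(objective = half_a, sigmoid = sigmoid_chembl_likeness()),
    lumo = list(objective = half_b, sigmoid = sigmoid_lumo())
  ), name = "both")
  r <- evaluate_objective(comp, mol_from_smiles("C"))
  expect_equal(r$score, 0.25)
  expect_equal(unname(r$sub["likeness_sigmoid"]), 0.5)
  expect_equal(unname(r$sub["lumo"]), 0)
  # monotone in an increasing factor's property
  up <- function(x) {
    o <- objective_custom(function(g, key) x, "x")
    evaluate_objective(
      objective_composite(list(list(objective = o,
                                    sigmoid = sigmoid_chembl_likeness()))),
      mol_from_smiles("C"))$score
  }
  xs <- c(0, 1, 1.5, 2, 3)
  expect_true(all(diff(vapply(xs, up, numeric(1))) > 0))
})

test_that("hard constraints reject before scoring, without counting", {
  base <- objective_size_parity()
  always <- objective_constrained(objective_size_parity(), function(g) TRUE)
  g <- mol_from_smiles("CCO")
  expect_identical(evaluate_objective(always, g)$score,
                   evaluate_objective(base, g)$score)

  never <- objective_constrained(objective_size_parity(), function(g) FALSE)
  r <- evaluate_objective(never, g)
  expect_true(r$reject)
  expect_identical(as.integer(objective_evaluations(never)), 0L)

  no_fluorine <- objective_constrained(
    objective_size_parity(), function(g) !("F" %in% mol_atoms(g)$element))
  rf <- evaluate_objective(no_fluorine, mol_from_smiles("CF"))
  expect_true(rf$reject)
  expect_identical(as.integer(objective_evaluations(no_fluorine)), 0L)
  ok <- evaluate_objective(no_fluorine, mol_from_smiles("CC"))
  expect_false(ok$reject)
  expect_identical(as.integer(objective_evaluations(no_fluorine)), 1L)
})

test_that("constrained runs only ever insert admissible molecules", {
  no_n <- objective_constrained(
    objective_size_parity(), function(g) !("N" %in% mol_atoms(g)$element))
  run <- evo_run(no_n, "C",
                 evo_config(capacity = 5, n_replaced = 2, max_steps = 12,
                            seed = 31, allowed_elements = c("C", "N", "O"),
                            max_heavy_atoms = 8))
  expect_gt(nrow(run$population), 1L)
  expect_false(any(grepl("N", run$population$smiles, fixed = TRUE)))
  # a constraint admitting only the seed stalls the run at the seed
  only_seed <- objective_constrained(
    objective_size_parity(),
    function(g) n_atoms(g) == 1L && all(mol_atoms(g)$element == "C"))
  stalled <- evo_run(only_seed, "C",
                     evo_config(capacity = 3, n_replaced = 1, max_steps = 3,
                                seed = 1))
  expect_identical(stalled$population$smiles, "C")
  expect_identical(as.integer(stalled$evaluations), 1L)
  # an inadmissible seed is refused outright
  never <- objective_constrained(objective_size_parity(), function(g) FALSE)
  expect_error(evo_run(never, "C", evo_config(capacity = 3, n_replaced = 1,
                                              max_steps = 3, seed = 1)),
               "rejected")
})

test_that("external evaluators distinguish failure from low scores", {
  flaky <- objective_external(function(smiles) {
    if (grepl("O", smiles, fixed = TRUE)) NA_real_ else nchar(smiles)
  }, name = "flaky")
  ok <- evaluate_objective(flaky, mol_from_smiles("CC"))
  expect_false(ok$reject); expect_identical(ok$score, 2)
  bad <- evaluate_objective(flaky, mol_from_smiles("CO"))
  expect_true(bad$reject)
  expect_true(is.na(bad$score))
  # errors count as failures too
  thrower <- objective_external(function(smiles) stop("boom"), "thrower")
  expect_true(evaluate_objective(thrower, mol_from_smiles("C"))$reject)
})

test_that("the toy electronic surrogate is deterministic and structural", {
  ev <- toy_electronic_evaluator()
  expect_identical(ev("CCO"), ev("CCO"))
  expect_identical(ev("CCO"), -1)        # one heteroatom, no multiple bond
  expect_identical(ev("C=O"), -0.5)      # one heteroatom, one double bond
  # wired through the composite, it drives a runnable case-study objective
  comp <- objective_composite(list(
    lumo = list(objective = objective_external(ev, "toy_lumo"),
                sigmoid = sigmoid_lumo())
  ), name = "toy_lumo_sigmoid")
  r <- evaluate_objective(comp, mol_from_smiles("C=O"))
  expect_equal(r$score, 1 / (1 + exp(-0.5)), tolerance = 1e-12)
})
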