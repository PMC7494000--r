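# molevolve

Evolutionary generation and optimisation of molecular graphs in R.

De novo molecular design asks for molecules that maximise a property — a
drug-likeness score, a synthesizability estimate, an electronic property —
out of a chemical space far too large to enumerate. `molevolve` explores
that space with an evolutionary algorithm that edits molecular graphs
directly: a population of up to λ unique molecules is repeatedly improved by
mutating its best members to replace its worst, under a *first improver*
policy (a mutant is inserted as soon as its score f(x′) ≥ f(x_replaced);
equal scores are accepted so plateaus remain traversable). With λ = 1 the
method reduces to a hill climber. A mutation applies k ~ U{1..k_max} graph
actions drawn uniformly from the seven atom-level operators

> append atom · remove atom · change bond (including ring closure) ·
> substitute atom type · insert carbon · cut atom · move group

filtered *a priori* so that every candidate is a connected, valence-correct
molecule within the configured element set and size limit. Uniqueness is
enforced by canonical aromatic SMILES, and every accepted improver is
recorded in an exploration tree whose edges carry the applied actions — the
whole search remains inspectable afterwards.

Built-in objectives: QED, synthetic-accessibility score (raw and normalised
(10 − s)/9), penalised logP `logP − SA − max(0, largest ring − 6)` with an
optional z-score-normalised variant, shingle-based ChEMBL-likeness over a
user-supplied weight table, sigmoid-composed multi-objective products
`∏ 1/(1+e^{s·a·(x−c)})`, hard-constraint wrappers that filter during
generation, and an external-evaluator contract for expensive properties
(e.g. DFT orbital energies). It is intended for cheminformatics researchers
and method developers who want a transparent, dataset-free baseline
generator they can bend to new objectives.

Chemistry plumbing rides on OpenBabel (SMILES parsing/canonical identity,
via ChemmineOB) and RDKit (QED/Crippen logP/SA score, through a persistent
Python helper process — `python` with `rdkit` must be on the PATH).

## A worked example

Hill-climb normalised penalised logP starting from methane, with a budget
of 1000 calls to the evaluation function:

```r
library(molevolve)

run <- evo_run(
  objective_plogp(normalised = TRUE),
  seeds = "C",
  config = evo_preset("hill-climber", seed = 1,
                      max_evaluations = 1000, budget_counting = "calls"))
run
#> <evomol_run> objective: plogp_normalised | steps: 57 | evaluations: 696 | population: 1
#> best: CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC  score = 11.194

tail(run$best_trace, 3)
#> # A tibble: 3 x 5
#>    step smiles                                 score evaluations evaluation_calls
#>   <int> <chr>                                  <dbl>       <int>            <int>
#> 1    41 CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC   10.7         266              328
#> 2    42 CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC  10.9         267              329
#> 3    43 CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC…  11.2         269              331
```

The search walks from methane to the linear C38 alkane — the molecule that
maximises this score in a 38-heavy-atom search space — reaching its final
best after 331 evaluation calls (269 unique molecules). `run$population` is
a tibble of the final population, `run$log` the per-step trace, and
`tidy(run)` / `glance(run)` give broom-style views. The exploration tree
exports to Graphviz or JSON:

```r
export_tree(run$tree, "dot", "tree.dot")
plot_progress(run)            # best/mean score per step, as ggplot
```

The same runs work from the shell:

```sh
./exec/molevolve --objective plogp-norm --preset hill-climber \
    --seed 1 --max-evals 1000 --out runs/plogp-hc
```

which writes `steps.csv`, `population.csv`, `tree.dot`, `tree.json` and the
resolved `config.json` (enough to reproduce the run bit for bit).

Constrained and composite objectives compose in the obvious way:

```r
halogen_free <- objective_constrained(
  objective_qed(), function(g) !any(mol_atoms(g)$element %in% c("Cl", "Br")))

likeness_gated <- objective_composite(list(
  list(objective = objective_clscore(read_shingle_table("weights.tsv")),
       sigmoid = sigmoid_chembl_likeness()),
  list(objective = objective_external(my_dft_lumo), sigmoid = sigmoid_lumo())
))
```

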