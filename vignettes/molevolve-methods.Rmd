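---
title: "Evolutionary molecular-graph optimisation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary molecular-graph optimisation: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

molevolve generates molecules by evolving molecular graphs directly: a
population of candidate molecules is repeatedly improved by small, chemically
meaningful graph edits, guided only by a user-chosen objective function. This
vignette explains the model behind the package, the parameters that matter,
the numerical and design choices that were genuinely open, and what the test
suite does and does not demonstrate.

## The graph model

Molecules are heavy-atom graphs with implicit hydrogens: every atom is
assumed to carry hydrogens up to its maximum valence, so the only valence
inconsistency that can arise is *hypervalence* (a bond-order sum exceeding
the element's maximum). Bonds have integer orders 1–3; "no bond" is order 0
and is never stored. A molecule is valid iff it is non-empty, connected, and
nowhere hypervalent.

The default valence table is C:4, N:3, O:2, F:1, P:3, S:2, Cl:1, Br:1. A
single maximum valence per element is the simplest reading of "the defined
valency"; expanded valences of S and P are excluded by default so that action
filtering never has to guess which valence state an atom is in. The table is
a run parameter (`valences =`), not a constant: pass your own to admit
hypervalent sulfur or additional elements. Formal charges are accepted on
*input* molecules only (ions, zwitterions); the effective maximum valence of
a charged atom is the table value plus its formal charge (the usual
isoelectronic adjustment: N⁺ binds like C, O⁻ like F), floored at zero. No
action ever creates or neutralises a charge.

Atom indices are stable for the lifetime of a molecule: removal leaves a hole
rather than re-indexing, so the actions recorded in logs and exploration
trees remain interpretable after later edits. Molecular *identity* is the
canonical aromatic SMILES ("canonical key"): graphs are kekulised internally
and aromaticity only reappears at this boundary, so Kekulé variants of one
aromatic system collapse to the same key. The key is what deduplicates the
population, keys the objective cache, and names tree nodes. SMILES parsing,
kekulisation and canonicalisation are delegated to OpenBabel (via ChemmineOB);
tests cross-check identity decisions against RDKit's independent
canonicaliser.

Coordinates, stereochemistry, isotopes and tautomer enumeration are out of
scope: no action touches them.

## The seven actions and their filters

Three primary actions span the search space:

* **append atom** (`Ad`) — add a new atom of an allowed element, single-bonded
  to an existing atom with free valence;
* **remove atom** (`Rm`) — delete an atom and its bonds;
* **change bond** (`Ch`) — set the order of any atom pair to 0–3, which covers
  bond deletion, order changes, and *creation* of a bond between previously
  unbonded atoms (ring closure); both endpoints need enough free valence for
  an increase.

Four secondary actions are shortcuts composed of primary effects; they speed
up exploration without extending the reachable space:

* **substitute atom type** (`Sub`) — change an atom's element, if its bond-order
  sum fits the new element's valence;
* **insert carbon** (`In`) — replace a bond by a carbon bridge: the old bond is
  removed and the new C is single-bonded to both former partners (legal even
  between saturated atoms, since each endpoint's bond-order sum can only
  decrease); carbon must be in the allowed element set;
* **cut atom** (`Ct`) — remove an atom with exactly two (mutually unbonded)
  neighbours and reconnect them with a single bond;
* **move group** (`Mv`) — detach one side of a *bridge* bond (an edge whose
  deletion splits the molecule; the "functional group" in the graph sense)
  and re-attach it, conserving the bond order, to another atom on the static
  side with enough free valence. Either side of a bridge may be the moved
  group, the destination must differ from the current anchor, and moving onto
  the group's own side is forbidden (it would disconnect the molecule).

Actions are *enumerated, not tried*: three a-priori filters decide legality
from graph analysis alone, so every action offered is guaranteed to yield a
valid molecule. The dislocation filter forbids edits that would disconnect
the graph (computed from articulation points and bridge edges, found by one
depth-first search). The valence filter forbids hypervalence. The charge
filter excludes any action that would add, delete or change a bond incident
to a formally charged atom — with the single exception of removing an atom,
so ionic subgraphs can be conserved or deleted but never rewired; we also
forbid substitution *on* a charged atom, since no charge bookkeeping is
defined for it (a conservative reading — the alternative would silently
change what the charge means). A fourth, optional filter freezes atoms:
substitute/cut/remove apply only to mutable atoms, and bond-touching pair
actions need at least one mutable member; appending *to* a frozen atom stays
legal, which is precisely how substituents are grown around a fixed core.
A size limit caps the number of heavy atoms (hydrogens never count).

Removing the last atom is forbidden: the empty molecule is unrepresentable.

## Mutation and the first-improver search

A mutation applies k successive actions, k drawn uniformly from
1..`max_actions`; at each sub-step the action *type* is drawn uniformly over
the types that currently have at least one legal action, then the action
uniformly within that type. Drawing over non-empty types only (rather than
re-drawing on an empty type) keeps the draw uniform over the offered action
space without wasted tries — the behaviour when a type is empty was an open
choice, decided this way once.

The improver search mutates a parent up to `max_tries` times (default 50)
and accepts the first candidate whose score is at least the score of the
individual it would replace. Accepting *equal* scores lets the search walk
fitness plateaus. Candidates already in the population — or identical to
their own parent, which inverse action pairs make possible — count as failed
tries. Duplicate and constraint checks apply to the final mutated graph only;
intermediate graphs need only be valid.

## The evolution loop

The population holds up to `capacity` unique molecules. Each step sorts by
score (ties broken by insertion step, older first — a stability choice that
aids reproducibility) and pairs the i-th best individual, as mutation parent,
with the i-th worst, as replacement slot. A failed search moves on to the
next-best parent for the same slot, each parent serving at most one slot per
step; the replaced individual is only removed when its improver is actually
inserted. While the population is below capacity, improvers are *added*
instead (floor score −∞), at most `n_replaced` per step and never more than
the number of individuals available to mutate — so a run seeded with a single
molecule grows 1, 2, 4, … individuals per step until full. With
`capacity = 1` the loop is a plain first-improver hill climber.

Runs stop at `max_steps`, at an optional evaluation budget, or at an optional
target score. Identical configuration and seed give bit-identical runs.

### Counting evaluations

Two counters are kept. `evaluations` counts unique molecules scored: the
objective cache is keyed by canonical key and a cache hit is free.
`evaluation_calls` counts every scoring request on a non-duplicate candidate,
i.e. what a cache-less implementation would perform — the convention usually
used when comparing evaluation budgets across molecular-generation methods.
`evo_config(budget_counting =)` selects which counter the `max_evaluations`
budget caps; the default is `"unique"`. Both counters appear in the step log
and in the best-score trace, so either convention can be read off any run.

## Objectives

* **QED** and the raw **synthetic-accessibility score** delegate to the
  standard published definitions (computed by RDKit through a persistent
  helper process; the fragment-contribution database is not re-derived).
  SAscore is reported raw (1–10, 1 best) or normalised to (10 − s)/9.
* **Penalised logP** is Crippen logP − SAscore − max(0, largest ring − 6),
  the largest ring taken over the smallest set of smallest rings. The
  normalised variant z-scores each component with the ZINC250k constants of
  the implementations this score originates from; the constants live in one
  place (`plogp_normalisation()`) and are configuration, not literals.
* **ChEMBL-likeness (CLscore)** is the mean weight of a molecule's shingles
  under a weight table read from TSV/JSON. A shingle here is the canonical
  SMILES of the subgraph induced by all atoms within graph distance r
  (r = 1..`radius_max`, default 3) of each heavy atom; distinct shingles
  count once (multiplicity off, matching the score's reference
  implementation),
  unknown shingles weigh 0, and a bond-less neighbourhood yields no shingle,
  so single-atom molecules score 0. The induced-subgraph form differs from
  bond-environment fragments only by ring-closure bonds between peripheral
  atoms; since the reference ChEMBL weight table is consumed as a file and
  never re-derived here, the table format — not the extraction detail — is
  the interoperability contract. A small synthetic table built from five
  molecules ships with the package for exercising the machinery.
* **Sigmoid composites** multiply factors of the form
  1/(1 + exp(s·a·(x − c))); ready-made shapes: a ChEMBL-likeness gate
  centred at 1.5 with steepness 10 (blocks likeness < 1, penalises 1–2), a
  LUMO shape centred at 0 eV rewarding low energies, a HOMO shape centred at
  −7 eV rewarding high energies. Each factor is strictly inside (0, 1)
  mathematically; in double precision the tails saturate beyond roughly
  |s·a·(x−c)| > 36.
* **Hard constraints** (`objective_constrained()`) reject candidates *before*
  scoring; a rejected candidate is a failed mutation try and never touches
  the evaluation counters, so 100 % of inserted molecules pass the predicate
  by construction.
* **External evaluators** (`objective_external()`) adapt a
  one-SMILES-in/one-number-out function (e.g. a DFT driver for orbital
  energies); `NA` or an error marks *failure*, which rejects the candidate
  rather than scoring it low, and results are cached so a costly evaluator
  runs once per molecule. No quantum chemistry ships with the package; a
  deterministic toy surrogate (`toy_electronic_evaluator()`) exists purely so
  the wiring is testable.

## The exploration tree

Every inserted improver becomes a node (one per canonical key) with an edge
from its parent labelled by the applied action sequence, in application
order. The tree records *history*: nodes persist after their molecule leaves
the population. A molecule that is replaced out of the population can later
be rediscovered and re-inserted; the tree then keeps its first lineage and
adds no second node or edge, preserving the one-node-per-key and
one-parent-per-node invariants. Exports: Graphviz DOT (scores on nodes for
colouring) and JSON, which round-trips losslessly.

## Reference parameter profiles

| profile | capacity | replaced/step | max actions | tries | steps | heavy atoms |
|---|---|---|---|---|---|---|
| `hill-climber` | 1 | 1 | 2 | 50 | 1500 | 38 |
| `population-1000` | 1000 | 10 | 2 | 50 | 1500 | 38 |
| `large-molecules` | 1000 | 10 | 3 | 50 | 3000 | 50 |

All presets use the full C/N/O/F/P/S/Cl/Br element set and are overridable
flag by flag (`evo_preset()`, or the `molevolve` command-line script).

## What the tests show — and at what scale

The test suite verifies the method end to end but at deliberately reduced
problem sizes so the default run stays within a desk-scale time budget:

* the capacity-1 normalised-plogP experiment runs at its full setting (1000
  evaluation calls per run): six seeded runs in the test suite, the full
  ten-run protocol in `scripts/acceptance.R`; each run converges to the
  linear C38 alkane, whose normalised plogP of 11.19 is the known plateau of
  this search space, with essentially zero run-to-run variance;
* the unnormalised plogP and QED capacity-1 checks use single seeded runs
  with evaluation budgets of a few thousand instead of 10-run averages at
  1500 steps; the full-element-set plogP run is the check most sensitive to
  this truncation, since its reference value reflects slow halogen/sulfur
  decoration of the alkane backbone over the full 1500-step protocol;
* the population-uniqueness and mean-QED checks use capacity 120 for 40
  steps; uniqueness is asserted exactly at every step, and the steady-phase
  mean is asserted monotone non-decreasing (replacement can only raise a
  slot's score) rather than asserted at its large-run asymptote;
* the population-beats-hill-climber check uses capacity 100 and at most 500
  steps under an evaluation cap, stopping as soon as the capacity-1 plateau
  is exceeded; within the cap the run reliably reaches the alkane plateau
  but the decoration phase beyond it is slow, so this check may fall short
  of the un-truncated protocol's value;
* the enumeration-equals-oracle and secondary-actions-are-shortcuts
  properties are checked on seeded random samples of molecules of up to 6
  and 4 heavy atoms respectively — the closed sets the properties range over
  are astronomically larger than any test budget. The shortcut property
  (every one-secondary-action product reachable by ≤ 4 primary actions) is
  checked at ≤ 4 atoms because it provably *fails* on some 5-atom molecules:
  substituting the central carbon of C–O–C–O–C to sulfur is a legal
  substitution, but both ether oxygens are valence-saturated, and a counting
  argument shows at least five primary actions are needed. Secondary actions
  remain shortcuts in the closure sense (they reach nothing that primary
  actions cannot), just not always within four steps.

The synthetic fixtures emulate what the method needs — valid seed molecules,
a shingle weight table, deterministic surrogate properties — not the
statistics of real compound collections: passing tests demonstrate
correctness of the search machinery and score assembly, not that any
particular objective is chemically meaningful, and the molecules that
maximise simple objectives (long alkanes and their decorated variants) are
exactly the degenerate optima such objectives are known to admit.

## Numerical choices and degenerate inputs

Sorting ties are broken by age; uniform draws use R's RNG exclusively, so a
seed fixes the whole run. Scores must be finite (a non-finite score is an
error, not a silent worst case); rejection is a distinct state, never a low
score. Single-atom molecules: no shingles (CLscore 0), no removable atom, no
bonds to change — append and substitute keep the search alive. The
evaluation-budget check happens before each scoring call, so a budget of B
never performs more than B countable evaluations. The objective cache and
the enumeration cache are bounded (cleared wholesale if they outgrow their
caps) to keep long runs at constant memory.

## Known limitations

* No crossover/recombination (a deliberate simplification that keeps the
  exploration tree readable), no diversity or niching mechanism, no learned
  action selection.
* The charge model freezes ionic subgraphs; chemistry that requires charge
  creation or neutralisation is outside the search space.
* Valence is a single integer per element: hypervalent S/P chemistry needs a
  custom valence table.
* Objective quality is the binding constraint in practice: the package
  optimises whatever it is given, including the degenerate optima of
  classical drug-likeness scores.
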