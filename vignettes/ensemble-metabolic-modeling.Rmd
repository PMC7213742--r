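---
title: "Ensemble modeling of genome-scale metabolic networks with gemsemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble modeling of genome-scale metabolic networks with gemsemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Why ensembles

A genome-scale metabolic network reconstruction (GENRE) is never certain.
Annotation gaps, ambiguous gene assignments, and incomplete biochemical
knowledge mean that many alternative networks are consistent with the same
evidence, and simulation results can depend strongly on which alternative
one happens to pick. gemsemble treats that uncertainty as data: instead of
one model, it works with an *ensemble* of model variants, runs every
constraint-based simulation across all of them, and returns distributions
rather than point estimates.

Storing hundreds of genome-scale models separately is wasteful because the
variants are nearly identical. gemsemble therefore stores one **base
model** — the union of every reaction any variant uses — plus a table of
**features** (the reaction attributes that vary: a bound or a
gene-protein-reaction rule) and, for every **member**, its value for each
feature. The total state storage is exactly
`|members| * |features|` scalar entries. Any member is materialised by
assigning its feature values onto the base model; nothing else differs
between members by construction. Reactions absent from a member are encoded
as bounds `(0, 0)` on the union reaction rather than removed structurally,
which is what makes every member reachable by attribute assignment alone.

## The constraint-based core

A model is a stoichiometric matrix $S$ (metabolites $\times$ reactions),
flux bounds $l \le v \le u$ (mmol gDW$^{-1}$ hr$^{-1}$), gene-protein-
reaction (GPR) rules, and a linear objective $c$ (usually flux through a
biomass reaction). The simulations are the standard linear programs:

* **FBA** maximises $c^\top v$ subject to $S v = 0$, $l \le v \le u$.
* **FVA** minimises and maximises each $v_j$ over the same polytope with
  the extra constraint $c^\top v \ge f \cdot z^\*$, where $z^\*$ is the FBA
  optimum and $f$ is `fraction_of_optimum` (default 1, since the tightest
  interpretation — variability among optima — is the usual question and the
  most conservative default).
* **Deletions** re-solve FBA after setting a reaction's bounds to
  $(0, 0)$, or, for a gene, after closing every reaction whose GPR rule
  evaluates false with that gene removed. An empty GPR evaluates true, so
  biomass, exchange, and spontaneous reactions survive all gene deletions.

A reaction is an exchange (boundary) reaction exactly when its
stoichiometry names a single metabolite; uptake is negative flux. A medium
is a named vector of maximum uptake rates: `set_medium()` sets
`lower_bound = -rate` for listed exchanges and closes uptake on all
unlisted ones, so a medium fully determines the nutrient environment.

### Numerical choices

All LPs are solved with the dense simplex in `pracma::linprog` after
shifting variables to the nonnegative orthant; this is why the package
requires every bound to be finite and refuses SBML files that omit explicit
flux-bound annotations rather than inventing defaults. Two properties of
that solver shaped the wrapper:

* its pivot tie-breaking is randomised, so every solve runs under a fixed
  private RNG seed — results are bit-reproducible and independent of the
  caller's random stream;
* it can stall on an unlucky pivot sequence, so a failed solve is retried
  under a short fixed list of alternative pivot seeds, and any claimed
  optimum is verified against the constraints before being accepted. Only
  after all attempts fail is a problem reported infeasible.

The feasibility/zero-flux tolerance is $10^{-6}$ throughout, a typical LP
precision for these problem scales. On toy networks the FBA optimum is
additionally cross-checked in the test suite against exhaustive vertex
enumeration of the flux polytope, which is the independent oracle for the
whole LP layer.

GPR rules use a case-insensitive `and`/`or` grammar with parentheses and no
negation, matching field convention; the parser reports the position of a
syntax error.

## Ensemble simulations

`ensemble_fba()`, `ensemble_fva()` and `ensemble_deletions()` lift the
single-model operations to all members (or an explicit subset, or a random
fraction — `ceiling(f * N)` members sampled without replacement under a
seed). The central correctness contract, asserted throughout the tests, is
*oracle equivalence*: the row for member $m$ equals the single-model result
on `extract_member(ensemble, m)` to within $10^{-6}$.

Work is partitioned by member; each worker applies states to its own
private copy of the base model and rows are merged by member id, so the
result is identical for any `workers` value and any evaluation order. A
member whose LP is infeasible keeps its row, flagged in a `status` column
with `NA` values — distribution analyses need to know their denominator, so
dropping such members silently would bias downstream statistics.

Because R's value semantics make in-place mutation unidiomatic, the
state-changing operations (`set_medium()`, `set_member_state()`,
`set_feature_across_members()`) return the modified object instead of
mutating their argument; the contracts are otherwise unchanged, and
"restoration after simulation" holds trivially because the caller's
ensemble is never touched.

## Generating ensembles by iterative gap-filling

Given a draft model, a universal reaction database, and a table of
growth/no-growth calls on defined media, the per-condition repair is a
single LP: merge the universal reactions into the draft, apply the
condition's medium, constrain the growth objective to at least
`growth_threshold`, and minimise the summed absolute flux through
universal reactions, splitting each reversible universal reaction into two
nonnegative variables to keep the objective linear. Universal reactions
carrying more than `flux_tolerance` flux form the solution and are added to
the draft with their database bounds before the next condition is
processed.

Two defaults deserve comment, since growth phenotyping data do not fix
them:

* `growth_threshold = 0.05` flux units — small enough to demand only
  "some" growth, large enough to clear solver tolerance by four orders of
  magnitude. It is user-settable everywhere it appears.
* `flux_tolerance = 1e-6` — the same zero-flux tolerance as the rest of the
  package.

Iterating over conditions matters because the flux-minimal repair for a
condition depends on what earlier repairs already added. Shuffling the
condition order across cycles (and optionally subsampling a fraction of
conditions, `ceiling(f * n)` without replacement) therefore produces
alternative repaired networks. `generate_gapfill_ensemble()` keeps one
member per *unique* added-reaction set, records the cycle and condition
order in each member's provenance, and drives subsampling and shuffling
from a single seed so a run is reproducible byte-for-byte. The continuous
flux-sum LP (rather than a mixed-integer count-minimising formulation) is
deliberate: it is the formulation the iterative procedure is built around,
it is fast, and its parsimony is exactly verifiable on small fixtures by
exhaustive subset enumeration — which the test suite does.

Conditions with a negative growth call are accepted in phenotype tables for
bookkeeping but never gap-filled on; reconciling no-growth observations
(consistency pruning) is a different problem and out of scope.

## Comparing results and guiding curation

With ensembles, a simulation output is a distribution paired by member
across conditions or edits. `compare_member_distributions()` runs a paired
t-test or Wilcoxon signed-rank test over the members present in both
inputs, reporting the mean paired difference as the effect estimate.
Identical inputs (all differences zero) return `p = 1` with a `degenerate`
flag rather than failing, because pipelines routinely compare a result to
itself; a nonzero shift with exactly zero variance — possible only in
constructed data — is likewise flagged and reported as `p = 0` rather than
left undefined. No multiple-testing correction is applied by default when
many columns are compared; `stats::p.adjust` composes naturally if needed.

The curation loop regresses a simulated outcome (typically biomass flux)
on the binarized member-by-feature state table — a bound state maps to 1
when nonzero, a GPR state to 1 when nonempty — and ranks features by
importance. The default regressor is a random forest with permutation
importance and out-of-bag $R^2$ as the quality score, but the regressor is
a *contract* (`f(X, y)` returning importances and a quality score): the
method needs importances, not any particular learner. A constant outcome
short-circuits to all-zero importances with a `no_signal` flag.
`curation_report()` joins the ranking to the ensemble's annotation
(reaction, attribute, state frequencies) plus distribution summaries — the
unsupervised summarisation step is interpreted as exactly these summary
statistics. The report is a hand-off to a human: the decision to fix a
feature (e.g. block a reaction the organism likely lacks) is applied with
`set_feature_across_members()`, after which simulation distributions can be
compared before/after.

## What the synthetic fixtures emulate

All tests and the acceptance script run on generated fixtures:

* `make_toy_model()` — parallel exchange/transporter/conversion chains
  feeding one biomass reaction, with a hand-computable optimum
  (uptake bound $\times$ number of sources at coefficient 1).
* `degrade_model()` — removes chosen reactions into a universal database
  seeded with decoy reactions producing dead-end metabolites. Mass balance
  forces decoy flux to zero, so decoys provably never enter a flux-minimal
  repair; the removed set is exact ground truth.
* `make_two_pathway_fixture()` — two carbon sources whose repairs interact:
  metabolite-doubling interconversions make reusing the first-repaired
  pathway cheaper than a direct repair, so the added set depends on
  condition order (`{RAP, RBA}` vs `{RBP, RAB}`).
* `make_synthetic_ensemble()` — 100 members over a two-source toy model in
  which one feature (a bypass conversion's upper bound) moves the biomass
  optimum from 10 to 15 and all other varying features are dead-end
  capacities with provably zero effect. The causal feature id is returned
  as ground truth for the curation loop.

Every generator is deterministic under its seed and asserts its own ground
truth at construction time. These fixtures reproduce the *logical*
structure of real use — presence/absence variation, order-dependent
gap-filling, a causal driver among neutral features — but not the scale or
messiness of genome-scale reconstructions: thousands of reactions,
degenerate alternate optima among repairs of equal cost, namespace
mismatches between draft and database, or noisy phenotype calls. Passing
tests show the algorithms are implemented correctly, not that any
particular organism's ensemble is well calibrated.

Problem sizes were chosen so the full suite exercises every code path in
well under a minute per file: ensembles of 5–100 members over networks of
4–15 reactions, universal databases of at most 10 reactions (so subset
enumeration, at $2^{|U|}$ LPs, stays exhaustive), and 20 gap-fill cycles
for the order-sensitivity demonstrations.

## Serialization

Models are written as SBML Level 3 with the flux-balance-constraints
extension (the de facto standard for constraint-based models; bounds become
shared parameters, GPRs become `fbc` association trees) or as a flat,
versioned JSON dialect mirroring the in-memory structure. An ensemble
archive is a directory holding `base.xml` plus `ensemble.json` (features,
members, states, provenance, format version) — no per-member model copies,
which is where the order-of-magnitude disk savings come from. There is no
standardised ensemble representation inside SBML itself, so the state
document is deliberately a separate, schema-versioned file; a future
standard could replace it without touching the base model format. Loading
rejects unknown schema versions explicitly rather than guessing.

## Known limitations

* The dense simplex backend is sized for toy and small networks; genome
  scale models would need a sparse LP solver behind the same `solve_lp`
  seam.
* Feature attributes cover reaction bounds and GPR rules only; metabolite
  or gene attributes, flux sampling, MILP-based strain design and
  community modeling are out of scope.
* Gene-rule features are represented, serialized, and unit-tested, but no
  shipped workflow varies GPRs across members.
* `workers > 1` uses process forking and falls back to serial evaluation
  on platforms without it; the determinism contract makes this invisible
  in results.
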