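---
title: "Explainable diagnostic Bayesian networks: model, influence score, and structure search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable diagnostic Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reasonbn)
```

## The problem

Computer-aided differential diagnosis (CADx) systems that emit a bare
class label are rarely trusted in radiology practice: a reader confronted
with "primary lung cancer, posterior 0.74" has no way to audit the claim.
`reasonbn` implements a CADx design in which every inference is
accompanied by *reasons* — small subsets of the entered findings whose
influence on the inferred diagnosis is quantified — and in which the model
itself is chosen to balance two objectives: inference accuracy and the
adequacy of the explanations it can produce.

The intended data are coded case tables: one row per patient case, one
categorical column per imaging finding (e.g. shape, cavitation) or
clinical datum (e.g. tumour-marker class, history of malignancy), and a
single diagnosis column with a small number of classes (three in the
motivating lung-nodule setting: primary lung cancer, lung metastasis,
benign nodule). Clinical columns may be missing; findings are assumed
coded for every case.

## The inference model

The model is a discrete Bayesian network over the schema's variables: a
directed acyclic graph `S` plus one conditional probability table (CPT)
per node. Two structural constraints are imposed throughout, including
during search:

* the graph is acyclic, and
* every node has **at most two parents**.

The parent cap bounds CPT size (at most 8 × 8 × 8 entries) and the space
of structures; it is also the cap used when the candidate structures are
enumerated by the search moves.

Parameters are estimated by smoothed counting
(`estimate_parameters()`): for node state `k` under a fixed joint parent
configuration, `p = (n_k + a) / (n + aK)` with pseudocount `a`
(default 1, Laplace). Counting is *available-case*: a case contributes to
a node's table only when the node and all of its parents are observed in
that row. The default pseudocount avoids zero probabilities, so entered
evidence can never have probability exactly zero under a fitted model; a
pseudocount of 0 gives maximum-likelihood tables and raises an error when
a family has no usable cases, since the distribution is then undefined.

Posteriors are computed **exactly**. The reference implementation is
variable elimination with a greedy min-fill ordering (`posterior()`);
when the total state space is small (`prod(|states|)` up to `2^20` by
default, covering every network used in the package's own simulations)
the scorer instead compiles the full joint array once and answers all
queries by marginalisation. Both paths are exact and the test suite
asserts they agree to machine precision; the `joint_limit` argument only
trades memory for speed, never changing results. `infer_diagnosis()`
returns the diagnosis state with the highest posterior; ties are broken
by schema state order, which makes inference deterministic.

## Reasons: the influence score

For one case with evidence `E` (the observed variable = state
assignments), every subset `R_c ⊂ E` with one or two elements is a
*reason candidate*. Candidates are scored by their influence on the
inferred diagnosis `d_f`:

* the **posterior shift** of a candidate is
  `p_d(R_c) = p(d_f | R_c) − p(d_f)`, where `p(d_f | R_c)` is computed
  with *only* the candidate entered as evidence (all other observed
  findings removed) and `p(d_f)` is the model's marginal, i.e. the
  training-data prior of the inferred class;
* a singleton's influence is its shift: `I(R_c) = p_d(R_c)`;
* a pair's influence subtracts a **synergy penalty**
  `f(R_c)` built from the element-wise effects: with
  `f_p = Σ p_d(R_ct)²` over singletons with non-negative shift and
  `f_n = Σ p_d(R_ct)²` over the rest,

  * if `sgn(p_d)·sgn(f_p − f_n) < 0`, the penalty is 0 (the elements
    pull the other way; the pair's effect is genuine),
  * else if `|p_d| ≥ |f_p − f_n|`, the penalty is `f_p − f_n` (the
    non-synergetic part is subtracted),
  * otherwise the penalty equals `p_d` itself, so `I = 0` (the pair adds
    nothing beyond its elements).

The branches are implemented exactly as the score defines them,
including their unit asymmetry: `f_p` and `f_n` are sums of *squared*
shifts compared against an unsquared `p_d`. We do not reinterpret this
(the squaring plays a role analogous to an L2 penalty, split by sign);
the package's job is to compute the score as defined. Two boundary
conventions are fixed and tested: `sgn(0) = 0`, so a zero net
element-wise effect can never trigger the opposite-sign branch (and a
pair whose singletons both shift nothing keeps its full shift as
influence), and the two-parent analogue holds for candidate size — pairs
are the largest candidates considered, which keeps per-case scoring at
`n + n(n−1)/2` posterior queries.

`derive_reasons()` rejects candidates with `I(R_c) < 0.05 · p(d_f)` —
applied to the *signed* influence, so negative-influence candidates are
always rejected (reasons are meant to justify the chosen diagnosis) —
and selects up to three of the remainder with the highest influence. The
derived reason set `R_d` is the union of the selected candidates'
elements. Tie-breaking (descending influence, then smaller candidate,
then lexicographic element names) is a package convention: the score
itself does not induce a tie order, and a deterministic rule makes
results reproducible and order-invariant, which the tests check. We also
apply rejection before the top-three cut; since rejection is a pure
filter on the same ranking, filtering before or after selecting yields
the same set.

A structural consequence worth knowing: evidence entered on a variable
that is d-separated from the diagnosis node cannot move the posterior, so
its influence is exactly zero and it can never become a reason. In a
collider topology (`X_a → X_b ← D` with `X_b` unobserved) evidence on
`X_a` is blocked; reversing the link between `X_b` and `D` unblocks it.
This is why the *structure* of the network, not just its fit, determines
explanation quality — and why the structure search below scores
explanations at all.

## The evaluation metric

A structure `S` is scored on a dataset by

* `V_i(S)`: inference accuracy, the fraction of cases whose inferred
  diagnosis matches the recorded one;
* `V_r(S)`: explanation adequacy, the **micro-averaged** F-measure of the
  derived reasons `R_d` against reference reasons `R_g` (expert-chosen
  sets of 1–7 elements in clinical use): precision
  `Σ|R_g ∩ R_d| / Σ|R_d|` and recall `Σ|R_g ∩ R_d| / Σ|R_g|` are pooled
  over cases *before* the harmonic mean, and any 0/0 ratio is defined as
  0. Elements match on exact variable = state identity, since both sets
  are drawn from the same coded vocabulary;
* `V(S) = (V_r(S) + V_i(S)) / 2`.

`cross_validated_score()` estimates these by stratified k-fold
cross-validation (default 5 folds): parameters are fitted on each
training split, held-out predictions and reasons are pooled across folds,
and the metrics are computed once on the pooled results. Pooling (rather
than averaging per-fold metrics) follows directly from the pooled sums in
the metric's definition. Stratification by diagnosis label is a package
choice: with three classes and datasets of under a hundred cases,
unstratified folds can easily lose a class from a training split, which
makes the fold unusable (the package raises an error in that event rather
than silently scoring it).

One pragmatic rule matters for search speed: if the pooled accuracy falls
below the **accuracy floor** (default 0.70), the score short-circuits to
`V = V_i` with `V_r = 0`, and reason derivation — much more expensive than
prediction — is skipped entirely. Models that inaccurate would be
clinically unacceptable regardless of their explanations.

## Annealed MCMC structure search

`run_search()` maximises `V(S)` by a simulated-annealing random walk over
legal structures:

1. start from the initial model (`build_initial_structure()`): no links
   at all, or — with expert prior knowledge — one link between the
   diagnosis node and each nominated variable;
2. propose a neighbour by one uniformly chosen legal move: *delete* an
   edge, *reverse* an edge, or *join* an unlinked ordered pair. Only
   moves whose result is acyclic and respects the two-parent cap are
   enumerated, so an illegal structure can never be proposed;
3. score the proposal by cross-validation (with the short-circuit);
4. replace the current structure with probability
   `P_m = 1` if the proposal scores higher, else
   `exp(−(V_current/V_temp) · β^{−(M−1)})`, with damping ratio
   `β = 0.999` by default;
5. stop at the iteration limit (`M_l`, default 10000) or after `M_c`
   (default 2500) *consecutive* iterations without replacement; the
   final structure is refitted on all training cases, and the model is
   flagged **discarded** when its training accuracy is below the floor.

Design decisions the method's definition leaves open, and how we
resolved them:

* *Move probabilities.* The update action should depend on the current
  structure; we draw uniformly over the set of currently legal moves,
  the simplest rule with that property
  (the mix of deletes/reverses/joins automatically tracks the structure).
* *Exponent of the acceptance rule.* We read the damping as
  `β^{−(M−1)}`, the only reading under which the acceptance probability
  of a downhill move shrinks as iterations grow — the stated qualitative
  behaviour. At equality and `M = 1` this gives `e^{−1}`, which the tests
  pin down.
* *Stagnation.* `M_c` counts consecutive non-replacements, matching
  annealing practice.
* *Prior-knowledge links* point from the diagnosis node to the variable
  by default (the generative reading: a disease expresses itself in
  findings); the direction is configurable, and the links are ordinary
  edges the search may delete or reverse later — the initialisation
  seeds, it does not freeze.
* *Score caching.* Scores are cached by canonical edge set, so revisited
  structures are not re-scored; with a fixed fold seed per search this
  changes nothing about the results. Likewise, CPTs are cached per
  (fold, node, parent set) across structures, exploiting that a single
  move changes at most two families; the tests assert the cached path
  equals a from-scratch evaluation.
* *Degenerate scores.* If a proposal scores exactly 0 (possible only via
  the short-circuit with zero accuracy) and the incumbent is no worse,
  the exponent diverges and the acceptance probability is taken as 0.

Determinism: a search is a pure function of (initial structure, cases,
configuration, seed). The seed drives proposals, acceptance draws, and
fold assignment; two runs with the same seed produce byte-identical
serialised models, and different seeds may legitimately end in different
local optima — the multiple-trial design this method is used with.

## Synthetic data

The study data this method was developed on are private clinical records,
so the package ships a generator (`make_ground_truth()`,
`sample_cases()`, `annotate_reference_reasons()`) that emulates their
*shape*: by default 49 imaging-finding variables and 37 clinical
variables with 2–8 states each, a three-state diagnosis, missing clinical
values, and per-case reference reasons of 1–7 elements. The generator
builds a ground-truth network (diagnosis parentless; a configurable
number of findings as its children; optional extra edges at a given
density), draws CPT rows from a symmetric Dirichlet sharpened by
tempering with exponent `s/(1−s)` for effect strength `s` (so `s = 0`
gives exactly uniform rows and a diagnosis independent of all findings),
and samples cases ancestrally.

Two emulation choices deserve emphasis:

* **Reference reasons are oracle-derived, not expert-derived.** Each
  case's `R_g` is built from the ground-truth model itself: observed
  singletons are ranked by the absolute posterior shift they induce on
  the *true* diagnosis, elements with shift ≥ 0.05 are kept (up to 7,
  at least 1). Real reference reasons encode radiologist judgement,
  inter-rater variation, and phrasing conventions that no generator
  reproduces. Passing the package's tests therefore demonstrates that
  the machinery recovers planted structure and explanations under its
  own assumptions — not that it attains any particular clinical
  F-measure.
* The generator makes no attempt to mimic the marginal distributions,
  inter-finding correlations, or missingness mechanism of real imaging
  data; all of its distributions are explicit parameters.

Problem sizes used by the package's own simulations were chosen to make
the full pipeline observable at interactive scale: the structure-recovery
experiments use 6 findings, 400 cases, strong effects
(`effect_strength = 0.85`), searches of 1000 iterations, and 5 seeds per
condition, at which scale a correct structure is comfortably separable
from the empty one while a complete search remains a matter of seconds to
minutes. When the iteration limit is scaled down from the production
10000 to 1000, the damping ratio is compressed with it
(`beta = exp(-0.01) ≈ 0.99`) so that the end-of-run damping
`β^{−(M_l−1)} ≈ e^{10}` matches the production schedule's: annealing
behaviour is a function of the *schedule*, not of `β` alone, and an
uncompressed 1000-iteration chain at `β = 0.999` is still hot — still
accepting downhill moves at several percent — when it stops. The full 87-variable schema is exercised by the generator and
I/O tests; searching it at the default 10000 iterations is the intended
production use and scales linearly in iterations.

## Numerical and interface conventions

* Distributions are normalised within 1e-9 (asserted), and the
  propagation engine is tested against brute-force joint enumeration at
  1e-9 on hundreds of seeded random models.
* Evidence with probability zero under a model raises an explicit
  inconsistent-evidence error rather than returning NaNs.
* Reports print metrics to three decimals and accuracies to one decimal
  percent, with half-up rounding (the convention used in the tables the
  report format mirrors).
* Model JSON round-trips write → read → write byte-identically;
  XMLBIF export is provided for interoperability with other
  Bayesian-network tools.
* All user-facing functions are data-first and return tibbles or objects
  with `tidy()`/`glance()` methods, so workflows compose with the pipe;
  `autoplot()` draws search traces and evaluation summaries.

## Known limitations

* Reason candidates are capped at two elements and three selected
  candidates (a computational-complexity cap that is part of the
  method); explanations needing three-way interactions are out of reach
  by design.
* Exact inference is exponential in treewidth in the worst case; the
  two-parent cap keeps practical networks tractable, but pathological
  structures on many variables could be slow.
* The combined metric weights accuracy and explanation adequacy equally;
  no weighting parameter is exposed because the metric's definition is
  part of the method.
* The search is a local annealer: different seeds can and do end in
  different local optima, which is why multiple trials with the
  discard rule are the recommended protocol.
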