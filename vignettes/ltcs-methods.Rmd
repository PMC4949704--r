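---
title: "Thermodynamically consistent sets of elementary flux modes: methods"
author: "ltcsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamically consistent sets of elementary flux modes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltcsr)
```

## The model

A metabolic network is a stoichiometric matrix $S \in \mathbb{R}^{m \times r}$
over the $m$ *internal* metabolites (boundary species are dropped at load
time), a reversibility flag per reaction, and — for thermodynamics — a
standard transformed Gibbs energy of formation $\Delta_f G'^0_k$ (kJ/mol)
and concentration bounds $[c_k^{\min}, c_k^{\max}]$ (M) per metabolite.
Concentrations enter only through $\ln(c_k/c^0)$ with $c^0 = 1$ M:

$$\Delta_f G'_k = \Delta_f G'^0_k + RT \ln(c_k/c^0), \qquad
  \Delta_r G_j = \sum_k S_{kj}\, \Delta_f G'_k .$$

A steady-state flux $v$ ($Sv = 0$, irreversible reactions nonnegative) is
**thermodynamically feasible (TF)** when some in-bounds concentration vector
makes $\mathrm{sign}(v_j)\,\Delta_r G_j < 0$ for every used reaction $j$.
An elementary flux mode (EFM) is a support-minimal such steady-state
direction; a set of TF EFMs is **consistent** when one concentration vector
certifies all members at once, and a **largest thermodynamically consistent
set (LTCS)** is a consistent set no further TF EFM can join.  One witness
vector certifies every nonnegative combination of a consistent set, because
each combination's support directions are a subset of the union of the
members' directions (conformality: members never oppose each other).

### Default parameters

| parameter | default | meaning |
|---|---|---|
| $T$ | 310.15 K | temperature (37 °C) |
| $R$ | 8.3145×10⁻³ kJ mol⁻¹ K⁻¹ | gas constant |
| $c_k^{\min}, c_k^{\max}$ | 10⁻⁷ M, 1 M | conservative bounds for unmeasured metabolites |
| $\varepsilon$ | 10⁻⁶ kJ/mol | margin realizing the strict inequality $\Delta_r G < 0$ |

Each metabolite's concentration range affords $RT\ln(10^7) \approx 41.6$
kJ/mol of adjustment, which calibrates how much formation-energy imbalance a
reaction can absorb.  The strict inequality is not representable in an LP,
so it is realized as $\Delta_r G \le -\varepsilon$; with $\varepsilon = 0$
equilibrium (zero-driving-force) fluxes would be admitted.  $\varepsilon$ is
configurable on every feasibility-touching function.

### Exemptions

Reactions touching a metabolite without a formation energy cannot be
checked and are exempted automatically, as are exchange reactions whose
internal stoichiometry is empty (their $\Delta_r G$ over internal
metabolites is identically zero).  Further reactions can be exempted
explicitly — the bundled example network exempts its boundary
uptake/secretion reactions, whose driving force involves external species
outside the model, so the feasibility question concentrates on the internal
interconversion.  Exempt reversible reactions are consequently not subject
to the no-cancelation rule; all consistency guarantees are stated over the
thermodynamically checked reactions.

## EFM enumeration

`enumerate_efms()` splits each reversible reaction into forward and
backward columns and enumerates the extreme rays of the pointed cone
$\{x \ge 0 : Sx = 0\}$ by the double-description (Motzkin) iteration,
using the combinatorial adjacency test (a positive/negative ray pair is
combined only if no third ray's zero set contains their common zero set).
Spurious two-cycles (forward plus backward of one split reaction) vanish on
merging and are dropped; a mode supported only by reversible reactions is
valid in both orientations and is reported once, oriented so its first
nonzero entry is positive.

Numerics: double precision with a $10^{-9}$ zero tolerance; every ray is
rescaled after each combination step (division by its smallest absolute
nonzero entry), which keeps the small-integer stoichiometries of desk-scale
models well conditioned.  Canonical output scaling is the same
smallest-entry normalization; `uptake_normalize()` provides the
unit-substrate-uptake convention used when comparing modes by yield.
Output order is deterministic: lexicographic by support, then by values.

The double description step is intended for desk-scale models (guard:
40 reactions, configurable); beyond that, matrices computed by a dedicated
enumerator are imported with `read_efms()`.  The enumeration is validated
in the test suite against an independent subset-rank oracle (a support set
is an EFM support iff the restricted nullspace is one-dimensional, nowhere
zero on the support, and sign-feasible) over dozens of seeded random
networks.

## Feasibility as linear programming

`efm_is_tf()` solves: find in-bounds $\ln c$ with
$\mathrm{sign}(e_j)\,\Delta_r G_j \le -\varepsilon - t$ for all non-exempt
supported $j$, maximizing the extra slack $t \in [0, 1]$.  Maximizing the
slack (rather than solving a bare feasibility problem) returns witnesses in
the interior of the feasible region, so replaying a witness through
`reaction_energy()` honors the $\varepsilon$ margin robustly.  When
infeasible, a deletion filter shrinks the constraint system to an
irreducible infeasible subset, reported as `violated_reactions`.

`energy_bounds()` gives the attainable $[\Delta_r G_j^{\min},
\Delta_r G_j^{\max}]$ by interval arithmetic (products at their upper,
substrates at their lower concentration bound for the maximum, and
conversely); these intervals are also the big-M constants below.

### The LP core

The instances here are tiny (tens of variables and rows) but numerically
delicate: the feasibility margin $\varepsilon$ is six orders of magnitude
below the big-M coefficients.  The package therefore carries its own dense
two-phase tableau simplex with Bland's anti-cycling rule — guaranteed
finite termination, no degeneracy stalls, explicit control of the
infeasibility threshold ($10^{-8}$, kept deliberately below $\varepsilon$) —
rather than relying on a general-purpose routine.  Row equilibration is
deliberately *not* applied: rescaling rows would shrink the
$\varepsilon$-gap below the detection threshold.

## The LTCS mixed-integer program

Variables: a binary $\lambda_i$ per TF EFM, a binary indicator $y_d$ per
reaction-direction $d$ used by any EFM (non-exempt reactions only), and the
continuous $\ln c$.  Constraints, per direction $d = (j, s)$:

$$\sum_{i \,:\, i \text{ uses } d} \lambda_i \le n\, y_d, \qquad
  s\,\Delta_r G_j(\ln c) \le -\varepsilon + M_d (1 - y_d),$$

with $M_d$ the attainable maximum of $s\,\Delta_r G_j$ plus $\varepsilon$
from `energy_bounds()` — the tightest finite constant available without
presolve.  Selecting any EFM forces the indicators of all its directions
on, which activates the corresponding energy constraints; a reaction used
in both directions forces two contradictory energy constraints, so opposed
modes can never be selected together.  The objective maximizes
$\sum_i \lambda_i$.

Tie-breaking among alternative optima: the objective coefficients are the
integers $W - i$ with $W = n(n+1)/2 + 1$.  Cardinality still dominates (no
index-sum difference can outweigh one membership), low EFM indices are
preferred among equal-cardinality optima, and the objective stays integral
— which the branch-and-bound exploits for exact floor-based bound pruning.
An integer-weighted secondary term was chosen over a small floating-point
perturbation precisely to keep pruning exact; set `tie_break = FALSE` for
the pure cardinality objective.

### Branch and bound

The solver is depth-first branch-and-bound on the LP relaxation with
first-fractional branching (fixed variable order, "take it" child first),
making results deterministic.  One subtlety is inherent to big-M indicator
constraints: the relaxation may park an indicator at $1 - \varepsilon/M_d$,
within ordinary integrality tolerance of 1 yet structurally fractional.
Candidates are therefore accepted only after re-solving the LP with all
integers pinned at their rounded values; if that pinned program is
infeasible, the offending binary is branched on explicitly instead.

### Enumeration by exclusion

`enumerate_ltcs()` repeats: solve, record $\mathcal{L}_l$, add an exclusion
constraint, until infeasible.  Two schemes:

* **cover** (default): require at least one EFM *never selected in any
  previous solution*, $\sum_{i \in Z} \lambda_i \ge 1$ with $Z$ the
  never-selected set.  Every TF EFM ends up in some returned set and the
  first set has globally maximal cardinality, but sets whose members were
  all seen before (in different combinations) are not revisited — the
  result is a covering family of maximal consistent sets, not necessarily
  all of them.
* **exhaustive** (`exhaustive = TRUE`): per found solution $P$, require
  $\sum_{i \notin P} \lambda_i \ge 1$.  This cut excludes exactly the
  subsets of $P$.  Any returned optimum is automatically maximal (a
  consistent strict superset would satisfy every cut and score higher), and
  the loop terminates exactly when every maximal consistent set has been
  found.  This form was chosen over classical no-good cuts because it makes
  the exhaustiveness argument a two-line proof; it is intended for small
  instances and is cross-checked against `brute_force_maximal_sets()` in
  the tests.

Both loops carry a 10,000-solution safety cap.  `solve_max_ltcs()` returns
`NULL` on infeasibility, which terminates the loop.  Witnesses attached to
returned sets are re-derived with maximal slack by `verify_consistency()`.

With yield constraints, the per-product indicator
$\varepsilon_{iu} = [Y_u^i \ge Y_{\min,u}]$ is precomputed from the yield
table and $\sum_i \lambda_i\,\varepsilon_{iu} \ge 1$ is added per required
product; the required products and thresholds are runtime parameters.

## Screening

Yields are molar flux ratios $Y_u^i = |e^i_u| / |e^i_{\text{substrate}}|$
read from designated reactions (an internal ATP-maintenance reaction may
serve as the "product" for energy yields); they are scale-invariant and
undefined for modes that do not take up the substrate.  An LTCS reaches
every yield between 0 and the maximum over its members by mixing a
maximum-yield with a zero-yield member, so `screen_by_yields()` keeps a set
iff its maximum meets each measured threshold (equality survives; undefined
maxima count as zero).  `direction_signature()` aggregates member signs per
reaction (`forward`, `backward`, `zero`, or the with-zeros variants; a
signature with idle members satisfies a `forward-or-zero`/`backward-or-zero`
rule, matching how a zero-flux subset should survive a direction
requirement).  `venn_segments()` partitions the union of selected sets by
membership bit-pattern and reports per segment the signed support
frequencies (percentage using each reaction, negative for backward — within
a segment mixed directions cannot occur on checked reactions) and the
support-cardinality distribution.  `decompose_flux()` solves
$v = \sum \alpha_i e^i$, $\alpha \ge 0$ by LP, minimizing $\sum \alpha_i$
as a deterministic tie-break among alternative decompositions;
`require_conformal = FALSE` skips the direction pre-check to expose
inconsistent decompositions such as superposing both directions of a
reversible reaction.

## The synthetic generator

`random_network()` emulates desk-scale core-model structure: sparse
internal columns touching 2–4 metabolites with coefficients in {1, 2},
plus boundary uptake/secretion reactions so nontrivial steady states
exist.  Draws are rejected until every metabolite has a potential producer
and consumer and the network admits 1–80 EFMs.  Formation energies are
i.i.d. normal with mean 0 and SD 10 kJ/mol: only formation-energy
*differences* matter, and this spread — against the ±41.6 kJ/mol of
concentration adjustment — yields a realistic mixture in which most modes
are individually feasible, some are not, and opposite-direction conflicts
on reversible reactions are common (in line with a core-model study where
a fifth of all modes were feasible).  Boundary reactions are exempt, every
internal reaction is checked, so generated instances exercise the
no-cancelation machinery.  All randomness is fixed by the seed;
`conflict_pair_fixture()` returns the bundled example network, which
guarantees at least two LTCSs downstream.

What the generator does *not* emulate: genome-scale topology (pathway
structure, cofactor coupling, compartments), correlated formation energies
along pathways, and measured (narrow) concentration windows.  Passing
tests on generated instances therefore demonstrate algorithmic
correctness — enumeration, feasibility, maximality, exhaustiveness against
oracles — not biological realism of any particular instance.

## Problem sizes and verification

The package verifies itself at sizes where independent oracles are exact:
the worked two-metabolite example end to end; 30+ seeded random networks
(6 metabolites, 10 reactions, 3 reversible) with the subset-rank EFM
oracle; exhaustive-mode agreement with subset-enumeration brute force for
up to ~14 TF EFMs; 1000-point random bracketing of the energy intervals;
and witness-replay margins on every feasibility result.  Genome-scale
inputs (hundreds of reactions, tens of thousands of EFMs) are supported
through `read_efms()` import and the same MILP machinery, but sit outside
the verified desk-scale envelope; the enumeration guard makes the boundary
explicit.

## Known limitations

* Formation energies are consumed as given (no group-contribution
  estimation, no pH/ionic-strength transformation, no uncertainty
  propagation).
* The LP/MILP stack is exact-arithmetic-free; all guarantees are within
  the stated tolerances ($10^{-9}$ LP pivoting, $10^{-8}$ infeasibility
  threshold, $\varepsilon$ margin).
* The cover-mode enumeration reproduces the exclusion scheme's covering
  semantics; use `exhaustive = TRUE` (small instances) when *all* maximal
  consistent sets are required.
* `read_efms()` reads the whole matrix into memory; truly massive EFM
  files should be pre-filtered externally.
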