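# ltcsr

Largest thermodynamically consistent sets of elementary flux modes.

## The problem

Elementary flux modes (EFMs) are the support-minimal steady-state flux
vectors of a stoichiometric metabolic network: every steady-state flux is a
nonnegative superposition of EFMs.  Metabolomics adds a second law on top of
stoichiometry: a flux is **thermodynamically feasible (TF)** only if some
metabolite concentration vector within measured (or default) bounds gives
every used reaction a negative Gibbs energy of reaction in its direction of
use,

    Δ_r G_j = Σ_k S_kj (Δ_f G'⁰_k + RT ln(c_k / c⁰)),
    sign(v_j) · Δ_r G_j < 0  for every reaction j in the support of v,
    ln(c_k^min/c⁰) ≤ ln(c_k/c⁰) ≤ ln(c_k^max/c⁰).

Two EFMs can each be feasible and still be jointly impossible — most simply
when they run the same reversible reaction in opposite directions, since
Δ_r G cannot be negative both ways at one concentration vector.  A set of TF
EFMs is **thermodynamically consistent** when a single concentration vector
certifies all of them at once (then every nonnegative combination of the set
is TF, and no member opposes another on any reaction).  A **largest
thermodynamically consistent set (LTCS)** is a consistent set to which no
further TF EFM can be added.  LTCSs segment the flux cone into the subcones
an organism can actually populate; screening them against measured yields
and known reaction directions narrows a network's possible phenotypes down
to the biologically relevant one.

`ltcsr` is for modelers doing constraint-based analysis of desk-scale
metabolic networks who want that thermodynamic segmentation end to end:

* `load_network()` / `load_thermo()` — SBML (core subset) or a TSV dialect,
  plus per-metabolite formation energies and concentration bounds;
* `enumerate_efms()` — exact double-description enumeration with signed,
  canonically scaled output (`read_efms()` imports externally computed
  matrices for larger models);
* `efm_is_tf()` / `filter_tf()` — the per-mode feasibility test as a linear
  program with a max-slack witness;
* `build_milp()` / `solve_max_ltcs()` / `enumerate_ltcs()` — the LTCS
  mixed-integer program (one binary per EFM, one indicator per used
  reaction-direction, big-M conditional energy constraints) and the
  exclusion loop that enumerates further sets, with a provably exhaustive
  mode for small instances;
* `verify_consistency()` / `verify_maximality()` /
  `brute_force_maximal_sets()` — certificates and an independent oracle;
* `efm_yields()`, `screen_by_yields()`, `direction_signature()`,
  `screen_by_directions()`, `venn_segments()`, `decompose_flux()` —
  phenotype screening and conformal flux decomposition within one set;
* `random_network()` — a seeded generator of small networks with
  thermodynamic data, so every stage is testable without downloads.

## Worked example

The bundled two-metabolite network (A and B; uptakes R1, R2; reversible
interconversion R3; secretions R4, R5) has four EFMs, all individually
feasible under symmetric formation energies:

```r
library(ltcsr)
toy  <- toy_fixture()
efms <- enumerate_efms(toy$network)
unclass(efms)
#>    EFM1 EFM2 EFM3 EFM4
#> R1    1    1    0    0
#> R2    0    0    1    1
#> R3    1    0   -1    0
#> R4    0    1    1    0
#> R5    1    0    0    1

tf    <- filter_tf(toy$network, toy$thermo, efms)$tf   # keeps all 4
ltcss <- enumerate_ltcs(toy$network, toy$thermo, tf)
for (l in ltcss) print(l)
#> LTCS #1: 3 EFM(s): EFM1, EFM2, EFM4
#> LTCS #2: 3 EFM(s): EFM2, EFM3, EFM4
```

EFM1 runs R3 forward (A→B) and EFM3 runs it backward, so they can never be
active together; the four feasible modes split into two overlapping LTCSs of
three modes each — strictly fewer than the four EFMs, which is the general
pattern whenever a reversible reaction is used in both directions.  Each set
carries a witness concentration vector proving joint feasibility, e.g.
`round(exp(ltcss[[1]]$witness), 4)` gives `A = 1.0000, B = 0.6786` (molar):
with equal formation energies, B below A makes A→B downhill for every
member.  The steady-state flux `v = (1, 2, -1, 2, 1)` uses R3 backward and
decomposes conformally inside the second set only:

```r
decompose_flux(toy$network, c(1, 2, -1, 2, 1), ltcss[[2]], tf)$coefficients
#> EFM2 EFM3 EFM4
#>    1    1    1
```

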