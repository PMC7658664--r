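---
title: "Methods: community flux balance analysis for a syngas co-culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community flux balance analysis for a syngas co-culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The modelling framework and its assumptions

`cofba` models a two-species chemostat community — an acetogen fixing
CO/H₂ into acetate and ethanol, and a chain elongator fermenting those into
butyrate and hexanoate — as a single stoichiometric network with two
internal compartments and one shared extracellular compartment. The core
assumptions are:

1. **Steady state.** All fluxes satisfy `S v = 0`; metabolites exchange
   only through the common medium.
2. **Environmental flux units.** All fluxes are per culture volume
   (mmol l⁻¹ h⁻¹) rather than per biomass; a species' specific flux is
   recovered as `v / (X_T φ_i)`. This lets species of unequal abundance be
   constrained in one LP.
3. **Equal growth rates.** In a chemostat at steady state every persisting
   species grows at the dilution rate `μ = 1/HRT`; the biomass reaction of
   species *i* is therefore fixed (both bounds) at `μ · X_T · φ_i`. We use
   an equality rather than a lower bound because chemostat steady state
   determines growth exactly.
4. **Defined medium.** Every exchange reaction that is not in the feed set
   (and is not water or CO₂, which are treated as freely available) is
   closed in the uptake direction. Without this closure the LP silently
   imports substrates "from nowhere", which invalidates any yield claim.

Measured products impose floors: each product's exchange must carry at
least `product_floor` (default 0.8) of the measured rate. Maintenance ATP
(`ATPM`) is a lower bound, `atpm_specific · X_T · φ_i`, because maintenance
is a requirement, not a fixed observation — and because diagnosing which
scenarios force maintenance to shrink is itself informative (see
`diagnose_infeasibility()`).

## Tunable parameters

| parameter | unit | default | rationale |
|---|---|---|---|
| `hrt` | h | 48 | typical retention time of the modelled runs; `μ = 1/48 ≈ 0.021 h⁻¹` |
| `community_biomass` (X_T) | gDW l⁻¹ | 0.4 | realistic density of a gas-limited syngas chemostat; not printed in the source data, chosen once |
| `atpm_specific` | mmol gDW⁻¹ h⁻¹ | 0.45 | common non-growth maintenance magnitude for anaerobes |
| `product_floor` | – | 0.8 | measured products must be ≥ 80 % reproduced |
| `etoh_uptake_vmax` | mmol l⁻¹ h⁻¹ | 0.25 | saturation of the elongator's ethanol uptake; the lever that makes its energy budget finite (below) |
| sampling `n` / `thin` | – | 15000 / 10 | 15000 retained samples; thinning 10 keeps the default run in tens of seconds on one CPU |

Abundance defaults derive from cell geometry: rods of 3.2 × 0.5 µm
(acetogen) and 12.5 × 1.5 µm (elongator) counted 10:1 give a volume ratio
of 36, a dry-mass ratio of 22 (`DW = 435·V^0.86`), and biomass fractions of
68.3 % / 31.7 %. Recomputing the fractions from the formulas gives 68.35 %,
slightly off the conventionally quoted 68.5 % — the difference is
intermediate rounding, and we report the recomputed value.

## What the toy models emulate — and what they do not

The generators build small, fully C/H/O-balanced networks. Reducing
equivalents are lumped into intracellular H₂ and energy into an explicit
ATP/ADP/phosphate cycle, so electron- and energy-limited behaviour emerges
from stoichiometry:

* **Acetogen** (≤ 20 reactions): CO dehydrogenase (CO + H₂O → CO₂ + 2[H]),
  lumped acetyl-CoA synthesis (2 CO₂ + 4[H]), acetate kinase as the sole
  ATP source, acetate reduction to ethanol, optional succinate overflow
  (2 acetyl-CoA → succinate + [H], excreted) and an optional formate
  valve. Exact closed forms: max acetate = 1/4 and max ethanol = 1/6 per
  CO, both electron-capped.
* **Elongator**: ethanol oxidation to acetyl-CoA (+2[H]), ATP-consuming
  acetate activation, condensation to a crotonyl-level C4, an
  ATP-conserving butyrate-forming step (lumping the substrate-level
  phosphorylation and ion-gradient coupling of chain elongation),
  elongation to hexanoate, CO₂ fixation into pyruvate for biomass (CO₂ is
  essential), and optionally succinate → crotonyl-C4 at zero ATP cost.
  Growth requires ethanol **and** acetate **and** CO₂ by construction;
  ethanol uptake saturates at `etoh_uptake_vmax`.

The community consequently shows the qualitative phenomena the framework
is meant to probe: the elongator consumes most of the acetogen's ethanol;
at a 70/30 elongator/acetogen biomass split on CO alone the scenario is
infeasible when succinate uptake is blocked and feasible when it is open
(the elastic diagnosis puts all slack on the elongator's maintenance and
biomass bounds — its ATP budget is the binding resource, since the
saturating ethanol uptake caps ATP-positive crotonyl flux at
`vmax/2 ≈ 0.125` mmol l⁻¹ h⁻¹ while maintenance demands
`0.45 · X_T · φ_ck`); and succinate strictly raises attainable hexanoate.
With every drain disabled, maximal hexanoate per CO equals the
electron-balance bound 1/16 exactly.

What the toys deliberately do **not** reproduce: gene-resolved pathways
(gene associations are synthetic labels, 1–2 per internal reaction with
occasional isoenzyme ORs, present only so candidate filters are
exercised), absolute flux magnitudes of real reconstructions, nitrogen/
phosphorus balance, thermodynamics, pH and acid toxicity, and gas–liquid
mass transfer. A green test on a toy therefore establishes that the
*procedure* is correct, not that any real-organism number is reproduced.

Synthetic "measurements" are the product exchanges of a canonical solve
(maximise hexanoate export, parsimonious tie-break), optionally perturbed
by multiplicative lognormal noise (default sd 0.05, mean-one
parameterisation) — measurements are positive rates, so multiplicative
noise is the natural error model. With zero noise the
constrain-and-resolve round trip recovers the generating exchanges to
1e-6, which is the analysis-stage self-consistency check.

## Numerical choices

* **LP solver.** A dense two-phase bounded-variable primal simplex
  (feasibility/optimality tolerance 1e-9, Bland's rule after 4000
  iterations, refactorisation every pivot). Networks here have at most a
  few hundred variables, where robustness beats speed. Infinite bounds are
  replaced by a scaled large box; a solution pinned to that box is
  reported as unbounded. Duals and reduced costs are returned and the
  strong-duality identity is used as an audit (`dual_gap`).
* **Vertex enumeration** (`enumerate_vertices()`) is an independent oracle
  for small polytopes, used by the tests; it shares no code with the
  simplex path.
* **Sampling** is artificial-centering hit-and-run: warm-up points are the
  FVA vertex solutions, chord directions are stored-point-minus-center
  (hence inside the null space), and each retained sample is re-projected
  onto `{S v = 0}` through an orthonormal row-space basis to stop
  numerical drift. Coordinate bounds get a 1e-9 slack in the chord ratio
  test so coordinates pinned at a bound to LP precision cannot freeze the
  walk; sampled points satisfy bounds to 1e-6 and steady state to well
  below 1e-6. Thinning defaults to 10 steps per retained sample — enough
  mixing for these small polytopes at interactive cost; raise it for
  larger networks.
* **Strain design** solves the bi-level programs exactly by implicit
  branch-and-bound over knockout subsets: subsets are pruned with an
  optimistic LP bound (max target under the partial knockout set, growth
  optimality ignored — a valid upper bound for every superset), and leaves
  are evaluated by a two-stage LP (max growth; then max and min target on
  the growth-optimal face). A strong-duality single-level MILP
  reformulation was considered and rejected: without an industrial MILP
  backend, big-M dual reformulations on a dense textbook simplex are
  numerically fragile, while implicit enumeration with LP bounds is exact
  at these candidate-set sizes and keeps the oracle (naive exhaustive
  enumeration in the tests) genuinely independent.
* **Tie-breaking.** Reported single solutions use a parsimonious
  second-stage LP (minimal total absolute flux at the fixed optimum).
  Equal-objective designs prefer fewer knockouts, then lexicographic ids.
* **Degenerate inputs.** Infeasible scenarios are first-class results:
  generators emit them flagged, the pipeline writes an elastic-relaxation
  diagnosis instead of failing, and `evaluate_mutant()` reports an
  infeasible mutant rather than raising.

## Open design decisions taken

* The tabular model dialect is tab-separated with arrow-syntax equations
  plus `#!` directive lines for compartments/formulas, because a published
  "table format" model has no standard schema and round-tripping formulas
  matters for the element audit.
* Extracellular namespace unification is an explicit per-species map, with
  an error on id collisions that disagree on formula — silent fuzzy
  matching risks wrong merges.
* Cross-fed metabolites are wired as *separate irreversible* reactions
  (producer→medium, medium→consumer, optional producer re-uptake) so each
  arrow of the dependency diagram is a separately reportable flux.
* The knockout-candidate notion of "extracellular reaction" excludes pure
  exchanges and translocations (same compound on both membrane sides) but
  keeps chemical conversions that deposit a product in the medium — the
  lumped overflow reactions would otherwise be unknockable artefacts of
  lumping.
* The sampler takes no objective: it characterises the whole constrained
  space, which is also why reported results are sample means ± sd rather
  than single FBA optima.

## Known limitations

Dense linear algebra bounds practical model size (≈ a few hundred
reactions). The sampler's mixing is adequate for toy polytopes but the
fixed thinning is not a convergence diagnostic; for larger models one
should monitor e.g. per-reaction running means. Only C, H and O are
audited for balance. Gene-protein-reaction logic supports `and`/`or`
without nesting parentheses beyond R's parser — adequate for the synthetic
associations used here.
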