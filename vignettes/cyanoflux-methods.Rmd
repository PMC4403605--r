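---
title: "Stoichiometric analysis of cyanobacterial product synthesis: models and methods"
author: "cyanoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometric analysis of cyanobacterial product synthesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanoflux)
```

## The modeling framework

Cyanobacteria such as *Synechocystis* sp. PCC 6803 can be engineered to
excrete fuels and bulk chemicals — ethanol, ethylene, lactate, alkanes,
isoprene and others — directly from CO~2~ and light. How many photons a
molecule of product must cost, how much ATP and NADPH its synthesis
route consumes, and which host reactions must change flux when a cell
switches from growing to producing are questions of *stoichiometry*
only, and flux-balance analysis (FBA) answers them without kinetic
parameters.

The package works on a stoichiometric model: a matrix $S$ (metabolites
$\times$ reactions) with the steady-state constraint $S v = 0$, flux
bounds $lb \le v \le ub$, and a linear objective. Three layers sit on
top of the LP core:

* **Yield accounting** — maximize export of a product at a fixed photon
  influx and normalize the characteristic fluxes per molecule of
  product (photons, NADPH, ATP, O~2~, Rubisco carboxylations, net CO~2~).
* **Trade-off scans** — walk the minimally required growth rate from
  100% to 0% of its maximum and maximize product flux at each step,
  tracing the production frontier.
* **Transition experiments** — at every step of that walk, run
  flux-variability analysis (FVA) over all reactions and classify each
  reaction's change between the growth-only and production-only
  endpoints into six categories (sign change; increase from flux / from
  zero; decrease to flux / to zero; no change).

## The core phototrophic network

Because the genome-scale reconstruction the analysis was originally run
on is an external input, the package generates a curated **core
network** (`generateCoreNetwork()`) that reproduces the stoichiometric
backbone the analysis depends on. Its light reactions are explicit:

* photosystem II and I each absorb **1 photon per electron**;
* the oxygen-evolving complex releases **1 lumen H⁺ per electron**
  (4 H⁺ and one O~2~ per 4 electrons);
* cytochrome b~6~f with Q-cycle translocates **2 lumen H⁺ per
  electron**;
* FNR reduces NADP⁺ with 2 reduced ferredoxins;
* the ATP synthase imports **14/3 H⁺ per ATP**.

Linear electron flow therefore pumps 6 lumen protons per NADPH, giving
an ATP/NADPH ratio of $6 / (14/3) = 9/7 \approx 1.29$ — the package
recomputes this by LP (`etcAtpNadphRatio()`), not from the closed form.
Cyclic electron flow and NDH-1 raise the ratio when demanded; a passive
lumen proton leak lets it fall below 9/7. Carbon enters as bicarbonate
through a cost-free Na⁺-dependent transporter (an ATP-dependent
alternative exists) or as CO~2~ by diffusion; the Calvin–Benson–Bassham
cycle (with Rubisco carboxylase and oxygenase as separate reactions),
lower glycolysis, phosphoketolase, pyruvate dehydrogenase, TCA
reactions, GS-GOGAT nitrogen assimilation from nitrate or ammonium, a
cost-free NAD(P)H interconversion and a maintenance ATP hydrolysis
complete the base network. Every non-exchange reaction is elementally
balanced over C, H, N, O, P and S with explicit protons, water and
charged-species formulas; photons and biomass are the only
unbalanced-by-design pseudo-species.

Extension packs add precursor metabolism for the product pathways:
`fermentative` (acetolactate/ketoisovalerate branch and the
acetoacetyl-CoA trunk), `isoprenoid_mep` (MEP pathway to DMAPP with
ferredoxin-dependent HDS/HDR), `fatty_acid` (malonyl-CoA and acyl-ACP
synthesis to C16/C18), `arginine_tca` (arginine biosynthesis with
P5C/glutamate recycling) and `photorespiration` (glycolate salvage).

### What the generator emulates — and what it does not

The core network reproduces the published light-reaction stoichiometry,
carbon fixation cost (3 ATP and 2 NADPH per CO~2~ to triose), and the
product-pathway chemistry, so per-product demands computed on it equal
the genome-scale values wherever those are determined by this backbone
(all fermentative products, the C4/C5 alcohols, isoprene, the fatty
alcohols). It does **not** match the genome-scale model's size
(hundreds of biosynthetic reactions), its exact biomass composition, or
its internal conventions for ferredoxin-coupled reactions. Consequently
active-reaction counts are core-scale (tens, not hundreds), the
biomass-row quantities are out of scope, and for products whose
published values depend on full-model ferredoxin conventions (propane,
pentadecane, heptadecane) the package reports its own computed values
and flags the difference via `knownDeviations()` rather than matching.
Passing tests therefore certify the stoichiometric accounting, not any
claim about the complete metabolic inventory of a real cell.

### Choices worth recording

* **MEP pathway energetics.** The CDP-ME segment (three enzymatic steps
  plus carrier-nucleotide recycling) is lumped into a single reaction
  charged at diphosphate level, 2 ATP → 2 ADP + P~i~. Charging full
  nucleotide-level CMP recycling (3 ATP-equivalents) would make
  isoprene ATP-limited and raise its photon demand above the
  electron-stoichiometric value of 56 = 2 × 28, which is inconsistent
  with the published ATP demand (17, within the 18 ATP that linear flow
  supplies at 56 photons). The lump is elementally balanced.
* **ATP synthase at 14/3 H⁺/ATP.** Not stated explicitly in the
  published work; it is the value that yields the printed
  linear-electron-chain ratio of 1.29 with the Q-cycle above.
* **Toy biomass.** `toyBiomassObjective()` drains 8 triose phosphate,
  3.5 acetyl-CoA and 2.5 glutamate and hydrolyzes 200 ATP per unit of
  biomass. The composition is a package invention, chosen once so that
  (i) the ATP/NADPH demand exceeds 9/7, as biomass synthesis does, and
  (ii) the maximal growth rate at the reference light fluxes is near a
  24-30 h doubling time. No published biomass-row number is asserted on
  it.
* **NDH-1 pumping stoichiometry** defaults to 2 H⁺ per electron and is
  configurable; it is irrelevant to yield-mode results (NDH-1 is
  off/unused there).

## Scenarios

Two constraint presets reproduce the two published regimes:

| parameter | yield mode | transition mode |
|---|---|---|
| photon influx (fixed) | 15.57 | 18.0 |
| maintenance ATP (mmol gDW⁻¹ h⁻¹) | 0 (reaction disabled) | ≥ 0.6312 |
| Rubisco oxygenase | decoupled, free | 3% of total Rubisco flux |
| respiration (cytochrome-c oxidase) | disabled | 10% of PSII O~2~ evolution |
| Mehler-like reaction | disabled | 10% of PSII O~2~ evolution |
| ROS evolution | disabled | 0.5% of each photosystem's electrons |
| nitrogen source | nitrate (ammonium selectable) | nitrate |

Three interpretation points were genuinely open and are resolved as
follows. "3% of flux through the oxygenase" is read as oxygenase = 3%
of *total* Rubisco flux, i.e. $v_{oxy} = (3/97)\,v_{carb}$ — "of flux
through" most naturally refers to total throughput; the coupling row is
built exactly that way and is switchable. The respiration and Mehler
couplings are tied *dynamically* to the PSII flux variable (a coupling
row), with a `dynamic_coupling = FALSE` variant that freezes them at
the initial wild-type value, since the published wording ("of the
initial oxygen evolution") supports either reading. The maintenance
demand is a **floor**, not an equality: the transition results
explicitly show the maintenance hydrolysis *increasing* toward the
production-only phenotype, which is only possible if the optimizer may
hydrolyze more than the basal demand.

## Yield accounting conventions

ATP demand is the flux through the ATP synthase; NADPH demand is the
FNR flux minus the NDH-1 flux; Rubisco is the carboxylase flux; O~2~
and CO~2~ are net exchange fluxes. Flux optima of FBA are degenerate,
and vertex-dependent reporting would be irreproducible, so
`stoichiometricSummary()` fixes the product at its optimum and reports
each demand as the **minimum of the corresponding flux over the optimal
polytope** — the unavoidable stoichiometric requirement, invariant to
which optimal vertex a solver happens to return. The active-reaction
count instead comes from a parsimonious (total-absolute-flux-minimal)
solution, in which futile cycles collapse to zero; the passive lumen
proton leak is exempt from that penalty because the penalty
approximates enzyme usage and the leak is not enzymatic.

Electrons entering pathways directly from reduced ferredoxin (the
aldehyde deformylating oxygenase, the MEP reductases) bypass FNR, so
the summary reports both the FNR-based NADPH count and the total
two-electron-equivalent demand; for such products the two differ and
only their sum is constrained by photon stoichiometry.

Units: the reference influx 15.57 is in µmol photons gDW⁻¹ h⁻¹, and
product fluxes are reported on the same µmol scale — only then do flux
× photons-per-product = influx and flux × LHV (kJ mol⁻¹ = J µmol⁻¹
after ÷1000) reproduce the published flux and yield columns, despite
the mmol label printed on those columns. `energeticYield()` follows
this µmol-consistent convention.

## Transition classification

For each reaction the flux range $[v^{min}, v^{max}]$ at each grid
point is summarized by its midpoint (for an interval the median and the
mean of the range coincide — the midpoint is used). With $a$ and $b$
the midpoints at 100% growth and 100% production: a reaction is below
focus when $|a| \le 10^{-6}$ and $|b| \le 10^{-4}$ mmol gDW⁻¹ h⁻¹;
a **sign change** when the product of the endpoint minima or maxima is
negative (tested first, mirroring its separate summary column);
**no change** when $|b-a| / \max(|a|,|b|) < 0.05$ — the symmetric
denominator avoids division by zero at either endpoint; otherwise an
increase (from zero iff $|a| \le 10^{-6}$) or a decrease (to zero iff
$|b| \le 10^{-4}$). Classification depends only on the endpoints, so
the grid density (default 101 points, configurable; growth enforced as
an inequality $\mu \ge f \mu_{max}$) cannot change the category counts
— a property the test suite verifies rather than assumes.

## Numerical choices

The LP engine is a bounded-variable two-phase revised simplex written
for this package (the target R environment ships no general LP solver):
product-form basis updates with periodic refactorization, Dantzig
pricing with a Bland's-rule fallback against cycling, warm starts
across FVA objectives, and single-threaded deterministic pivoting so
degenerate optima are reported reproducibly — ranges, not vertices, are
the contract. Feasibility/optimality tolerances are $10^{-9}$; every
reported optimum carries a primal-dual agreement check at $10^{-7}$
relative. When an objective is fixed for FVA or flux minimization it is
fixed at its optimum minus an absolute slack of $10^{-9}$ to avoid
numerical infeasibility. Reported fluxes are rounded to $10^{-6}$ —
below the smallest classification threshold — so solver-level noise can
neither flip a trajectory category nor activate a phantom reaction.
Stoichiometric coefficients are written as rational literals (14/3,
3/97) and kept as double-precision numbers throughout; a dedicated
exact-rational layer would not change any reported quantity at these
tolerances.

Isoenzyme handling: explicit `isoenzyme_group` keys merge reactions
into one representative carrying the summed bounds (scale-equivalent
members are converted to the representative's flux scale); for external
models without a published grouping, `collapseIsoenzymes(auto_group =
TRUE)` groups reactions with identical stoichiometry up to positive
scaling. This heuristic need not reproduce the original count of
classification-eligible reactions exactly, since the original grouping
was not published.

## Problem sizes in the shipped tests

The test suite and the acceptance script run the full pipeline at core
scale: ~80-110 reactions per model, FVA over all reactions, transition
experiments on 3-5 point grids (category counts are
endpoint-determined, see above), and trade-off frontiers on 5-9 point
grids. These sizes keep the whole suite near half a minute while
exercising every code path; all quantitative claims are invariant to
the grid sizes used.

## Limitations

Kinetics, enzyme capacities, product toxicity and the photosynthetic
sink effect are outside the framework: computed flux distributions are
stoichiometric target states, not predictions of what a strain will do
after pathway insertion. Genome-scale quantities (total reaction
counts, biomass-row demands, transition category counts in the hundreds)
require the original genome-scale SBML as an input; the reader
(`readSBMLModel()`) accepts it, but the packaged core network does not
impersonate it.

## A worked example

```{r example, eval = FALSE}
core <- generateCoreNetwork(extensions = "fermentative")
eth <- augmentWithProduct(core, "ethanol")
stoichiometricSummary(eth, "ethanol")      # photons 24, NADPH 6, ATP 7, ...
etcAtpNadphRatio(core)                      # 9/7
```
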