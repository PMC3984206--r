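---
title: "Methods: mass-balance food webs and MPA trophic dependency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass-balance food webs and MPA trophic dependency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpaweb)
```

## What the package models

`mpaweb` quantifies how much of the trophic functioning of a shelf ecosystem
is underwritten by a marine protected area (MPA) embedded in it.  The system
of reference is the Mauritanian shelf with the Banc d'Arguin National Park:
a two-habitat food web in which the MPA's truly sedentary groups — benthic
invertebrates, resident zooplankton, benthic phytoplankton, macrophytes —
exist alongside their shelf counterparts, while mobile consumers split their
invertebrate and plankton feeding across the two habitats according to a
per-group share `pBA`.

The analysis proceeds in four stages, each an exported module surface:

1. **Static mass balance** (`balance()`): an Ecopath-type solution of
   `B_i (P/B)_i EE_i = Y_i + sum_j B_j (Q/B)_j DC_{ij} + BA_i` per group,
   producing the consumption-flow matrix, trophic levels, and the mortality
   partition `P/B = F + M2 + M0 + BA`.
2. **MPA dependency** (`iterate_dependency()`): the share of every group's
   consumption, production and catch originating — directly or through the
   food web — from the MPA's sedentary set.
3. **Structure diagnostics**: mixed trophic impacts (`mti_matrix()`) and
   log-normal trophic spectra (`build_spectrum()`).
4. **Dynamics** (`simulate_foodweb()` and the `scenario_*()` wrappers):
   effort-driven foraging-arena biomass projections, vulnerability fitting,
   and the two management scenarios (a hypothetical fleet inside the MPA;
   loss of the MPA's habitat).

## The mass balance and its conventions

Each consumer or producer group must arrive at `balance()` with exactly one
unknown among biomass, P/B and EE (Q/B may be carried implicitly as
P/Q x Q/B; total mortality `Z` stands in for P/B where tables print it that
way).  Unknown biomasses couple across groups through predation and are
solved as one linear system; unknown EE and P/B then follow per group.
Detritus is not balanced — its ecotrophic efficiency is diagnosed from the
detrital budget with a configurable unassimilated fraction (default 0.2).

Conventions that the literature leaves open, fixed here:

* **Biomass accumulation** is a relative rate (yr^-1) applied to biomass, so
  the accumulation flow is `ba * B`; values like -0.05 in published tables
  are typical relative rates.  A `ba_absolute` switch interprets the column
  as a flow instead.
* **Import and trophic levels**: imported diet is assigned the consumer's
  own diet-weighted mean prey level, i.e. the diet is renormalised over
  modelled prey — the convention of the standard software, so published TL
  columns remain comparable.
* **Unbalanced inputs** (EE > 1) are returned with diagnostics and a
  warning, never silently clamped: re-parameterising an infeasible web is
  the modeller's loop, not the solver's.

## Dependency on the protected area

With the balanced flow matrix `Q[j,i]` (predator j, prey i) and the
sedentary set `Nba`, the direct MPA-origin consumption of predator `j` is
`Qba_dir_j = sum_{i in Nba} Q[j,i]`.  Indirect origin propagates through
intermediate consumers: prey `i` converts MPA-origin consumption `Qba_i`
into production with its gross efficiency `(P/Q)_i`, passes on the fraction

`t_i = EE_i (1 - fY_i) (1 - fBA_i)`

that is neither lost to detritus, nor fished (`fY = Y/P`, the fished
fraction of production), nor accumulated (`fBA = BA/(P/B)`), and that flow
is divided among `i`'s predators by their predation shares.  The totals are
the fixed point of

`Qba_j <- Qba_dir_j + sum_i (P/Q)_i t_i Qba_i Q[j,i] / sum_k Q[k,i]`

iterated to a 1e-10 tolerance (default cap 1000 iterations; the map is a
positive contraction whenever every `t_i (P/Q)_i < 1`, so convergence is
geometric and monotone from below — synthetic webs converge in well under
200 iterations).  Afterwards the proportions of consumption, production and
catch from the MPA coincide per group: `pqba = ppba = pyba = Qba/Q`.

Three deliberate choices:

* **Detritus-mediated paths are excluded** by construction: `t_i` retains
  only the production consumed by predators, and detritus is neither a
  member of `Nba` nor a carrier.
* **Sedentary-set members count fully** (`nba_full = TRUE`): they live in
  the MPA, so the ecosystem totals treat their consumption and production
  as entirely MPA-origin; the propagation itself never routes *through*
  them (their onward flow is already captured by the direct term of their
  predators), which keeps direct and indirect contributions additive.
* **Two conventions for the fished fraction** are implemented — the literal
  product above (default) and the flow-accounting ratio `M2 B / P`.  They
  differ only for fished or accumulating groups; both are exposed because
  the verbal definition underdetermines the algebra.

`dependency_by_paths()` recomputes the same quantity by exhaustive
depth-first enumeration of all prey-to-predator paths leaving `Nba`.  It is
exponential and restricted to acyclic webs, but entirely independent of the
fixed-point code; the test suite holds the two within 1e-8 on generated
webs, and it supplies the ground truth shipped with synthetic bundles.

Ecosystem totals are flow-weighted means: consumption- production- and
catch-weighted over the 47 consumer groups, with a second production total
that adds the MPA's own primary producers (benthic phytoplankton, algae and
eelgrass) fully to the numerator and all producers to the denominator.

## Mixed trophic impacts and trophic spectra

The net direct impact of group `i` on `j` is its share in `j`'s diet minus
its share of the predation pressure on `j`; the Leontief-type closure
`(I - q)^{-1} - I` accumulates all indirect routes.  Fleets can join as
pseudo-groups (catch composition as "diet", landings as "predation");
the default excludes them, matching the usual group-only presentation.

Trophic spectra spread each group's quantity (biomass, production, catch,
F, or the MPA-origin share of production) over a trophic-level grid
(default 1.0-5.6, step 0.1) with a log-normal kernel centred, in the
median, on the group's TL.  The within-group standard deviation follows
`sigma(TL) = 0.10 + 0.05 (TL - 2)` (floored at 0.02): variability grows
with trophic level, as omnivory does.  The cited convention for `sigma` is
not fully specified in the source literature, so the rule is exposed and
all spectrum-based landmarks are treated as sigma-sensitive qualitative
quantities.  Numerical details: kernel mass is computed per bin from the
log-normal CDF, the lowest bin collects all mass below TL 1 (a basal spike
has nowhere lower to live), weights are renormalised so each group's total
is conserved exactly, and a warning reports any group whose raw kernel
would leak more than 0.1% past the grid top.  Median-centring biases the
smoothed mean TL upward by about `sigma^2 / (2 TL)` — under 0.005 TL for
typical parameters — and basal spikes are quantised to the first bin
midpoint, so first-moment preservation is only guaranteed away from the
TL = 1 edge.

## Dynamics: foraging arenas at desk scale

Biomass dynamics follow the foraging-arena form: the flow on each link is
`Q = a v B_i B_j / (2 v + a B_j)` with exchange rate `v = V Q0 / B_i0` and
search rate `a` calibrated so the base-state flow equals the mass-balance
flow exactly; `V >= 1` is the familiar vulnerability multiplier (`V = 1`
collapses to donor control, large `V` to mass action).  Producers follow a
saturating production response with half-saturation at twice base biomass —
`P(B) = 3 (P/B)_0 B_0 B / (B + 2 B_0)` — an assumption the source system
leaves unspecified and a stated fidelity limit.  The detrital pool is held
at its base size.  Fishing mortality is the base fleet pattern scaled by
yearly effort multipliers, plus optional per-group forcings.

Integration is classic RK4 on a monthly base step, with automatic
substepping wherever per-biomass turnover would violate the explicit
stability bound: plankton-speed groups (Q/B above 100 yr^-1) make a fixed
monthly step linearly unstable, so the step refines locally instead of
globally slowing the whole web.  States falling below 1e-10 of initial
biomass clamp to that floor and the event is logged.  With unit effort and
no accumulation terms the base year is an equilibrium by construction, and
the suite holds 5-year drift under 0.5%.

Vulnerability fitting minimises the sum of squared log-residuals between
simulated and observed biomass/catch series by bounded coordinate search,
one multiplier per predator (the desk-scale parameterisation); a flat
objective returns the lower bound with a non-identifiability diagnostic.

### Scenarios

* **Fictive MPA fleet**: per-group extra mortality
  `F_{y,i} = pBA_i min(0.02 * 2^(y-1991), cap_i)`, cap 0.4 yr^-1 for
  juveniles and the small coastal/shelf fish, 0.8 yr^-1 otherwise; its
  catch accrues to a fleet named `fictive`.
* **Habitat loss**: extra mortality on the MPA-resident groups starting at
  0.02 yr^-1 and doubling yearly.  A doubling-forever forcing would
  exterminate the macrophytes too, whereas the reference behaviour is a
  partial (~40%) macrophyte decline alongside extinction of the other
  forced groups.  With the saturating producer response the equilibrium
  under extra mortality `Mx` is `B/B0 = 3 (P/B)_0 / ((P/B)_0 + Mx) - 2`,
  so `Mx = (3/2.6 - 1) (P/B)_0 ~= 0.154 (P/B)_0` yields a 40% decline in
  closed form; the macrophyte forcing is capped there (configurable), and
  the remaining groups cap only at an integrator-sanity 256 yr^-1.
* **Status quo**: constant effort, the baseline for `end_state_ratios()`
  (per-group and biomass-weighted aggregate end-biomass ratios, flagged
  undefined where the baseline itself sits at the extinction floor).

Scenario magnitudes at this desk scale are indicative: they depend on the
producer response, the uniform default vulnerabilities, and the synthetic
diet stand-in described next.  The suite therefore asserts their sign
structure (targeted MPA-dependent groups decline, some prey are released,
total catch rises while its mean trophic level falls, the forcing
calibration reproduces the partial macrophyte decline), not their exact
percentages.

## The packaged 51-group table and the synthetic diet stand-in

`table1_fixture()` ships the published base-year parameter table verbatim:
51 groups, three fleets, with the printed TL, biomass, Z, P/B, Q/B, EE,
P/Q, BA and landings, and a per-group record of which printed values were
estimated rather than input.  The published diet-composition matrix and
per-group `pBA` values exist only in supplementary material that cannot be
redistributed here, so `synthetic_base_diet()` builds a clearly-labelled
synthetic stand-in:

* prior weights combine prey availability (production), a trophic-level
  kernel centred one level below the predator, and habitat feasibility
  (sedentary MPA prey only for `pBA > 0` predators, weighted by `pBA`;
  shelf counterparts — including the shelf half of the phytoplankton pair —
  weighted by `1 - pBA`; benthic prey discounted for pelagic feeders;
  MPA residents feeding only inside);
* iterative proportional fitting reconciles those priors with the predation
  total each prey group must supply under the printed balance
  (`B (P/B) EE - Y - BA`), the detrital pool absorbing the slack;
* the default `base_pba()` shares follow the published text (0.5 for
  juvenile, coastal and migratory groups; 0 for sardine, stated to feed
  entirely outside; judgement values for partial users of the area), and
  the two published sensitivity variants transform them (`M30` halves
  them, `P30` raises juveniles to 1 and seven coastal groups by half) along
  with the sedentary biomass (0.7x / 1.3x).

The reconstruction reproduces the printed per-group EEs through its flows
to machine precision and leaves computed trophic levels close to print.
Consequences worth stating plainly: ecosystem-level aggregates, which the
printed table pins tightly, are faithful; per-group dependency values,
which hinge on unpublished diet detail, are indicative only — a group whose
printed TL forces most of its intake onto trophic-level-1 resources (the
mullet is the clearest case) can only register MPA dependency through the
benthic-phytoplankton fraction the availability prior assigns it.  Nothing
in the stand-in is calibrated against the published dependency results
themselves.

## The synthetic-web generator

`generate_web()` emulates the study design at arbitrary size: one producer
per habitat, sedentary invertebrates on each side, mobile consumers in a
strict trophic order whose invertebrate feeding splits by a drawn `pBA`
(default range 0.2-0.8), one or more fleets harvesting drawn fractions
(0.05-0.2) of production, effort trending geometrically (default 7%/yr
over 16 years, echoing the reference period's effort growth), and
log-normal observation noise (default sd 0.1).  Consumption rates fall
with trophic rank, gross efficiencies sit in 0.05-0.3, ecotrophic
efficiency targets in 0.3-0.95 — all within the spread of the published
table.  Biomasses are assigned from the top of the web downwards so every
realised EE equals its target exactly: generated webs pass `balance()`
with zero violations by construction, and their acyclicity makes the
path-enumeration oracle exact.  What the generator does **not** emulate:
diet cycles and cannibalism (tested separately with hand-built loops),
multi-stanza life histories, environmental forcing, and the skewed
biomass-dominance structure of the real table — so green synthetic tests
certify the algorithms, not the realism of any particular parameterisation.

All generated artefacts are bit-reproducible under a fixed seed.

## Problem sizes and defaults

The suite and the acceptance script run the 51-group model (dependency in
well under a second; each 66-year scenario in tens of seconds with the
stability-based substepping) and synthetic webs of 7-10 groups for the
oracle, equilibrium and recovery studies; the vulnerability-recovery study
uses a 16-year single-fleet series at 10% observation noise and recovers
per-predator multipliers within 20% for groups whose biomass moves by more
than 30% over the series.  Key defaults: dependency tolerance 1e-10,
spectrum grid 1.0-5.6 by 0.1, `sigma0 = 0.10`, slope 0.05, vulnerability
2 for unfitted predators, 12 base integration steps per year, extinction
floor 1e-10 of initial biomass.

## Known limitations

* The 51-group diet matrix is a constrained reconstruction, not data;
  per-group dependency and anything downstream of diet detail inherit that.
* `pBA` enters the statics only through the diet priors; the fictive-fleet
  scenario uses it directly, as the targeting rule is defined in its terms.
* The producer response and detritus closure are structural assumptions;
  scenario magnitudes (not signs) move with them.
* Trophic spectra quantise basal spikes to the first bin and are
  sigma-sensitive; spectrum landmarks are qualitative.
* No multi-stanza consistency, discards, mediation, or spatial dynamics.
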