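---
title: "Modelling seasonal cambial cell production"
author: "cambium package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seasonal cambial cell production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cambium)
```

## The model in brief

The package simulates one radial file of cambial cells through a growing
season. The state of a cell is its radial diameter, its amount of a
hypothetical differentiation inhibitor, and a stress flag; everything else
(cell-cycle phase, growth rate, fate) derives from those. The central
assumptions are:

* **Phase from size.** A cell is in G1, S, G2 or M according to diameter
  bands with fixed critical thresholds; division happens at a critical
  diameter, producing two daughters of half the size.
* **Inhibitor economy.** The inhibitor enters the system once per season,
  as the initial cell's supply. It is never created or destroyed inside the
  file: each division splits the mother's amount `α : 1 − α` with the
  larger share (α = 0.8286 by default) going to the proximal daughter, the
  one nearer the initial. A cell's concentration is amount over diameter,
  so it falls as the cell grows, and falls geometrically down the file with
  each division. When a cell's concentration is below the minimum `C_min`
  it loses the ability to divide and transfers to the enlargement zone;
  the number of such transfers in a season is the simulated cell
  production.
* **Growth rates.** The G1 rate is a Gompertz function of the cell's own
  current concentration, `exp(−exp(−c·C))` µm/day — bounded in (0, 1],
  equal to `exp(−1)` at zero concentration and increasing in `C`. S, G2
  and M run at a constant observed rate `V0`. The initial cell's first
  cycle after dormancy is special: a constant rate carries it from its
  initial diameter to its first division in a configurable period `d`.
* **Climate enters twice.** The environmental forcing is a daily integral
  growth rate `Gr(t) ∈ [0, 1]` supplied externally (in practice by the
  environmental block of the Vaganov–Shashkin model; computing it is out of
  scope here). It determines the seasonal supply through a six-regressor
  linear model on the summary statistics of `Gr` (plus the previous
  season's skewness), and it flags *stress divisions*: a division preceded
  by three or more strictly declining days of `Gr` marks both daughters as
  stressed, which changes their G1 rate through the stress coefficient
  `S`.

## Parameters

| name | meaning | units | default |
|------|---------|-------|---------|
| `D_S`, `D_G2`, `D_M` | phase thresholds G1→S, S→G2, G2→M | µm | 8.5, 8.7, 9.0 |
| `D_div` | critical diameter for division | µm | 9.5 |
| `D_init` | initial-cell diameter after dormancy | µm | 2.0 |
| `C_min` | minimum concentration for division | rel. units | 0.03 |
| `V0` | growth rate in S/G2/M | µm/day | 0.68 |
| `c_g1` | G1 Gompertz parameter | rel. units | 0.071 |
| `S_stress` | stress coefficient in the G1 rate | rel. units | 100 |
| `alpha` | proximal daughter's inhibitor share | — | 0.8286 |
| `d_init` | period of the initial division | days | 7.5 |

The diameter thresholds, `C_min`, `V0`, `c_g1`, `S_stress` and `alpha` are
season-invariant values estimated from anatomical observations of Siberian
larch; they are the package defaults and everything in the test suite uses
them. `d_init` appears in the growth-rate rule for the initial cell but no
fitted value is published for it, so it is an explicit configuration
parameter; 7.5 days is the package default and gives an initial rate of
1 µm/day, comfortably above the asymptotic G1 rate, consistent with the
first division happening within the first simulated week.

Three conventions were genuinely open and are exposed as switches on
`cambium_params()`:

* **`stress_mode`.** Taken literally, the stressed G1 rate multiplies the
  exponent argument by `S = 100`, which *accelerates* stressed cells.
  Biologically, climate stress is expected to slow cambial growth, and a
  divisor reading (`c·C/S`) does that. The default is the literal printed
  form (`"literal"`); `"reciprocal"` is provided, and the direction of each
  mode is pinned by property tests.
* **`g1_env_coupling`.** The G1 rate rule contains no `Gr(t)` term, so by
  default the daily forcing affects G1 cells only through the seasonal
  supply and stress flags (`"none"`). Reported correlations between G1
  kinetics and the external rate suggest a direct coupling may be intended;
  `"multiplicative"` scales the G1 rate by the day's `Gr`.
* **`mad_scaled` / skewness.** The supply regression's `mad` term is the
  raw median absolute deviation (no 1.4826 normal-consistency factor),
  which is the literal reading of "median absolute deviation"; skewness is
  the population moment coefficient `g1 = m3/m2^1.5`, defined as 0 for a
  constant sequence (the 0/0 case). The mad convention is switchable
  because the regression's coefficients were fitted under an unstated one.

## Numerical design

**Event-driven integration.** Within a regime the diameter grows linearly,
so phase-boundary crossings are solved exactly as
`(threshold − diameter)/rate` rather than by time stepping. All cells
advance concurrently in daily steps; a cell's G1 rate is recomputed at day
boundaries and phase boundaries (its concentration is constant between
divisions, but the daily forcing and the coupling option are not). Division
events spawn daughters mid-day, which then advance over the remainder of
that day. Times are reported to 0.001 day in the division log; internal
arithmetic is exact to double precision, and the test suite checks the
engine against an independent fixed-step integrator (`dt = 5e-4` day)
within ±1 cell and ±0.01 day per event.

**Tie-breaks and degenerate inputs.** Exit uses a strict inequality:
concentration exactly equal to `C_min` retains division ability. Exit is
evaluated at birth and again at the division diameter — concentration only
falls between those two points, so intermediate checks would be redundant.
A supply at or below `C_min · D_init` cannot support any division and
returns production 0 immediately; a non-positive predicted supply is
flagged, warned about, and treated the same way rather than clamped
silently. The initial cell (position 0) never exports: when its
concentration falls below threshold it halts at the division diameter and
the rest of the file drains.

**Termination.** Inhibitor amounts are conserved, so a literal "supply
consumed" never occurs; it is operationalised as *no cell in the file has
concentration ≥ `C_min`*, checked at day boundaries. The simulated season
length is then the time of the last division or export; if the
environmental season ends first, the environmental length is reported. A
generous division cap (10^5) guards against non-termination and is asserted
never to fire.

**Inversion of the production response.** Observed cell counts are mapped
back to supplies by bisection on the predicate `production ≥ target`. The
response is globally increasing but locally jagged — a marginal cell that
divides rather than exporting strands its daughters in the file at season
end, so the staircase has narrow islands and, on short seasons, a
season-length-limited falling branch. After bisection the inverter
therefore scans a fine grid below the bracket and a geometric grid above it
for the equality plateau, and reports `attained = FALSE` with the
closest-production supply when the target genuinely cannot be realised.

**Optimisation.** Average-season tuning minimises a weighted squared error
on production and first-division day. The objective is piecewise constant
in most parameters, so the optimiser is derivative-free by design: a
deterministic coarse grid picks starting points, Nelder–Mead refines them
(bound violations penalised), and one-dimensional problems use
golden-section search. Identical inputs always give identical results.

## What the synthetic generator emulates — and what it does not

No environmental or anatomical series are distributed with the package, so
every workflow is exercised on synthetic fixtures with recorded ground
truth. A synthetic season is a sinusoidal bell over days of year 127–285
(the average season bounds for the reference site) with:

* a per-year peak drawn from 0.55–1.0 and a per-year bell exponent from
  0.7–2.2 — wet years with broad flat maxima alongside dry, peaked ones;
* a small positive per-year baseline (0.003–0.08): inside a detected
  growing season the limiting-factor rate stays above zero, and its
  seasonal minimum varies between years (this also keeps the `min`
  regressor of the supply model identifiable);
* AR(1) day-to-day noise (σ = 0.05, ρ = 0.6);
* two injected stress dips per season, 3–6 strictly declining daily steps
  each, placed without overlap so the stress detector provably fires inside
  every dip.

Under the default regression these conditions give seasonal supplies of
about 2.5 ± 0.4 relative units and productions in the low tens of cells
(interannual CV ≈ 20–25 %), matching the magnitude of cell-count series
from semi-arid Siberian larch. The generator does **not** emulate actual
station climatology (no temperature or moisture is modelled), long-memory
climate persistence across years, age trends, or measurement error in cell
counts other than optional Poisson jitter. Passing recovery tests therefore
demonstrate that the workflow is self-consistent and statistically
well-behaved under realistic variability — not that the model is validated
against real wood anatomy, which requires the original measurement series.

Recovery itself is defined against the recorded truth: the refit regression
should reproduce the generating supplies (exactly, when noise is off) and
the productions simulated from predicted supplies should reproduce the
clean productions. Under supply noise of 0.15 × the mean, supply recovery
stays above R² = 0.9 at 40 seasons while production recovery is limited to
about 0.85 by the staircase response — a few tenths of a unit of supply
error can flip a whole 2–3-cell tread, an intrinsic property of the
division cascade rather than an estimation failure.

## Problem sizes

The test suite simulates full 159-day seasons for ledger, determinism,
monotonicity and plausibility checks; cross-checks against the fixed-step
reference integrator use five random 45–70-day seasons (the reference costs
2000 steps per day); recovery studies use 40 synthetic years, and inversion
round-trips use 60–110-day seasons. These sizes keep the complete suite
around a minute on one core while leaving every code path exercised at
full seasonal scale somewhere.

## Known limitations

* Enlargement, wall thickening and lignification are outside the model:
  production counts cells entering enlargement, not finished tracheids, and
  simulated season length consequently undershoots the environmental
  season.
* Phloem-side divisions are ignored (xylem mother cells outnumber them
  severalfold).
* The stress coefficient's direction and the G1–environment coupling are
  unresolved in the source material; both defaults follow the printed
  equations literally and both alternatives are one switch away.
* The first season of a record has no predecessor for the skewness term;
  the configurable default (0) is used with a warning.
* The production response is a staircase: headline statistics of multi-year
  fits should be read with a ±1–2 cell quantisation floor in mind.
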