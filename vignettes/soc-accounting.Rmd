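---
title: "Four-pool SOC dynamics and regional carbon accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-pool SOC dynamics and regional carbon accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatsoc)
```

## The model

Soil organic carbon (SOC) in cropped topsoil is represented by four pools,
each with first-order kinetics on a daily time step:

* **labile-C** and **resistant-C** — the fast and slow fractions of
  undecomposed fresh residue (half-lives 0.1 y and 2.3 y);
* **light-C** — the biologically reactive soil fraction (half-life 7.6 y);
* **heavy-C** — the decomposition-resistant soil fraction (half-life 73 y in
  the calibrated parameter set, 105.4 y in the original).

One day of the model is, in order: add the day's fresh-residue carbon to the
labile and resistant pools; decompose every pool $i$ by
$D_i = C_i\,(1 - e^{-K_i f})$, where $f$ is a non-negative environmental
rate modifier ($f = 1$ at reference conditions); route the transfer
fractions, light gaining $F_{LL} D_L + F_{RL} D_R$ and heavy gaining
$F_{LH} D_{LC}$; release the remainder of every flux as CO~2~ (the heavy
pool decomposes to CO~2~ only). Reported SOC density (0–30 cm,
Mg C ha^-1^) is the total of the four pools. The daily operator conserves
mass exactly: the change in total carbon equals input minus CO~2~ at every
step, a property the test suite asserts to relative 1e-10 over
10^4^-day trajectories.

Two numerical points are deliberate. First, decomposition uses the exact
per-pool exponential $1 - e^{-Kf}$ rather than the Euler increment $Kf$:
the update is unconditionally stable and agrees with the continuous
solution for an isolated pool, and this discrete operator — inputs, then
simultaneous decomposition, then transfers — *is* the model definition, so
the closed-form affine-map oracle in the tests can match it bit for bit.
Second, rate constants and half-lives interconvert with a 365.25-day year
($t_{1/2} = \ln 2 / (365.25\,K)$); this convention reproduces all three
tabulated half-lives (7.6, 73, 105.4 y) at their printed precision, whereas
a 365-day year does not. Simulated years are 365 days.

With a constant modifier and constant daily inputs the map is affine, so the
steady state is available in closed form (`steady_state()`): at the fixed
point each pool's daily decomposition equals its daily supply. The
steady-state stock is linear in the inputs, which the tests exploit.

### Parameters

| symbol | default | meaning |
|---|---|---|
| `K_L`, `K_R` | from 0.1 y, 2.3 y half-lives | fresh-residue pool rates (d^-1^) |
| `K_LC` | 2.5e-4 d^-1^ (7.6 y) | light-C rate |
| `K_HC` | 2.6e-5 d^-1^ (73 y); original 1.8e-5 (105.4 y) | heavy-C rate |
| `F_LL` | 0.3 | decomposed labile-C routed to light-C |
| `F_RL` | 0.45 | decomposed resistant-C routed to light-C |
| `F_LH` | 0.3 (original 0.45) | decomposed light-C routed to heavy-C |

The `"modified"` (calibrated) set is the default. The source material is
internally inconsistent about the heavy pool: its parameter table gives the
calibrated half-life as 73 y while the initialization text lists 105.4 y.
We follow the parameter table; both sets are selectable via
`soc_params(variant=)`.

### Environmental modifiers

The rate constants apply at modifier 1. The default mode is *neutral*
($f \equiv 1$): decomposition rates are taken as already representative of
the regional climate, which is also how the calibrated constants are
defined. Because temperature and moisture control of decomposition is real
but its functional form is not pinned down by the calibration data, a
*climate* mode is provided as a configurable alternative: a Q10 temperature
response ($f_T = Q_{10}^{(T - T_{ref})/10}$, default $Q_{10} = 2$,
$T_{ref} = 20$ °C) times a moisture response that scales linearly with the
rolling 30-day precipitation total and saturates at 1 (default reference
60 mm/30 d). Both normalise to 1 at reference conditions.

## Carbon input from yields

Annual above-ground residue mass is economic yield times a
residue-to-yield ratio (default 1.5, a wheat harvest index of about 0.4 —
a conventional value, configurable). Root mass is 40% of residue mass;
residue and root carbon content is 45%. The retained fraction of
above-ground residue differs by region — 0.95 in Queensland, 0.83 in
Western Australia, 0.705 in New South Wales, Victoria and South Australia
(midpoint of 24–35% burned) — and is held constant over time. Roots are
always returned to the soil; retention applies to above-ground residue
only. Whether roots should also be discounted is genuinely open; we return
them fully because burning and baling remove shoot material, not root
systems. Manure input is fixed at zero.

Fresh residue carbon splits 0.59 labile / 0.41 resistant by default (the
conventional fast/slow split for cereal residue; configurable). Annual
totals are spread uniformly over the year by default; a harvest-day pulse
mode exists, and either schedule conserves the annual total exactly.

## Spin-up and initialisation

Observed initial SOC fixes the total but not its distribution across pools.
`spin_up()` starts from a 0.25/0.75 light/heavy split of the observed
total, runs the model for 100 years (recycling the available forcing
cyclically), then rescales all pools by a common factor so the total again
equals the observed initial SOC while keeping the spun-up proportions. The
spin-up length is configurable because the source description of the
spin-up window is ambiguous; 100 years is the default.

## Evaluation statistics and calibration

Observations reported for 0–10 cm or 0–20 cm layers are harmonised to
0–30 cm by fixed coefficients 2.35 and 1.32 — assigned so the shallower
layer gets the larger multiplier, as any cumulative depth distribution
requires. Model evaluation uses RMSE (absolute units; a normalised
percent-of-observed-mean variant is behind a flag), the relative mean
deviation RMD $= 100\,\overline{(P-O)}/\bar O$, the Nash–Sutcliffe model
efficiency EF, and OLS regression of predictions on observations with
t-tests of slope = 1 and intercept = 0 at $\alpha = 0.05$.

Calibration of the five key parameters (`K_LC`, `K_HC`, `F_LL`, `F_RL`,
`F_LH`) is an exhaustive grid search. The objective is the **mean absolute
per-trial mean deviation**: each site's mean deviation (predicted minus
observed over that site's observations) is taken in absolute value before
averaging across sites. Averaging the signed deviation over everything
instead would let a positive bias at one site cancel a negative bias at
another — empirically that pooled objective has a near-flat floor across
the parameter grid and cannot identify the generating parameters even at 1%
observation noise, while the per-site form recovers them exactly. The
signed pooled mean deviation is still reported alongside the winner as the
model-bias statistic. Ties break deterministically to the first grid point
in lexicographic parameter order. Default grids bracket the calibrated
values (e.g. `K_HC` over [1e-5, 5e-5]); the original search intervals are
not documented, so these are package choices.

Parameter recovery needs informative trials. The packaged synthetic
calibration fixture is four 50-year trials with annual SOC sampling: a
low-input site, a high-input site, a drier site (modifier 0.6) and a bare
fallow. The fallow isolates the pool kinetics from the input-pathway
fractions, and the input/modifier contrasts break the remaining
rate-versus-fraction trade-offs; designs with a single treatment type and
five-yearly sampling leave the grid under-determined.

## Regional Monte Carlo and decadal accounting

A region is one simulation unit: area (Mha), an empirical sample of topsoil
grid cells, an annual yield series, a retention fraction and (optionally) a
daily climate series. Uncertainty propagation draws, per ensemble member,
one grid cell (uniform with replacement — the empirical soil PDF; no
distribution family is imposed) and one carbon-input multiplier (uniform on
mean ± 10%), then runs spin-up plus simulation; the default ensemble is 300
runs per region (the source alternately mentions 300 and 500; 300 is the
default and it is configurable). Confidence bounds are empirical 2.5/97.5
percentiles across runs.

Decadal accounting uses start-of-year densities: a decade's stock change is
(density at decade end − density at decade start) × area, so decades
telescope exactly to the whole-period total, and 1 Mg ha^-1^ × 1 Mha =
1 Tg with no hidden factors. Belt aggregation sums areas and stock changes
(confidence bounds sum too, which is how the published belt bounds relate
to the regional ones) and area-weights densities and inputs. Loss rates are
|change|/10 Tg yr^-1^; period shares are percentages of the total change.

`required_extra_input()` finds by bisection (tolerance 1e-3
Mg C ha^-1^ yr^-1^) the smallest additional annual input that keeps SOC at
the end of a horizon at or above its starting value, returning 0 when the
baseline already does.

## The synthetic data, and what passing tests do not show

The generators emulate the statistical shape of the real inputs: daily
temperature as a seasonal sinusoid plus noise (warmest in January), rainfall
as a two-state Markov occurrence chain with gamma amounts tuned to the
target annual total (realistic dry-spell structure, no interannual climate
modes), yields rising linearly to double over 50 years with mean-corrected
lognormal noise (CV 0.2), regional soil grids with initial SOC uniform
within each region's published density range, and the five published region
areas summing to 15.08 Mha. Depth-degraded observations are created by
dividing the 0–30 cm truth by the depth coefficients, so conversion is
exactly invertible at zero noise. Every generator is a pure function of
(spec, seed).

What the synthetic world does **not** contain: spatial autocorrelation in
soils or climate, drought years correlated between yield and decomposition,
evolving management, erosion or leaching losses, or nitrogen limitation.
Passing tests therefore demonstrate that the machinery — kinetics,
input accounting, calibration, uncertainty propagation, aggregation — is
correct and self-consistent, not that the packaged defaults reproduce any
particular historical SOC trajectory; reproducing one requires the real
climate, soil and yield inputs. Under the synthetic defaults the simulated
belt loses carbon fastest in the first decades and approaches a new
equilibrium as rising yields lift inputs, the same qualitative pattern the
real analysis shows.

Problem sizes used by the shipped tests and the acceptance script: 50
simulated years per region (plus 100 spin-up years), 25 grid cells per
region, 300-run ensembles for five regions, and a 3^5^-point calibration
grid over four 50-year trials. These sizes exercise every code path at
full ensemble size while keeping a complete run in the order of seconds.

## Known limitations

* The environmental-response forms (Q10 × linear moisture) are plausible
  defaults, not calibrated relationships; neutral mode is the default.
* Calibration is exhaustive grid search only — no gradient or Bayesian
  refinement, and no per-site parameter sets.
* Whether regional confidence intervals should also carry parameter
  uncertainty is open; they propagate soil and input uncertainty only.
* Cropland area and retention rates are fixed over time by assumption.
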