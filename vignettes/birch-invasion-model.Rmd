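---
title: "Modelling birch woodland invasion under deer browsing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling birch woodland invasion under deer browsing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(birchspread)
```

## The problem

Upland birchwoods in the Scottish Highlands regenerate poorly where red
deer browse heavily, but the response of a landscape to deer management
unfolds over decades and depends jointly on browsing pressure, ground
cover, and the location of surviving seed sources. `birchspread`
implements a spatially explicit stochastic simulator of birch invasion
that makes that joint dependence quantitative: it tracks adult trees
individually, juvenile trees as per-square-metre stage-structured
counts, and drives both with simple stochastic environmental processes.
This vignette records the model, its assumptions, the defaults and
their rationale, and the design decisions a maintainer would want
explained.

## Model structure and assumptions

One annual cycle applies, in fixed order: (1) draw the year's browsing
proportion; (2) redraw the substrate field; (3) recruitment; (4)
juvenile survival and tier transitions; (5) graduation of 2–3 m
survivors into 3.0-m adults; (6) adult growth and mortality; (7)
removal of overtopped adults. Two rules are deliberately asymmetric to
the rest of the bookkeeping: newly established juveniles are held in a
separate pool for exactly one annual cycle (they survive at the 0–2 m
rate but cannot advance), and adults are removed when ≥ 90 % of their
crown area is covered by the union of crowns of strictly taller
neighbours. There is no other density-dependent mortality: the model
targets invasion of open ground, not the dynamics of closed stands, so
competition for light among established adults is reduced to the
overtopping rule, and juvenile competition is reduced to a hard cap of
50 juveniles per 1-m² cell.

### Stochastic drivers

Substrate favorability (per cell) and annual browsing proportion are
both truncated normals on [0, 1], sampled by inverse-CDF conditioning
rather than by clipping: clipping would place point masses at 0 and 1
and systematically distort the ends of scenario gradients. The
browsing SD defaults to 0.13, the interannual SD of observed browse
damage; the substrate SD is not separately reported in the source data
and defaults to the same 0.13 (both configurable). Substrate is
redrawn independently each year — favorability varies among years but
not directionally (no litter/soil feedback, which operates on longer
time scales than the 30-y horizon); a flag allows freezing the field.

### Dispersal and recruitment

The per-area deposition density is log-normal in distance,
`D(r) = dlnorm(r; ln m0 + 2*sigma^2, sigma) / (2*pi*r)`, so that the
*per-area* density (what a seedling quadrat samples) peaks exactly at
the modal distance `m0` (default 0.67 m). The log-scale SD is not
reported; the default `sigma = 1` makes the density fall below 1e-5 of
its peak by 100 m, consistent with seedling densities approaching zero
beyond that distance, and the kernel is truncated there. Annual
per-adult production is `STR * multiplier / window`: the reported total
of 1046 potential recruits per adult is interpreted as production over
the 27-year accumulation window that the seedling surveys integrate.
This annualization is the single most consequential free choice in the
parameterization and both the window and the multiplier (default 1.10,
the validation calibration) are configurable. All adults produce
equally; no size–fecundity term is reported. Recruitment noise is
Poisson, the canonical count model and the likelihood used by the
inverse fit.

The simulator evaluates the expected-recruitment field by binning
adults to their 1-m cells and convolving (FFT) with a *cell-averaged*
kernel stamp: entry (di, dj) is D averaged over the source position
uniform within its cell. The pointwise kernel vanishes at r = 0, so a
point evaluation would starve the source cell; averaging integrates
the within-cell position out and keeps the stamp's total mass equal to
the kernel's in-range mass. The exact point-to-cell-centre field
(`expected_recruitment_field()`) is retained as the reference
implementation — it is what the inverse model fits — and the two agree
to well under 1 % on landscape totals (tested).

### Juvenile demography

Transitions are conditional on survival (survive w.p. `s`, then
advance w.p. `g`), keeping every parameter interpretable as a
probability. Defaults `s1 = s2 = 0.95`, `g1 = 0.0065` (midpoint of the
fitted 0.1–1.2 %/y interval), `g2 = 0.20` ("much higher" than g1) sit
inside the fitted credible intervals; all are configurable. Browsing
enters as a linear multiplicative reduction of all four rates,
`m(b) = 1 - 0.48 b`: b = 1 reproduces the maximal fitted 48 %
reduction and b ≈ 0.21 the mean fitted 10 % reduction. This is the
simplest functional form consistent with the reported numbers; the
original hierarchical form is not published.

### Adult demography

Height growth `a*exp(-k*h)` is anchored exactly at the two reported
rates (0.019 m/y at 3 m, 0.005 m/y at 25 m). Growth is modelled
directly in height even though the decline was described against
diameter, because no height–diameter conversion is reported; composing
an assumed allometry into the growth law would add an invisible degree
of freedom. The height–dbh allometry used for basal area,
`dbh_cm = (h - 1.3)^1.25`, and the crown radius `0.15 h` are documented
assumptions (no allometry is printed); quantities that depend on them
are therefore reported in relative terms (percent change in basal
area). Overtopped fractions are computed by rasterizing crown discs on
a 0.5-m subgrid; removal is simultaneous, and equal heights never
overtop each other.

## Scenario experiments

The full-scale experiments place adults in a 2 × 2 km landscape:
either uniformly in a central 16-ha core block at 250 or 500 trees/ha,
or 8000 adults split over ten 0.1-ha patches placed disjointly in a
central 100-ha block (the "woodland islet" scenario keeps the total of
the 500 trees/ha core model rather than its density, matching the
reference carbon example of an initial population of 8000 adults).
Initial heights are uniform on [3, 20] m. The scenario grid crosses
mean browsing and mean substrate favorability over 0, 0.1, …, 1.0 (121
combinations; 12 100 runs at 100 replicates), holding the initial
adult map fixed across gradient levels within a replicate (common
random numbers). Per-run seeds derive reproducibly from a master seed,
so grids are order-independent and parallelizable.

The package's own reduced-scale experiment — used by the test suite
and the acceptance script — runs the core model on a 400 × 400 m
landscape with a 4-ha core at the same densities, a 3 × 3 subgrid of
browsing and substrate means spanning [0, 1], 30 years, and 10
replicates per grid mean (4–10 for the auxiliary arms). The patch arm
preserves the full-scale proportions rather than absolute sizes:
per-patch adult density 8000/ha (ten 0.025-ha patches of 200 adults)
inside a block occupying one quarter of the landscape. These problem
sizes were chosen so a full analysis runs on a single CPU in minutes.

### What the reduced scale does and does not show

Qualitatively the reduced experiment reproduces the full-scale
structure: browsing dominates, substrate is second, seed availability
acts positively, and concentrating seed sources into islets does not
help. Two quantitative caveats are expected and observed. First, the
relative penalty of the islet configuration is *amplified* at reduced
scale: the patches occupy a larger share of the landscape, local
recruitment saturates the per-cell cap sooner, and demographic
stochasticity in small patches weighs more, so the management effect
can exceed the (small) density effect in magnitude — at full scale it
is the weakest of the four. Second, the decline in adult basal area
over 30 years is dominated by background mortality
(1 − 0.975³⁰ ≈ 53 %): under the anchored height-growth rates,
surviving trees add only a few percent of basal area in 30 years, so
high-browsing scenarios (no graduate inflow) decline by ~50 % rather
than the ~38 % reported at full scale; reproducing a smaller decline
would require a faster diameter-growth law than the printed height
anchors imply. Strong-regeneration corners, where graduates offset
mortality, do fall inside the reported 17–38 % band.

## Inverse modelling

`fit_dispersal()` maximizes the Poisson likelihood of quadrat seedling
counts with per-quadrat mean
`area * (sum_c f_c cover_qc) * STR * sum_a D(r_aq)` — recruitment
accumulated over the survey window, consistent with the forward
model's annualization. Favorabilities are identified only up to scale
against STR, so they are normalized to `max f = 1` after fitting (the
fit is invariant to class relabeling, and estimates are equivariant to
translating all coordinates). Both log-normal and negative-exponential
kernels are fitted and compared by AIC; multi-start Nelder–Mead guards
against local optima; an all-zero survey raises a boundary flag rather
than claiming convergence. CIs are nonparametric bootstrap percentiles
over quadrats.

`fit_stage_rates()` uses a one-step conditional Poisson likelihood:
each year's tier counts given the previous year's, under the
simulator's transition law with a free recruitment-inflow parameter.
This is a deliberately concrete substitute for the unpublished
hierarchical Bayesian formulation; it is validated by parameter
recovery, not by matching unpublished posteriors. Uncertainty comes
from a two-stage bootstrap (transects, then plots within transects),
which propagates both interannual and spatial heterogeneity into the
intervals; plot- and year-level variance components of tier-1 survival
are reported as moment estimates from aggregated observed/expected
ratios. If browsing does not vary in the data, the browsing effect is
flagged unidentifiable instead of being reported.

`fit_adult_mortality()` fits the demographic-equilibrium diameter
density `phi(d) ~ exp(-m T(d)) / g(d)`, with `T(d)` the time to grow
to d, by maximum likelihood over m with a 95 % profile-likelihood
interval; with constant growth this collapses analytically to the
exponential-rate estimator, which the tests exploit as an oracle. The
normalization range defaults to the observed diameter range and is
configurable.

## Synthetic data

The generators in `gen_adult_map()`, `gen_quadrat_survey()`,
`gen_transect_series()` and `gen_dbh_sample()` emulate the field
protocols behind the three fits — clustered adult maps, 0.25-m²
quadrats with Dirichlet ground cover, six transects of ten plots
monitored for eight years across a browsing gradient, and a 40-core
diameter sample — each seed-deterministic and carrying its
`truth_bundle()`. They emulate the *designs*, not the full messiness of
field data: no observation error in browsed fractions, no missing
years, no spatial autocorrelation in cover, and interannual variation
realized independently per transect. Passing recovery tests therefore
demonstrates internal consistency of estimator and generator, not
robustness to every field artefact.

## Numerical choices

Truncated-normal sampling is inverse-CDF (exact); `sd = 0` returns the
clamped mean. The kernel stamp averages D over a 5 × 5 within-cell
midpoint rule; FFT sizes are padded to 2-3-5-smooth integers. The
overtopping rasterization uses subcell centres at 0.5 m (scaling the
resolution with coordinates leaves decisions unchanged). GLM effect
models use quasi-Poisson (Pearson-dispersion-inflated) standard errors
and Wald 95 % CIs; the predicted-versus-observed validation uses an
identity link, because the unbiasedness question (slope 1, intercept
0) lives on the count scale; perfect fits are handled by small
numerical tolerances. The multiplier calibration searches the
0.80–1.10 grid in steps of 0.05 (only the range is prescribed) with a
lexicographic objective: slope distance from 1 first, intercept
distance from 0 as tie-break. Degenerate inputs (empty populations,
all-zero surveys, constant predictors, single-valued diameter samples)
are either well-defined no-ops or explicit errors, never silent.

## Known limitations

Dispersal is isotropic (directional variants were rejected in the
source model selection and are out of scope); there are no seed banks,
no litter/nutrient feedbacks, no other herbivore species, and browsing
is an exogenous driver — deer population dynamics are not modelled.
The adult allometries (crown radius, height–dbh) are assumptions, so
absolute basal areas and carbon stocks should be read as indicative;
relative comparisons across scenarios are the intended use. The
stage-rate fitter's variance components are moment-based summaries,
not a full hierarchical posterior.
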