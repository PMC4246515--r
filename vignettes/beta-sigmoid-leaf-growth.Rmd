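---
title: "Modelling grass leaf growth with the beta sigmoid function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling grass leaf growth with the beta sigmoid function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betaleaf)
```

## The problem

Grass leaves (maize, *Miscanthus*, *Brachypodium*, ...) grow from a
basal meristem hidden inside the pseudo-whorl, elongate over one to a
few weeks, and then stop: growth is *determinate*. Simple daily ruler
measurements of visible leaf length therefore trace a sigmoid that
genuinely reaches its asymptote. Comparing genotypes or treatments
needs more than final length: when growth starts and stops, how fast
the leaf elongates at its peak, and for how long it sustains near-peak
elongation all carry independent biological signal.

`betaleaf` makes those quantities routine: fit one four-parameter
curve per leaf, then read every derived quantity off the fitted curve.

## The growth model

Leaf length against thermal time $t$ (°Cd) follows the beta sigmoid

$$L(t) = L_m\left(1 + \frac{t_e - t}{t_e - t_m}\right)
  \left(\frac{t - t_0}{t_e - t_0}\right)^{\frac{t_e - t_0}{t_e - t_m}},
  \qquad t_0 \le t \le t_e,$$

with $L(t) = L_m$ for $t > t_e$ and $L(t) = 0$ before $t_0$. Unlike
the logistic or Gompertz families, this curve attains its asymptote at
a *finite* time $t_e$ with zero slope there — exactly the behaviour of
a determinate organ — and every parameter is directly interpretable:
$L_m$ is the final length (mm), $t_0$ the start of growth, $t_m$ the
moment of fastest elongation, $t_e$ the end of growth.

Its analytic derivative is the bell-shaped leaf elongation rate (LER)
curve implemented in `beta_rate()`; the closed-form maximum
(`beta_max_rate()`) is

$$LER_{max} = L_m\,\frac{2t_e - t_m - t_0}{(t_e - t_m)(t_e - t_0)}
  \left(\frac{t_m - t_0}{t_e - t_0}\right)^{\frac{t_m - t_0}{t_e - t_m}}.$$

Thermal time is used as the clock because leaf elongation in grasses
scales nearly linearly with temperature above a species-specific base:
`accumulate_gdd()` sums daily mean temperature excess over the base
(clipped at zero — the standard growing-degree-day convention; below
the base the plant essentially does not grow). The base temperature is
always an explicit argument (e.g. 10 °C for maize, 8 °C for
*Miscanthus*); published sources occasionally disagree on the value
for a species, so the package deliberately ships no species table.

## Working assumptions

- **$t_0 = 0$ at sowing by default.** Freely estimated $t_0$ values
  are poorly constrained by data that only start once the leaf tip
  emerges, and routinely come out negative. `fit_growth(fix_t0 =
  FALSE)` frees it for the occasions where early data exist.
- **Additive, homoscedastic measurement noise** on leaf length — a
  ruler error, a few mm, independent of leaf size.
- **One curve per leaf** is the default unit of analysis; replicates
  can be pooled into one joint fit per group (`run_batch(pool =
  TRUE)`), but per-leaf fitting keeps between-plant variation visible
  to the downstream statistics and is the recommended route.

## Fitting: numerical choices

`fit_growth()` / `fit_cell_profile()` minimise the residual sum of
squares with bounded Levenberg–Marquardt (via `minpack.lm::nlsLM`),
relative SSE tolerance $10^{-10}$, at most 200 iterations.

- **Ordering constraints by reparameterisation.** Box bounds cannot
  express $t_m < t_e$, so the optimiser works on $(L_m, t_m,
  \Delta t_e)$ with $t_e = t_m + \Delta t_e$ and $\Delta t_e$ bounded
  below by a small positive value (similarly $P_m < P_e$, $L_b < L_m$
  for cell profiles). Bounds: $L_m \in (0, 10\,\max L]$, $t_m$ and
  $\Delta t_e$ each within twice the last observed abscissa.
- **Starting values** are rule-based (`initial_guess()`):
  $L_{m,0} = 1.05\,\max L$; $t_{e,0}$ = first time the series reaches
  95% of its maximum; $t_{m,0}$ = midpoint of the steepest sampling
  interval. Cell profiles apply the same rules to a running-median
  smooth of the profile, because raw cell lengths scatter strongly and
  a single outlier would otherwise drag the start.
- **Deterministic multistart.** The least-squares surface is
  multimodal for noisy sigmoid data, so the first three starts (the
  rule-based one plus two ±20% perturbations from a fixed sign
  pattern) are always explored and the lowest SSE kept; up to five
  total restarts run while no start has beaten the starting SSE. A fit
  that still cannot match its starting SSE is returned with
  `converged = FALSE`, never silently dropped — `run_batch()` keeps
  one output row per input leaf regardless.
- **Inverse evaluation** (`time_at_length()`, `rate_window()`,
  `zone_lengths()`) uses Brent's bracketed root search on the monotone
  interval, tolerance $10^{-9}$ of the parameter span.
- $R^2$ is the centred definition $1 - SSE/SS_{tot}$; a zero-variance
  series makes it undefined and is reported as an error.

## Derived parameters

`derive_growth()` computes, per fitted leaf: $LER_{max}$; timing
points for fractions of final length (defaults 20%, 50%, 90%) and for
absolute lengths (default 100 mm — for small-statured species an
absolute milestone like 20 mm is the better choice; the set is fully
configurable); LEDs as plain differences of those time points; and
steady-state windows — the thermal-time interval over which LER stays
above a fraction (defaults 90% and 95%) of $LER_{max}$. A stricter
fraction necessarily gives a narrower, nested window; the package
computes both directly from the rate curve by root finding, so the
widths are guaranteed consistent with the thresholds. An absolute
milestone a particular leaf never reaches yields `NA` with a warning
rather than failing the batch.

Day equivalents of any time point are reported only when the
experiment ran at (approximately) constant temperature and the daily
degree-day accrual is supplied (`day_equiv`), because only then is the
conversion well defined.

For cell-length profiles, `zone_lengths()` derives the division zone
as the basal stretch where the *fitted* profile stays at or below a
threshold (40 µm by default — the operational upper size of dividing
cells), and the elongation zone as the remainder up to $P_e$. Using
the fitted curve rather than raw cells makes the zone estimate robust
to the very large cell-to-cell scatter.

## What the synthetic generator emulates — and what it does not

`simulate_leaf_series()` adds additive Gaussian noise to an exact beta
sigmoid at a daily sampling schedule (default 18 points at
14 °Cd/day, noise sd 5 mm — a realistic ruler error);
`simulate_experiment()` adds 4% between-leaf biological variation
around cohort means (control-like 535/0/167/231 vs transgenic-like
743/0/180/246, n = 9/11), matching the design of a typical maize
overexpression comparison. `simulate_cell_profile()` uses
multiplicative noise (cv 0.25 in the tests) because cell-length
scatter grows with cell size.

Real data differ in ways the generator does not model: residuals of
real growth series show serial correlation (smooth over- and
undershoot, not white noise); cell profiles deviate systematically
from the model in the first ~3 mm above the base, where very short
cells sit below the fitted curve (no correction is applied — a known,
documented bias of the functional form); and temperature fluctuates,
so thermal time is only piecewise-linear in calendar time. Passing
recovery tests on synthetic data therefore demonstrates the
correctness of the estimation machinery, not the adequacy of the model
for any particular crop.

## Group statistics

Two groups: Student's pooled-variance t-test (`ttest_two_groups()`;
Welch behind a flag), reporting the percent difference of means. Three
or more: one-way ANOVA with Scheffé post hoc contrasts
(`anova_scheffe()`) — the Scheffé pairwise p-value is
$P\!\left(F_{k-1,\,N-k} \ge F_{ij}/(k-1)\right)$, conservative by
construction — plus a compact letter display built by insert-and-absorb
over the significant-difference graph. No multiplicity control is
applied *across* the many derived parameters; treat per-parameter
p-values accordingly.

## Validation problem sizes

The test suite exercises: noiseless recovery on 50 randomised
parameter sets (all parameters within 0.1%); noisy recovery at noise
sd = 1% of $L_m$, 15 points per series, 200 seeds (median parameter
error under 2%); closed-form $LER_{max}$ against a 0.01 °Cd grid
maximum; inverse round trips to $10^{-6}$ °Cd; and byte-identical
batch determinism. These sizes run in seconds on one CPU and were
chosen to make the checks statistically meaningful, not exhaustive.

## Known limitations

- The beta sigmoid is determinate by construction; indeterminate or
  multiphasic growth (stress interruptions, regrowth after cutting)
  will fit poorly and should be flagged by low $R^2$.
- Heteroscedastic positional scatter in cell profiles is not modelled
  (ordinary, not weighted, least squares).
- The division/elongation zone split inherits the 40 µm convention;
  it is a configurable operational definition, not a measurement of
  mitotic activity.
- Thermal-time conversion uses daily means without an upper
  temperature cap or organ-level temperature correction.
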