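---
title: "Marginal warming from livestock methane: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal warming from livestock methane: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ch4margin)
```

## The question

Livestock are the largest single source of anthropogenic methane. Because
CH4 lives in the atmosphere for only about a decade, a slowly declining CH4
emission stream causes no *additional* warming — which is sometimes read as
meaning that reducing livestock CH4 is unimportant for stringent
temperature goals. `ch4margin` implements the counter-analysis: it
quantifies the *marginal* warming that future livestock CH4 emissions cause
(the warming with, compared to without, those emissions, all else equal),
and expresses unmitigated livestock CH4 as a cost to the remaining carbon
budget by constructing a temperature-matched CO2 pathway.

## The emulator

The forward model is a reduced-complexity pulse-response chain,
`emissions -> concentration -> radiative forcing -> temperature`,
applied independently to net CO2 and livestock CH4.

**Carbon cycle.** A CO2 pulse leaves an airborne fraction
$\mathrm{IRF}(t) = a_0 + \sum_{i=1}^{3} a_i e^{-t/\tau_i}$ with defaults
$a_0 = 0.2173$, $a = (0.2240, 0.2824, 0.2763)$ and
$\tau = (394.4, 36.54, 4.304)$ years; the fractions sum to one
(conservation is validated at construction). Mass converts to mixing ratio
at 7.814 Gt CO2 per ppm. Annual concentration anomalies are the discrete
convolution of emissions with this kernel.

**Methane.** A single well-mixed box with perturbation lifetime
$\tau_{\mathrm{CH4}} = 12$ years (configurable 11.8-12.4) and 2.75 Mt CH4
per ppb: $dC/dt = E/m - C/\tau$. A constant source $E$ asymptotes to
$E\tau/m$; a pulse decays exponentially.

**Forcing.** CH4 forcing is linear: direct radiative efficiency
$3.63\times10^{-4}$ W m$^{-2}$ ppb$^{-1}$ times an indirect-effects
multiplier of 1.65 that stands in for CH4-driven tropospheric ozone and
stratospheric water vapour. CO2 forcing defaults to a linearization about
400 ppm (0.0134 W m$^{-2}$ ppm$^{-1}$); a logarithmic mode
($5.35\,\ln(C/C_0)$ W m$^{-2}$) is available.

**Temperature.** A two-mode energy-balance response
$R(t) = \sum_j (q_j/d_j)\,e^{-t/d_j}$ with $q = (0.631, 0.429)$ K (W
m$^{-2}$)$^{-1}$ and $d = (8.4, 409.5)$ years: a fast mixed-layer mode and
a slow deep-ocean mode. A sustained unit forcing equilibrates at
$\sum_j q_j = 1.06$ K (W m$^{-2}$)$^{-1}$.

These defaults are a deterministic, AR5-era metric-style approximation of a
median probabilistic simple-climate-model response; every coefficient is
configurable through `gas_cycle_params()`, `thermal_params()` or a YAML
file (`read_emulator_params()`). With the defaults the implied
GWP$_{100}$(CH4) is about 29 (computed by `metric()` and checked against a
numerical integration oracle in the test suite), and the implied
equilibrium climate sensitivity is on the warm side of typical median
calibrations — a point we return to under *Limitations*.

**Why linearized CO2 forcing by default?** Marginal warming is a
difference of two runs. Under linear kernels the decomposition
total = legacy + marginal is exact and marginal warming equals the warming
of the future-only emissions, so attribution results are additive across
sectors and pathways. In logarithmic mode the package still reports an
exact decomposition — marginal is *defined* as
`warming(full) - warming(zeroed after split)` — but the parts are no longer
independently recomputable: the log-forcing curvature at scenario-scale
concentration anomalies (tens of ppm) is of order 0.05 degC, far from
negligible. Linear mode is therefore the default for all attribution and
inversion work.

## Discretization

Emissions are applied at mid-year; concentrations, forcings and
temperatures are reported at year-end. Concentration kernels are sampled
analytically at half-integer ages, so the box-model and IRF closed forms
are reproduced exactly at those times, and the temperature step integrates
$R(t)$ exactly over each year of piecewise-constant forcing (a step forcing
$F$ held for $n$ years gives exactly $F\sum_j q_j(1 - e^{-n/d_j})$).
Holding each year's forcing at its year-end value does introduce a genuine
first-order bias in end-to-end pulse responses — up to about 5% of the
pulse-response peak when compared against a 0.1-year reference simulation
of the same kernels — which is immaterial next to the structural
uncertainty the configurable coefficients represent, but is asserted
honestly in the test suite rather than claimed away. Convolutions are
direct sums, not FFTs, so a zero-emission prefix yields an exactly zero
response and nonnegative emissions can never produce negative
concentrations by round-off.

## The synthetic scenarios

The package does not bundle any scenario-database extract. Instead
`make_mitigation_scenario()` deterministically generates a stylized deep
mitigation scenario from its published anchor facts:

* net CO2: 35 Gt/yr in 2020, geometric decline of 4.9%/yr to 2030,
  net-zero in 2055, negative thereafter to -10 Gt/yr in 2100. One free
  anchor (2042) between 2030 and net-zero is solved by root-finding so the
  trapezoidal cumulative emission from 2018 to net-zero is 580 Gt — the
  remaining carbon budget for a 50/50 chance of 1.5 degC. The 2020 level
  and all anchors are calibration choices, configurable in
  `scenario_config()`.
* livestock CH4: the 2010 level is fixed by requiring a 38% drop to 70
  Mt/yr by 2050 (hence 112.9 Mt/yr in 2010), 115 Mt/yr in 2020, declining
  further to 55 Mt/yr by 2100. The 2100 level is a calibration choice (a
  continued gentle decline); it is configurable.
* business-as-usual CH4 (`make_bau_livestock_ch4()`): identical to the
  mitigation pathway through 2020, monotone growth to 1.3 x the 2010 level
  (146.8 Mt/yr) by 2050, held constant afterwards (the projections being
  emulated stop at 2050; a linear-continuation alternative is available).

Interpolation between anchors uses a shape-preserving monotone cubic
(Fritsch-Carlson), applied per maximal monotone run of anchors so the
curve can never overshoot the local anchor range; plain linear
interpolation is available. A stylized 1850-2020 `historical_backdrop()`
(smooth curves through round waypoints, joining the scenario segment
exactly at 2000-2020) exists solely so legacy warming can be displayed; it
is synthetic, flagged as such, and no marginal or budget quantity depends
on it.

What the generators deliberately do *not* emulate: interannual
variability, multi-model spread, regional structure, the non-CO2 gases
other than livestock CH4, and any coupling between the CO2 and CH4
pathways. Tests passing on these scenarios therefore demonstrate the
correctness and calibration of the *method*, not skill against real
scenario-database inputs.

## Attribution, inversion, stabilization, mitigation potentials

**Attribution.** `marginal_warming()` zeroes emissions after a split year
(default 2020 — the generators' historical/projection boundary; zeroing
begins the following year) and differences the two warming runs.
`attribute_warming()` additionally splices the historical backdrop and
reports the exact total = legacy + marginal decomposition at the report
years (default 2050 and 2100).

**Budget inversion.** `adjust_co2_for_ch4()` asks: if livestock CH4
follows the higher (e.g. business-as-usual) pathway, how much harder must
net CO2 work for the *combined* warming trajectory to stay virtually
identical? The adjusted pathway comes from a one-parameter family — the
reference decline increments over 2020-2035 are scaled, after which the
pathway rejoins the reference shape via a linearly tapering offset pinned
to the same 2100 floor, honouring "more and earlier net CO2 removal"
through the earlier zero-crossing this produces. The scalar is found by a
bracketed root solve (bracket [0.5, 3], tolerance 1e-4, deterministic)
that equalizes the largest warm and cool deviations over 2020-2100, which
is the minimax solution for a family whose cooling is monotone in the
parameter. We match the full trajectory rather than only the peak (the
alternative — matching at peak warming only — would leave end-of-century
temperatures visibly different). A one-parameter family cannot drive an
80-year trajectory difference identically to zero; the achieved residual
is reported, compared against a 0.01 degC acceptance threshold, and
flagged (`converged`) rather than hidden. The resulting `budget_report`
carries the net-zero year (linear interpolation of the first downward
zero-crossing), the geometric 2020-2030 reduction rate, the trapezoidal
cumulative budget from 2018, and deltas against the reference.

**Stabilization rate.** `stabilizing_decline_rate()` finds, by bisection
on `T(end) - T(start)`, the constant exponential CH4 decline rate at which
CH4-induced warming is the same at the end of the evaluation window as at
its start. Defaults: a 100-year constant-emission spin-up (a stylized
industrial century, long enough to charge the slow ocean mode) and a
2020-2060 window (the mid-century horizon at which the stabilization claim
is aimed; the window must span at least 40 years). A positive rate is
required only because of ocean thermal inertia, so the result is sensitive
to both choices: longer spin-ups or longer windows give smaller rates. The
bisection is validated against a brute-force grid scan at 0.01
percentage-point resolution.

**Mitigation potentials.** `mitigation_potential()` implements the
adoption-schedule arithmetic for emerging technologies (synthetic
inhibitors, a methane vaccine, low-emissions breeding, seaweed additives):
`emissions_2010 x growth x efficacy x adoption` summed over applicable
(production system x income group) cells, with growth 1.3 to approximate a
2050 baseline. System-level 2010 emissions by income group are not public
at the granularity needed, so the bundled table
(`gleam_2010_synthetic.csv`) is synthetic: its TMR total is
back-calibrated so the TMR-inhibitor schedule (30% efficacy, full feedlot
adoption) reproduces the published 0.8 Mt potential exactly, the remaining
cells are stylized to total roughly the scenario's 112.9 Mt 2010 level,
and real extracts can be supplied via `read_livestock_table()`.
`apply_to_pathway()` couples a potential back into a CH4 pathway as a
linear wedge from 2025 (commercialization years vary by technology; the
ramp is configurable) reaching full size in 2050.

## Numerical and design choices, in brief

* Annual time step; an emission value for year $t$ is the total for
  calendar year $t$.
* Net-zero detection uses the *first* downward zero-crossing; pathways
  that never cross report an explicit "never" (`NA`), which propagates
  through budget integrals rather than erroring.
* Geometric reduction rates require strictly positive endpoint values.
* The inversion's identity case (alternative = reference CH4) recovers the
  reference CO2 pathway with zero deltas; uniformly higher alternative CH4
  can never increase the remaining budget (both are tested).
* All generators, solvers and runners are deterministic: there is no
  randomness anywhere in the package.
* Problem sizes are small by design — century-scale annual series (~100 to
  ~330 points) and scalar root solves — so every analysis, including the
  full inversion, runs in seconds.

## Limitations

* The emulator is a single deterministic trajectory standing in for the
  median of a probabilistic ensemble; parameter (especially thermal)
  uncertainty is not propagated. The default thermal amplitudes imply an
  equilibrium sensitivity near 3.9 K, warmer than typical median
  calibrations near 3 K; temperature-level results inherit that warmth
  (their ratios and budget deltas are much less sensitive). Users wanting
  a cooler calibration can rescale `q` via configuration.
* No carbon-cycle feedbacks (state-dependent IRF), no CH4 lifetime
  chemistry feedbacks, no N2O or aerosols.
* The scenario generators encode printed anchor facts, not actual
  scenario-database trajectories; the historical backdrop is stylized and
  is used for display-oriented legacy quantities only.
* Mitigation-potential ranges for income-group-dependent schedules are
  only as good as the supplied emissions table; with the synthetic bundled
  table only the calibrated TMR cell is quantitatively meaningful.
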