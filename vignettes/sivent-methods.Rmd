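---
title: "Model-based selection of volume-controlled ventilation settings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based selection of volume-controlled ventilation settings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sivent)
```

## The problem

A ventilated ICU patient's clinician faces an enormous space of
volume-controlled (VC) ventilation settings: respiratory rate, tidal
volume, peak inspiratory flow, flow waveform and plateau time multiply
into 189,000 combinations at typical ventilator resolutions. Most are
safe for some patients and dangerous for others, because the pressures a
given volume prescription produces depend on the patient's respiratory
mechanics — elastance `E_rs` (cmH2O/L, stiffness) and resistance `R_rs`
(cmH2O·s/L) — which differ between patients and drift over hours.

`sivent` implements a decision-support pipeline that (i) identifies
`E_rs` and `R_rs` from routine airway pressure–flow data, (ii) forecasts
the range the elastance may occupy in the next monitoring interval, and
(iii) forward-simulates every setting combination through a lung model,
eliminating those whose predicted pressures violate accepted safety
thresholds and narrowing the rest by a clinical objective.

## The lung model

Everything rests on the single-compartment linear model

$$P_{aw}(t) = E_{rs}\,V(t) + R_{rs}\,\dot V(t) + \mathrm{PEEP},$$

with airway pressure in cmH2O, volume in L and flow in L/s. It is the
simplest clinically validated description of passive inflation, and its
linearity is what makes both the identification (linear regression) and
the protocol stage (closed-form outcome formulas, monotonicity in
`E_rs`) tractable.

Within a VC breath the ventilator prescribes the flow profile:

* **square** — constant flow $\dot V_{max}$ for
  $T_{flow} = V_T/\dot V_{max}$;
* **ramp** — descending from $\dot V_{max}$ to zero over
  $T_{flow} = 2V_T/\dot V_{max}$.

The ramp definition is a genuine design choice: ventilator manuals
disagree on whether a "ramp" preserves the set peak flow or the
inspiratory time, and on its terminal flow. We use the standard
descending ramp to zero, scaled so both the set peak flow *and* the set
tidal volume are honoured. Outcomes follow in closed form:

* plateau pressure $P_{PLAT} = E_{rs} V_T + \mathrm{PEEP}$,
* driving pressure $\Delta P = E_{rs} V_T$,
* square peak pressure
  $P_{MAX} = E_{rs} V_T + R_{rs} \dot V_{max} + \mathrm{PEEP}$,
* ramp peak pressure: the maximum of the model pressure at flow onset,
  at end of flow, and at the interior stationary point
  $t^* = T_{flow} - R_{rs}/E_{rs}$ when it lies inside the flow phase.

Sampled waveforms (50 Hz) reproduce these within one sample's pressure
increment; the property suite checks that agreement on random grid
points.

```{r}
mech <- respiratory_mechanics(E_rs = 43.5, R_rs = 26.2, PEEP = 13)
compute_outcomes(mech, vc_settings(RR = 20, VT_perkg = 4, peak_flow = 30,
                                   T_plat = 0.5), weight = 65)
```

## Identification and breath quality

Per breath, integrating the model from breath start $t_0$ to each
inspiratory sample $t_i$ yields one linear equation per sample in
$(E_{rs}, R_{rs})$, with trapezoidal cumulative integrals of volume and
of $(P - \mathrm{PEEP})$ as coefficients. The stacked system is solved by
nonnegative least squares (Lawson–Hanson, `pracma::lsqnonneg`), because
negative mechanics are nonphysical. Integration smooths sensor noise —
the classic advantage of integral over derivative formulations. We
regress over inspiration only: the passive-expiration samples contain no
independent information under this model, and the model-fit statistic
(APE, the median absolute percentage error between fitted and measured
inspiratory pressure) is defined over inspiration.

Breaths are segmented from the raw stream by threshold-plus-persistence
rules (flow > 0.1 L/s and pressure > PEEP + 2 sustained 8 samples for
inspiration onset; the mirrored rule for expiration), then filtered:
minimum peak inspiratory volume 40 mL, peak pressure above PEEP + 1,
expiration within 4.125 s of onset. "True breath" criteria then reject
fits with APE > 15%, nonpositive elastance, or elastance outside the
5th–95th percentile of the patient's collected estimates.

Two implementation choices deserve note:

* **The percentile reference is the patient's full record**, not an
  expanding window of previously accepted breaths. An accepted-only
  expanding window is a feedback trap under a drifting elastance: the
  band never follows the trend, entire intervals are rejected, and
  interval medians clamp at the baseline value (we observed exactly this
  on the default virtual patient). A retrospective pipeline naturally
  computes the band from all collected valid estimates; `process_stream()`
  therefore identifies everything first and filters second. The
  criterion still costs ~10% of genuinely fine breaths — any
  percentile-of-own-population filter does — and biases the medians of
  the most extreme interval toward the record median; interval medians
  over ~150 breaths absorb this with errors of a few percent at worst.
* **Interval PEEP** is the median per-breath PEEP estimate (median
  pre-inspiratory pressure), rounded to integer cmH2O, matching the
  resolution at which PEEP is set clinically.

## Forecasting the next-interval elastance

Successive 10-min interval medians $(E_{rs,N}, E_{rs,N+1})$ form
transition pairs. The conditional distribution
$P(E_{rs,N+1} \mid E_{rs,N})$ is estimated by a two-dimensional kernel
method: one Gaussian kernel per pair on each axis, truncated to
$[0,\infty)$ (elastance is nonnegative) and renormalised by its
half-line mass. Conditioning collapses this into a mixture of the
truncated x-kernels with weights proportional to the y-kernel values at
the conditioning point, so the density integrates to one by
construction. Percentile forecasts invert the numerically accumulated
CDF (1000-point grid over $[0, 1.5\max x_i]$, linear interpolation).

**Bandwidth.** The default rule (`"residual"`) applies the normal-
reference rule $0.9\min(s, \mathrm{IQR}/1.34)\,n^{-1/5}$ to the
*residuals* of a linear fit of next-interval on current-interval
elastance, and uses that bandwidth on both axes. Successive elastances
are strongly dependent, so their marginal spread is dominated by
between-patient variation; a marginal-Silverman bandwidth (available as
`"silverman"`) therefore over-smooths the conditional bands badly — on
a synthetic law with known conditional spread it produced 96% / 82%
empirical coverage against the nominal 90% / 50%, while the residual
rule lands at 89–92% / 48–60% across seeds. The residual scale is the
scale on which the transition density actually varies.

Queried far outside the data support (all kernel weights underflowing to
zero) the model refuses to extrapolate and raises an error. Within the
support but near its edges, kernel weighting mean-reverts: the forecast
band need not bracket the conditioning value there, which matters for
the protocol ordering property below.

```{r}
set.seed(1)
y <- runif(300, 15, 60)
model <- fit_transition_model(cbind(y, y * exp(rnorm(300, 0, 0.08))))
forecast_percentiles(model, Ers_N = 43.5)
```

## The protocol

For one interval the deterministic protocol (`run_vent()`) runs four
stages:

1. **V** — enumerate all 189,000 combinations and compute outcomes at
   the interval elastance (vectorised closed forms);
2. **E** — eliminate combinations violating: $P_{MAX} < 40$,
   $P_{PLAT} < 30$ cmH2O (strict, as the guidelines print them), I:E
   denominator in $[1, 3]$ (inclusive — the guideline states a closed
   range), infeasible timing ($T_{exp} \le 0$), or the RR / tidal-volume
   grid ranges (inclusive, they coincide with the grid);
3. **N** — keep the combinations tying the minimum driving pressure;
   since $\Delta P = E_{rs} V_T$, this retains exactly the lowest
   surviving tidal-volume tier (all ties kept);
4. **T** — tabulate survivors with their outcomes.

The stochastic variant (`run_sivent()`) forecasts the 5th and 95th
elastance percentiles and simulates each combination twice; both ends of
the forecast pressure range must be safe. Pressures being monotone in
elastance, the stochastic survivor set is contained in the deterministic
one whenever the forecast band brackets the current elastance — a
provable ordering the test suite asserts on every synthetic run. The
narrowing objective uses the 95th-percentile driving pressure; with
$\Delta P$ linear in elastance this selects the same tidal-volume tier
as any percentile. Plateau time counts as inspiratory time in the I:E
ratio (an inspiratory hold), and PEEP is a clinician input, not a grid
axis.

```{r}
run_vent(interval_summary(43.5, 26.2, 13), weight = 65)
```

**Boundary audit.** Interval mechanics enter as numbers printed to
0.1 cmH2O/L. Each run can re-run the elimination with the elastance
perturbed by ±0.05 cmH2O/L and report how many combinations change final
status, bounding how much of any count difference input rounding can
explain. Published per-interval counts for this protocol family came
from an independent closed-source implementation; our counts agree with
the published worked examples to within 0.2–0.7% in most regimes (and
within ~8% where the peak-pressure limit interacts with unpublished
waveform-sampling conventions), while the audit shows essentially none
of the residual is attributable to input rounding — it measures
convention differences (discrete waveform construction, I:E rounding),
not mechanics.

## The virtual patient

Because no public record of ventilated-patient streams exists for this
protocol family, the package generates its own test subjects
(`virtual_patient_config()`, `generate_patient_stream()`):

* elastance follows a seeded multiplicative log-normal walk across
  intervals (default step SD 0.05, reflected at 8–73 cmH2O/L — the span
  of reported cohort medians), with additional per-breath multiplicative
  jitter (`breath_E_sd`, default 0.05: with sensor noise alone,
  per-breath estimates have an unrealistic ~0.3% CV and any percentile
  criterion degenerates; a few percent of breath-to-breath elastance
  variability is what passive patients actually show);
* breaths are built by the package's own waveform engine; expiration is
  passive relaxation at the time constant $\tau = R_{rs}/E_{rs}$, so
  expiratory pressure returns to PEEP while expiratory flow decays
  exponentially;
* pressure carries additive Gaussian sensor noise (default SD
  0.5 cmH2O);
* asynchronous breaths (default 5% of breaths) carry a mid-inspiration
  negative pressure deflection — the simplest effort-like distortion
  that reliably drives the model-fit APE over the 15% threshold.

What the generator does *not* emulate: real asynchrony morphology
(double-triggering, flow starvation), intrinsic PEEP, nonlinear or
volume-dependent elastance, secretions, leaks, or ventilator rise-time
dynamics. Tests passing on this generator therefore demonstrate the
pipeline's internal consistency — segmentation, identification,
filtering, forecasting and elimination compose correctly, and the
protocol's ordering and monotonicity properties hold — not clinical
performance on real waveforms.

## Numerical choices and degenerate inputs

* Trapezoidal quadrature throughout (waveform integration and the
  identification integrals); estimates change by <0.1% under halving of
  the 0.02-s sample period.
* Rank-deficient identification systems (zero flow) return an invalid
  estimate rather than raising; zero fitted pressures are excluded from
  the APE median.
* Threshold comparisons at the elimination stage use a 1e-9 tolerance on
  the inclusive I:E bounds; driving-pressure ties in the narrowing stage
  likewise.
* An empty survivor set is a legitimate protocol outcome (it occurs for
  stiff patients whose forecast upper percentile makes even the minimum
  tidal volume unsafe) and propagates as an empty table plus a warning
  at the CLI.
* Ramp peak pressure with $E_{rs} = 0$ skips the stationary-point
  formula (endpoints only).

## Problem sizes in the test suite

The test suite exercises full 189,000-point grids for all protocol
properties. Stream-level tests use 1–18 intervals of 10 minutes at
50 Hz (up to 540,000 samples); the cohort-level acceptance property uses
20 virtual patients (10 to fit the transition model, 10 to evaluate,
18 intervals each), and the coverage property uses 500 training and 200
held-out transitions. These sizes keep the full suite within a few
minutes on one core while leaving every property's sample size large
enough for its binomial or quantile tolerances.

## Known limitations

* The protocol inherits every limitation of the single-compartment
  model: no intrinsic PEEP, no patient effort, no nonlinear recruitment.
* Published worked-example survivor counts are reproduced only up to the
  unpublished discretisation conventions of the original implementation
  (see the boundary-audit discussion above).
* The transition model is population-level; per-patient models would
  need longer records than the 3-h evaluation horizon provides.
* The forecast band is honest only within the training support; the
  package refuses to extrapolate far outside it.
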