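---
title: "Reservoir-wave analysis: model, fitting techniques and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reservoir-wave analysis: model, fitting techniques and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reswave)
```

## The model

`reswave` decomposes an arterial pressure beat $P(t)$ into a reservoir
component $P_r$ and an excess component $P_{ex} = P - P_r$. The reservoir
pressure satisfies the first-order relation

$$\frac{dP_r}{dt} = a\,P - (a+b)\,P_r + b\,P_\infty, \qquad P_r(0) = P(0),$$

whose closed-form solution is

$$P_r(t) = \frac{b}{a+b}P_\infty + e^{-(a+b)t}\left[\int_0^t a\,P(\vartheta)\,
e^{(a+b)\vartheta}\,d\vartheta + P_0 - \frac{b}{a+b}P_\infty\right].$$

Here $a$ and $b$ are the systolic and diastolic rate constants (1/s) and
$P_\infty$ is the asymptotic pressure toward which diastole decays. For
$t > T_N$ (the dicrotic notch, taken as the local minimum of measured
pressure at end-systole) and negligible wave activity, the relation reduces
to a single exponential,

$$P_r(t) = (\bar P_n - P_\infty)\,e^{-b\,(t - T_N)} + P_\infty,
\qquad \bar P_n = P_r(T_N).$$

The working assumptions are therefore: a single-exponential diastolic decay
(no multi-exponential run-off), little wave activity in diastole, and a
pressure-only formulation — the velocity waveform enters only through the
velocity split $U_r = (P - P_\infty)/\bar R$ with
$\bar R = (\langle P\rangle - P_\infty)/\langle U\rangle$ averaged over
diastole, and $U_{ex} = U - U_r$.

## The four fitting techniques

The decay parameters are not observable directly; they come from a bounded
nonlinear least-squares fit of the diastolic exponential to the measured
pressure. Two design axes generate the four standard techniques compared
throughout:

| technique      | free parameters            | window                 |
|----------------|----------------------------|------------------------|
| `3dof_whole`   | $\bar P_n, P_\infty, b$    | all of $[T_N, T)$      |
| `2dof_whole`   | $P_\infty, b$ ($\bar P_n = P_n$) | all of $[T_N, T)$ |
| `3dof_last23`  | $\bar P_n, P_\infty, b$    | last two thirds        |
| `2dof_last23`  | $P_\infty, b$ ($\bar P_n = P_n$) | last two thirds  |

"Last two thirds" is read literally as $[T_N + (T - T_N)/3,\; T)$. After the
decay fit, the systolic rate constant $a$ is obtained by solving the closed
form at the notch for $P_r(T_N) = \bar P_n$, as a one-dimensional bounded
least-squares problem.

Solver settings follow the conventions of the field: Levenberg–Marquardt
with hard non-negativity bounds on $P_\infty$, $b$ and (when free)
$\bar P_n$; initial values $P_\infty = 60$ mmHg (7999.2 Pa), $b = 1$ /s,
$\bar P_n = P_n$, $a = 10$ /s; relative tolerance $10^{-12}$; $a$ bounded
above by 100 /s (configurable). `minpack.lm::nls.lm` exposes `ftol`/`ptol`
rather than a single relative tolerance; both are set to the configured
value. All internal units are SI (Pa, m/s, s); mmHg is converted at the I/O
boundary with 133.32 Pa/mmHg.

A fit is reported with a `converged` flag rather than an exception; the
systolic solve additionally demands that the notch equation is actually
satisfied (residual below $10^{-6}$ of the notch pressure), so a minimiser
stuck at a bound is flagged, not silently accepted. Cohort summaries exclude
non-converged fits listwise and report the exclusion count.

## Numerical evaluation of the convolution

The closed form contains the integral
$\int_0^t aP(\vartheta)e^{(a+b)\vartheta}d\vartheta$ multiplied by
$e^{-(a+b)t}$; evaluated naively the two factors overflow/underflow for
stiff rate constants. `reservoir_pressure_full()` instead propagates

$$I_{i+1} = I_i\,e^{-k\,\Delta t} + a\left[(w_0 - w_1)\,p_i + w_1\,p_{i+1}\right],
\qquad k = a + b,$$

with weights $w_0 = (1 - e^{-k\Delta t})/k$ and
$w_1 = (1 - w_0/\Delta t)/k$ chosen so that each step integrates a linear
segment of $P$ **exactly** (exponential-integrator weights). Every term is a
decay, never a growth, so the recursion is unconditionally stable; and since
the data only determine $P$ at the samples, the result is the exact solution
of the reservoir relation for the piecewise-linear reading of the record. A
plain trapezoidal rule was rejected: against an adaptive ODE oracle it
leaves errors of several pascals at 200 Hz, whereas the exponential weights
agree with `deSolve` on linearly interpolated samples to about
$5\times10^{-5}$ Pa.

Assembly of the full $P_r$ is hybrid by default: diastole from the fitted
exponential (which is the branch the diastolic error $X^2$ is judged on),
systole from the closed form, continuous at the notch because $a$ is solved
to hit $\bar P_n$ there. A `"full"` assembly (closed form everywhere) is
available for comparison. $X^2$ is the mean squared $P - P_r$ over **all**
of diastole regardless of the fitting window, with $N$ = diastolic sample
count — this is what makes the window choice visible as an error increase.

## Wave intensity analysis

Wave speed comes from the early-systolic slope of the PU loop,
$c = (1/\rho)\,\Delta P^+/\Delta U^+$ with $\rho = 1050$ kg/m³. "The linear
part" is operationalised as: start at the pressure foot (last pre-peak
sample at the minimum level), grow the window while the least-squares $P$
versus $U$ fit keeps $R^2 \ge 0.98$ (minimum 5 samples), stop 30 ms past
the peak of $dP/dt$. The detected region is reported for audit.

Wave intensity uses first differences of consecutive samples,
$dI = \Delta P\,\Delta U$, split by the water-hammer characteristics into
$dI^\pm = \pm(\Delta P \pm \rho c\,\Delta U)^2/(4\rho c)$; the identity
$dI^+ + dI^- = \Delta P\,\Delta U$ holds algebraically at every sample and
is asserted in the tests at machine precision. Wave areas integrate lobes of
$dI^\pm$ over time (sum × $\Delta t$, J/m²), with lobes bounded by
crossings of a noise floor of 0.5% of the series maximum:

* **FCW** — the dominant $dI^+$ lobe starting in early systole (before
  $0.5\,T_N$). "Dominant" rather than "first", because a single noisy
  sample can otherwise masquerade as the first lobe.
* **FEW** — the dominant $dI^+$ lobe, distinct from the FCW, starting in
  late systole ($[0.4\,T_N,\, T_N + 10\,\mathrm{ms}]$). Selecting by lobe
  *start* keeps the FEW detectable when, at 200 Hz, its lobe merges with
  the small early-diastolic forward wave just after the notch.
* **BCW** — the largest-magnitude $dI^-$ lobe between the FCW start and the
  FEW end, reported as a magnitude.

Lobes below 2% of the largest lobe's area are discarded as edge fragments.
Gap merging between lobes exists as an option but is off by default: the
genuine boundary between compression and expansion lobes at the pulse peak
is itself a short below-floor run and must not be closed. A missing FEW or
BCW yields a zero area with a flag, not an error.

First differences amplify measurement noise quadratically in $dI$, which
fragments lobes; `analyze_subject()` therefore applies Savitzky–Golay
smoothing (cubic, 9-sample window ≈ 40 ms at 200 Hz) to both waveforms
before the loop and intensity computations. The window preserves cubic
trends exactly and is short relative to the ≈150 ms systolic lobes. Pass
`sg_window = NULL` to disable it for clean data.

## The synthetic-data generator

No public single-beat carotid dataset with known reservoir ground truth
exists, so validation rests on a generator that *constructs* beats from the
model plus an explicit wave content:

* excess pressure = systolic forward half-sine (default 4000 Pa, onset
  20 ms, duration 300 ms) + optional mid-systolic backward half-sine
  (default 600 Pa at 140 ms, 150 ms wide) + a small forward early-diastolic
  half-sine starting at the notch (default 400 Pa, 80 ms), which both
  emulates residual early-diastolic wave activity and produces the dicrotic
  dip that makes the notch a genuine local minimum;
* reservoir pressure by adaptive ODE integration (`deSolve::lsoda`,
  `rtol` $10^{-10}$) of $dP_r/dt = a\,P_{ex} - b\,(P_r - P_\infty)$ — an
  equivalent rewriting of the reservoir relation that depends only on the
  chosen excess, keeping the generator independent of the estimator's
  quadrature;
* velocity from $U_r = (P - P_\infty)/\bar R$ and the water-hammer link
  $U_{ex} = (P_{ex,\rightarrow} - P_{ex,\leftarrow})/(\rho c)$, so the
  excess loop has exact slope $\rho c$ and wave-speed recovery is testable;
* i.i.d. Gaussian noise added to $P$ and $U$ after construction (defaults
  20 Pa and 0.004 m/s, the scale of ensemble-averaged tracings; no baseline
  wander).

Defaults describe a healthy middle-aged carotid artery: $a = 8$ /s,
$b = 2$ /s, $P_\infty = 60$ mmHg, $P_0 = 74$ mmHg, $T = 0.95$ s
(≈63 bpm), $T_N = 0.35$ s, $c = 6$ m/s, $\bar R = 4\times10^4$ Pa·s/m,
$f_s = 200$ Hz. `cohort_params()` adds truncated-normal between-subject
spread of plausible population width (e.g. $b \sim N(2, 0.4^2)$ on
$[0.5, 5]$); invalid draws are resampled up to a bounded retry count.
Per-subject noise seeds derive deterministically from the master seed.

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: tonometer contact artifacts and calibration
drift, Doppler spectral broadening, beat-to-beat and respiratory
variability, skewed or multi-bump ejection profiles, multi-exponential
diastolic run-off, and any spatial (propagative) behaviour of the reservoir
itself. The generator's diastole is model-matched by construction except
for the explicit tail wave, so real-data fits will generally be worse than
the synthetic recovery figures.

## Design choices where the convention is genuinely open

* **$X^2$ branch.** In diastole $P_r$ is taken from the fitted exponential
  (not the closed form); the two coincide only at a perfect fit, and the
  exponential is the branch the fit actually optimises.
* **$\bar P_n$ vs the closed form at $T_N$.** In 3-DOF fits the free
  $\bar P_n$ is authoritative: the systolic branch is solved to meet it, so
  the assembled waveform is continuous even when $\bar P_n \ne P_n$.
* **PRI/PEI.** Integrals of the absolute waveforms over the full cardiac
  cycle (trapezoid). This matches the magnitudes such parameters take for
  a ≈1 s beat with a ≈20 kPa reservoir peak; baselines relative to
  diastolic pressure are left to the caller.
* **Maxima.** Absolute maxima over the beat, not relative to diastolic
  pressure.
* **$U_r$ numerator.** The measured $P$ (not $P_r$), exactly as the
  decomposition defines it; a `use_reservoir_pressure` switch offers the
  $(P_r - P_\infty)/\bar R$ variant found elsewhere in the literature.
* **Alignment.** Sequentially recorded $P$ and $U$ are aligned foot-to-foot
  using intersecting tangents at sub-sample resolution (rounded only at the
  end, which keeps relative lags exact); a cross-correlation fallback on
  the normalised derivatives is available where foot detection is fragile.
* **Notch search.** Local minimum between the systolic peak and 60% of the
  beat, strict over a ±10 ms neighbourhood; a beat without a genuine dip
  raises an error and the caller may supply $T_N$ manually.
* **Cohort inference.** One-way ANOVA with Tukey's post-hoc test across the
  four techniques per parameter, plus paired two-tailed t-tests for
  measured- vs excess-derived wave intensity parameters, at $\alpha=0.05$.
  The fitting technique is arguably a within-subject factor; the one-way
  treatment is kept as the primary output because it is the convention the
  comparison mirrors, and the long-format `table` returned by
  `summarize_cohort()` lets users refit a repeated-measures model directly.

## Problem sizes used in the validation suite

The test suite and `scripts/acceptance.R` use: 100 generator beats for the
closed-form vs ODE agreement (tolerance 0.1 Pa; observed ≈ $10^{-4}$ Pa);
500 noise replicates (σ = 50 Pa) for the decay-fit Monte Carlo (median $b$
within 5%); wave speeds 4–12 m/s for loop recovery (within 3%); and a
200-subject synthetic cohort for the directional comparison of the four
techniques. Round-trip checks that are limited by the sampling of the
waveform rather than by the algorithms (recovering $P_{ex}$ and $a$ with
exactly matching parameters) are run at finer grids (1–8 kHz) at their
stated tolerances and additionally at 200 Hz at the tolerance that sampling
permits.

## Known limitations

* The pressure-only reservoir formulation inherits its usual caveats: it
  assumes the diastolic decay is site-independent and the excess is
  proportional to aortic inflow; neither is verified here.
* A single-exponential decay cannot represent multi-exponential run-off;
  subjects whose diastole genuinely needs two time constants will show
  inflated $X^2$ under every technique.
* Lobe-based wave areas depend on the noise floor and on lobe topology at
  200 Hz; heavily damped or fused lobes can shift area between FCW and FEW.
* The percentage comparisons between techniques are properties of the
  analysed cohort; on synthetic cohorts only their directions, not their
  magnitudes, are stable characteristics.
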