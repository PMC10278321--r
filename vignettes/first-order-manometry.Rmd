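---
title: "A first-order model of spinal manometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A first-order model of spinal manometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfmanometry)
```

## The physical model and its assumptions

A spinal manometer is a graduated vertical tube of bore area $A$
connected to the subarachnoid space through a spinal needle of hydraulic
resistance $R$. Treating the CSF source as a constant-pressure reservoir
and the needle as a laminar Poiseuille conduit, volume conservation in
the tube gives

$$A\,\frac{dh}{dt} = \frac{P_{CSF} - \rho\,h(t)}{R}, \qquad h(0) = 0,$$

a first-order linear system with time constant $\tau = RA/\rho$ and step
response $h(t) = (P_{CSF}/\rho)\,(1 - e^{-t/\tau})$. The assumptions
behind this — and where they bend on a real bench — are:

* **Laminar, fully developed flow in the needle.** Reynolds numbers for
  ml-per-minute flows through sub-millimetre bores are far below
  transition; entrance effects and bevel geometry are absorbed into a
  *measured* $R$ rather than modelled. This is why the drop-weight
  estimate of $R$ is preferred to the geometric one: nominally identical
  gauges differ in inner diameter, and $R \propto d^{-4}$ amplifies that
  fourfold in the exponent.
* **Constant source pressure.** On the bench this is a wide reservoir;
  `reservoir_pressure_drop_fraction()` quantifies the head lost to the
  fluid that fills the manometer, $(A/A^{*})\,h_{eq}/P_0$, and the
  ten-diameters rule ($D^{*} \ge 10D$) keeps it under 1 %.
* **No capillarity.** At a ~3–4 mm bore the capillary rise is a few mm
  and is neglected throughout.
* **A dry tube at $t=0$ and no needle dead volume.** Real columns carry
  an early-time offset from the needle and hub dead volume; the bundled
  bench data show it clearly (first-graduation crossings arrive 20–25 %
  later than the ideal curve predicts, and free fits return a larger
  $\tau$ and $P_\infty$ than the theoretical ones while remaining
  excellent exponentials, $R^2 > 0.999$). The model deliberately does
  not include this transient; see *Limitations*.

Units are canonical cm–g–s throughout: pressure in cmH2O with the
convention that a column of density $\rho$ g/ml and height $h$ cm exerts
$\rho h$ cmH2O, resistance in cmH2O·s/ml, viscosity in cmH2O·s
(conversion from mPa·s via 1 cmH2O = 98.0665 Pa, so 1.002 mPa·s =
1.0218e-5 cmH2O·s; the rounded working value 1e-5 is exported as
`mu_csf_rounded`). Interfaces that naturally speak millimetres (bore
and needle diameters, the catalog file) convert once at parse time.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| fluid density $\rho$ | g/ml | 1.0006 | CSF at body-like composition; bench fluids (Ringer lactate, saline) match it to ~0.5 %. The drop-weight table reproduces its printed flow rates at either $\rho = 1$ or $1.0006$ (both are exposed). |
| fluid viscosity $\mu$ | cmH2O·s | 1.0218e-5 | water-like CSF at 20 °C; enters only the geometric (Poiseuille) route to $R$. Pleocytosis or high protein move it too little to matter. |
| manometer bore | cm | 0.37 | the bench instrument; $A = \pi d^2/4$ is derived, never stored independently. |
| driving pressure $\Delta P$ | cmH2O | 13 (explicit) | the nominal bench head. Kept explicit everywhere because the bundled resistance table is internally consistent with $\Delta P \approx 15$ (see *Data notes*). |

## The estimator

`fit_rise()` minimises the sum of squared height residuals of
$h(t) = h_\infty (1 - e^{-t/\tau})$. Two structural facts shape the
implementation:

1. **The amplitude is conditionally linear.** For fixed $\tau$ the
   optimal $h_\infty$ is the closed-form projection
   $\sum g h / \sum g^2$ with $g = 1 - e^{-t/\tau}$. The joint problem
   is therefore solved by *variable projection*: a 1-D search over
   $\tau$ of the profiled sum of squares, which cannot diverge the way
   a naive 2-D Newton iteration can.
2. **$\tau$ has a physical anchor.** A first-order system crosses 63 %
   of equilibrium at $t = \tau$, so the search starts from the
   interpolated first crossing of $0.63\,\max h$ and brackets
   $[\tau_0/100,\ 100\,\tau_0]$ — generous enough for any plausible
   misreading of the anchor.

The bracketed search (`stats::optimize`, tolerance
$\sqrt{\varepsilon}$) is polished by damped Gauss–Newton steps until the
relative change in the residual sum of squares falls below $10^{-10}$
or 500 iterations elapse; non-convergence raises a classed condition
carrying the best iterate rather than returning silently. Degenerate
inputs (all heights equal, or fewer than three points for the joint
fit) are rejected up front. $R^2$ is the coefficient of determination
$1 - SS_{res}/SS_{tot}$ about the mean observed height. The test suite
cross-checks the whole estimator against `stats::nls` on noisy data;
the two agree to $10^{-5}$ in both parameters.

The companion fixed-parameter modes (`fixed_tau`, `fixed_p`) exist
because the validation question "how well does the *theoretical* curve
predict the bench data" and the statistical question "how well does the
*best* exponential fit" need different curves; `rms_error()` takes
$(P_\infty, \tau)$ explicitly so both protocols are one call each.

The τ-vs-R regression across needles (`tau_r_regression()`) is ordinary
least squares via `stats::lm`; under the model the slope *is* the
manometer area, so the implied bore $\sqrt{4\,\mathrm{slope}/\pi}$ is
reported as a physical sanity check (the bundled published pairs give
2.92 mm against a manufacturer-stated 3.05 ± 0.08 mm).

## The simulator and the synthetic-data generator

`simulate_rise()` integrates the governing ODE with a fixed-step
classical RK4 scheme. A guard rejects steps above $\tau/10$; at the
default steps used in the tests ($\le \tau/1000$) the trace agrees with
the closed form to below $10^{-6}$ cm over $5\tau$, and the suite
verifies both the empirical convergence order and agreement with an
independent adaptive solver (`deSolve::lsoda`). Pulsatile forcing is
additive sinusoids — one cardiac, one respiratory — because amplitude
and frequency are the only physiologically reported features;
amplitudes default to the ranges observed at lumbar puncture (cardiac
0.1–0.2 cm, respiratory 0.2–0.5 cm, ~1 cm with deep breathing).
Steady-state ripple in a simulated trace matches the analytic low-pass
gain $1/\sqrt{1 + (2\pi f \tau)^2}$ within 2 %, which is the quantitative
form of the clinical observation that pulsation is invisible in the
column.

`crossing_times()` converts a trace into bench-protocol readings: the
linearly interpolated first passage of each graduation. Linear
interpolation is adequate because the integration step is orders of
magnitude below the graduation spacing.

`generate_noisy_rise()` produces seeded synthetic datasets for the
estimator: exact graduation-crossing times from the closed form, with
i.i.d. Gaussian reading noise (default σ = 0.1 cm, about a tenth of a
graduation) added to the recorded heights. It emulates reading error
only — **not** the dead-volume transient, meniscus formation, or
drop-discretised flow of a real bench — so parameter-recovery results
on synthetic data demonstrate estimator correctness, not robustness to
those systematics. Everything stochastic flows from an explicit integer
seed, which is written into all output metadata.

Problem sizes used by the test suite were chosen to make each property
sharp at desk scale: 16 parameter combinations for noiseless recovery,
200 seeded datasets (σ = 0.1 cm, τ ≈ 110.6 s, P = 24 cmH2O) for the
recovery study — the median |τ̂ − τ|/τ must stay below 5 % and the
estimate distribution must straddle the truth — and traces of $8\tau$
at 100–200 samples per forcing cycle for the ripple checks.

## Numerical choices and edge cases

* `time_to_fraction(1, tau)` is a domain error, not `Inf`: equilibrium
  is reached only asymptotically and finite return types are kept
  finite.
* Extrapolation from a reading at $t \le 0$ is rejected (zero
  denominator); on noiseless data any $t > 0$ recovers the truth to
  $10^{-9}$ relative, but users should prefer $t \gtrsim \tau$ since
  the noise amplification factor is $1/(1 - e^{-t/\tau})$.
* Duplicated observation times within a replicate are rejected at parse
  time rather than averaged; heights must be nondecreasing in a
  *reading-protocol* dataset, while the fitter itself accepts arbitrary
  (t, h) pairs so pooled replicates and noisy simulations remain
  fittable.
* Decimal commas in rise CSVs are normalised at read time behind an
  explicit flag; the bundled bench table ships comma-normalised with the
  raw transcription alongside (`inst/extdata/table2_raw.txt`).
* Each bundled fixture is revalidated on load against frozen row counts
  and column sums, so a silent edit of the shipped data fails loudly.

## Data notes (bundled bench tables)

Three internal inconsistencies in the bundled measurements are surfaced
rather than patched:

* **Driving pressure.** The drop-weight protocol states a 13 cmH2O
  head, yet every tabulated resistance times its tabulated flow rate
  gives ≈ 15.0 cmH2O. `resistance_from_flow()` therefore takes
  $\Delta P$ explicitly, and the reproduction report prints the
  back-calculated $\Delta P$ per measurement next to resistances
  recomputed at the user's $\Delta P$.
* **One flow-rate entry.** The Braun Spinocan M3 row prints
  0.0107 ml/s, but its own mass and duration give 0.0106 at any
  admissible density; the other eight rows reproduce exactly at 4
  decimals.
* **RMS validation errors.** Under the theoretical-τ protocol
  (P = 13, τ from mean resistance and bore) the Pajunk Sprotte and
  Braun Spinocan data give ≈ 0.68 and ≈ 0.45 cmH2O, in line with the
  recorded 0.68 and 0.43; the M. Schilling data give ≈ 0.66 where 1.18
  was recorded, and no protocol implemented here (fitted-τ gives
  0.03–0.05) reproduces that value. The report shows both protocols per
  needle.

## Limitations

The model omits needle dead volume and meniscus formation, visible as
the early-time offset in the bench rises; fits to real data therefore
return an *effective* (τ, P∞) slightly above the theoretical ones even
when the exponential shape is excellent. It assumes Newtonian,
temperature-stable fluid and a vertical, uniform-bore manometer. It is
a bench/simulation tool: no claim is made about in-vivo sources, where
the CSF compartment is compliant rather than an ideal
constant-pressure reservoir.
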