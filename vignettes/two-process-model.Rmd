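---
title: "Methods: the two-process model as a forced relaxation oscillator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-process model as a forced relaxation oscillator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twoprocess)
```

## The model

Homeostatic sleep pressure $H$ relaxes exponentially toward a
state-dependent asymptote,

$$\frac{dH}{dt} = -\frac{H}{\chi_w} + \frac{\mu_w}{\chi_w}
\ \text{(wake)}, \qquad
\frac{dH}{dt} = -\frac{H}{\chi_s} + \frac{\mu_s}{\chi_s}
\ \text{(sleep)},$$

which integrates in closed form within each vigilance state; the package
never integrates these equations numerically. Wake switches to sleep when
$H$ reaches the upper threshold $H^+(t) = H_0^+ + a\,C(t)$ and sleep
switches to wake at the lower threshold $H^-(t) = H_0^- + a\,C(t)$, with
$C(t) = \cos(2\pi t/T_f)$ by default. Only the *active* threshold matters
in each state (upper during wake, lower during sleep): the underlying
neuronal mutual-inhibition picture is a hysteresis loop, and the package
deliberately permits the pressure to leave the inter-threshold band, as
the hysteretic reading implies.

An affine change of variable ($H \mapsto (H-\mu_s)/(\mu_w-\mu_s)$) removes
the two asymptotes ([`rescale_params()`]): simulated switch times are
exactly invariant, which the suite asserts to $10^{-6}$ h. A second exact
symmetry is time rescaling: a $T_f = 25$ h forcing with the homeostatic
time constants multiplied by $25/24$ reproduces the 24 h solution with
time stretched by $25/24$ — the argument that connects laboratory
free-run (circa 25 h) observations to the 24 h parameterisation.

## Parameters

| parameter | meaning | units | default |
|---|---|---|---|
| `chi_s` | sleep dissipation time constant | h | 4.2 |
| `chi_w` | wake rise time constant | h | 18.2 |
| `H0_plus` | mean upper threshold | pressure | 0.67 |
| `H0_minus` | mean lower threshold | pressure | 0.17 |
| `a` | circadian threshold amplitude | pressure | 0.12 |
| `mu_w`, `mu_s` | asymptotes | pressure | 1, 0 |
| `T_f` | circadian (forcing) period | h | 24 |
| `waveform` | threshold modulation $C$ | — | cosine |

The defaults are the standard human values used across the literature;
murine time constants (8.3 h / 1.7 h) are available as the `mouse`
fixture. Internally all times are hours (every published constant is
printed in hours); rotation numbers are reported per forcing period,
i.e. per "day" when $T_f = 24$.

Validation policy: impossible parameters (non-positive time constants or
period, negative amplitude, inverted asymptotes or thresholds) fail at
construction. Thresholds outside the asymptote band ($H_0^+ \ge \mu_w$ or
$H_0^- \le \mu_s$) are *constructible but flagged* — they describe
perpetual wake/sleep, which `natural_periods()` rejects explicitly and
the simulator reports as a non-terminating status. This keeps degenerate
corners of parameter scans representable instead of unreachable.

## The waveform and the phase convention

Only the sinusoid is built in: it is the form the model's methods
literature actually prints, and the exact shape used to generate the
published figures is not stated. The waveform is nonetheless a pluggable
pure function `f(t, T_f)` (range within $[-1,1]$), so the skewed
empirical waveform of the original 1984 parameterisation can be supplied
without touching the core. Phase 0 is the circadian *maximum*
($C(0)=1$), so the circadian minimum — the raster plots' marker — sits at
$t \equiv T_f/2 \pmod{T_f}$.

## Event detection

Within a state the pressure is a known exponential, so switching is a
scalar root-finding problem for
$g(t) = H(t) - H^{\text{active}}(t)$:

* **Analytic window.** A crossing cannot occur before the pressure
  reaches the near extreme of the oscillating threshold band and must
  occur by the time it passes the far extreme (or, when the asymptote
  lies inside the band, within one forcing period of settling past the
  band midline). These logarithmic bounds shrink the search to a few
  hours regardless of the time constants.
* **Bracketing.** $g$ is scanned on a uniform grid of step $T_f/2048$
  (configurable); the fastest published dynamics (polyphasic cycles of
  $T_{nat} \approx 1.6$ h) retain ~70 grid points per cycle. The first
  sign change is refined by bisection to $10^{-9}$ h. Tangencies narrower
  than the grid step are undetectable by construction and surface as an
  `UNRESOLVED` status, never as silent interpolation.
* **Zero amplitude** uses the exact logarithm directly, which is what
  makes the simulation-vs-formula acceptance comparison meaningful at
  $10^{-6}$ h over arbitrary valid parameters.
* **Minimum dwell.** After each switch the state must move $10^{-6}$ h
  off the threshold before a new crossing is accepted, preventing
  zero-length episode loops at tangencies. If at a switch the new active
  threshold has already been passed (possible at high amplitude), the
  state re-switches after the dwell rather than being clamped; such
  immediate re-switches are recorded in the switch log.
* **Non-termination** (asymptote entirely outside the active band) is
  detected analytically and reported: as a classed error by default, or
  as a flagged partial result for use inside scans.

The cosine path is implemented in C++ (Rcpp) because a tongue scan
evaluates on the order of $10^9$ exponentials; a pure-R mirror drives
arbitrary pluggable waveforms and doubles as an independent
implementation, cross-checked against the C++ route in the tests.

## Initial conditions and transients

The published description of the model never states how its simulations
were initialised. The package's declared choice: wake at $t = 0$ with
$H = (H_0^+ + H_0^-)/2$, and a discarded transient of $50\,T_f$ before
any episode is retained or counted. At small circadian amplitude the
attractor is unique, so classification is initial-condition-insensitive
after a transient of this length; at high amplitude several attractors
may coexist, and the simulator then reports the one reached from the
default state — `init` allows deliberate exploration of coexistence.
Episodes are clipped to the retained window so they tile it exactly;
onset counts use unclipped switch times only.

## Rotation numbers and classification

The dynamics reduce to a circle map: an upper-threshold hit at circadian
phase $\phi$ determines the next hit. `rotation_number()` iterates this
first-return map (default 100 discarded + 400 averaged iterations) and
returns the reciprocal mean lift increment — sleep onsets per forcing
period. Onset-to-onset accumulation is used instead of day-boundary bin
counts because bin counting aliases near tongue edges; the day-boundary
count (`sleeps_per_day()`) is retained as a cross-check, with agreement
within $1/50$ asserted on records of $\ge 50$ forcing periods.

`classify_rotation()` finds the minimal-denominator rational within
`tol = 1e-3` of the estimate, restricted to denominators $\le 12$, via
the Stern–Brocot simplest-fraction search (the same best-approximation
structure as continued-fraction convergents; the test oracle is an
independent exhaustive search). The tolerance matches the finite
iteration count: a 400-iteration estimate of a locked orbit is exact to
crossing precision, while a quasiperiodic estimate carries $O(1/400)$
error, so `1e-3` with $q_{max} = 12$ accepts genuine low-order locking
and rejects spurious high-order locking.

## Scans

`tongue_scan()` sweeps one natural-period-moving parameter against the
circadian amplitude; each cell is an independent pure function of its
parameters (results do not depend on evaluation order), annotated with
the analytic $T_{nat}$ for the dual horizontal axes of the published
tongue diagram. The published figure used roughly 110,000 cells; the
package's test-scale default is a 60 × 40 grid
($H_0^+ \in [0.3, 0.95]$, $a \in [0, 0.12]$, ~10 s on one CPU), with the
full-resolution scan available through the CLI. Because the exact
published sweep ranges are unprinted, the scaled grid stands in for the
figure, and the structural assertions — analytic zero-amplitude row,
(1,1) as the widest plateau at $a = 0.08$, tongue tips at
$T_{nat} = (m/n)\,T_f$ within grid resolution, staircase monotonicity,
plateau growth with amplitude, Farey ordering — replace pixel-level
comparison. The published bound $0.068 < n/m < 2.54$ depends on those
unstated ranges and is deliberately not reproduced.

## What the simulations do and do not establish

Everything here is the deterministic skeleton of the model. A green
suite establishes the closed forms, the exactness of the event-driven
integration, the two rescaling symmetries, and the entrainment structure
(tongues, staircase, phase-of-entrainment ordering across the monophasic
tongue). It does not speak to: REM/non-REM substructure (absent from the
model), stochastic threshold perturbations and noise-driven switching
(discussed only qualitatively in the source literature), scheduled sleep
or wake-effort overrides, light-feedback extensions of the circadian
process, or the skewed 1984 threshold waveform. Chaotic dynamics at high
amplitude are expected but not diagnosed (no Lyapunov machinery); cells
that fail to classify are surfaced as `UNRESOLVED`.

## Numerical summary

| quantity | value |
|---|---|
| crossing scan step | $T_f/2048$ (configurable) |
| crossing bisection tolerance | $10^{-9}$ h |
| minimum dwell after a switch | $10^{-6}$ h |
| rotation number iterations | 400 (+100 transient) |
| classification tolerance / max denominator | $10^{-3}$ / 12 |
| default transient | $50\,T_f$ |
| switch-point residual (asserted) | $< 10^{-7}$ pressure units |
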