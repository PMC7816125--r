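---
title: "The IME1 promoter lncRNA circuit: model, numerics, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The IME1 promoter lncRNA circuit: model, numerics, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imeswitch)
```

## The biological circuit

Entry into meiosis in budding yeast is gated by the master transcription
factor Ime1. Its promoter is unusually long and is traversed by two long
noncoding RNAs: *IRT1*, whose transcription through the promoter represses
*IME1* (transcriptional interference), and *IRT2*, transcribed upstream of
*IRT1*. The regulatory twist this package models is that *IRT2* acts on
*IRT1* in two opposite ways depending on its own transcription level: a
low, threshold-crossing level of *IRT2* transcription *licenses* the
*IRT1* promoter (chromatin opening, a one-way switch), while higher
*IRT2* transcription *represses* *IRT1* dose-dependently, again by
interference. *IRT1* itself is driven by the transcription factor Rme1,
which is abundant in cells expressing a single mating type (haploid-like
cells, which must not sporulate) and scarce in MATa/alpha diploids (which
may). The net effect is a cell-type-specific switch on Ime1.

## Model

All variables are dimensionless and scaled to [0, 1]; time is in hours.
The two dynamical variables are the *IME1* mRNA level $I_m$ and Ime1
protein level $I_p$:

$$\frac{dI_m}{dt} = \frac{s}{s + k_3 I_1} - k_4 I_m
\quad (s > 0; \text{ the synthesis term is } 0 \text{ when } s = 0),
\qquad
\frac{dI_p}{dt} = k_5 I_m - k_6 I_p,$$

with $I_m(0) = I_p(0) = 0$. The algebraic rates are:

* starvation input $s(t)$: a step function, $s \equiv 1$ from $t = 0$ by
  default (`starvation_signal()`; the package generalizes it to an
  arbitrary nonnegative step schedule because the mRNA equation has an
  explicit no-synthesis branch at $s = 0$, which the hysteresis analysis
  exercises);
* *IRT2* rate: $I_2 = \max(I_p - k_2,\, 0)$ — IRT2 transcription tracks
  Ime1 protein once it passes the threshold $k_2$ (`irt2_rate()`);
* the latch: $\chi = 1$ iff $I_2 \ge A$ **or** $I_1 > 0$; otherwise 0
  (`update_chi()`). Once *IRT2* transcription reaches the licensing
  threshold $A$, $\chi$ switches on, and because $I_1 > 0$ whenever
  $\chi = 1$ and $r > 0$, it then holds itself on even after $I_2$
  collapses — a hysteretic, self-latching switch. It can release only
  when $r = 0$ (no Rme1 to sustain *IRT1*);
* *IRT1* rate: $I_1 = \chi\, r / (r + k_1 I_2)$, with the $0/0$ case at
  $r = I_2 = 0$ defined as 0 (`irt1_rate()`). Rme1 drives *IRT1*; *IRT2*
  represses it dose-dependently;
* *IME1* transcription rate $I_t = s/(s + k_3 I_1)$, reported as a
  diagnostic column (`ime1_transcription_rate()`).

Default parameters (the published simulation values): $k_1 = 5$,
$k_2 = 0.05$, $k_3 = 10$, $k_4 = k_5 = k_6 = 1\,/\mathrm{h}$, $A = 0.01$,
and Rme1 level $r \in [0, 5]$.

Three *IRT2* regimes are supported (`irt2_mode()`): `wildtype` as above;
`activating_only`, which clamps $I_2 \equiv A$ for $t > 0$ (licensing
without repression); and `null`, $I_2 \equiv 0$ (no *IRT2* at all). The
clamps mirror how the counterfactuals are defined in the underlying
model: set $I_2 = A$ or $I_2 = 0$.

## Hybrid integration

The right-hand side is discontinuous in $\chi$, so `simulate_circuit()`
treats $\chi$ as a discrete mode of the integration rather than a
continuous state. Between switches the smooth ODE is integrated with the
adaptive Runge–Kutta 4(5) pair (deSolve's `ode45`, relative tolerance
$10^{-9}$, absolute $10^{-12}$). Threshold crossings are watched on the
dense solver output ($I_p$ against $k_2$ and $k_2 + A$); a bracketing
interval is refined by bisection on the crossing time (re-integrating
from the last pre-crossing state; tolerance $10^{-6}$ h) and polished
with one Newton step using $dI_p/dt$, which places the trigger on its
threshold to $\sim 10^{-10}$. The integration restarts at each
latch-flipping event. Events reported: `i2_onset` (first $I_p = k_2$),
`chi_activation` ($I_2$ reaching $A$), `chi_deactivation` (only possible
when $r = 0$). One-step ordering within the latch update follows the
narrative of the mechanism: $I_2$ is evaluated from the current $I_p$,
$\chi$ from ($\chi_{prev}$, $I_2$, previous $I_1$), then $I_1$ from the
new $\chi$. Both thresholds are inclusive ($\ge$), exactly as defined.

Under `activating_only` the clamp makes $I_2 = A \ge A$ immediately, so
the latch activation is recorded at $t = 0$; under `null` no events occur.

Two independent checks guard the integrator:

* a closed-form oracle, `closed_form_cascade()`: before the latch fires
  $I_1 = 0$ and the system is a linear two-stage cascade with full drive,
  solvable in closed form (with the repeated-eigenvalue variant when
  $k_4 = k_6$; defaults give $I_p(t) = 1 - (1 + t)e^{-t}$). The test
  suite holds the integrator to within $10^{-6}$ of it, and the located
  event times to the analytic roots of $(1+t)e^{-t} = 0.95$ and $0.94$
  ($\approx 0.355$ and $0.394$ h);
* a hand-written fixed-step RK4 fallback (`stepper = "rk4"`), which
  converges to the adaptive result as the step shrinks; its error is
  dominated by step-quantized latch switching, which is why the
  event-aware adaptive path is the default.

Output is resampled onto a uniform grid (default 0.01 h) plus the event
times, so trajectories are comparable across solver settings. Cell-type
presets (`simulate_cell_type()`) set $r = 5$ for haploid-like cells (the
top of the published range) and $r = 0.1$ for diploids; the source model
does not print the values used for its cell-type figures, so these are
this package's declared choices, exposed as arguments. Steady-state runs
use a 50 h horizon — at the default unit rates that is 50 relaxation
times, far past any transient.

## Steady states and the dose-response

With constant $s$, `fixed_point()` solves the self-consistency equation

$$I_p = \frac{k_5}{k_4 k_6}\cdot\frac{s}{s + k_3 I_1(I_p)},$$

which on the active branch ($I_p \ge k_2$, wildtype) is a quadratic in
$I_p$, solved exactly. Roots violating their branch assumption are
discarded (e.g. at $r = 0.1$ the quadratic also yields $0.0379 < k_2$,
which is not a fixed point of the actual piecewise map); if more than one
consistent root survives, the one reached by forward integration from
the resting initial state is selected and all roots are recorded in the
result. The latch-never-fires case (reachability of $A$ is checked
against the unrepressed plateau) returns the cascade steady state with
$\chi^* = 0$ and a warning in the wildtype regime, silently for `null`
where it is the expected behavior. An `method = "integration"` route
reads the state off a long simulation instead and is used to cross-check
the algebra; `dose_response()` verifies a configurable fraction (default
10%) of its grid this way at $10^{-4}$ tolerance.

Representative exact values with defaults, each reproduced by the test
suite against brute-force bisection of the self-consistency map:
$I_p^*(r{=}0.25) = 1/2$ exactly; $I_p^*(r{=}5) \approx 0.0946$
(repressed haploid); $I_p^*(r{=}0.1) \approx 0.792$ (active diploid);
$I_p^* = 1$ for $r = 0$ or `null` mode.

`sigmoid_metrics()` summarizes a dose-response curve: `r_half` is the
Rme1 level at which $I_p^*$ crosses half of its low-$r$ plateau (the
half-maximal response, refined by root-finding on the fixed-point map so
it is grid-independent; with defaults the wildtype value is exactly
$r_{1/2} = 0.25$, and the activating-only clamp shifts it 45-fold to
$1/180$). `dynamic_range` is $I_p^*(r_{min})/I_p^*(r_{max})$
($\approx 10.6$ for wildtype) and `max_abs_slope` the steepest descent
per decade of $r$. A curve is classified `switch_like` when the dynamic
range is at least 5 **and** `r_half` sits at or above 0.05 — i.e. a
high-contrast transition positioned inside the physiological Rme1
window. The thresholds operationalize the qualitative notion of a
two-plateau, bimodal dose-response; no numeric criterion exists in the
source, so they are package configuration (`dr_min`, `r_half_min`).
Under the defaults only the dual-function wildtype regime is
switch-like: the `activating_only` clamp still represses but its
transition collapses to implausibly small $r$, and `null` is flat at the
plateau — reproducing the claim that removing either face of the *IRT2*
dual function abrogates the bimodal Rme1–Ime1 relationship.

## Synthetic data

No numeric observations are published for this model, so the package
generates its own, with the statistical structure the analysis assumes.

`generate_time_course()` emulates bulk time courses (the analogue of
blot quantifications): the true $(I_m, I_p)$ at the design times receive
independent multiplicative lognormal noise, observed
$= \text{true}\cdot e^{\varepsilon}$,
$\varepsilon \sim N(0, \sigma^2)$ — positive, ratio-scaled measurements.
Defaults: $\sigma = 0.1$, 20 time points on $(0, 10]$ h (t = 0 is
excluded: the truth is exactly zero there and log-scale residuals would
be undefined), 3 replicates per point — triplicate being the norm for
such quantifications. Ground truth, noise spec and seed are stored in
the object's attributes; regeneration with the same seed is bit-for-bit
identical (one PRNG: Mersenne-Twister with inversion sampling, applied
without disturbing the caller's RNG state).

`generate_cell_population()` emulates a steady-state single-molecule
FISH readout: each cell draws an Rme1 level from a sampler (point mass,
lognormal, or mixture — `cell_r_sampler()`), its steady-state mRNA level
$I_m^*$ comes from the fixed point, and the copy number is
Poisson(`copy_scale` $\times I_m^*$). Cells above the `threshold` of 30
copies — the standard high-expresser criterion for this locus — are
counted into `fraction_high`. The model does not relate its
dimensionless units to absolute copies; `copy_scale = 50` copies per
unit $I_m$ is a declared synthetic choice, placing the repressed
haploid mean ($\approx 4.7$ copies) and the derepressed mean (50 copies)
on opposite sides of the 30-copy cut, and is never presented as inferred
biology. With it, the wildtype haploid population has essentially no
high expressers (Poisson tail beyond 30 at mean 4.7 is $< 10^{-10}$)
while the *IRT2*-null population is $> 95\%$ high — the synthetic
analogue, at the level of the model only, of the derepression seen in
*irt2* mutants.

What the generators deliberately do not emulate: intrinsic stochastic
circuit dynamics (no SSA/Langevin — cell-to-cell variability enters only
through $r$ and Poisson counting), transcriptional bursting, delays, or
correlated measurement error. Passing tests therefore certify the
pipeline's self-consistency under the declared observation models, not
agreement with the real smFISH or blot distributions, whose raw values
are not published.

## Parameter recovery

`fit_parameters()` minimizes the sum of squared log-residuals (matching
the lognormal noise model) between a synthetic dataset and the model at
the design times, over a free parameter subset, using Nelder–Mead on a
logistic box transform of the bounds — derivative-free, hence robust to
the latch discontinuity. Defaults: bounds $[0.05, 100]$ for rate-like
parameters, lower bound $10^{-4}$ for $k_2$ and $A$ (excluding
degenerate always-on circuits), start at the geometric mean of the
bounds, up to 500 iterations at relative tolerance $10^{-10}$; the
objective's internal simulations run at relaxed tolerances (rtol
$10^{-7}$, event tolerance $10^{-5}$ h) because estimation error is
noise-limited orders of magnitude before it is integrator-limited. A
start whose loss is already below $10^{-10}$ (the integrator noise
floor; only possible on noise-free data at truth) is returned as-is.
Two guards make failure modes explicit rather than silent: freeing
$\{k_5, k_6\}$ jointly is rejected up front (only their ratio is
observable at steady state), and a free parameter to which the objective
does not respond at all — e.g. $k_1$ fitted from data sampled entirely
before the latch fires at $\approx 0.39$ h — is flagged
`converged = FALSE` with a note, detected by a finite-difference probe
around the start.

`recovery_experiment()` repeats generate-then-fit across seeds (each
replicate's dataset seed is a deterministic substream of the master
seed) and reports per-parameter relative-error distributions; its
defaults are the generator's defaults, with the start deliberately
displaced to truth $\times 1.5$. On noise-free data truth is recovered
exactly; at $\sigma = 0.1$, $k_3$ is recovered to a few percent. $k_1$
is a different story, and a genuine property of the model rather than a
solver artifact: at the haploid Rme1 level ($r = 5$) the repression term
is $r/(r + k_1 I_2)$ with $k_1 I_2 \approx 0.22 \ll r$, so the
observables' elasticity with respect to $k_1$ is only $\approx 0.04$ —
the circuit output barely feels $k_1$ there, and its median recovery
error at $\sigma = 0.1$ sits around 30% even though the optimizer
verifiably finds the global minimum of the objective (the test suite
cross-checks it against a grid-search oracle, and the error scales
linearly as the noise is reduced). Users fitting $k_1$ should either
observe at lower $r$, where the parameter actually shapes the output, or
average more replicates.

## Limitations

* The model is the published six-equation circuit; no delays, bursting,
  chromatin state beyond the one-bit latch, or time-varying Rme1.
* The latch release (at $r = 0$) follows the literal indicator
  definition; biologically, chromatin-level memory might outlast it.
* Steady-state algebra assumes constant $s$; step schedules are handled
  by the simulator only.
* Dose-response metrics summarize one curve; no bifurcation continuation
  or stability eigen-analysis is attempted (reachability is checked by
  forward integration).
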