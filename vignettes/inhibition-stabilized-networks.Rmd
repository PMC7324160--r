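---
title: "Inhibition-stabilized networks: model, inference and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inhibition-stabilized networks: model, inference and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isnfit)
```

This vignette is the package's account of the science it implements: the
rate model and its assumptions, what each tunable parameter means, how the
inference works, what the synthetic-data generator does and does not emulate,
and the numerical and design choices made where the design was genuinely open.

## The two-population model

Population-averaged excitatory and inhibitory firing rates evolve as

$$\tau_E \dot r_E = -r_E + \phi_E(W_{EE} r_E - W_{EI} r_I + I_{EX}),$$
$$\tau_I \dot r_I = -r_I + \phi_I(W_{IE} r_E - W_{II} r_I + I_{IX} + \lambda L),$$

where $\phi_A(x) = a_A [x - x_{0A}]_+$ is a rectified-linear transfer
function (a softplus variant $b\log(1+e^{(a/b)(x-x_0)})$ is available; it
converges to the rectified-linear curve as $b \to 0$ and is overflow-guarded
for very large inputs). $\lambda L$ is optogenetic drive into the inhibitory
population: intensity $L$ times opsin efficacy $\lambda$.

Assumptions inherited from this model family:

* homogeneous populations — a single scalar rate per population; cell-to-cell
  heterogeneity only enters the synthetic generator (below);
* instantaneous opsin activation — $\lambda L$ switches with the light; any
  opsin kinetics would make fitted time constants upper bounds;
* laser intensity is used on a *normalized* scale where the inhibitory
  dose-response minimum sits at 1 ($L_0$ normalization, below); raw mW are
  converted upstream.

The equilibrium has two branches. On the interior branch (both populations
above threshold) the rates are linear in $L$ with denominator
$D = W_{EI}W_{IE} - (W_{II}+1)(W_{EE}-1)$, and
$dr_I/dL = -(W_{EE}-1)\lambda/D$: for $D > 0$ the slope is negative —
*paradoxical* — exactly when $a_E W_{EE} > 1$, the ISN condition. Once the
excitatory population is silenced the boundary branch applies,
$r_I = [I_{IX} + \lambda L - x_{0I}]_+ / (W_{II}+1)$, with positive slope
$\lambda/(W_{II}+1)$. Two parameter-free consequences follow and are kept as
tests: the inhibitory minimum coincides with the excitatory silencing
intensity, and the high-intensity inhibitory slope is the same with and
without excitatory blockers (the blocker transform does not touch $W_{II}$ or
$\lambda$).

When both branches are simultaneously self-consistent (a bistable
configuration) `fixed_point()` returns the interior branch and sets a
`bistable` flag. Single-valued response curves are assumed throughout — the
experiments this models produce single-valued dose-response curves, and
nothing downstream handles hysteresis.

## Pharmacological phases

The experiments have three phases: intact, excitatory blockers, and
excitatory plus inhibitory blockers. Blockade is modeled by survival factors
$\epsilon_E, \epsilon_I \in [0,1]$: excitatory blockers scale
$\{W_{EE}, I_{EX}, W_{IE}, I_{IX}\}$ by $\epsilon_E$ — external glutamatergic
input is blocked along with recurrent excitation — and inhibitory blockers
additionally scale $\{W_{EI}, W_{II}\}$ by $\epsilon_I$. The opsin efficacy is
never scaled: direct photocurrent is not synaptic. $\epsilon_E$ is shared
between the two blocker phases within a session (one $(\epsilon_E,
\epsilon_I)$ pair per session), since the blockers are applied cumulatively
within a recording day.

## Identifiability and parameter counting

The equilibrium is invariant under a two-parameter rescaling family
(`rescale_params()`): $\{W_{EE}-1, W_{EI}, I_{EX}, x_{0E}\}$ by $\gamma_E$ and
$\{W_{IE}, W_{II}+1, I_{IX}, x_{0I}, \lambda\}$ by $\gamma_I$. Gains can
therefore be pinned at $a_E = a_I = 1$ without loss of generality, leaving 11
free equilibrium parameters in the canonical single-session setup (9
structural + 2 efficacies); the time constants only enter the dynamics. With
a single phase, only ratios are identifiable — `fit_global()` warns and fits
anyway; with all three phases all 11 parameters are identifiable.

## Parameter inference

`fit_global()` performs multi-restart bounded least squares: starting points
are i.i.d. uniform on $[0, 10]$ per structural parameter (efficacies on
$[0,1]$), each restart runs a bounded Levenberg–Marquardt minimization of the
residual between observed mean rates and the model fixed points across all
phases and sessions, and the restart with the smallest residual sum of
squares wins. Design choices:

* **Residual weighting** — unweighted squared error by default; SEM weighting
  is available behind `weight_sem = TRUE`. Which the original analyses used is
  not documented, so unweighted is the default and the choice is explicit.
* **Singular parameter points** ($D \approx 0$) get a large finite penalty
  instead of an error, so the optimizer can traverse them.
* **Restart count** — the default is $10^3$; on noiseless synthetic curves
  the global minimum (zero residual) is reached far earlier, and an
  exhaustive $10^4$ remains available via the argument.
* **Determinism** — the restart stream is fixed by `seed`.

`bootstrap_fit()` wraps the global fit in unit resampling. The resampling
unit is a genuinely open choice (trials, units, or sessions); the package
resamples **units within each (session, population) stratum** with
replacement, which preserves the shape of the dataset, and the resampler is
injectable for anything else. Note that the resample distribution of $W_{EE}$
is strongly right-skewed — occasional resamples support near-degenerate
large-$W_{EE}$ solutions — so median and histogram mode are both reported and
can differ substantially; this mirrors how such fits behave on recorded data.

`fit_time_constants()` holds the equilibrium connectivity fixed and fits
$(\tau_E, \tau_I)$ to step-response traces by Nelder–Mead on log time
constants from the deterministic start $\tau_E = \tau_I = 10$ ms. Traces that
sit at the fixed point carry no information and are flagged non-identifiable.

## Stability analysis

At an interior fixed point the Jacobian is $2 \times 2$ and its eigenvalues
have a closed form (`eigenvalues_closed_form()`), implemented with the ratio
$r = \tau_E a_I W_{IE} / (\tau_I a_E W_{EI})$ and evaluated so that the
$W_{IE} \to 0$ (triangular) limit is finite. A nonzero imaginary part marks
damped oscillations. `stability_boundary_ratio()` bisects
$\max \mathrm{Re}\,\lambda$ over $\tau_I/\tau_E \in [10^{-3}, 10^3]$ to
tolerance $10^{-8}$; since the determinant of the Jacobian does not depend on
the ratio and the trace is monotone in it, stability flips exactly once, at
$(a_I W_{II}+1)/(a_E W_{EE}-1)$ when $a_E W_{EE} > 1$ and never when
$a_E W_{EE} \le 1$ (boundary $=\infty$). One caution: $\max \mathrm{Re}\,
\lambda$ itself is *not* monotone in the ratio — in the real-eigenvalue
region the fast eigenvalue initially decreases — so the implementation
bisects on the sign, which is monotone, not on the value. The boundary is
evaluated at the resting ($L=0$) operating point.

Because printed best-fit parameters are rounded to two decimals, the boundary
computed from them can differ from one computed from unrounded fit values by
a percent or two; agreement beyond that is not meaningful.

## Stimulating a subset of inhibitory cells

`build_three_pop()` splits the inhibitory population into a stimulated subset
P (fraction `frac`) and a remainder I. The construction is defined by two
requirements: each population's inhibitory input is split `frac : (1-frac)`
between P and I from the source model's inhibitory weight onto it, and the I
and P rows copy the source inhibitory row (inputs and thresholds included).
These force the conservation identity $W_{XI} + W_{XP} = W_{XI}^{src}$ and
the reduction property: at `frac = 1` the (E, P) subsystem is exactly the
source two-population model with I decoupled. The reduction property is the
construction's correctness check and is enforced in the tests.

The closed-form response of the stimulated population (`delta_rP()`) shows
that with two inhibitory populations an unstable excitatory subnetwork does
not imply paradoxical suppression of the stimulated subset: withdrawal of
inhibition from the non-stimulated cells can outweigh withdrawal of
excitation. As `frac` shrinks the initial slope of the stimulated
population's dose-response rises monotonically from the full-stimulation
(paradoxical) value toward non-paradoxical — the mechanism by which viral
(partial) and transgenic (near-complete) opsin expression produce different
average responses. In the simplified model where connectivity depends only on
the presynaptic identity, the response factor is
$[1+(k_I-1)W] / [1+(k_P+k_I-1)W]$, paradoxical iff negative, reducing in the
large-$W$ limit to $k_I < 1$ and $k_P > 1-k_I$.

The general fixed point (`fixed_point_3pop()`) is solved by active-set
enumeration over the 8 rectification patterns, tested in order of decreasing
number of active populations (a deterministic tie-break); when several
patterns are self-consistent the one reached by integrating the dynamics from
the resting state is returned, and divergence yields an `"unstable"` verdict.
No values of $\tau_P$ are established for this model, so the numeric
$3\times3$ eigensolver takes all three time constants as inputs.

## The unit-level pipeline

* **Classification.** Pharmacological: Welch's unequal-variance t-test on
  per-trial steady-state rates at maximum intensity vs baseline within the
  fully-blocked phase; inhibitory iff the change is positive and $p <
  \alpha$ (default 0.01). The test is two-sided with the sign requirement
  applied separately — sidedness is not pinned down by the verbal rule
  "positive and significant", and this reading is the more conservative one.
  High-power classification applies the same test in the intact phase; it is
  deliberately stringent (an inhibitory unit suppressed at every tested
  intensity is missed). Width classification fits a kernel density
  (`stats::density`, default bandwidth) to the waveform widths and thresholds
  at the minimum between the two dominant modes; it requires a bimodal
  distribution and at least 20 units.
* **Normalization.** $L_0$ is the free breakpoint of a continuous two-segment
  piecewise-linear least-squares fit to the session's average inhibitory
  dose-response (50-point grid over interior intensities, then
  `stats::optimize` refinement). A non-negative first-segment slope means no
  paradoxical minimum and $L_0$ is undefined. Normalized slopes are invariant
  under the raw laser unit because $L_0$ absorbs the scale.
* **Initial slope.** The OLS slope of mean rate against normalized intensity
  over $[0, 1]$. A two-point difference would also be defensible; OLS uses
  every pre-minimum point and is robust to grid density, and is the
  documented choice. The normalized slope divides by (baseline + 0.1 spk/s);
  the floor keeps near-silent units finite and bounds normalized slopes below
  by about $-1$ on the normalized range.
* **Transient detection.** The onset bin carries a stimulation artifact and
  is dropped. Binned 1-ms rates in the 1–12 ms post-onset window are compared
  with the 12 ms immediately before onset (the matched-duration baseline
  choice) by a two-sample KS test, with the positive-sign requirement. Peak
  amplitude, latency, FWHM (linear interpolation at half-max) and the
  baseline re-crossing time are measured on a 3-ms boxcar-smoothed PSTH
  (smoothing is display/shape machinery only, not part of the test).
  Detection power is intrinsically limited: the comparison has only 12 bins a
  side, and at high stimulation the model transient re-crosses baseline
  within the window, so resolving it in a pooled PSTH takes many sweeps.
* **Steady state and strata.** Steady-state windows default to the last
  300 ms of a 600 ms pulse (800 ms pulses for dynamics); depth strata are
  superficial $\le 400\,\mu m$ and deep $\ge 500\,\mu m$, with the gap
  excluded.
* **Population SEM.** Population curves report the SEM of the across-units
  *summed* counts per trial — the uncertainty appropriate for Poisson-like
  counts — rather than the across-unit variance of means.

## The synthetic-data generator

`generate_dataset()` emulates the experimental design: a laser grid spanning
0–10 mW with 100 repetitions per level and 600 ms pulses (300 ms steady-state
window), three pharmacological phases, an 80/20 E/I unit mixture, waveform
widths from two Gaussian modes at 0.58 ms (E) and 0.46 ms (I) with 0.05 ms
spread, per-session blocker efficacies and light-coupling scales ($L_0$ drawn
from 0.8–1.6 mW, within the observed 0.3–2.7 mW range). Trial counts are
Poisson around the model mean — the simplest noise model consistent with
count data; a negative-binomial over-dispersion factor is available. Unit
heterogeneity is a multiplicative log-normal rate factor ($\sigma = 0.5$ by
default, a realistic breadth for cortical rate distributions).

What it does **not** emulate — and hence what passing tests do and do not
show about recorded data: no spike sorting or waveform noise, no
trial-to-trial correlations or slow drift, no depth-dependent light
attenuation (depth is metadata), no opsin kinetics, and homogeneous
within-population tuning (every unit is a scaled copy of the population
curve). One consequence worth knowing: the log-normal unit factors multiply
the E and I population curves by their sample means, which corresponds to a
diagonal conjugation of the weight matrix — $W_{EE}$ and $W_{II}$ are
invariant to it, but scale-carrying parameters ($W_{EI}$, $W_{IE}$, inputs,
thresholds, $\lambda$) are recovered up to those factors unless the
heterogeneity is small or the unit count large.

## Numerical choices

* Dynamics: fixed-step explicit Euler, default $dt = 0.1$ ms with the guard
  $dt \le \min(\tau)/10$; convergence is verified by $dt$-halving. Rates
  cannot go negative (the transfer function is non-negative and decay is
  proportional to $-r$); divergent trajectories are capped at a configurable
  ceiling and flagged. With complex eigenvalues the excitatory relaxation
  shows sub-percent damped ripples — expected behavior, not integrator error.
* Stability bisection: tolerance $10^{-8}$ on the ratio, bracket
  $[10^{-3}, 10^3]$.
* $L_0$ fit: 50-point breakpoint grid plus golden-section refinement.
* Fixed-point branch selection tolerance: interior branch requires strictly
  positive rates; singular determinant threshold $10^{-9}$ inside the
  optimizer (penalty), $10^{-12}$ in the user-facing solver (error).

## Problem sizes

The test-suite and acceptance computations use desk-scale problem sizes
chosen so the checks are sharp but quick: noiseless recovery uses 10
intensities per phase and two sessions; the restart count for acceptance fits
is $10^3$; bootstrap demonstrations use 8 resamples of 24–96 units; the
transient-detection demonstration pools 56 units at several thousand sweeps
(the model transient at 2.6× the inhibitory minimum is ~1 spk/s on a ~9 spk/s
baseline, smaller than the measured transients on recorded data, so the
12-bin KS comparison needs more sweeps than a typical single experiment
provides).

## Known limitations

* Bistable parameter regions are flagged but not analyzed (no hysteresis).
* The bootstrap median of $W_{EE}$ is a skewed summary; compare with the mode.
* Only the sign conditions of the three-population fixed point are treated in
  closed form; its full stability analysis is numeric and depends on
  $\tau_P$, for which no measured value exists.
* The high-power classifier misses inhibitory units whose rates never exceed
  baseline in the tested intensity range — with moderately coupled networks
  this requires intensities several times $L_0$.
* All inference assumes the steady-state window truly reaches equilibrium;
  with $\tau_I$ of tens of ms and 600 ms pulses this is comfortable, but much
  shorter pulses would bias the fits.
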