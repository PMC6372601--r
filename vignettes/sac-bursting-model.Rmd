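---
title: "A conductance-based model of spontaneous bursting in developing starburst amacrine cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based model of spontaneous bursting in developing starburst amacrine cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacburst)
```

## The biological problem

During stage II of retinal development, starburst amacrine cells (SACs)
burst autonomously: seconds of fast subthreshold voltage oscillations and a
large calcium load, followed by tens of seconds of hyperpolarized silence.
These bursts, synchronized through cholinergic coupling, seed the retinal
waves that refine the early visual system, and the bursting disappears as
the retina matures. `sacburst` implements a five-variable conductance-based
model of a single immature SAC that reproduces this behavior from membrane
biophysics alone, plus the analysis toolkit used to characterize it:
fixed-point and bifurcation analysis of the fast subsystem, calcium-defined
burst statistics, and scripted pharmacology experiments.

## The model

The membrane potential $V$ (mV) obeys

$$C_m \frac{dV}{dt} = I_L(V) + I_C(V) + I_K(V,N) + I_{sAHP}(V,R)
  + I_{ext} + \sigma \xi_t,$$

with leak $I_L = -g_L (V - V_L)$, a voltage-gated calcium current of
Morris–Lecar form $I_C = -g_C M_\infty(V) (V - V_C)$, a fast voltage-gated
potassium current $I_K = -g_K N (V - V_K)$, and a slow
afterhyperpolarization current $I_{sAHP} = -g_{sAHP} R^4 (V - V_K)$ carried
by calcium-gated potassium (SK-like) channels. $\xi_t$ is white noise with
amplitude $\sigma$ (pA·ms$^{1/2}$). The gating variables follow

$$\tau_N \dot N = \Lambda(V) (N_\infty(V) - N), \qquad
  \tau_C \dot C = -\tfrac{\alpha_C}{H_X} C + C_0 + \delta_C I_C(V),$$
$$\tau_S \dot S = \alpha_S C^4 (1 - S) - S, \qquad
  \tau_R \dot R = \alpha_R S (1 - R) - R,$$

where $C$ is intracellular calcium (nM), $S$ the fraction of saturated
calmodulin (four calcium ions bind calmodulin), and $R$ the fraction of
bound channel terminals (four bound terminals open one channel — hence the
$R^4$ conductance). The sigmoids are
$M_\infty(V) = \tfrac12[1+\tanh((V-V_1)/V_2)]$,
$N_\infty(V) = \tfrac12[1+\tanh((V-V_3)/V_4)]$, and
$\Lambda(V) = \cosh((V-V_3)/2V_4)$ is a voltage-dependent rate factor.
Sodium channels are deliberately absent: blocking them experimentally does
not alter SAC bursting, and omitting them keeps the fast subsystem planar.

Units are fixed globally to (ms, mV, pF, pA, nS, nM), chosen so that
nS·mV = pA and pA/pF = mV/ms; the right-hand sides need no hidden
conversion factors, and a dimensional self-test in the suite verifies this.
The defaults built into `sac_params()` are the calibrated values
(capacitance 22 pF, leak 2 nS at −70 mV, sAHP 2 nS, `tau_N` = 5 ms,
`tau_C` = 2 s, `tau_S` = `tau_R` = 8.3 s, and so on); the conductances
`g_C` = 12 nS and `g_K` = 10 nS are the working point used for the
bifurcation analysis, since only ranges ([3, 20] and [1, 20] nS) are
physiologically constrained.

```{r}
p <- sac_params()
timescale_summary(p)
```

The membrane time is $\tau_L = C_m/g_L = 11$ ms; calcium is ~180× slower
and the sAHP cascade ~750× slower. This three-timescale structure is what
licenses the central analysis device: on the fast timescale, $C, S, R$ are
frozen and the model collapses to a planar Morris–Lecar-type system in
$(V, N)$ driven by a single constant $I_{tot} = I_{sAHP} + I_{ext}$
(`rhs_fast()`).

## Bifurcation structure of the fast subsystem

Equilibria satisfy $N = N_\infty(V)$ and a scalar current balance
$\Phi(V) = 0$, so `find_fixed_points()` uses a dense sign scan plus
bisection rather than a 2-D Newton iteration — exhaustive and free of
basin-of-attraction issues. Stability comes from the analytic Jacobian
(`fast_jacobian()`, checked against finite differences in the suite). At
the working point the structure as $I_{tot}$ grows is:

* a stable low-voltage rest state (between −70 and −60 mV) coexisting with
  a saddle and an unstable focus;
* a homoclinic bifurcation near −5.8 pA creating a stable limit cycle
  (fast oscillations) that coexists with the rest state;
* a saddle-node near −3.7 pA where the rest state and saddle annihilate,
  leaving the cycle as the only attractor;
* a Hopf bifurcation near 250 pA where the cycle dies into a depolarized
  stable state.

```{r, eval = FALSE}
locate_saddle_node(p)$I_sn    # -3.69 pA
locate_homoclinic(p)$I_hc     # -5.76 pA
locate_hopf(p)$I_hopf         # 250.2 pA
```

The saddle-node is refined by Newton iteration on the fold conditions
$\Phi = \Phi' = 0$ (the fold voltage does not depend on $I_{tot}$, which
enters $\Phi$ linearly, so the refinement is exact to machine precision).
The Hopf is a bisection on the Jacobian trace along the focus branch with
the determinant checked positive. The homoclinic deliberately does *not*
use continuation software — such connections are notoriously fragile for
continuation — but bisects on the existence of the limit cycle, probed by
direct simulation from the perturbed unstable focus. Near the connection
the cycle period grows steeply (a diagnostic the locator reports:
the period ~0.1 pA above the boundary is more than twice the period 2 pA
above), which distinguishes a homoclinic loss from a Hopf. The probe uses
dt = 0.01 ms and a 30 s horizon: at the routine step of 0.05 ms the
forward-Euler amplitude bias shifts the detected boundary by ~0.25 pA,
which we verified against an adaptive-step reference integration.

Bursting is the slow traversal of this diagram. During the active phase
calcium loads, $R$ grows, and $I_{sAHP}$ drags $I_{tot}$ leftwards until
the cycle dies at the homoclinic; during silence calcium unloads, the sAHP
decays, and the cell re-crosses the fold. Two triggers exist: at
$I_{ext} = 0$ no rest state survives the sAHP decay and bursting is
periodic and deterministic (*dynamically driven*); for
$I_{ext}$ below the fold a stable rest state exists and noise must carry
the cell across (*noise driven*). `region_map_2d()` classifies parameter
cells by phase-portrait signature (counts of stable low-/high-voltage
states plus cycle existence) into the qualitative regions A–E used
throughout the two-parameter diagrams; signatures outside the legend are
labelled `other` rather than forced.

## Stochastic integration

`simulate_sac()` uses fixed-step Euler–Maruyama with dt = 0.05 ms by
default. Additive noise rules out naive adaptive steppers, and 0.05 ms
resolves both `tau_N` = 5 ms and the ~30 ms oscillation period by large
margins; dt-halving changes a converged deterministic trajectory by well
under 0.5 mV. Noise enters only the voltage equation; the per-step kick is
$(\sigma\sqrt{dt}/C_m)\,z$ with $z$ standard normal, so the injected
current has spectral density $\sigma^2$ (the scheme has to be stated
explicitly because $\sigma$ is meaningless without it). With all voltage-
gated conductances removed the voltage is an Ornstein–Uhlenbeck process
whose stationary variance $\sigma^2/(2 g_L C_m)$ the suite reproduces
within 10%. The drift preserves $N, S, R \in [0,1]$ and $C \ge 0$ exactly;
only discretization can overshoot, so overshoots are clamped and counted
(rare: fewer than one per 10^6 steps at the default step). All randomness
flows from one integer seed through R's generator, so every trajectory is
bit-reproducible. The default initial condition is the clamped steady
state at −70 mV (`clamp_steady_state()`), the least-informative
reproducible rest; trajectories are subsampled to a 1 ms grid by default
to keep multi-hundred-second runs small.

## Burst statistics and the interburst-interval law

A burst is operationally a calcium excursion: $C$ above 150 nM for longer
than 1 s (`burst_config()`); runs touching the trace boundary are
discarded and dips are never merged. Interburst intervals (IBIs) are
onset-to-onset — this matches the "bursting period" usage; the
offset-to-onset gap is available as an option. In heat maps over
$(g_C, g_K)$, cells whose ensemble produced no interval are *missing*,
not zero (near the fold line bursts become too rare to sample); in the
$\tau_{IBI}(I_{ext})$ curve, a non-bursting point is recorded as zero by
convention.

Near the saddle-node the passage time obeys the normal-form square-root
law

$$\tau_{IBI} = \frac{K}{\sqrt{I_{ext} - I_c}}, \qquad I_{ext} > I_c,$$

with the critical current $I_c$ shifted below the deterministic fold by
noise. `fit_sqrt_law()` fits $(K, I_c)$ by nonlinear least squares
(Levenberg–Marquardt) over the positive-IBI points in a window defaulting
to $[-20, 40]$ pA, and reports 95% confidence intervals. Two functional
forms are selectable, differing exactly by a factor 2 in $K$
(`form = "eq"` versus `form = "half"`); both are in circulation for this
law and the fitted form is always recorded with the result. On synthetic
curves the estimator recovers the generating parameters exactly
(noiseless) and without bias (5% multiplicative noise, checked over 100
replicates).

At the reference conditions ($\sigma = 4$, sweep of $I_{ext}$ with five
500 s trajectories per point — the desk-scale version of the full
20 × 2000 s protocol) the fitted critical current lands at
$I_c \approx -4.7$ pA with the mean IBI decreasing monotonically from
~21 s near the fold to ~5.6 s at 17.5 pA, and collapsing to zero above
~20 pA where the cell stays continuously loaded (no refractory period).
The fitted prefactor is $K \approx 32$ s·pA$^{1/2}$ — consistent with the
simulated tens-of-seconds intervals, and roughly fifty times the published
value of 0.657 for this quantity. We report the fitted value with its
confidence interval and note that 32 s ≈ 0.53 min: the published constant
is consistent with our curve only if read in minutes (or as the
theoretical normal-form constant rather than a fit); a sub-second IBI at
$I_{ext} = 0$ would contradict the intervals the law is meant to describe.

Noise reshapes the IBI distribution. At $\sigma = 1$ intervals cluster
tightly around the deterministic period (~17 s); at $\sigma = 20$ the mean
collapses and the distribution broadens enormously, with the decaying-
exponential component of a Gaussian+exponential density fit
(`fit_ibi_distribution()`) absorbing about half the weight. Because the
mixture nests the pure Gaussian, model selection uses a residual-based AIC
rather than raw residuals. At $\sigma \approx 8$ a second mode of short
intervals appears, matching the short-burst phenomenology reported for
this noise range.

## In-silico experiments

`run_pulse_experiment()` reproduces the classic stimulation protocol: a
+150 pA, 60 ms pulse on a cell resting at −4 pA baseline with weak noise.
The control cell oscillates during the pulse (cycles counted by hysteresis
crossing, ≥3 peaks with >5 mV swing) and hyperpolarizes afterwards — the
calcium loaded in 60 ms feeds the slow cascade, so the
afterhyperpolarization develops over the following seconds, reaching
~9 mV below baseline. The cadmium variant zeroes both calcium-related
conductances ($g_C$ and $g_{sAHP}$) and shows only a raised plateau, no
oscillations, no afterhyperpolarization. The baseline of −4 pA and pulse
noise $\sigma = 1$ are our choices for an unstated quiet-rest condition:
−4 pA is the canonical noise-driven setting of the heat-map protocol.

`run_developmental_scenario()` encodes the maturation/pharmacology
presets as (g_K, V_3, I_ext) changes at $\sigma = 4$ over 600 s, with
$g_C$ left at its default because the original protocol specifies only the
potassium-side parameters (a logged assumption). Three of the five
scenarios behave as published: lowering $g_K$ to 8 nS at $V_3 = -34$ mV
(TEA-like blockade) produces bursting, the P22 preset with a −10 pA
inhibitory current is silent, and removing that inhibition restores
bursting. Two do not, and the disagreement is structural, not numerical:
with $g_C = 12$ nS the calcium window current at −70 mV (+9.6 pA) exceeds
anything the leak and potassium currents can balance at hyperpolarized
voltages, so *no* low-voltage rest state exists at $I_{tot} = 0$ for any
$(g_K, V_3)$ — verified analytically from $\Phi$ and against an
adaptive-integrator cross-check. Consequently the P4 preset
($g_K = 8$, $V_3 = -16$) parks in a stable depolarized focus
(continuously calcium-loaded rather than discretely bursting), and the P8
preset ($g_K = 10$, $V_3 = -34$) retains a small subthreshold cycle whose
noise-driven calcium excursions the 150 nM / 1 s rule counts as bursts.
Reproducing the published silent-P8 / bursting-P4 pair requires a smaller
calcium conductance than the working point, which the original protocol
does not state; we keep the stated conditions and report the flags the
model actually produces. The restored-bursting configuration caps its
depolarization near −28 mV rather than −20 mV for the same reason.

The fast-firing frequency deserves the same candor: on the limit cycle at
$I_{tot} = 0$ the model fires at ~30 Hz (verified against an
adaptive-step reference), while the "~20 Hz" figure describes firing
during actual bursts — when the sAHP holds $I_{tot}$ a few pA negative
and the period has already stretched on its way to the homoclinic
divergence (~100 ms within 0.1 pA of the boundary).
`measure_fast_frequency()` reports the frequency at whatever $I_{tot}$ it
is asked about, and errors (rather than returning 0) where no cycle
exists.

## Problem sizes and what the tests show

The suite and the acceptance script run desk-scale versions of the full
protocols: ensembles of 2–5 trajectories of 200–2000 s at dt = 0.1 ms for
burst statistics (the compiled inner loop integrates ~5 × 10^6 steps per
second of wall time), coarse heat-map grids, and the full-resolution
deterministic bifurcation locators. Passing tests therefore demonstrate
the mechanism and its statistics under sampling noise appropriate to those
ensemble sizes — they bound, but do not eliminate, the sampling
variability a 20 × 2000 s production run would reduce. The synthetic
fixtures (step-function calcium traces, closed-form square-root curves,
Gaussian/exponential samples) exercise the detectors and estimators
against known ground truth; they do not emulate bleed-through between
bursts, drifting baselines, or measurement noise in real calcium imaging,
so the detectors' field performance on experimental traces is outside
what the suite establishes.

## Known limitations

* Forward Euler–Maruyama is first-order; deterministic bifurcation
  locators compensate with small steps, but stochastic quantities carry a
  scheme-dependent bias of a few percent.
* The nonlinear sodium–calcium-exchanger flux is linearized into the
  calcium decay term (valid while $C \ll H_X = 1800$ nM; bursts here peak
  around 400–900 nM).
* The biochemical constants upstream of the lumped parameters
  ($\delta_C$, $\alpha_C$, $C_0$, ...) are documented but not derivable
  in-package; they enter only through their calibrated values.
* Single-cell only: cholinergic coupling, synchrony, and wave propagation
  are out of scope.
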