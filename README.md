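# sacburst

Simulator and analysis toolkit for the spontaneous bursting of immature
**starburst amacrine cells (SACs)** — the retinal interneurons that, during
stage II of development, burst autonomously and drive cholinergic retinal
waves. The package is aimed at computational neuroscientists who want to
simulate the single-cell mechanism, map its bifurcation structure, and
reproduce its burst statistics and pharmacology in silico.

## The model

A five-variable conductance-based model with three timescales:

```
C_m dV/dt = -g_L (V - V_L) - g_C M∞(V) (V - V_C) - g_K N (V - V_K)
            - g_sAHP R^4 (V - V_K) + I_ext + σ ξ_t
τ_N dN/dt = Λ(V) (N∞(V) - N)                      (fast K+ gating, ~ms)
τ_C dC/dt = -(α_C/H_X) C + C_0 + δ_C I_C(V)       (calcium, ~2 s)
τ_S dS/dt = α_S C^4 (1 - S) - S                   (calmodulin, ~8 s)
τ_R dR/dt = α_R S (1 - R) - R                     (sAHP terminals, ~8 s)
```

Fast voltage-gated calcium (depolarizing) and potassium (hyperpolarizing)
currents generate ~30 ms subthreshold oscillations; the calcium load drives
a slow calcium-gated potassium conductance (`g_sAHP R^4`, fourth-order
because four calmodulin-bound terminals open one channel) whose
afterhyperpolarization terminates the burst and sets the long refractory
period. On the fast timescale the model reduces to a planar Morris–Lecar-
type system in `(V, N)` with the slow current frozen as a parameter
`I_tot`; bursting is a slow traversal of that subsystem's bifurcation
diagram: a **saddle-node** near −3.7 pA starts repetitive firing, a
**homoclinic** connection near −5.8 pA ends it (a square-wave burster),
and a **Hopf** at ~250 pA bounds the oscillatory range from above.

The stochastic system is integrated by Euler–Maruyama with a compiled
(Rcpp) inner loop; bifurcations are located by sign-scan root finding,
Newton-refined fold conditions, trace bisection, and cycle-existence
bisection (no continuation software — homoclinic connections defeat it).
Burst statistics use the calcium rule "above 150 nM for more than 1 s",
and the interburst-interval law `τ_IBI = K / sqrt(I_ext - I_c)` is fitted
by nonlinear least squares.

## Worked example

```r
library(sacburst)
p <- sac_params()                 # calibrated defaults, g_K = 10, g_C = 12 nS

# Fast-subsystem equilibria at I_tot = -10 pA: rest + saddle + focus
find_fixed_points(-10, p)[, c("V_star", "N_star", "stability_class")]
#>      V_star       N_star stability_class
#> 1 -70.31950 2.379952e-06            sink
#> 2 -52.91157 3.439276e-04          saddle
#> 3 -27.57276 3.240822e-01  unstable_focus

locate_saddle_node(p)$I_sn        # -3.69 pA: onset of repetitive firing

# Deterministic (dynamically driven) bursting at I_ext = 0, no noise
tr <- simulate_sac(sac_params(sigma = 0), T = 3e5, seed = 1)
ev <- detect_bursts(tr)           # 18 bursts in 300 s
ib <- interburst_intervals(ev)
c(mean_s = mean(ib) / 1000, cv = sd(ib) / mean(ib))
#>  mean_s      cv
#>  16.97    0.041                  # periodic: ~17 s period, CV ~4%

# Pulse experiment: oscillations + afterhyperpolarization, abolished by
# zeroing the calcium-related conductances ("cadmium")
run_pulse_experiment("control", seed = 3)
#> Pulse experiment (control): oscillations yes (5 peaks), AHP yes, max V = 2.0 mV
run_pulse_experiment("cadmium", seed = 3)
#> Pulse experiment (cadmium): oscillations no (1 peaks), AHP no, max V = -28.7 mV
```

The sink at −70.3 mV is the resting cell; the saddle and unstable focus
organize the escape to fast firing. In the noise-free run the cell bursts
with a clock-like ~17 s period set by the sAHP cascade; with noise
(`sigma = 4`, the default) the period acquires the variability analysed by
`ibi_vs_iext()` / `fit_sqrt_law()`.

A thin command-line wrapper over the same functions is installed at
`inst/cli/sacburst` (subcommands `simulate`, `fixed-points`,
`continuation`, `map2d`, `ibi-sweep`, `heatmap`, `experiment`).

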