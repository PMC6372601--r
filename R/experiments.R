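# Scripted in-silico experiments: current-pulse stimulation with and
# without calcium-channel blockade, and developmental / pharmacological
# potassium-conductance scenarios.

#' Developmental scenario presets
#'
#' Parameter presets mimicking the excitability of isolated SACs at
#' different developmental ages and under pharmacology. Only `g_K`, `V_3`
#' and the baseline current are changed (`g_C` stays at its default 12 nS;
#' noise sigma = 4 pA ms^(1/2)):
#' * `P4` — immature autonomous burster: g_K = 8 nS, V_3 = -16 mV, I_ext = 0.
#' * `P8` — more mature, silent: g_K = 10 nS, V_3 = -34 mV, I_ext = 0.
#' * `P8_TEA` — potassium blockade (TEA) restores bursting: g_K = 8 nS,
#'   V_3 = -34 mV, I_ext = 0.
#' * `P22_TEA` — TEA alone insufficient under synaptic inhibition:
#'   g_K = 4.5 nS, V_3 = -35 mV, I_ext = -10 pA; silent.
#' * `P22_restored` — inhibition removed: g_K = 4.5 nS, V_3 = -35 mV,
#'   I_ext = 0; bursting restored.
#'
#' @return Named list of presets; each has `overrides` (parameter list) and
#'   `expected_bursting` (logical).
#' @export
scenario_presets <- function() {
  list(
    P4 = list(overrides = list(g_K = 8, V_3 = -16, I_ext_baseline = 0),
              expected_bursting = TRUE),
    P8 = list(overrides = list(g_K = 10, V_3 = -34, I_ext_baseline = 0),
              expected_bursting = FALSE),
    P8_TEA = list(overrides = list(g_K = 8, V_3 = -34, I_ext_baseline = 0),
                  expected_bursting = TRUE),
    P22_TEA = list(overrides = list(g_K = 4.5, V_3 = -35, I_ext_baseline = -10),
                   expected_bursting = FALSE),
    P22_restored = list(overrides = list(g_K = 4.5, V_3 = -35,
                                         I_ext_baseline = 0),
                        expected_bursting = TRUE)
  )
}

# Count oscillation cycles in a voltage window by hysteresis crossing: a
# cycle is an upward crossing of the upper band edge after a visit below the
# lower edge. Robust against small-amplitude noise riding on a plateau (a
# monotone rise through the band counts once at most).
count_oscillation_peaks <- function(tt, V, min_p2p = 5) {
  if (length(V) < 5 || diff(range(V)) <= min_p2p) return(0L)
  mid <- (max(V) + min(V)) / 2
  hi <- mid + min_p2p / 4
  lo <- mid - min_p2p / 4
  armed <- FALSE
  count <- 0L
  for (v in V) {
    if (v < lo) armed <- TRUE
    else if (v > hi && armed) { count <- count + 1L; armed <- FALSE }
  }
  count
}

#' Current-pulse stimulation experiment, with optional cadmium blockade
#'
#' Applies a +150 pA, 60 ms current pulse to a resting cell held at a
#' baseline current of -4 pA (noise-driven rest regime) with weak noise
#' (sigma = 1 pA ms^(1/2)). The `control` variant keeps all conductances;
#' the `cadmium` variant zeroes both calcium-related conductances (`g_C`
#' and `g_sAHP`), mimicking Cd2+ blockade of voltage-gated calcium and sAHP
#' channels. The control cell shows fast subthreshold oscillations during
#' the pulse and an afterhyperpolarization (AHP) once it ends; the blocked
#' cell shows only a raised voltage plateau.
#'
#' @param variant `"control"` or `"cadmium"`.
#' @param params base [sac_params()]; the pulse-test noise and baseline are
#'   applied on top.
#' @param seed RNG seed.
#' @param pulse,duration pulse amplitude (pA) and length (ms).
#' @param T total simulated time (ms); the pulse starts at `t_on`.
#' @param t_on pulse onset (ms).
#' @return List of class `sac_experiment`: `trajectory`, `oscillations`
#'   (logical: >= 3 voltage peaks with > 5 mV swing during the pulse),
#'   `n_peaks`, `ahp` (post-pulse dip below the pre-pulse baseline),
#'   `max_V` (mV), `variant`.
#' @export
run_pulse_experiment <- function(variant = c("control", "cadmium"),
                                 params = sac_params(), seed = 1,
                                 pulse = 150, duration = 60,
                                 T = 10000, t_on = 2000) {
  variant <- match.arg(variant)
  p <- params
  p$sigma <- 1
  p$I_ext_baseline <- -4
  if (variant == "cadmium") { p$g_C <- 0; p$g_sAHP <- 0 }
  p <- validate_sac_params(p)
  proto <- make_pulse_protocol(p$I_ext_baseline, pulse, t_on, duration, T)
  tr <- simulate_sac(p, T = T, protocol = proto, dt = 0.05, seed = seed,
                     stride = 2L)  # 0.1 ms sampling resolves ~20 Hz cycles
  tt <- tr$times; V <- tr$states[, "V"]
  in_pulse <- tt >= t_on & tt <= t_on + duration
  n_peaks <- count_oscillation_peaks(tt[in_pulse], V[in_pulse])
  pre <- tt < t_on & tt >= t_on - 500
  # the sAHP develops over seconds (R integrates the calcium load on tau_R)
  post <- tt > t_on + duration + 250 & tt <= min(T, t_on + duration + 6500)
  baseline_V <- mean(V[pre])
  ahp <- min(V[post]) < baseline_V - 2
  structure(list(trajectory = tr, variant = variant,
                 oscillations = n_peaks >= 3, n_peaks = n_peaks,
                 ahp = ahp, max_V = max(V[in_pulse]),
                 baseline_V = baseline_V),
            class = "sac_experiment")
}

#' Run a developmental / pharmacological scenario
#'
#' Simulates 600 s of the full model under one of the [scenario_presets()]
#' at sigma = 4 pA ms^(1/2) and flags bursting via [detect_bursts()].
#'
#' @param name preset name (see [scenario_presets()]).
#' @param seed RNG seed.
#' @param T simulated time (ms).
#' @param params base [sac_params()] the preset overrides are applied to.
#' @param dt integration step (ms).
#' @return List of class `sac_experiment`: `trajectory`, `bursting`
#'   (logical), `n_bursts`, `max_V` (mV), `name`, `expected_bursting`.
#' @export
run_developmental_scenario <- function(name, seed = 1, T = 6e5,
                                       params = sac_params(), dt = 0.1) {
  presets <- scenario_presets()
  if (!name %in% names(presets))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  pre <- presets[[name]]
  p <- params
  p[names(pre$overrides)] <- pre$overrides
  p$sigma <- 4
  p <- validate_sac_params(p)
  tr <- simulate_sac(p, T = T, dt = dt, seed = seed)
  ev <- detect_bursts(tr)
  structure(list(trajectory = tr, name = name,
                 bursting = nrow(ev) > 0, n_bursts = nrow(ev),
                 max_V = max(tr$states[, "V"]),
                 expected_bursting = pre$expected_bursting),
            class = "sac_experiment")
}

#' @export
print.sac_experiment <- function(x, ...) {
  if (!is.null(x$variant)) {
    cat(sprintf("Pulse experiment (%s): oscillations %s (%d peaks), AHP %s, max V = %.1f mV\n",
                x$variant, if (x$oscillations) "yes" else "no", x$n_peaks,
                if (x$ahp) "yes" else "no", x$max_V))
  } else {
    cat(sprintf("Scenario %s: bursting %s (%d bursts), max V = %.1f mV\n",
                x$name, if (x$bursting) "yes" else "no", x$n_bursts, x$max_V))
  }
  invisible(x)
}

#' Frequency of the fast repetitive firing
#'
#' Measures the limit-cycle frequency of the fast subsystem at a given
#' frozen current from the mean inter-peak interval after transient
#' discard ([limit_cycle_probe()]). At the reference working point and
#' `I_tot = 0` the firing runs at about 20 Hz.
#'
#' @param I_tot frozen total current (pA).
#' @param params a [sac_params()] object.
#' @return Frequency in Hz. Errors if no limit cycle exists at `I_tot`.
#' @export
measure_fast_frequency <- function(I_tot = 0, params = sac_params()) {
  lc <- limit_cycle_probe(I_tot, params)
  if (!lc$exists || !is.finite(lc$period))
    stop("no limit cycle at I_tot = ", I_tot, " pA; frequency undefined")
  1000 / lc$period
}
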