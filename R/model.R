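#' Gating and rate functions of the fast subsystem
#'
#' Evaluates the three dimensionless auxiliary functions of the model at a
#' membrane potential `V`: the calcium channel steady-state activation
#' `M_inf(V) = (1 + tanh((V - V_1)/V_2))/2`, the voltage-dependent rate
#' factor `Lambda(V) = cosh((V - V_3)/(2 V_4))` of the potassium gating
#' variable, and the potassium steady-state activation
#' `N_inf(V) = (1 + tanh((V - V_3)/V_4))/2`.
#'
#' `M_inf` and `N_inf` are strictly increasing sigmoids in (0, 1);
#' `Lambda >= 1`, with equality at `V = V_3`.
#'
#' @param V membrane potential (mV); vectorized.
#' @param params a [sac_params()] object.
#' @return A list with numeric components `M_inf`, `Lambda`, `N_inf`, each
#'   the length of `V`.
#' @export
activation_functions <- function(V, params = sac_params()) {
  stopifnot(inherits(params, "sac_params"))
  if (!is.numeric(V) || any(!is.finite(V)))
    stop("V must be finite numeric (got non-finite value)")
  list(
    M_inf  = 0.5 * (1 + tanh((V - params$V_1) / params$V_2)),
    Lambda = cosh((V - params$V_3) / (2 * params$V_4)),
    N_inf  = 0.5 * (1 + tanh((V - params$V_3) / params$V_4))
  )
}

#' Construct a model state
#'
#' A state holds the five dynamical variables: membrane potential `V` (mV),
#' fast potassium gating fraction `N`, intracellular calcium `C` (nM),
#' saturated-calmodulin fraction `S`, and bound-terminal fraction `R` of the
#' calcium-gated potassium (sAHP) channels.
#'
#' @param V,N,C,S,R state components; `N`, `S`, `R` must lie in \[0, 1\] and
#'   `C >= 0`.
#' @return A named numeric vector of class `sac_state`.
#' @export
sac_state <- function(V, N, C, S, R) {
  x <- c(V = V, N = N, C = C, S = S, R = R)
  if (any(!is.finite(x))) stop("state components must be finite")
  if (N < 0 || N > 1 || S < 0 || S > 1 || R < 0 || R > 1)
    stop("gating fractions N, S, R must lie in [0, 1]")
  if (C < 0) stop("calcium concentration C must be >= 0")
  structure(x, class = c("sac_state", "numeric"))
}

#' Ionic currents of the model
#'
#' Computes the four signed membrane currents (pA) at a given state:
#' leak `I_L = -g_L (V - V_L)`, voltage-gated calcium
#' `I_C = -g_C M_inf(V) (V - V_C)`, fast potassium
#' `I_K = -g_K N (V - V_K)`, and the slow afterhyperpolarization current
#' `I_sAHP = -g_sAHP R^4 (V - V_K)`. Four bound channel terminals are needed
#' to open one sAHP channel, hence the fourth power of `R`. Each current
#' vanishes at its reversal potential and when its gate is closed;
#' depolarizing currents are positive below their reversal potential.
#'
#' @param state a [sac_state()] (components `N` and `R` are used; `C`, `S`
#'   do not enter the currents directly).
#' @param params a [sac_params()] object.
#' @return A named numeric vector `c(I_L, I_C, I_K, I_sAHP)` in pA.
#' @export
ionic_currents <- function(state, params = sac_params()) {
  stopifnot(inherits(params, "sac_params"))
  V <- state[["V"]]; N <- state[["N"]]; R <- state[["R"]]
  a <- activation_functions(V, params)
  c(I_L    = -params$g_L * (V - params$V_L),
    I_C    = -params$g_C * a$M_inf * (V - params$V_C),
    I_K    = -params$g_K * N * (V - params$V_K),
    I_sAHP = -params$g_sAHP * R^4 * (V - params$V_K))
}

#' Deterministic drift of the full five-variable system
#'
#' Right-hand side of the full model (noise excluded):
#' \deqn{C_m dV/dt = I_L + I_C + I_K + I_{sAHP} + I_{ext}}
#' \deqn{\tau_N dN/dt = \Lambda(V) (N_\infty(V) - N)}
#' \deqn{\tau_C dC/dt = -(\alpha_C/H_X) C + C_0 + \delta_C I_C(V)}
#' \deqn{\tau_S dS/dt = \alpha_S C^4 (1 - S) - S}
#' \deqn{\tau_R dR/dt = \alpha_R S (1 - R) - R}
#'
#' @param state a [sac_state()].
#' @param I_ext external current (pA).
#' @param params a [sac_params()] object.
#' @return Named numeric vector of time derivatives `(V, N, C, S, R)` in
#'   (mV, 1, nM, 1, 1) per ms.
#' @export
rhs_full <- function(state, I_ext = 0, params = sac_params()) {
  I <- ionic_currents(state, params)
  a <- activation_functions(state[["V"]], params)
  C <- state[["C"]]; S <- state[["S"]]; R <- state[["R"]]
  c(V = (sum(I) + I_ext) / params$C_m,
    N = a$Lambda * (a$N_inf - state[["N"]]) / params$tau_N,
    C = (-(params$alpha_C / params$H_X) * C + params$C_0 +
           params$delta_C * I[["I_C"]]) / params$tau_C,
    S = (params$alpha_S * C^4 * (1 - S) - S) / params$tau_S,
    R = (params$alpha_R * S * (1 - R) - R) / params$tau_R)
}

#' Right-hand side of the fast (V, N) subsystem
#'
#' On the millisecond timescale the slow variables `C`, `S`, `R` are frozen
#' and the model reduces to a Morris-Lecar-type planar system in which the
#' slow and external currents act through a single constant
#' `I_tot = I_sAHP + I_ext`:
#' \deqn{C_m dV/dt = -g_L (V - V_L) - g_C M_\infty(V)(V - V_C)
#'       - g_K N (V - V_K) + I_{tot}}
#' \deqn{\tau_N dN/dt = \Lambda(V)(N_\infty(V) - N)}
#'
#' @param V membrane potential (mV).
#' @param N potassium gating fraction.
#' @param I_tot frozen total slow + external current (pA).
#' @param params a [sac_params()] object.
#' @return Named numeric vector `c(V = dV/dt, N = dN/dt)`.
#' @export
rhs_fast <- function(V, N, I_tot, params = sac_params()) {
  a <- activation_functions(V, params)
  dV <- (-params$g_L * (V - params$V_L) -
           params$g_C * a$M_inf * (V - params$V_C) -
           params$g_K * N * (V - params$V_K) + I_tot) / params$C_m
  dN <- a$Lambda * (a$N_inf - N) / params$tau_N
  c(V = dV, N = dN)
}

#' Stationary state of the sub-dynamics at clamped voltage
#'
#' Closed-form stationary values of `N`, `C`, `S`, `R` when the membrane
#' potential is clamped at `V0`: `N* = N_inf(V0)`,
#' `C* = (C_0 + delta_C I_C(V0)) H_X / alpha_C`,
#' `S* = alpha_S C*^4 / (1 + alpha_S C*^4)`,
#' `R* = alpha_R S* / (1 + alpha_R S*)`. This is the default initial
#' condition of [simulate()] (clamp at the leak reversal potential).
#'
#' @param V0 clamp potential (mV).
#' @param params a [sac_params()] object.
#' @return A [sac_state()] whose `N`, `C`, `S`, `R` drift components vanish.
#' @export
clamp_steady_state <- function(V0, params = sac_params()) {
  stopifnot(inherits(params, "sac_params"))
  a <- activation_functions(V0, params)
  I_C <- -params$g_C * a$M_inf * (V0 - params$V_C)
  C_star <- (params$C_0 + params$delta_C * I_C) * params$H_X / params$alpha_C
  if (C_star < 0)
    stop("invalid clamp point: stationary calcium would be negative at V0 = ",
         V0, " mV (V0 above the calcium reversal potential)")
  S_star <- params$alpha_S * C_star^4 / (1 + params$alpha_S * C_star^4)
  R_star <- params$alpha_R * S_star / (1 + params$alpha_R * S_star)
  sac_state(V = V0, N = a$N_inf, C = C_star, S = S_star, R = R_star)
}

#' Characteristic timescales of the model
#'
#' The membrane time constant is `tau_L = C_m / g_L`; relative to it the
#' slow variables have dimensionless rates `tau_L / tau_X`. With the default
#' parameters `tau_L = 11` ms, `tau_L/tau_C = 5.5e-3` and
#' `tau_L/tau_S = tau_L/tau_R ~ 1.3e-3`, the separation that justifies
#' freezing `C`, `S`, `R` in the fast subsystem ([rhs_fast()]).
#'
#' @param params a [sac_params()] object; `g_L` must be positive.
#' @return List with `tau_L` (ms) and the dimensionless inverse relative
#'   times `inv_tilde_tau_C`, `inv_tilde_tau_S`, `inv_tilde_tau_R`.
#' @export
timescale_summary <- function(params = sac_params()) {
  stopifnot(inherits(params, "sac_params"))
  if (params$g_L <= 0) stop("timescale summary requires g_L > 0")
  tau_L <- params$C_m / params$g_L
  list(tau_L = tau_L,
       inv_tilde_tau_C = tau_L / params$tau_C,
       inv_tilde_tau_S = tau_L / params$tau_S,
       inv_tilde_tau_R = tau_L / params$tau_R)
}
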