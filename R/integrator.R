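#' Piecewise-constant stimulation protocols
#'
#' A stimulation protocol is an ordered, gapless list of segments
#' `(t_start, t_end, I_ext)` covering `[0, T]`, giving the external current
#' (pA) injected in each time window.
#'
#' @param segments a data frame or 3-column matrix with columns
#'   `t_start`, `t_end`, `I_ext` (ms, ms, pA).
#' @return An object of class `sac_protocol`.
#' @seealso [constant_protocol()], [make_pulse_protocol()]
#' @export
stim_protocol <- function(segments) {
  seg <- as.data.frame(segments)
  names(seg) <- c("t_start", "t_end", "I_ext")
  if (nrow(seg) < 1L) stop("protocol needs at least one segment")
  if (any(!is.finite(as.matrix(seg)))) stop("protocol entries must be finite")
  if (is.unsorted(seg$t_start, strictly = TRUE) && nrow(seg) > 1L)
    stop("protocol segments must be sorted by t_start")
  if (any(seg$t_end <= seg$t_start))
    stop("each protocol segment must have t_end > t_start")
  if (nrow(seg) > 1L && any(abs(seg$t_start[-1] - seg$t_end[-nrow(seg)]) > 1e-9))
    stop("protocol segments must be contiguous (no gaps or overlaps)")
  if (seg$t_start[1] != 0) stop("protocol must start at t = 0")
  structure(seg, class = c("sac_protocol", "data.frame"))
}

#' @rdname stim_protocol
#' @param I_ext constant external current (pA).
#' @param T protocol duration (ms).
#' @export
constant_protocol <- function(I_ext, T) {
  stim_protocol(data.frame(t_start = 0, t_end = T, I_ext = I_ext))
}

#' Build a single-step current-pulse protocol
#'
#' Three segments: baseline current, baseline + pulse during
#' `[t_on, t_on + duration]`, baseline again until `T`. The canonical
#' stimulation experiment applies a +150 pA pulse for 60 ms on a resting
#' cell.
#'
#' @param baseline baseline external current (pA).
#' @param pulse pulse amplitude added to the baseline (pA).
#' @param t_on pulse onset time (ms).
#' @param duration pulse duration (ms).
#' @param T total protocol duration (ms).
#' @return A `sac_protocol`.
#' @export
make_pulse_protocol <- function(baseline, pulse, t_on, duration, T) {
  if (t_on < 0 || t_on + duration > T)
    stop("pulse window must lie inside [0, T]")
  if (pulse == 0 || duration == 0) return(constant_protocol(baseline, T))
  seg <- data.frame(
    t_start = c(0, t_on, t_on + duration),
    t_end   = c(t_on, t_on + duration, T),
    I_ext   = c(baseline, baseline + pulse, baseline))
  seg <- seg[seg$t_end > seg$t_start, ]  # drop empty lead segment if t_on = 0
  stim_protocol(seg)
}

#' Simulate the full five-variable stochastic model
#'
#' Integrates the model with a fixed-step Euler-Maruyama scheme (compiled
#' inner loop). White current noise of amplitude `sigma` (pA ms^(1/2))
#' enters only the voltage equation: the per-step voltage kick is
#' `(sigma sqrt(dt)/C_m) z` with `z` standard normal, so the injected
#' current has spectral density `sigma^2`. The run is bit-reproducible for
#' identical `(params, protocol, T, dt, seed, init)`. Discretization
#' overshoots of the gating variables out of \[0, 1\] (or calcium below 0)
#' are clamped and counted; with the default `dt` they are rare.
#'
#' @param params a [sac_params()] object; `params$sigma` sets the noise
#'   amplitude (set `sigma = 0` for deterministic runs).
#' @param T duration (ms).
#' @param protocol a `sac_protocol`, or `NULL` for a constant current equal
#'   to `params$I_ext_baseline`.
#' @param dt time step (ms), in (0, 0.5].
#' @param seed integer RNG seed.
#' @param init initial [sac_state()], or `"auto"` for
#'   `clamp_steady_state(-70)`, a clamped rest point.
#' @param stride sampling stride in steps of `dt`; the default samples every
#'   `round(1/dt)` steps, i.e. a 1 ms output grid.
#' @return A `sac_trajectory`: list with `times` (ms), `states` (matrix with
#'   columns `V`, `N`, `C`, `S`, `R`), `n_clamped`, and `metadata`.
#' @examples
#' p <- sac_params(sigma = 0)
#' tr <- simulate_sac(p, T = 10000, seed = 1)
#' range(tr$states[, "V"])
#' @export
simulate_sac <- function(params, T, protocol = NULL, dt = 0.05, seed = 1,
                         init = "auto", stride = NULL) {
  stopifnot(inherits(params, "sac_params"))
  if (!(dt > 0 && dt <= 0.5)) stop("dt must lie in (0, 0.5] ms")
  if (T < dt) stop("T must be at least dt")
  if (is.null(protocol)) protocol <- constant_protocol(params$I_ext_baseline, T)
  if (!inherits(protocol, "sac_protocol")) stop("protocol must be a sac_protocol")
  if (max(protocol$t_end) < T)
    stop("protocol must cover [0, T]")
  if (identical(init, "auto")) init <- clamp_steady_state(-70, params)
  if (!inherits(init, "sac_state")) stop("init must be a sac_state or \"auto\"")
  if (is.null(stride)) stride <- max(1L, as.integer(round(1 / dt)))

  segm <- as.matrix(as.data.frame(protocol))
  set.seed(as.integer(seed))
  res <- .sim_full_cpp(param_vector(params), segm, T, dt, params$sigma,
                       as.numeric(init), as.integer(stride))
  sam <- res$samples
  colnames(sam) <- c("t", "V", "N", "C", "S", "R")
  structure(list(
    times = sam[, "t"],
    states = sam[, c("V", "N", "C", "S", "R"), drop = FALSE],
    n_clamped = res$n_clamped,
    n_steps = res$n_steps,
    metadata = list(params = params, dt = dt, seed = seed,
                    protocol = as.data.frame(protocol), stride = stride,
                    T = T)),
    class = "sac_trajectory")
}

#' @export
print.sac_trajectory <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("SAC trajectory: %.4g s, dt = %g ms, stride = %d, seed = %s\n",
              md$T / 1000, md$dt, md$stride, format(md$seed)))
  cat(sprintf("  %d samples; V in [%.2f, %.2f] mV; C in [%.1f, %.1f] nM\n",
              length(x$times), min(x$states[, "V"]), max(x$states[, "V"]),
              min(x$states[, "C"]), max(x$states[, "C"])))
  if (x$n_clamped > 0)
    cat(sprintf("  %g clamping events over %g steps\n", x$n_clamped, x$n_steps))
  invisible(x)
}

#' Simulate the deterministic fast (V, N) subsystem
#'
#' Integrates [rhs_fast()] at frozen `I_tot` with fixed-step Euler. Used by
#' the limit-cycle probe and for phase-portrait inspection.
#'
#' @param I_tot frozen total current (pA).
#' @param params a [sac_params()] object.
#' @param T duration (ms).
#' @param dt time step (ms).
#' @param init numeric `c(V, N)` initial condition.
#' @param stride sampling stride in steps (default 1: full resolution).
#' @return A data frame with columns `t`, `V`, `N`.
#' @export
simulate_fast <- function(I_tot, params = sac_params(), T = 5000, dt = 0.05,
                          init, stride = 1L) {
  stopifnot(inherits(params, "sac_params"))
  if (!(dt > 0 && dt <= 0.5)) stop("dt must lie in (0, 0.5] ms")
  out <- .sim_fast_cpp(param_vector(params), I_tot, T, dt,
                       as.numeric(init), as.integer(stride))
  data.frame(t = out[, 1], V = out[, 2], N = out[, 3])
}

#' Write or read a trajectory as delimited text
#'
#' Columnar text with header `t_ms V_mV N C_nM S R` at 9 significant
#' digits, plus a sidecar `<path>.meta` with the run metadata (parameters,
#' dt, seed, stride). Round-trips losslessly at the stated precision.
#'
#' @param traj a `sac_trajectory`.
#' @param path output file path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "sac_trajectory"))
  tab <- cbind(t_ms = traj$times, traj$states)
  colnames(tab) <- c("t_ms", "V_mV", "N", "C_nM", "S", "R")
  utils::write.table(format(as.data.frame(tab), digits = 9, trim = TRUE,
                            scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  md <- traj$metadata
  meta <- c(sprintf("dt = %.9g", md$dt),
            sprintf("seed = %s", format(md$seed)),
            sprintf("stride = %d", md$stride),
            sprintf("T = %.9g", md$T),
            sprintf("param.%s = %.9g", names(md$params), unlist(md$params)))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory`: a data frame with the sampled columns.
#' @export
read_trajectory <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
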