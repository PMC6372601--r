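# Burst detection and interburst-interval (IBI) statistics.
#
# A burst is operationally a calcium excursion: the intracellular Ca2+
# concentration exceeds a threshold (default 150 nM) for longer than a
# minimum duration (default 1 s). IBIs are onset-to-onset by default.

#' Burst detection configuration
#'
#' @param calcium_threshold calcium level defining the active phase (nM).
#' @param min_duration minimal above-threshold time to count as a burst (ms).
#' @return A list of class `burst_config`.
#' @export
burst_config <- function(calcium_threshold = 150, min_duration = 1000) {
  if (calcium_threshold <= 0) stop("calcium_threshold must be > 0")
  if (min_duration <= 0) stop("min_duration must be > 0")
  structure(list(calcium_threshold = calcium_threshold,
                 min_duration = min_duration), class = "burst_config")
}

#' Detect bursts in a calcium trace
#'
#' Finds maximal runs of samples with `C > threshold` lasting at least
#' `min_duration`. Runs touching either end of the trace are discarded
#' (their true extent is unknown) and no gap-merging is performed: two
#' excursions separated by any sub-threshold dip are two bursts.
#'
#' @param trace a `sac_trajectory` from [simulate_sac()], or a data frame /
#'   list with components `times` (ms) and calcium samples (`C` column of
#'   `states`, or a `C` component).
#' @param config a [burst_config()].
#' @return Data frame with one row per burst: `t_onset`, `t_offset`,
#'   `duration` (ms).
#' @export
detect_bursts <- function(trace, config = burst_config()) {
  stopifnot(inherits(config, "burst_config"))
  if (inherits(trace, "sac_trajectory")) {
    tt <- trace$times; C <- trace$states[, "C"]
  } else if (!is.null(trace$times) && !is.null(trace$C)) {
    tt <- trace$times; C <- trace$C
  } else stop("trace must be a sac_trajectory or have times and C components")
  if (!length(tt)) stop("empty trace")
  above <- C > config$calcium_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  # discard boundary-touching runs
  keep[keep & (starts == 1L | ends == length(above))] <- FALSE
  if (!any(keep))
    return(data.frame(t_onset = numeric(0), t_offset = numeric(0),
                      duration = numeric(0)))
  on <- tt[starts[keep]]
  off <- tt[ends[keep]]
  dur <- off - on
  ok <- dur >= config$min_duration
  data.frame(t_onset = on[ok], t_offset = off[ok], duration = dur[ok])
}

#' Interburst intervals from detected bursts
#'
#' Onset-to-onset differences between consecutive bursts (the "bursting
#' period"); optionally offset-to-onset (the silent gap).
#'
#' @param events burst data frame from [detect_bursts()].
#' @param mode `"onset"` (default) or `"gap"`.
#' @return Numeric vector of intervals (ms); empty for fewer than 2 bursts.
#' @export
interburst_intervals <- function(events, mode = c("onset", "gap")) {
  mode <- match.arg(mode)
  if (nrow(events) < 2L) return(numeric(0))
  ev <- events[order(events$t_onset), ]
  if (mode == "onset") diff(ev$t_onset)
  else ev$t_onset[-1] - ev$t_offset[-nrow(ev)]
}

#' Pooled IBI statistics over an ensemble of simulations
#'
#' Runs `n_traj` independent trajectories (seeds `base_seed`,
#' `base_seed + 1`, ...), detects bursts in each, and pools the
#' within-trajectory interburst intervals.
#'
#' @param params a [sac_params()] object (noise from `params$sigma`,
#'   current from `params$I_ext_baseline`).
#' @param n_traj number of trajectories (>= 1).
#' @param T duration of each trajectory (ms).
#' @param base_seed seed of the first trajectory.
#' @param config a [burst_config()].
#' @param dt integration step (ms).
#' @return List of class `ibi_stats`: `ibis` (ms), `mean_ibi` (ms, `NA` if
#'   no interval), `n_bursts`, `n_trajectories`, `n_zero_burst`,
#'   `total_time` (ms).
#' @export
ibi_ensemble <- function(params, n_traj = 5, T = 5e5, base_seed = 1,
                         config = burst_config(), dt = 0.1) {
  if (n_traj < 1) stop("n_traj must be >= 1")
  ibis <- numeric(0)
  n_bursts <- 0L
  n_zero <- 0L
  for (k in seq_len(n_traj)) {
    tr <- simulate_sac(params, T = T, dt = dt, seed = base_seed + k - 1L)
    ev <- detect_bursts(tr, config)
    n_bursts <- n_bursts + nrow(ev)
    if (nrow(ev) == 0L) n_zero <- n_zero + 1L
    ibis <- c(ibis, interburst_intervals(ev))
  }
  structure(list(ibis = ibis,
                 mean_ibi = if (length(ibis)) mean(ibis) else NA_real_,
                 n_bursts = n_bursts, n_trajectories = n_traj,
                 n_zero_burst = n_zero, total_time = n_traj * T),
            class = "ibi_stats")
}

#' Mean IBI heat map over the (g_C, g_K) plane
#'
#' Per-cell [ibi_ensemble()]; cells where the ensemble produced no interval
#' are reported as missing (`NA`), not zero — near the saddle-node line the
#' sampling yields rare or no bursts.
#'
#' @param gC_range,gK_range `c(from, to)` conductance ranges (nS).
#' @param resolution grid step (nS), > 0.
#' @param params base [sac_params()] object.
#' @param n_traj,T,base_seed,config,dt passed to [ibi_ensemble()].
#' @return Data frame with `g_C`, `g_K`, `mean_ibi` (ms, `NA` when missing),
#'   `n_bursts`.
#' @export
ibi_heatmap <- function(gC_range, gK_range, resolution = 0.25,
                        params = sac_params(), n_traj = 5, T = 5e5,
                        base_seed = 1, config = burst_config(), dt = 0.1) {
  if (resolution <= 0) stop("resolution must be > 0")
  gCs <- seq(gC_range[1], gC_range[2], by = resolution)
  gKs <- seq(gK_range[1], gK_range[2], by = resolution)
  rows <- list()
  cell <- 0L
  for (gk in gKs) for (gc in gCs) {
    cell <- cell + 1L
    p <- params; p$g_C <- gc; p$g_K <- gk
    p <- validate_sac_params(p)
    st <- ibi_ensemble(p, n_traj = n_traj, T = T,
                       base_seed = base_seed + (cell - 1L) * n_traj,
                       config = config, dt = dt)
    rows[[cell]] <- data.frame(g_C = gc, g_K = gk, mean_ibi = st$mean_ibi,
                               n_bursts = st$n_bursts)
  }
  do.call(rbind, rows)
}

#' Mean IBI as a function of the external current
#'
#' Runs [ibi_ensemble()] at each requested `I_ext`. Where the ensemble
#' yields no interval the mean IBI is recorded as 0 by convention (the cell
#' does not burst, or bursts without a refractory period).
#'
#' @param I_values external currents to sample (pA).
#' @param params base [sac_params()] (its `sigma` applies; the default
#'   sweep condition is sigma = 4, g_K = 10, g_C = 12).
#' @param n_traj,T,base_seed,config,dt passed to [ibi_ensemble()].
#' @return Data frame with `I_ext` (pA), `mean_ibi` (ms), `n_bursts`,
#'   `n_intervals`.
#' @export
ibi_vs_iext <- function(I_values, params = sac_params(), n_traj = 5,
                        T = 5e5, base_seed = 1, config = burst_config(),
                        dt = 0.1) {
  rows <- lapply(seq_along(I_values), function(i) {
    p <- params; p$I_ext_baseline <- I_values[i]
    st <- ibi_ensemble(p, n_traj = n_traj, T = T,
                       base_seed = base_seed + (i - 1L) * n_traj,
                       config = config, dt = dt)
    data.frame(I_ext = I_values[i],
               mean_ibi = if (is.na(st$mean_ibi)) 0 else st$mean_ibi,
               n_bursts = st$n_bursts, n_intervals = length(st$ibis))
  })
  do.call(rbind, rows)
}

#' Fit the square-root law of the interburst interval
#'
#' Near the saddle-node bifurcation the mean interburst interval follows
#' \deqn{\tau_{IBI} = K / \sqrt{I_{ext} - I_c}, \quad I_{ext} > I_c,}
#' with \eqn{\tau_{IBI} = 0} below the critical current `I_c` (no bursting).
#' Fits `(K, I_c)` by nonlinear least squares over the curve points with
#' positive mean IBI inside the fit window. Two functional forms are
#' selectable: `"eq"` is the law above; `"half"` uses
#' `K / (2 sqrt(I_ext - I_c))` (the two differ exactly by a factor 2 in
#' `K`; both are in circulation for this law, so the form used is always
#' reported).
#'
#' @param curve data frame from [ibi_vs_iext()] (`I_ext` in pA, `mean_ibi`
#'   in ms).
#' @param form `"eq"` (default) or `"half"`.
#' @param window fit window on `I_ext` (pA).
#' @return List of class `sqrt_law_fit`: `K` (s pA^(1/2)), `I_c` (pA),
#'   `K_ci`, `I_c_ci` (95% confidence intervals), `residual_norm` (s),
#'   `form`, `n_points`, and the fitted model object.
#' @export
fit_sqrt_law <- function(curve, form = c("eq", "half"), window = c(-20, 40)) {
  form <- match.arg(form)
  pts <- curve[curve$mean_ibi > 0 &
                 curve$I_ext >= window[1] & curve$I_ext <= window[2], ]
  if (nrow(pts) < 4L)
    stop("need at least 4 points with positive mean IBI inside the window")
  df <- data.frame(I = pts$I_ext, tau = pts$mean_ibi / 1000)  # ms -> s
  fac <- if (form == "half") 2 else 1
  I_c0 <- min(df$I) - 1
  K0 <- fac * stats::median(df$tau * sqrt(pmax(df$I - I_c0, 0.1)))
  fit <- tryCatch(
    minpack.lm::nlsLM(tau ~ K / (fac * sqrt(I - I_c)), data = df,
                      start = list(K = K0, I_c = I_c0),
                      upper = c(K = Inf, I_c = min(df$I) - 1e-6),
                      lower = c(K = 0, I_c = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("square-root-law fit failed: ",
                             conditionMessage(e)))
  est <- stats::coef(fit)
  ci <- tryCatch(suppressMessages(stats::confint.default(fit)),
                 error = function(e) matrix(NA_real_, 2, 2))
  structure(list(K = unname(est["K"]), I_c = unname(est["I_c"]),
                 K_ci = unname(ci["K", ]), I_c_ci = unname(ci["I_c", ]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 form = form, n_points = nrow(df), model = fit),
            class = "sqrt_law_fit")
}

#' @export
print.sqrt_law_fit <- function(x, ...) {
  cat(sprintf("Square-root IBI law fit (form = %s, %d points)\n",
              x$form, x$n_points))
  cat(sprintf("  K   = %.4g s pA^(1/2)  [95%% CI %.4g, %.4g]\n",
              x$K, x$K_ci[1], x$K_ci[2]))
  cat(sprintf("  I_c = %.4g pA          [95%% CI %.4g, %.4g]\n",
              x$I_c, x$I_c_ci[1], x$I_c_ci[2]))
  cat(sprintf("  residual norm = %.4g s\n", x$residual_norm))
  invisible(x)
}

#' Fit the IBI distribution by a Gaussian or Gaussian + exponential model
#'
#' Histograms the intervals (1 s bins), converts to a density, and fits by
#' least squares either a Gaussian density or a two-component mixture of a
#' Gaussian and a decaying exponential. At low noise the interval
#' distribution is approximately Gaussian; increasing noise produces an
#' exponential right tail.
#'
#' Because the mixture nests the Gaussian (weight 1), raw residual
#' comparison would always prefer it; model selection therefore uses a
#' residual-based AIC (`n log(SSE/n) + 2k` over the histogram bins) so the
#' exponential component must earn its two extra parameters.
#'
#' @param ibis interburst intervals (ms); at least 20.
#' @param model `"gaussian"`, `"gaussian_plus_exponential"`, or `"both"`
#'   (default: fit both and report which fits better).
#' @param bin_width histogram bin width (ms).
#' @return List with per-model parameter estimates, residual norms and AIC,
#'   and `selected`, the better-fitting model.
#' @export
fit_ibi_distribution <- function(ibis,
                                 model = c("both", "gaussian",
                                           "gaussian_plus_exponential"),
                                 bin_width = 1000) {
  model <- match.arg(model)
  if (length(ibis) < 20L) stop("need at least 20 intervals")
  x <- ibis / 1000  # work in seconds
  bw <- bin_width / 1000
  breaks <- seq(0, max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  df <- data.frame(mid = h$mids, dens = h$density)
  fits <- list()
  mu0 <- mean(x); sd0 <- max(stats::sd(x), bw / 2)
  if (model %in% c("both", "gaussian")) {
    fg <- tryCatch(
      minpack.lm::nlsLM(dens ~ stats::dnorm(mid, mu, sd), data = df,
                        start = list(mu = mu0, sd = sd0),
                        lower = c(mu = 0, sd = 1e-3)),
      error = function(e) NULL)
    if (!is.null(fg))
      fits$gaussian <- list(pars = stats::coef(fg),
                            residual_norm = sqrt(sum(stats::resid(fg)^2)),
                            aic = aic_sse(sum(stats::resid(fg)^2),
                                          nrow(df), 2L))
  }
  if (model %in% c("both", "gaussian_plus_exponential")) {
    fe <- tryCatch(
      minpack.lm::nlsLM(
        dens ~ w * stats::dnorm(mid, mu, sd) + (1 - w) * rate * exp(-rate * mid),
        data = df,
        start = list(w = 0.5, mu = mu0, sd = sd0, rate = 1 / mu0),
        lower = c(w = 0, mu = 0, sd = 1e-3, rate = 1e-4),
        upper = c(w = 1, mu = Inf, sd = Inf, rate = Inf)),
      error = function(e) NULL)
    if (!is.null(fe))
      fits$gaussian_plus_exponential <-
        list(pars = stats::coef(fe),
             residual_norm = sqrt(sum(stats::resid(fe)^2)),
             aic = aic_sse(sum(stats::resid(fe)^2), nrow(df), 4L))
  }
  if (!length(fits)) stop("distribution fit failed for all requested models")
  sel <- names(fits)[which.min(vapply(fits, `[[`, 0, "aic"))]
  c(fits, list(selected = sel))
}

aic_sse <- function(sse, n, k) n * log(max(sse, 1e-300) / n) + 2 * k
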