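# Bifurcation analysis of the fast (V, N) subsystem.
#
# Equilibria satisfy N = N_inf(V) and the scalar current balance
#   Phi(V) = -g_L (V - V_L) - g_C M_inf(V) (V - V_C)
#            - g_K N_inf(V) (V - V_K) + I_tot = 0,
# so the 2D root problem collapses exactly to a 1D sign scan plus bisection.
# The Jacobian determinant is -(Lambda/tau_N) Phi'(V)/C_m at an equilibrium,
# hence folds of Phi are saddle-node bifurcations of the planar system.

phi_balance <- function(V, I_tot, params) {
  a <- activation_functions(V, params)
  -params$g_L * (V - params$V_L) -
    params$g_C * a$M_inf * (V - params$V_C) -
    params$g_K * a$N_inf * (V - params$V_K) + I_tot
}

phi_balance_dV <- function(V, params) {
  a <- activation_functions(V, params)
  dM <- (1 / (2 * params$V_2)) / cosh((V - params$V_1) / params$V_2)^2
  dN <- (1 / (2 * params$V_4)) / cosh((V - params$V_3) / params$V_4)^2
  -params$g_L -
    params$g_C * (dM * (V - params$V_C) + a$M_inf) -
    params$g_K * (dN * (V - params$V_K) + a$N_inf)
}

#' Jacobian of the fast subsystem at a point
#'
#' Analytic 2x2 Jacobian of [rhs_fast()] with respect to `(V, N)`.
#'
#' @param V,N evaluation point.
#' @param params a [sac_params()] object.
#' @return A 2x2 numeric matrix (rows/cols ordered `V`, `N`).
#' @export
fast_jacobian <- function(V, N, params = sac_params()) {
  a <- activation_functions(V, params)
  dM <- (1 / (2 * params$V_2)) / cosh((V - params$V_1) / params$V_2)^2
  dN <- (1 / (2 * params$V_4)) / cosh((V - params$V_3) / params$V_4)^2
  dLam <- sinh((V - params$V_3) / (2 * params$V_4)) / (2 * params$V_4)
  FV <- (-params$g_L - params$g_C * (dM * (V - params$V_C) + a$M_inf) -
           params$g_K * N) / params$C_m
  FN <- -params$g_K * (V - params$V_K) / params$C_m
  GV <- (dLam * (a$N_inf - N) + a$Lambda * dN) / params$tau_N
  GN <- -a$Lambda / params$tau_N
  matrix(c(FV, FN, GV, GN), 2, 2, byrow = TRUE,
         dimnames = list(c("V", "N"), c("V", "N")))
}

#' Classify an equilibrium of the fast subsystem
#'
#' Computes the eigenvalues of the analytic Jacobian at `(V_star, N_star)`
#' and assigns a stability class: `sink` (real negative), `saddle` (real,
#' opposite signs), `source` (real positive), `stable_focus` /
#' `unstable_focus` (complex pair, sign of real part).
#'
#' @param V_star,N_star equilibrium coordinates.
#' @param I_tot frozen total current (pA); unused by the Jacobian itself but
#'   recorded for context.
#' @param params a [sac_params()] object.
#' @return List with `eigenvalues` (complex pair, ms^-1) and
#'   `stability_class`.
#' @export
classify_fixed_point <- function(V_star, N_star, I_tot, params = sac_params()) {
  J <- fast_jacobian(V_star, N_star, params)
  ev <- eigen(J, only.values = TRUE)$values
  if (is.complex(ev) && any(abs(Im(ev)) > 1e-12)) {
    cls <- if (Re(ev[1]) < 0) "stable_focus" else "unstable_focus"
  } else {
    ev <- complex(real = Re(ev), imaginary = 0)
    re <- Re(ev)
    cls <- if (all(re < 0)) "sink" else if (all(re > 0)) "source" else "saddle"
  }
  list(eigenvalues = ev, stability_class = cls)
}

#' Find all equilibria of the fast subsystem
#'
#' Solves `N* = N_inf(V*)` together with the scalar current balance by a
#' dense sign scan of `Phi(V)` over `V` in \[-90, 60\] mV (widened downward
#' when a strongly negative `I_tot` pushes the leak-balanced rest state
#' below the potassium reversal), followed by bisection to
#' `|dV| < 1e-8` mV. Every root is classified via [classify_fixed_point()].
#'
#' @param I_tot frozen total current (pA).
#' @param params a [sac_params()] object.
#' @param n_scan number of scan nodes (default 1501).
#' @param V_range scan window (mV).
#' @return A data frame with one row per equilibrium: `V_star`, `N_star`,
#'   `stability_class`, `re1`, `im1`, `re2`, `im2` (eigenvalue parts),
#'   `stable` (logical).
#' @export
find_fixed_points <- function(I_tot, params = sac_params(), n_scan = 1501,
                              V_range = c(-90, 60)) {
  stopifnot(inherits(params, "sac_params"))
  # at strongly hyperpolarizing currents the rest state sits below V_K,
  # where only the leak balances I_tot; widen the window to include it
  if (params$g_L > 0)
    V_range[1] <- min(V_range[1], params$V_L + I_tot / params$g_L - 1)
  Vs <- seq(V_range[1], V_range[2], length.out = n_scan)
  f <- phi_balance(Vs, I_tot, params)
  roots <- numeric(0)
  for (i in seq_len(n_scan - 1)) {
    if (f[i] == 0) { roots <- c(roots, Vs[i]); next }
    if (f[i] * f[i + 1] < 0) {
      r <- stats::uniroot(function(v) phi_balance(v, I_tot, params),
                          c(Vs[i], Vs[i + 1]), tol = 1e-9)$root
      roots <- c(roots, r)
    }
  }
  if (f[n_scan] == 0) roots <- c(roots, Vs[n_scan])
  if (!length(roots))
    stop("no equilibrium found in the scan window; Phi should change sign ",
         "over [", V_range[1], ", ", V_range[2], "] mV for physical parameters")
  roots <- sort(roots)
  out <- do.call(rbind, lapply(roots, function(V) {
    N <- activation_functions(V, params)$N_inf
    cl <- classify_fixed_point(V, N, I_tot, params)
    data.frame(V_star = V, N_star = N,
               stability_class = cl$stability_class,
               re1 = Re(cl$eigenvalues[1]), im1 = Im(cl$eigenvalues[1]),
               re2 = Re(cl$eigenvalues[2]), im2 = Im(cl$eigenvalues[2]),
               stable = cl$stability_class %in% c("sink", "stable_focus"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Locate a saddle-node (fold) bifurcation in I_tot
#'
#' Bisects the bracket on the equilibrium count of the fast subsystem, then
#' refines with Newton iteration on the fold conditions `Phi(V) = 0`,
#' `Phi'(V) = 0` (`Phi'` is independent of `I_tot`, so the fold voltage is
#' found first and the fold current follows in closed form). Tolerance
#' 0.01 pA.
#'
#' @param params a [sac_params()] object.
#' @param bracket `c(lo, hi)` current interval (pA) across which the root
#'   count changes.
#' @return List with `I_sn` (pA), `V_sn` (mV), and residuals of the fold
#'   conditions.
#' @export
locate_saddle_node <- function(params = sac_params(), bracket = c(-10, 0)) {
  count <- function(I) nrow(find_fixed_points(I, params))
  lo <- bracket[1]; hi <- bracket[2]
  c_lo <- count(lo); c_hi <- count(hi)
  if (c_lo == c_hi)
    stop("root count does not change over the bracket [", lo, ", ", hi, "] pA")
  while (hi - lo > 0.01) {
    mid <- (lo + hi) / 2
    if (count(mid) == c_lo) lo <- mid else hi <- mid
  }
  # Merging pair: locate the two closest roots on the side with more roots
  many <- if (c_lo > c_hi) find_fixed_points(lo, params) else
    find_fixed_points(hi, params)
  V0 <- if (nrow(many) >= 2) {
    gaps <- diff(many$V_star)
    mean(many$V_star[which.min(gaps) + 0:1])
  } else mean(many$V_star)
  # Newton on Phi'(V) = 0 (independent of I_tot)
  V <- V0
  for (i in 1:100) {
    g <- phi_balance_dV(V, params)
    h <- 1e-5
    gp <- (phi_balance_dV(V + h, params) - phi_balance_dV(V - h, params)) / (2 * h)
    step <- g / gp
    V <- V - step
    if (abs(step) < 1e-12) break
  }
  I_sn <- -phi_balance(V, 0, params)  # Phi(V; I) = Phi(V; 0) + I
  list(I_sn = I_sn, V_sn = V,
       residual_phi = abs(phi_balance(V, I_sn, params)),
       residual_dphi = abs(phi_balance_dV(V, params)))
}

#' Locate a Hopf bifurcation in I_tot
#'
#' Bisects on the sign of the Jacobian trace along the focus equilibrium
#' branch, requiring positive determinant (non-degeneracy). Tolerance
#' 0.1 pA.
#'
#' @param params a [sac_params()] object.
#' @param bracket `c(lo, hi)` current interval (pA) spanned by a focus
#'   branch whose trace changes sign.
#' @return List with `I_hopf` (pA), `V_star` (mV), `trace`, `determinant`
#'   at the returned point.
#' @export
locate_hopf <- function(params = sac_params(), bracket = c(200, 310)) {
  focus_trace <- function(I) {
    fp <- find_fixed_points(I, params)
    foc <- fp[fp$stability_class %in% c("stable_focus", "unstable_focus"), ]
    if (!nrow(foc)) {
      # fall back to the equilibrium with largest imaginary part
      foc <- fp[which.max(abs(fp$im1)), ]
    }
    J <- fast_jacobian(foc$V_star[1], foc$N_star[1], params)
    list(tr = sum(diag(J)), det = det(J), V = foc$V_star[1])
  }
  lo <- bracket[1]; hi <- bracket[2]
  s_lo <- sign(focus_trace(lo)$tr); s_hi <- sign(focus_trace(hi)$tr)
  if (s_lo == s_hi)
    stop("Jacobian trace does not change sign over the bracket")
  while (hi - lo > 0.1) {
    mid <- (lo + hi) / 2
    if (sign(focus_trace(mid)$tr) == s_lo) lo <- mid else hi <- mid
  }
  I_h <- (lo + hi) / 2
  ft <- focus_trace(I_h)
  if (ft$det <= 0)
    warning("determinant not positive at the located point; not a Hopf")
  list(I_hopf = I_h, V_star = ft$V, trace = ft$tr, determinant = ft$det)
}

#' Probe for a stable limit cycle of the fast subsystem
#'
#' Runs the deterministic fast subsystem from the unstable focus (or source)
#' perturbed by +1 mV, over a 5 s horizon with the first 2 s discarded. A
#' cycle is deemed present when the voltage peak-to-peak amplitude exceeds
#' 5 mV and is sustained in the final third of the analysis window; the
#' period is the mean inter-peak interval.
#'
#' @param I_tot frozen total current (pA).
#' @param params a [sac_params()] object.
#' @param T,transient horizon and discarded transient (ms).
#' @param dt integration step (ms).
#' @return List with `exists` (logical), `V_min`, `V_max` (mV), `period`
#'   (ms, `NA` when no cycle), `n_peaks`.
#' @export
limit_cycle_probe <- function(I_tot, params = sac_params(), T = 5000,
                              transient = 2000, dt = 0.05) {
  fp <- find_fixed_points(I_tot, params)
  src <- fp[fp$stability_class %in% c("unstable_focus", "source"), ]
  if (!nrow(src))
    return(list(exists = FALSE, V_min = NA_real_, V_max = NA_real_,
                period = NA_real_, n_peaks = 0L))
  # a stable planar cycle must enclose a repelling equilibrium; probe from it
  v0 <- src$V_star[which.max(src$V_star)] + 1
  n0 <- activation_functions(v0, params)$N_inf
  tr <- simulate_fast(I_tot, params, T = T, dt = dt, init = c(v0, n0))
  keep <- tr$t >= transient
  V <- tr$V[keep]; tt <- tr$t[keep]
  last_third <- tt >= (transient + 2 * (T - transient) / 3)
  amp_sustained <- diff(range(V[last_third]))
  if (!is.finite(amp_sustained) || amp_sustained <= 5)
    return(list(exists = FALSE, V_min = min(V), V_max = max(V),
                period = NA_real_, n_peaks = 0L))
  mid <- (max(V) + min(V)) / 2
  pk <- which(V[-c(1, length(V))] > V[-c(length(V) - 1, length(V))] &
                V[-c(1, length(V))] >= V[-(1:2)]) + 1L
  pk <- pk[V[pk] > mid]
  # collapse plateaus of equal samples
  if (length(pk) > 1) pk <- pk[c(TRUE, diff(pk) > 2)]
  period <- if (length(pk) >= 3) mean(diff(tt[pk])) else NA_real_
  list(exists = TRUE, V_min = min(V), V_max = max(V),
       period = period, n_peaks = length(pk))
}

#' Locate the homoclinic bifurcation in I_tot
#'
#' Bisects on the existence of the stable limit cycle ([limit_cycle_probe()])
#' to a 0.05 pA tolerance. Continuation software notoriously struggles with
#' this connection; direct phase-portrait inspection is robust here. Near
#' the located point the cycle period grows steeply, the signature that the
#' cycle is lost by touching the saddle rather than by a Hopf; the periods
#' measured just above the boundary are returned as supporting evidence.
#'
#' @param params a [sac_params()] object.
#' @param bracket `c(lo, hi)` current interval (pA); cycle absent at `lo`,
#'   present at `hi`.
#' @param tol bisection tolerance (pA).
#' @return List with `I_hc` (pA) and `period_near`, `period_far`: cycle
#'   periods at `I_hc + 0.1` and `I_hc + 2` pA.
#' @export
locate_homoclinic <- function(params = sac_params(), bracket = c(-10, -3.8),
                              tol = 0.05) {
  # Long horizon and fine step: close to the connection the approach to (or
  # escape from) the cycle is slow, and the Euler amplitude bias at coarser
  # dt shifts the detected boundary by a few tenths of a pA.
  ex <- function(I) limit_cycle_probe(I, params, T = 30000,
                                      transient = 20000, dt = 0.01)$exists
  lo <- bracket[1]; hi <- bracket[2]
  if (ex(lo) == ex(hi))
    stop("limit-cycle existence does not differ across the bracket")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ex(mid)) hi <- mid else lo <- mid
  }
  I_hc <- (lo + hi) / 2
  p_near <- limit_cycle_probe(I_hc + 0.1, params, T = 30000,
                              transient = 10000, dt = 0.01)$period
  p_far <- limit_cycle_probe(I_hc + 2, params, T = 10000,
                             transient = 5000, dt = 0.01)$period
  list(I_hc = I_hc, period_near = p_near, period_far = p_far)
}

#' One-parameter bifurcation diagram in I_tot
#'
#' Scans a current range, records all equilibrium branches and limit-cycle
#' extremes per grid node, and detects events: saddle-node where the root
#' count changes (refined by [locate_saddle_node()]), Hopf where a focus
#' branch's eigenvalue real part crosses zero ([locate_hopf()]), and
#' homoclinic where the stable cycle appears or disappears
#' ([locate_homoclinic()]).
#'
#' @param params a [sac_params()] object.
#' @param I_range `c(from, to)` scanned interval (pA).
#' @param step grid step (pA), > 0.
#' @param probe_cycles also probe the limit cycle per node (slower).
#' @return List of class `sac_bifdiag` with `branches` (data frame: `I_tot`,
#'   `V_star`, `N_star`, `stability_class`), `cycles` (data frame per node:
#'   `I_tot`, `exists`, `V_min`, `V_max`, `period`), and `events` (data
#'   frame: `type`, `I_tot`).
#' @export
continue_in_current <- function(params = sac_params(), I_range = c(-70, 310),
                                step = 1, probe_cycles = TRUE) {
  if (step <= 0) stop("step must be > 0")
  grid <- seq(I_range[1], I_range[2], by = step)
  br <- do.call(rbind, lapply(grid, function(I) {
    fp <- find_fixed_points(I, params)
    cbind(I_tot = I, fp[, c("V_star", "N_star", "stability_class")])
  }))
  counts <- vapply(grid, function(I) nrow(find_fixed_points(I, params)), 0L)
  events <- data.frame(type = character(0), I_tot = numeric(0))
  for (i in seq_len(length(grid) - 1)) {
    if (counts[i] != counts[i + 1]) {
      sn <- tryCatch(locate_saddle_node(params, c(grid[i], grid[i + 1])),
                     error = function(e) NULL)
      if (!is.null(sn))
        events <- rbind(events, data.frame(type = "saddle_node", I_tot = sn$I_sn))
    }
  }
  # Hopf: sign change of focus real part along branch
  focus_re <- vapply(grid, function(I) {
    fp <- find_fixed_points(I, params)
    foc <- fp[fp$stability_class %in% c("stable_focus", "unstable_focus"), ]
    if (!nrow(foc)) NA_real_ else foc$re1[which.max(foc$V_star)]
  }, 0)
  for (i in seq_len(length(grid) - 1)) {
    if (!is.na(focus_re[i]) && !is.na(focus_re[i + 1]) &&
        sign(focus_re[i]) != sign(focus_re[i + 1]) &&
        sign(focus_re[i]) != 0) {
      hp <- tryCatch(locate_hopf(params, c(grid[i], grid[i + 1])),
                     error = function(e) NULL)
      if (!is.null(hp))
        events <- rbind(events, data.frame(type = "hopf", I_tot = hp$I_hopf))
    }
  }
  cycles <- NULL
  if (probe_cycles) {
    cyc <- lapply(grid, function(I) {
      lc <- limit_cycle_probe(I, params)
      data.frame(I_tot = I, exists = lc$exists, V_min = lc$V_min,
                 V_max = lc$V_max, period = if (is.null(lc$period)) NA else lc$period)
    })
    cycles <- do.call(rbind, cyc)
    for (i in seq_len(length(grid) - 1)) {
      if (cycles$exists[i] != cycles$exists[i + 1]) {
        hc <- tryCatch(
          locate_homoclinic(params, sort(c(grid[i], grid[i + 1]))),
          error = function(e) NULL)
        if (!is.null(hc))
          events <- rbind(events,
                          data.frame(type = "homoclinic", I_tot = hc$I_hc))
      }
    }
  }
  events <- events[order(events$I_tot), ]
  rownames(events) <- NULL
  structure(list(branches = br, cycles = cycles, events = events,
                 I_range = I_range, step = step),
            class = "sac_bifdiag")
}

#' @export
print.sac_bifdiag <- function(x, ...) {
  cat(sprintf("Bifurcation diagram over I_tot in [%g, %g] pA (step %g)\n",
              x$I_range[1], x$I_range[2], x$step))
  if (nrow(x$events)) {
    cat("Events:\n")
    for (i in seq_len(nrow(x$events)))
      cat(sprintf("  %-12s at I_tot = %.3f pA\n",
                  x$events$type[i], x$events$I_tot[i]))
  } else cat("No events detected in range.\n")
  invisible(x)
}

# Phase-portrait signature of one parameter cell: equilibrium counts split
# into low/high voltage stable states plus cycle existence.
cell_signature <- function(params, I_tot = 0, V_split = -40) {
  fp <- find_fixed_points(I_tot, params)
  lc <- limit_cycle_probe(I_tot, params)
  list(n_stable_low = sum(fp$stable & fp$V_star <= V_split),
       n_stable_high = sum(fp$stable & fp$V_star > V_split),
       n_unstable = sum(!fp$stable),
       n_fp = nrow(fp),
       cycle = lc$exists)
}

signature_label <- function(sig) {
  key <- c(sig$n_stable_low > 0, sig$n_stable_high > 0, sig$cycle)
  if (key[1] && !key[2] && !key[3]) {
    if (sig$n_stable_low >= 2) "B_bistable_low" else "A"
  } else if (key[1] && !key[2] && key[3]) "B"
  else if (key[1] && key[2] && !key[3]) "C"
  else if (!key[1] && !key[2] && key[3]) "D"
  else if (!key[1] && key[2] && !key[3]) "E"
  else if (key[1] && key[2] && key[3]) "CD_mixed"
  else "other"
}

#' Two-parameter region map of the fast subsystem
#'
#' Classifies each cell of a parameter grid by its phase-portrait signature
#' (counts of stable low-/high-voltage equilibria, unstable equilibria, and
#' stable-cycle existence) and assigns the qualitative region label used in
#' the model's two-parameter diagrams: `A` single stable low-voltage rest
#' state; `B` stable low-voltage state coexisting with fast oscillations;
#' `C` bistable low/high rest states; `D` oscillations only; `E` stable
#' high-voltage state; plus `B_bistable_low` (two low rest states),
#' `CD_mixed`, and `other` for signatures outside the legend. Bursting is
#' possible in the cycle-bearing regions (`B`, `D`).
#'
#' @param axis_x name of the x parameter: `"I_tot"`, `"g_C"`, or `"V_3"`.
#' @param x_grid,gK_grid numeric grids for the x parameter and for `g_K`
#'   (nS on the y axis).
#' @param params base [sac_params()] object.
#' @param I_tot frozen current used when `axis_x` is not `"I_tot"` (pA).
#' @return A data frame of class `sac_regionmap` with one row per cell:
#'   the two coordinates, signature counts, `cycle`, `label`.
#' @export
region_map_2d <- function(axis_x = c("I_tot", "g_C", "V_3"),
                          x_grid, gK_grid, params = sac_params(),
                          I_tot = 0) {
  axis_x <- match.arg(axis_x)
  if (!length(x_grid) || !length(gK_grid)) stop("grids must be non-empty")
  rows <- list()
  for (gk in gK_grid) {
    for (xv in x_grid) {
      p <- params
      p$g_K <- gk
      it <- I_tot
      if (axis_x == "I_tot") it <- xv else p[[axis_x]] <- xv
      p <- validate_sac_params(p)
      sig <- cell_signature(p, I_tot = it)
      rows[[length(rows) + 1L]] <- data.frame(
        x = xv, g_K = gk,
        n_stable_low = sig$n_stable_low, n_stable_high = sig$n_stable_high,
        n_unstable = sig$n_unstable, n_fp = sig$n_fp, cycle = sig$cycle,
        label = signature_label(sig), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- axis_x
  structure(out, class = c("sac_regionmap", "data.frame"),
            axis_x = axis_x)
}
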