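test_that("fixed-point census matches the phase-portrait structure", {
  p <- default_params()
  fp <- find_fixed_points(-10, p)
  expect_equal(nrow(fp), 3L)
  expect_equal(fp$stability_class,
               c("sink", "saddle", "unstable_focus"))
  expect_true(fp$V_star[1] >= -70.5 && fp$V_star[1] <= -60)

  fp0 <- find_fixed_points(0, p)
  expect_equal(nrow(fp0), 1L)
  expect_false(fp0$stable)

  # every returned equilibrium zeroes the fast drift
  for (I in c(-10, 0, 100, 300)) {
    fp <- find_fixed_points(I, p)
    for (i in seq_len(nrow(fp))) {
      d <- rhs_fast(fp$V_star[i], fp$N_star[i], I, p)
      expect_lt(max(abs(d)), 1e-10)
    }
  }
})

test_that("leak-only balance gives the closed-form equilibrium", {
  p <- sac_params(g_C = 0, g_K = 0)
  for (I in c(-10, 0, 15)) {
    fp <- find_fixed_points(I, p)
    expect_equal(nrow(fp), 1L)
    expect_equal(fp$V_star, p$V_L + I / p$g_L, tolerance = 1e-7)
    expect_equal(fp$stability_class, "sink")
    # diagonal Jacobian eigenvalues
    Lam <- cosh((fp$V_star - p$V_3) / (2 * p$V_4))
    ev <- sort(c(fp$re1, fp$re2))
    expect_equal(ev, sort(c(-p$g_L / p$C_m, -Lam / p$tau_N)),
                 tolerance = 1e-6)
  }
})

test_that("analytic Jacobian agrees with central finite differences", {
  p <- default_params()
  set.seed(11)
  h <- 1e-5
  for (i in 1:100) {
    V <- stats::runif(1, -90, 40); N <- stats::runif(1)
    J <- fast_jacobian(V, N, p)
    fd <- matrix(0, 2, 2)
    fd[, 1] <- (rhs_fast(V + h, N, 0, p) - rhs_fast(V - h, N, 0, p)) / (2 * h)
    fd[, 2] <- (rhs_fast(V, N + h, 0, p) - rhs_fast(V, N - h, 0, p)) / (2 * h)
    expect_lt(max(abs(J - fd)), 1e-6)
  }
})

test_that("root count matches a brute-force dense scan across parameter draws", {
  set.seed(99)
  brute_count <- function(I, p) {
    Vs <- seq(min(-90, p$V_L + I / p$g_L - 1), 60, length.out = 20001)
    f <- -p$g_L * (Vs - p$V_L) -
      p$g_C * 0.5 * (1 + tanh((Vs - p$V_1) / p$V_2)) * (Vs - p$V_C) -
      p$g_K * 0.5 * (1 + tanh((Vs - p$V_3) / p$V_4)) * (Vs - p$V_K) + I
    sum(f[-1] * f[-length(f)] < 0)
  }
  for (i in 1:100) {
    p <- sac_params(g_C = stats::runif(1, 3, 20),
                    g_K = stats::runif(1, 1, 20))
    I <- stats::runif(1, -70, 310)
    expect_equal(nrow(find_fixed_points(I, p)), brute_count(I, p))
  }
})

test_that("saddle-node of the fast subsystem sits at the reported current", {
  p <- default_params()
  sn <- locate_saddle_node(p, c(-10, 0))
  expect_equal(sn$I_sn, -3.7, tolerance = 0.2 / 3.7)
  expect_lt(sn$residual_phi, 1e-8)
  expect_lt(sn$residual_dphi, 1e-8)
  # count collapses from 3 to 1 across the fold
  expect_equal(nrow(find_fixed_points(sn$I_sn - 0.1, p)), 3L)
  expect_equal(nrow(find_fixed_points(sn$I_sn + 0.1, p)), 1L)
})

test_that("Hopf bifurcation is located with vanishing trace and positive determinant", {
  p <- default_params()
  hp <- locate_hopf(p, c(200, 310))
  expect_equal(hp$I_hopf, 250, tolerance = 5 / 250)
  expect_lt(abs(hp$trace), 1e-2)
  expect_gt(hp$determinant, 0)
  # beyond the Hopf only a stable high-voltage state remains
  fp <- find_fixed_points(300, p)
  expect_true(all(fp$stable))
  expect_false(limit_cycle_probe(300, p)$exists)
})

test_that("limit cycle exists in the firing range and not outside it", {
  p <- default_params()
  lc <- limit_cycle_probe(0, p)
  expect_true(lc$exists)
  expect_gt(lc$n_peaks, 10)
  expect_false(limit_cycle_probe(-20, p)$exists)
})

test_that("homoclinic point is below the fold with diverging period", {
  p <- default_params()
  hc <- locate_homoclinic(p)
  sn <- locate_saddle_node(p)
  expect_lt(hc$I_hc, sn$I_sn)
  expect_equal(hc$I_hc, -5.8, tolerance = 0.2 / 5.8)
  # period divergence near the connection
  expect_gt(hc$period_near, 2 * hc$period_far)
})

test_that("one-parameter continuation orders the three events correctly", {
  p <- default_params()
  bd <- continue_in_current(p, I_range = c(-10, 5), step = 1,
                            probe_cycles = TRUE)
  ev <- bd$events
  expect_true(all(c("homoclinic", "saddle_node") %in% ev$type))
  I_hc <- ev$I_tot[ev$type == "homoclinic"][1]
  I_sn <- ev$I_tot[ev$type == "saddle_node"][1]
  expect_lt(I_hc, I_sn)
  # along the stable branch, a perturbed fast run converges back
  br <- bd$branches
  stab <- br[br$stability_class == "sink", ]
  pick <- stab[seq(1, nrow(stab), length.out = min(10, nrow(stab))), ]
  for (i in seq_len(nrow(pick))) {
    tr <- simulate_fast(pick$I_tot[i], p, T = 3000, dt = 0.05,
                        init = c(pick$V_star[i] + 0.5, pick$N_star[i]))
    expect_lt(abs(tr$V[length(tr$V)] - pick$V_star[i]), 0.1)
  }
})

test_that("region map signatures reflect the phase portraits", {
  p <- default_params()
  # reference working point: oscillations only
  rm1 <- region_map_2d("I_tot", x_grid = 0, gK_grid = 10, params = p)
  expect_equal(rm1$label, "D")
  expect_true(rm1$cycle)
  expect_equal(rm1$n_stable_low + rm1$n_stable_high, 0L)
  # below the fold: stable low-voltage rest coexisting with the cycle
  rm2 <- region_map_2d("I_tot", x_grid = -5, gK_grid = 10, params = p)
  expect_equal(rm2$label, "B")
  # far below: rest only
  rm3 <- region_map_2d("I_tot", x_grid = -30, gK_grid = 10, params = p)
  expect_equal(rm3$label, "A")
  expect_false(rm3$cycle)
  # depolarized potassium half-activation, low g_K: cycle persists
  rm4 <- region_map_2d("V_3", x_grid = -34, gK_grid = 8, params = p)
  expect_true(rm4$cycle)
})
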