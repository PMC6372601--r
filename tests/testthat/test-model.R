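test_that("parameter constructor validates and matches the reference table", {
  p <- sac_params()
  expect_s3_class(p, "sac_params")
  expect_equal(p$C_m, 22)
  expect_equal(p$g_L, 2)
  expect_equal(p$g_sAHP, 2)
  expect_equal(p$V_L, -70)
  expect_equal(p$V_C, 50)
  expect_equal(p$V_K, -90)
  expect_equal(p$V_1, -20)
  expect_equal(p$V_2, 20)
  expect_equal(p$V_3, -25)
  expect_equal(p$V_4, 7)
  expect_equal(p$tau_N, 5)
  expect_equal(p$tau_R, 8300)
  expect_equal(p$tau_S, 8300)
  expect_equal(p$tau_C, 2000)
  expect_equal(p$delta_C, 10.503)
  expect_equal(p$alpha_S, 1 / 200^4)
  expect_equal(p$alpha_C, 4865)
  expect_equal(p$alpha_R, 4.25)
  expect_equal(p$H_X, 1800)
  expect_equal(p$C_0, 88)
  # working point of the bifurcation analysis
  expect_equal(p$g_K, 10)
  expect_equal(p$g_C, 12)

  expect_error(sac_params(g_K = -1), "g_K")
  expect_error(sac_params(tau_N = 0), "tau_N")
  expect_error(sac_params(nonsense = 1), "unknown parameter")
  expect_error(sac_params(V_K = 10), "V_K < V_L < V_C")
})

test_that("activation functions hit their anchor points and stay bounded", {
  p <- default_params()
  a1 <- activation_functions(p$V_1, p)
  expect_equal(a1$M_inf, 0.5)
  a3 <- activation_functions(p$V_3, p)
  expect_equal(a3$Lambda, 1)
  expect_equal(a3$N_inf, 0.5)
  a0 <- activation_functions(0, p)
  expect_equal(a0$M_inf, (1 + tanh(1)) / 2, tolerance = 1e-12)

  V <- seq(-100, 80, by = 0.5)
  a <- activation_functions(V, p)
  expect_true(all(a$M_inf > 0 & a$M_inf < 1))
  expect_true(all(a$N_inf > 0 & a$N_inf < 1))
  expect_true(all(a$Lambda >= 1))
  expect_true(all(diff(a$M_inf) > 0))
  expect_true(all(diff(a$N_inf) > 0))

  expect_error(activation_functions(NaN, p), "finite")
  expect_error(activation_functions(Inf, p), "finite")
})

test_that("ionic currents vanish at reversal potentials and closed gates", {
  p <- default_params()
  s <- sac_state(V = p$V_C, N = 0.3, C = 100, S = 0.2, R = 0.4)
  expect_equal(ionic_currents(s, p)[["I_C"]], 0)
  s <- sac_state(V = p$V_K, N = 0.3, C = 100, S = 0.2, R = 0.4)
  I <- ionic_currents(s, p)
  expect_equal(I[["I_K"]], 0)
  expect_equal(I[["I_sAHP"]], 0)
  s <- sac_state(V = -30, N = 0, C = 100, S = 0.2, R = 0)
  I <- ionic_currents(s, p)
  expect_equal(I[["I_K"]], 0)
  expect_equal(I[["I_sAHP"]], 0)

  # calcium window current at the leak reversal, g_C = 12
  s <- sac_state(V = -70, N = 0, C = 0, S = 0, R = 0)
  M <- (1 - tanh(2.5)) / 2
  expect_equal(ionic_currents(s, p)[["I_C"]], 12 * M * 120, tolerance = 1e-12)
  expect_equal(ionic_currents(s, p)[["I_C"]], 9.6377, tolerance = 1e-4)
})

test_that("sAHP current uses fourth-power gating", {
  p <- default_params()
  at_R <- function(R) {
    s <- sac_state(V = -60, N = 0, C = 0, S = 0, R = R)
    ionic_currents(s, p)[["I_sAHP"]]
  }
  expect_equal(at_R(1), -p$g_sAHP * (-60 - p$V_K))
  expect_equal(at_R(0.5) / at_R(1), 0.5^4)
  expect_equal(at_R(0.25) / at_R(0.5), 0.5^4)
})

test_that("full drift matches hand-computed values and stationarity", {
  p <- default_params()
  # calcium production at V = -70 with empty store
  s <- sac_state(V = -70, N = 0, C = 0, S = 0, R = 0)
  d <- rhs_full(s, I_ext = 0, p)
  I_C <- 12 * (1 - tanh(2.5)) / 2 * 120
  expect_equal(d[["C"]], (88 + 10.503 * I_C) / 2000, tolerance = 1e-12)
  expect_equal(d[["C"]], 0.0946, tolerance = 1e-3)

  # N at its nullcline for arbitrary V
  for (V in c(-80, -40, 0, 30)) {
    Ninf <- 0.5 * (1 + tanh((V + 25) / 7))
    s <- sac_state(V = V, N = Ninf, C = 50, S = 0.1, R = 0.1)
    expect_equal(rhs_full(s, 0, p)[["N"]], 0, tolerance = 1e-14)
  }

  # dimensional self-check: dV/dt at V = -60, clamped rest gates, I_ext = 10
  s <- clamp_steady_state(-60, p)
  d <- rhs_full(s, I_ext = 10, p)
  I_L <- -2 * (-60 + 70)
  I_C <- -12 * 0.5 * (1 + tanh((-60 + 20) / 20)) * (-60 - 50)
  I_K <- -10 * s[["N"]] * (-60 + 90)
  I_sAHP <- -2 * s[["R"]]^4 * (-60 + 90)
  expect_equal(d[["V"]], (I_L + I_C + I_K + I_sAHP + 10) / 22,
               tolerance = 1e-12)
})

test_that("clamped steady state zeroes the slow drift and matches closed forms", {
  p <- default_params()
  # alpha_S C^4 = 1 at C = 200 nM implies S* = 1/2
  expect_equal(p$alpha_S * 200^4, 1)
  # forced S = 1 gives the saturation value of R
  expect_equal(p$alpha_R * 1 / (1 + p$alpha_R * 1), 4.25 / 5.25)
  s <- clamp_steady_state(-70, p)
  expect_equal(s[["C"]], (88 + 10.503 * 12 * (1 - tanh(2.5)) / 2 * 120) *
                 1800 / 4865, tolerance = 1e-12)
  expect_equal(s[["C"]], 70.0, tolerance = 1e-3)

  set.seed(42)
  for (V0 in stats::runif(100, -90, 40)) {
    s <- clamp_steady_state(V0, p)
    d <- rhs_full(s, I_ext = 0, p)
    expect_lt(max(abs(d[c("N", "C", "S", "R")])), 1e-12)
  }

  expect_error(clamp_steady_state(55, p), "clamp")
})

test_that("fast subsystem drift equals the (V, N) block of the full drift", {
  p <- default_params()
  set.seed(7)
  for (i in 1:100) {
    s <- sac_state(V = stats::runif(1, -90, 40), N = stats::runif(1),
                   C = stats::runif(1, 0, 500), S = stats::runif(1),
                   R = stats::runif(1))
    I_ext <- stats::runif(1, -20, 20)
    I_tot <- ionic_currents(s, p)[["I_sAHP"]] + I_ext
    df <- rhs_fast(s[["V"]], s[["N"]], I_tot, p)
    dfull <- rhs_full(s, I_ext, p)
    expect_equal(df[["V"]], dfull[["V"]], tolerance = 1e-12)
    expect_equal(df[["N"]], dfull[["N"]], tolerance = 1e-12)
  }
})

test_that("timescale summary reproduces the membrane-time identities", {
  p <- default_params()
  ts <- timescale_summary(p)
  expect_equal(ts$tau_L, 11)
  expect_equal(ts$inv_tilde_tau_C, 5.5e-3)
  expect_equal(ts$inv_tilde_tau_S, 11 / 8300)
  # proportionality in g_L
  ts2 <- timescale_summary(sac_params(g_L = 4))
  expect_equal(ts2$tau_L, ts$tau_L / 2)
  expect_error(timescale_summary(sac_params(g_L = 0)), "g_L")
})

test_that("state constructor enforces physical ranges", {
  expect_error(sac_state(V = 0, N = 1.2, C = 1, S = 0, R = 0), "\\[0, 1\\]")
  expect_error(sac_state(V = 0, N = 0.2, C = -1, S = 0, R = 0), "C")
  expect_error(sac_state(V = NaN, N = 0.2, C = 1, S = 0, R = 0), "finite")
})
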