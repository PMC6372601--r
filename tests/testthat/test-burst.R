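test_that("burst detection applies the threshold/duration rule exactly", {
  cfg <- burst_config()
  # 2 s excursion at 200 nM bracketed by 100 nM
  tr <- make_calcium_trace(10000, 10, function(t)
    if (t >= 4000 && t < 6000) 200 else 100)
  ev <- detect_bursts(tr, cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration, 2000, tolerance = 0.02)
  # 0.5 s excursion is below the minimum duration
  tr <- make_calcium_trace(10000, 10, function(t)
    if (t >= 4000 && t < 4500) 200 else 100)
  expect_equal(nrow(detect_bursts(tr, cfg)), 0L)
  # two 1.5 s excursions separated by a sub-threshold dip: no merging
  tr <- make_calcium_trace(10000, 10, function(t)
    if ((t >= 2000 && t < 3500) || (t >= 4000 && t < 5500)) 200 else 100)
  ev <- detect_bursts(tr, cfg)
  expect_equal(nrow(ev), 2L)
  # boundary-touching runs are discarded
  tr <- make_calcium_trace(10000, 10, function(t) 200)
  expect_equal(nrow(detect_bursts(tr, cfg)), 0L)
  expect_error(detect_bursts(list(times = numeric(0), C = numeric(0)), cfg),
               "empty")
})

test_that("detected bursts are disjoint, sorted, and satisfy the predicate", {
  cfg <- burst_config()
  set.seed(15)
  n_checked <- 0L
  for (rep in 1:20) {
    # random step landscape crossing the threshold (500 ms plateaus, so
    # above-threshold runs of three or more samples qualify as bursts)
    n <- 200
    lv <- stats::rbinom(n, 1, 0.5) * 250
    tr <- list(times = seq(0, by = 500, length.out = n), C = lv)
    ev <- detect_bursts(tr, cfg)
    n_checked <- n_checked + nrow(ev)
    if (nrow(ev) > 1) {
      expect_true(all(diff(ev$t_onset) > 0))
      expect_true(all(ev$t_onset[-1] > ev$t_offset[-nrow(ev)]))
    }
    for (i in seq_len(nrow(ev))) {
      expect_gte(ev$duration[i], cfg$min_duration)
      inside <- tr$times >= ev$t_onset[i] & tr$times <= ev$t_offset[i]
      expect_true(all(tr$C[inside] > cfg$calcium_threshold))
    }
  }
  expect_gt(n_checked, 50)  # the generator did exercise the detector
})

test_that("burst count is invariant under trace oversampling", {
  cfg <- burst_config()
  lev <- function(t) if ((t >= 3000 && t < 6200) || (t >= 8000 && t < 9500))
    300 else 80
  coarse <- make_calcium_trace(20000, 1, lev)
  fine <- make_calcium_trace(20000, 0.1, lev)
  expect_equal(nrow(detect_bursts(coarse, cfg)),
               nrow(detect_bursts(fine, cfg)))
})

test_that("interburst intervals are onset-to-onset and order-invariant", {
  ev <- data.frame(t_onset = c(10e3, 70e3, 130e3),
                   t_offset = c(12e3, 73e3, 133e3))
  expect_equal(interburst_intervals(ev), c(60e3, 60e3))
  expect_equal(interburst_intervals(ev[c(3, 1, 2), ]), c(60e3, 60e3))
  expect_equal(interburst_intervals(ev[1, , drop = FALSE]), numeric(0))
  expect_equal(interburst_intervals(ev, mode = "gap"), c(58e3, 57e3))
})

test_that("square-root law is recovered exactly from noiseless data", {
  I <- seq(-4, 40, by = 1)
  for (form in c("eq", "half")) {
    fac <- if (form == "half") 2 else 1
    tau_s <- 0.657 / (fac * sqrt(I - (-5)))
    curve <- data.frame(I_ext = I, mean_ibi = tau_s * 1000)
    fit <- fit_sqrt_law(curve, form)
    expect_equal(fit$K, 0.657, tolerance = 1e-6)
    expect_equal(fit$I_c, -5, tolerance = 1e-6)
    expect_lt(fit$residual_norm, 1e-8)
  }
})

test_that("square-root-law estimator is accurate and unbiased under noise", {
  set.seed(21)
  I <- seq(-4, 40, length.out = 30)
  K_true <- 0.657; Ic_true <- -5
  tau_s <- K_true / sqrt(I - Ic_true)
  Ks <- numeric(100); Ics <- numeric(100)
  for (r in 1:100) {
    noisy <- tau_s * (1 + stats::rnorm(length(I), 0, 0.05))
    fit <- fit_sqrt_law(data.frame(I_ext = I, mean_ibi = noisy * 1000), "eq")
    Ks[r] <- fit$K; Ics[r] <- fit$I_c
  }
  expect_lt(abs(mean(Ks) - K_true) / K_true, 0.02)   # unbiased
  expect_lt(max(abs(Ks - K_true) / K_true), 0.10)    # accurate per replicate
  expect_lt(abs(mean(Ics) - Ic_true), 0.2)
})

test_that("fit window and positivity filtering are honoured", {
  I <- seq(-30, 60, by = 2)
  tau <- numeric(length(I))
  tau[I > -5] <- 0.5 / sqrt(I[I > -5] + 5)
  curve <- data.frame(I_ext = I, mean_ibi = tau * 1000)
  fit <- fit_sqrt_law(curve, "eq", window = c(-20, 40))
  expect_equal(fit$n_points, sum(tau > 0 & I >= -20 & I <= 40))
  expect_error(fit_sqrt_law(curve[curve$mean_ibi == 0, ], "eq"),
               "at least 4")
})

test_that("distribution model selection identifies the generating family", {
  set.seed(31)
  g <- stats::rnorm(500, mean = 15e3, sd = 2e3)
  fg <- fit_ibi_distribution(g)
  expect_equal(fg$selected, "gaussian")
  mix <- c(stats::rnorm(250, 15e3, 1.5e3), stats::rexp(250, 1 / 8e3))
  fm <- fit_ibi_distribution(mix)
  expect_equal(fm$selected, "gaussian_plus_exponential")
  expect_error(fit_ibi_distribution(g[1:10]), "at least 20")
})

test_that("ensemble pooling is seed-stable and consistent under growth", {
  p <- sac_params(sigma = 4, I_ext_baseline = 0)
  a <- ibi_ensemble(p, n_traj = 2, T = 1e5, base_seed = 3, dt = 0.1)
  b <- ibi_ensemble(p, n_traj = 2, T = 1e5, base_seed = 3, dt = 0.1)
  expect_identical(a$ibis, b$ibis)
  # zero-burst bookkeeping below the critical current without noise
  p0 <- sac_params(sigma = 0, I_ext_baseline = -10)
  s0 <- ibi_ensemble(p0, n_traj = 2, T = 1e5, base_seed = 1, dt = 0.1)
  expect_equal(s0$n_bursts, 0L)
  expect_equal(s0$n_zero_burst, 2L)
})
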