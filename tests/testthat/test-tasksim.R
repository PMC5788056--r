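test_that("minimum-jerk reach satisfies its boundary conditions", {
  spec <- reach_spec(start = c(0, 0), target = c(0, 10), tf = 0.3)
  tr <- min_jerk(spec)
  n <- length(tr)
  expect_equal(c(tr$x[1], tr$y[1]), c(0, 0))
  expect_equal(c(tr$x[n], tr$y[n]), c(0, 10))
  # midpoint symmetry
  expect_equal(tr$y[(n + 1) / 2], 5)
  # endpoint velocity/acceleration vanish and peak speed is 1.875 d / tf
  # (analytic maximum of the quintic derivative); finite differences on a
  # dense grid
  dense <- min_jerk(reach_spec(start = c(0, 0), target = c(0, 10),
                               tf = 0.3, rate = 20000))
  d <- delayrep:::fd_derivatives(dense$y, 1 / dense$rate)
  expect_lt(abs(d$v[1]), 1e-4)
  expect_lt(abs(d$v[length(dense)]), 1e-4)
  expect_lt(abs(d$a[1]), 0.5)
  expect_equal(max(abs(d$v)), 1.875 * 10 / 0.3, tolerance = 1e-6)
})

test_that("figure-eight path has a 1:2 frontal:sagittal frequency ratio", {
  spec <- track_spec("figure_eight", A = 8, T_cycle = 5)
  tr <- figure_eight(spec)
  expect_equal(c(tr$x[1], tr$y[1]), c(0, 0))
  expect_equal(range(tr$x), c(-8, 8), tolerance = 1e-6)
  expect_equal(range(tr$y), c(-8, 8), tolerance = 1e-6)
  i_quarter <- which.min(abs(tr$t - 5 / 4))
  expect_equal(tr$x[i_quarter], 8, tolerance = 1e-9)
  expect_equal(tr$y[i_quarter], 0, tolerance = 1e-9)
  # sagittal completes two cycles per trial: period T/2
  half <- round(5 / 2 * tr$rate)
  expect_equal(tr$y[1:(length(tr) - half)], tr$y[(half + 1):length(tr)],
               tolerance = 1e-9)
})

test_that("sinusoid mixture uses Hz components with the stated phases", {
  spec <- track_spec("sinusoid_mixture")
  tr <- sinusoid_mixture(spec)
  expect_equal(tr$y[1], 2 * sum(sin(spec$phi)), tolerance = 1e-12)
  expect_equal(tr$x, rep(0, length(tr)))
  # single component, phi = 0 -> pure sine through 0
  one <- track_spec("sinusoid_mixture", A = 2, fr = 0.5, phi = 0, dur = 10)
  s1 <- sinusoid_mixture(one)
  expect_equal(s1$y, 2 * sin(2 * pi * 0.5 * s1$t), tolerance = 1e-12)
  expect_error(sinusoid_mixture(track_spec("sinusoid_mixture",
                                           fr = c(0.1, 0.2),
                                           phi = c(0, 0, 0))),
               "same length")
})

test_that("blind reach endpoints follow each representation's prediction", {
  spec <- reach_spec(start = c(0, 0), target = c(0, 10))
  none <- simulate_blind_reach(spec, representation_params("none"),
                               noise_sd = 0)
  expect_equal(none$endpoint, c(0, 10), tolerance = 1e-9)
  # time representation: no overshoot, endpoint on target
  tm <- simulate_blind_reach(spec,
                             representation_params("time", tau_hat = 0.1),
                             noise_sd = 0)
  expect_equal(tm$endpoint, c(0, 10), tolerance = 1e-9)
  # gain 1.2: endpoint 12 cm out
  gn <- simulate_blind_reach(spec,
                             representation_params("gain", g_hat = 1.2),
                             noise_sd = 0)
  expect_equal(gn$endpoint, c(0, 12), tolerance = 1e-9)
  # spatial shift 1.5 cm along the reach
  sh <- simulate_blind_reach(
    spec, representation_params("spatial_shift", dx_hat = 1.5),
    noise_sd = 0)
  expect_equal(sh$endpoint, c(0, 11.5), tolerance = 1e-9)
  # mechanical overshoots
  mc <- simulate_blind_reach(
    spec, representation_params("mechanical", tau_hat = 0.1), noise_sd = 0)
  expect_gt(mc$endpoint[2], 10.5)
})

test_that("noiseless blind reaches are rotation-equivariant across targets", {
  params <- representation_params("gain", g_hat = 1.2)
  dists <- vapply(c(45, 90, 135), function(deg) {
    tg <- 10 * c(cos(deg * pi / 180), sin(deg * pi / 180))
    ep <- simulate_blind_reach(reach_spec(start = c(0, 0), target = tg),
                               params, noise_sd = 0)$endpoint
    sqrt(sum(ep^2))
  }, numeric(1))
  expect_equal(dists, rep(12, 3), tolerance = 1e-9)
})

test_that("blind tracking reproduces the constructed lags and amplitudes", {
  spec <- track_spec("sine", A = 8, T_cycle = 5)
  base <- simulate_blind_tracking(spec, representation_params("none"),
                                  baseline_lag = 0.2)
  expect_equal(target_hand_delay(base$hand, base$target), -0.2)

  tm <- simulate_blind_tracking(spec,
                                representation_params("time",
                                                      tau_hat = 0.5),
                                baseline_lag = 0.2)
  expect_equal(target_hand_delay(tm$hand$y, base$hand$y, rate = 200), 0.7)

  sh <- simulate_blind_tracking(
    spec, representation_params("spatial_shift", dx_hat = 4),
    baseline_lag = 0.2)
  expect_equal(sh$hand$y, base$hand$y + 4, tolerance = 1e-12)

  # gain amplitude ratio (half peak-to-peak) equals g_hat to 1e-6
  gn <- simulate_blind_tracking(spec,
                                representation_params("gain", g_hat = 1.5),
                                baseline_lag = 0)
  ratio <- (max(gn$hand$y) - min(gn$hand$y)) /
    (max(gn$target$y) - min(gn$target$y))
  expect_equal(ratio, 1.5, tolerance = 1e-6)

  # time variant changes lag but not amplitude
  ratio_t <- (max(tm$hand$y) - min(tm$hand$y)) /
    (max(base$hand$y) - min(base$hand$y))
  expect_equal(ratio_t, 1, tolerance = 1e-6)
})

test_that("predicted frequency responses separate gain from mechanical", {
  freqs <- sort(c(0.31, 0.67, 0.23, 0.42, 0.54))
  gn <- frequency_response_prediction(
    representation_params("gain", g_hat = 1.15), freqs, 2)
  expect_equal(gn$amp_cm, rep(2.3, 5))
  expect_equal(diff(range(gn$db_diff)), 0, tolerance = 1e-9)

  mech <- frequency_response_prediction(
    representation_params("mechanical", tau_hat = 0.2), freqs, 2)
  expect_equal(mech$amp_cm[1], 2, tolerance = 1e-2) # ~flat at low freq
  expect_true(all(diff(mech$db_diff) > 0))
  # dB-difference slope across the five mixture frequencies
  slope_m <- unname(coef(lm(mech$db_diff ~ freqs))[2])
  slope_g <- unname(coef(lm(gn$db_diff ~ freqs))[2])
  expect_gt(slope_m, 0.5)
  expect_lt(abs(slope_g), 1e-6)

  # time and shift leave amplitude unchanged
  tmr <- frequency_response_prediction(
    representation_params("time", tau_hat = 0.5), freqs, 2)
  expect_equal(tmr$amp_cm, rep(2, 5))

  # non-flat baseline: gain still flat in dB, mechanical still rising
  At <- 2 + 0.1 * (2 * pi * freqs)^2
  gn2 <- frequency_response_prediction(
    representation_params("gain", g_hat = 1.15), freqs, At)
  expect_equal(diff(range(gn2$db_diff)), 0, tolerance = 1e-9)
  mech2 <- frequency_response_prediction(
    representation_params("mechanical", tau_hat = 0.2), freqs, At)
  expect_true(all(diff(mech2$db_diff) > 0))
})
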