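test_that("reach amplitude recovers the movement extent", {
  spec <- reach_spec(start = c(0, 0), target = c(0, 10))
  tr <- min_jerk(spec)
  ra <- reach_amplitude(tr)
  expect_lt(abs(ra$amplitude - 10), 0.05)
  # time-reversed trajectory: same amplitude by symmetry
  rev <- trajectory(x = rev(tr$x), y = rev(tr$y), rate = tr$rate)
  expect_equal(reach_amplitude(rev)$amplitude, ra$amplitude,
               tolerance = 1e-9)
  # gain-scaled reach
  g <- gain_model(tr, 1.2, c(0, 0))
  expect_lt(abs(reach_amplitude(g)$amplitude - 12), 0.06)
  # no movement
  still <- trajectory(x = rep(1, 50), y = rep(2, 50), rate = 100)
  expect_error(reach_amplitude(still), "no movement")
})

test_that("tracking R2 is 1 for offset-matched tracking and ~0 for noise", {
  tg <- figure_eight(track_spec("figure_eight"))
  expect_equal(tracking_r2(tg, tg), 1)
  off <- spatial_shift_model(tg, 3, c(0, 1))
  expect_equal(tracking_r2(off, tg), 1)
  # uncorrelated hand with equal variance: the error variance is twice the
  # hand variance, so the score is ~ -1 on average (Monte-Carlo oracle:
  # 1 - [var(h) + var(t)] / var(h) with var(h) = var(t))
  set.seed(8)
  n <- length(tg)
  sdx <- sd(tg$x); sdy <- sd(tg$y)
  r2s <- replicate(200, {
    hand <- trajectory(x = rnorm(n, 0, sdx), y = rnorm(n, 0, sdy),
                       rate = tg$rate)
    tracking_r2(hand, tg)
  })
  expect_lt(abs(mean(r2s) + 1), 0.05)
  still <- trajectory(x = rep(0, n), y = rep(0, n), rate = tg$rate)
  expect_error(tracking_r2(still, tg), "zero variance")
})

test_that("conic ellipse fit recovers known center and angle to 1e-6", {
  cases <- list(
    list(theta = 0, center = c(0, 0)),          # b=0, a<c branch
    list(theta = pi / 2, center = c(2, -1)),    # b=0, a>c branch
    list(theta = pi / 6, center = c(1, 2)),     # b<0, a<c
    list(theta = pi / 3, center = c(-1, 4)),    # b<0, a>c
    list(theta = 2 * pi / 3, center = c(0, 1)), # b>0, a>c
    list(theta = 5 * pi / 6, center = c(3, 3))  # b>0, a<c
  )
  for (cs in cases) {
    P <- ellipse_points(cs$theta, a = 3, b = 1.2, center = cs$center)
    f <- fit_ellipse(P[, 1], P[, 2])
    expect_false(f$fallback)
    expect_equal(f$theta, cs$theta, tolerance = 1e-6)
    expect_equal(f$center, cs$center, tolerance = 1e-6)
    expect_equal(f$slope, tan(cs$theta), tolerance = 1e-5)
    expect_equal(f$intercept, cs$center[2] - tan(cs$theta) * cs$center[1],
                 tolerance = 1e-5)
  }
})

test_that("ellipse fit is translation-equivariant", {
  P <- ellipse_points(pi / 6, a = 3, b = 1, center = c(0, 0))
  f0 <- fit_ellipse(P[, 1], P[, 2])
  dshift <- c(2.5, -1.5)
  f1 <- fit_ellipse(P[, 1] + dshift[1], P[, 2] + dshift[2])
  expect_equal(f1$center, f0$center + dshift, tolerance = 1e-8)
  expect_equal(f1$theta, f0$theta, tolerance = 1e-8)
  expect_equal(f1$intercept,
               f0$intercept + dshift[2] - f0$slope * dshift[1],
               tolerance = 1e-7)
})

test_that("ellipse fit degeneracy handling follows the fallback rule", {
  expect_error(fit_ellipse(1:5, 2 * (1:5)), "at least 6")
  expect_error(fit_ellipse(1:10, 2 * (1:10)), "collinear")
  # near-collinear: principal-axis fallback recovers the line slope
  set.seed(13)
  u <- 8 * sin(seq(0, 2 * pi, length.out = 500))
  v <- 1.5 * u + rnorm(500, 0, 1e-4)
  f <- fit_ellipse(u, v)
  expect_true(f$fallback)
  expect_equal(f$slope, 1.5, tolerance = 1e-3)
})

test_that("shift-model tracking yields intercept ~ dx and slope ~ 1", {
  spec <- track_spec("sine", A = 8, T_cycle = 5)
  sh <- simulate_blind_tracking(
    spec, representation_params("spatial_shift", dx_hat = 4),
    baseline_lag = 0.2)
  f <- fit_ellipse(sh$target$y, sh$hand$y)
  expect_equal(f$intercept, 4, tolerance = 1e-6)
  expect_equal(f$slope, 1, tolerance = 1e-6)
})

test_that("gain-model slope recovery converges at 2% with isotropic noise", {
  spec <- track_spec("sine", A = 8, T_cycle = 5)
  gn <- simulate_blind_tracking(spec,
                                representation_params("gain", g_hat = 1.2),
                                baseline_lag = 0)
  set.seed(99)
  n <- length(gn$target) # 1001 samples
  u <- gn$target$y + rnorm(n, 0, 0.05)
  v <- gn$hand$y + rnorm(n, 0, 0.05)
  f <- fit_ellipse(u, v)
  expect_equal(f$slope, 1.2, tolerance = 0.02)
})

test_that("cross-correlation delay equals the brute-force search exactly", {
  rate <- 200
  set.seed(31)
  signals <- list(
    sine = sine_traj(A = 8, T_cycle = 5, rate = rate)$y,
    mixture = sinusoid_mixture(track_spec("sinusoid_mixture",
                                          dur = 20))$y,
    noise = as.numeric(stats::filter(rnorm(1000), rep(0.2, 5),
                                     sides = 2))[3:998]
  )
  for (g in signals) {
    for (k in c(-37, 0, 11, 100)) {
      n <- length(g)
      idx <- pmin(pmax(seq_len(n) + k, 1), n)
      h <- g[idx] # h leads g by k samples (held ends)
      got <- target_hand_delay(h, g, rate = rate, max_lag = 1.5)
      oracle <- brute_force_lag(h, g, rate, max_lag = 1.5)
      expect_identical(got, oracle)
    }
  }
  expect_equal(target_hand_delay(signals$sine, signals$sine, rate = rate), 0)
  expect_error(target_hand_delay(rep(1, 100), rnorm(100), rate = 100),
               "constant")
})

test_that("sign convention: positive delay means the hand leads", {
  tr <- sine_traj(A = 8, T_cycle = 5, rate = 200)
  lead <- time_model(tr, 0.5) # hand precedes the target
  expect_gt(target_hand_delay(lead$y, tr$y, rate = 200), 0.49)
  lag <- delayrep:::shift_samples(tr, -round(0.2 * 200))
  expect_lt(target_hand_delay(lag$y, tr$y, rate = 200), -0.19)
})

test_that("moving average shrinks symmetrically at edges", {
  x <- 1:10
  sm <- moving_average(x, 3)
  expect_equal(sm[1], 1) # window shrinks to the single point
  expect_equal(sm[2], 2)
  expect_equal(sm[10], 10)
  expect_equal(sm[5], 5)
  expect_equal(moving_average(rep(4, 200), 101), rep(4, 200))
})
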