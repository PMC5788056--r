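test_that("cohort generation is deterministic given spec and seed", {
  sp <- cohort_spec(n_participants = 2, group = "delay", task = "track_sine",
                    trials_nd = 3, trials_pd = 3, seed = 5)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_spec(n_participants = 2, group = "delay",
                                    task = "track_sine", trials_nd = 3,
                                    trials_pd = 3, seed = 6))
  expect_false(identical(c1, c3))
})

test_that("noiseless single-participant trials are identical within a session", {
  sp <- cohort_spec(n_participants = 1, group = "delay", task = "track_sine",
                    tracking_noise_sd = 0, param_jitter_sd = 0,
                    trials_nd = 3, trials_pd = 3, seed = 2)
  coh <- generate_cohort(sp)
  tr <- coh[[1]]$trials
  expect_identical(tr[[1]]$hand$y, tr[[2]]$hand$y)
  expect_identical(tr[[2]]$hand$y, tr[[3]]$hand$y)
})

test_that("control cohorts show near-zero session differences in reach amplitude", {
  sp <- cohort_spec(n_participants = 8, group = "control", task = "reach",
                    seed = 1)
  coh <- generate_cohort(sp)
  amp <- vapply(coh, function(s) mean(s$trials$amplitude), numeric(1))
  ses <- vapply(coh, function(s) s$session, character(1))
  delta <- mean(amp[ses == "post_delay"]) - mean(amp[ses == "post_no_delay"])
  expect_lt(abs(delta), 0.5)
})

test_that("gain cohorts show the predicted ~2 cm amplitude increase", {
  sp <- cohort_spec(n_participants = 8, group = "delay", task = "reach",
                    true_model = representation_params("gain", g_hat = 1.2),
                    seed = 1)
  coh <- generate_cohort(sp)
  amp <- vapply(coh, function(s) mean(s$trials$amplitude), numeric(1))
  ses <- vapply(coh, function(s) s$session, character(1))
  delta <- mean(amp[ses == "post_delay"]) - mean(amp[ses == "post_no_delay"])
  expect_equal(delta, 2, tolerance = 1)
})

test_that("parameter recovery identifies each generating model", {
  gen_and_recover <- function(tm, noise = 0) {
    sp <- cohort_spec(n_participants = 1, group = "delay",
                      task = "track_sine", true_model = tm,
                      tracking_noise_sd = noise, param_jitter_sd = 0,
                      trials_nd = 3, trials_pd = 3, seed = 4)
    coh <- generate_cohort(sp)
    recover_parameters(coh[[1]], coh[[2]])
  }
  rg <- gen_and_recover(representation_params("gain", g_hat = 1.2))
  expect_equal(rg$best$variant, "gain")
  expect_equal(rg$fits$value[rg$fits$variant == "gain"], 1.2,
               tolerance = 1e-3)
  expect_equal(which.min(rg$fits$residual[-1]),
               which(rg$fits$variant[-1] == "gain"))

  rt <- gen_and_recover(representation_params("time", tau_hat = 0.5))
  expect_equal(rt$best$variant, "time")
  expect_lt(abs(rt$fits$value[rt$fits$variant == "time"] - 0.5),
            0.005 + 1e-12) # one sample at 200 Hz

  rs <- gen_and_recover(representation_params("spatial_shift", dx_hat = 4))
  expect_equal(rs$best$variant, "spatial_shift")
  expect_equal(rs$fits$value[rs$fits$variant == "spatial_shift"], 4,
               tolerance = 1e-3)
})

test_that("control data recovers near-identity effect parameters", {
  sp <- cohort_spec(n_participants = 1, group = "control",
                    task = "track_sine", tracking_noise_sd = 0.1,
                    trials_nd = 5, trials_pd = 5, seed = 2)
  coh <- generate_cohort(sp)
  r <- recover_parameters(coh[[1]], coh[[2]])
  f <- r$fits
  expect_equal(f$value[f$variant == "gain"], 1, tolerance = 0.02)
  expect_lt(abs(f$value[f$variant == "spatial_shift"]), 0.05)
  # the time fit reports the lead over the target, which for control data
  # is the (negative) baseline lag itself
  expect_equal(f$value[f$variant == "time"], -0.2, tolerance = 0.005)
})

test_that("recovered-gain RMSE grows with tracking noise", {
  rmse_at <- function(noise_sd) {
    errs <- vapply(1:20, function(r) {
      sp <- cohort_spec(n_participants = 1, group = "delay",
                        task = "track_sine",
                        true_model = representation_params("gain",
                                                           g_hat = 1.2),
                        tracking_noise_sd = noise_sd, param_jitter_sd = 0,
                        trials_nd = 3, trials_pd = 3, seed = 100 + r)
      coh <- generate_cohort(sp)
      f <- recover_parameters(coh[[1]], coh[[2]],
                              variants = "gain")$fits
      f$value[f$variant == "gain"] - 1.2
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  rmse <- vapply(c(0, 0.1, 0.5, 1), rmse_at, numeric(1))
  expect_true(all(diff(rmse) >= 0))
})

test_that("reach recovery returns the generating gain", {
  sp <- cohort_spec(n_participants = 1, group = "delay", task = "reach",
                    true_model = representation_params("gain", g_hat = 1.2),
                    endpoint_noise_sd = 0, param_jitter_sd = 0,
                    trials_nd = 9, trials_pd = 9, seed = 1)
  coh <- generate_cohort(sp)
  f <- recover_parameters(coh[[1]], coh[[2]])$fits
  expect_equal(f$value[f$variant == "gain"], 1.2, tolerance = 1e-3)
  expect_lt(f$residual[f$variant == "gain"], 1e-8)
  expect_error(recover_parameters(coh[[1]], coh[[1]]), NA)
})

test_that("recovery refuses sessions with too few trials", {
  sp <- cohort_spec(n_participants = 1, group = "delay", task = "track_sine",
                    trials_nd = 2, trials_pd = 2, seed = 3)
  coh <- generate_cohort(sp)
  expect_error(recover_parameters(coh[[1]], coh[[2]]), "insufficient")
})
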