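#' Synthetic cohort specification
#'
#' Describes a participant-like dataset with the two-session structure the
#' analysis assumes: a Post No Delay session generated under the veridical
#' mapping and a Post Delay session generated under `true_model` (except
#' for the control group, whose two sessions are exchangeable). Trial
#' counts default to the experimental protocol: 45 reaches per session;
#' 15 (post-no-delay) / 45 (post-delay) figure-eight tracks; one 120 s
#' mixture track; 10/30 pong trials.
#'
#' @param n_participants Number of participants (>= 1).
#' @param group `"delay"`, `"control"`, `"abrupt"` or `"gradual"`.
#' @param task `"reach"`, `"track_eight"`, `"track_sine"`,
#'   `"track_mixture"` or `"pong"`.
#' @param true_model A [representation_params()]: the ground-truth
#'   representation generating the Post Delay session.
#' @param endpoint_noise_sd Reach endpoint noise SD per axis, cm
#'   (default 1).
#' @param tracking_noise_sd Tracking motor-noise SD, cm (default 0.1);
#'   added per sample and low-pass smoothed at 5 Hz so trajectories stay
#'   kinematically plausible.
#' @param baseline_lag Baseline target-to-hand lag, s (default 0.2).
#' @param trials_nd,trials_pd Trials in the two sessions (defaults by
#'   task).
#' @param param_jitter_sd Between-participant multiplicative SD on the
#'   active model parameter (default 0.1).
#' @param rate Sampling rate, Hz (default 200).
#' @param reach_distance Reach target distance, cm (default 10).
#' @param pong Optional [pong_config()] for `task = "pong"`.
#' @param seed Integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 8,
                        group = c("delay", "control", "abrupt", "gradual"),
                        task = c("reach", "track_eight", "track_sine",
                                 "track_mixture", "pong"),
                        true_model = representation_params("gain",
                                                           g_hat = 1.2),
                        endpoint_noise_sd = 1, tracking_noise_sd = 0.1,
                        baseline_lag = 0.2, trials_nd = NULL,
                        trials_pd = NULL, param_jitter_sd = 0.1,
                        rate = 200, reach_distance = 10, pong = NULL,
                        seed = 1L) {
  group <- match.arg(group)
  task <- match.arg(task)
  if (n_participants < 1) stop("n_participants must be >= 1")
  if (endpoint_noise_sd < 0 || tracking_noise_sd < 0)
    stop("noise SDs must be >= 0")
  defaults <- switch(task,
                     reach = c(45L, 45L),
                     track_eight = c(15L, 45L),
                     track_sine = c(15L, 45L),
                     track_mixture = c(1L, 1L),
                     pong = c(10L, 30L))
  if (is.null(trials_nd)) trials_nd <- defaults[1]
  if (is.null(trials_pd)) trials_pd <- defaults[2]
  structure(list(n_participants = as.integer(n_participants), group = group,
                 task = task, true_model = true_model,
                 endpoint_noise_sd = endpoint_noise_sd,
                 tracking_noise_sd = tracking_noise_sd,
                 baseline_lag = baseline_lag,
                 trials_nd = as.integer(trials_nd),
                 trials_pd = as.integer(trials_pd),
                 param_jitter_sd = param_jitter_sd, rate = rate,
                 reach_distance = reach_distance, pong = pong,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Jitter the active parameter of a representation multiplicatively.
jitter_params <- function(params, sd) {
  if (sd <= 0 || params$variant == "none") return(params)
  eps <- 1 + stats::rnorm(1L, 0, sd)
  eps <- max(eps, 0.05)
  switch(params$variant,
    time = representation_params("time", tau_hat = params$tau_hat * eps),
    spatial_shift = representation_params("spatial_shift",
                                          dx_hat = params$dx_hat * eps),
    gain = representation_params("gain", g_hat = params$g_hat * eps),
    mechanical = representation_params("mechanical",
                                       b_over_k = params$b_over_k * eps,
                                       m_over_k = params$m_over_k * eps^2))
}

# Per-sample Gaussian noise, low-pass smoothed at 5 Hz so synthetic hands
# remain kinematically plausible.
tracking_noise <- function(n, sd, rate, cutoff = 5) {
  if (sd <= 0) return(numeric(n))
  e <- stats::rnorm(n, 0, sd)
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  as.numeric(signal::filtfilt(bf, e))
}

reach_targets <- function(distance) {
  ang <- c(45, 90, 135) * pi / 180
  list(right = distance * c(cos(ang[1]), sin(ang[1])),
       middle = distance * c(cos(ang[2]), sin(ang[2])),
       left = distance * c(cos(ang[3]), sin(ang[3])))
}

#' Generate a synthetic cohort
#'
#' Produces, deterministically for a given seed, a list of per-session
#' datasets: the Post No Delay session under the veridical mapping and the
#' Post Delay session under the (per-participant jittered) ground-truth
#' model — except for the control group, whose sessions are exchangeable.
#'
#' @param spec A [cohort_spec()].
#' @return List of `session_data` objects (two per participant), each a
#'   list with `participant`, `session`, `task`, `trials`, `params` (the
#'   representation actually used) and `gen` (generation settings).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  sessions <- list()
  for (p in seq_len(spec$n_participants)) {
    pd_params <- if (spec$group == "control")
      representation_params("none")
    else jitter_params(spec$true_model, spec$param_jitter_sd)
    for (ses in c("post_no_delay", "post_delay")) {
      params <- if (ses == "post_no_delay")
        representation_params("none") else pd_params
      n_tr <- if (ses == "post_no_delay") spec$trials_nd else spec$trials_pd
      trials <- switch(spec$task,
        reach = gen_reach_trials(spec, params, n_tr),
        track_eight = gen_track_trials(spec, params, n_tr, "figure_eight"),
        track_sine = gen_track_trials(spec, params, n_tr, "sine"),
        track_mixture = gen_track_trials(spec, params, n_tr,
                                         "sinusoid_mixture"),
        pong = gen_pong_trials(spec, ses, n_tr))
      sessions[[length(sessions) + 1L]] <- structure(
        list(participant = p, session = ses, task = spec$task,
             trials = trials, params = params,
             gen = list(baseline_lag = spec$baseline_lag, rate = spec$rate,
                        reach_distance = spec$reach_distance,
                        endpoint_noise_sd = spec$endpoint_noise_sd,
                        tracking_noise_sd = spec$tracking_noise_sd,
                        group = spec$group, seed = spec$seed)),
        class = "session_data")
    }
  }
  sessions
}

gen_reach_trials <- function(spec, params, n_tr) {
  targets <- reach_targets(spec$reach_distance)
  raw <- lapply(targets, function(tg) {
    simulate_blind_reach(reach_spec(start = c(0, 0), target = tg,
                                    rate = spec$rate),
                         params, noise_sd = 0)$endpoint_raw
  })
  labels <- rep(names(targets), length.out = n_tr)
  do.call(rbind, lapply(seq_len(n_tr), function(i) {
    tg <- targets[[labels[i]]]
    ep <- raw[[labels[i]]] + stats::rnorm(2L, 0, spec$endpoint_noise_sd)
    data.frame(trial = i, target = labels[i],
               target_x = tg[1], target_y = tg[2],
               end_x = ep[1], end_y = ep[2],
               amplitude = sqrt(sum(ep^2)))
  }))
}

gen_track_trials <- function(spec, params, n_tr, path_kind) {
  ts <- track_spec(path_kind, rate = spec$rate)
  sim <- simulate_blind_tracking(ts, params,
                                 baseline_lag = spec$baseline_lag)
  lapply(seq_len(n_tr), function(i) {
    n <- length(sim$hand)
    hand <- traj_like(sim$hand,
                      sim$hand$x + tracking_noise(n, spec$tracking_noise_sd,
                                                  spec$rate),
                      sim$hand$y + tracking_noise(n, spec$tracking_noise_sd,
                                                  spec$rate))
    list(trial = i, target = sim$target, hand = hand)
  })
}

gen_pong_trials <- function(spec, ses, n_tr) {
  cfg <- if (is.null(spec$pong)) pong_config() else spec$pong
  sched <- if (ses == "post_no_delay") delay_schedule("none")
  else switch(spec$group,
              control = delay_schedule("none"),
              gradual = delay_schedule("gradual"),
              delay_schedule("abrupt"))
  cfg$delay_schedule <- sched
  recs <- simulate_pong_session(cfg, policy_chaser(lag = spec$baseline_lag),
                                n_trials = n_tr)
  lapply(seq_along(recs), function(i)
    list(trial = i, hit_times = recs[[i]]$hit_times,
         hit_count = recs[[i]]$hit_count, tau = recs[[i]]$tau,
         hand = recs[[i]]$hand))
}

#' Recover representation parameters from a session pair
#'
#' For each candidate variant, finds the single parameter minimizing the
#' mean squared discrepancy between the model's prediction and the Post
#' Delay data, using the Post No Delay session to estimate the imagined
#' cursor (tracking) or the baseline geometry (reaching). Bounded scalar
#' search (golden-section for the continuous variants; an exact grid over
#' integer-sample lags for the time variant). Residuals are reported per
#' variant so model selection stays with the caller.
#'
#' @param nd,pd `session_data` objects: the Post No Delay and Post Delay
#'   sessions of one participant.
#' @param variants Candidate variants to fit.
#' @param bounds Named list of search bounds: `tau` (s), `dx` (cm),
#'   `g` (dimensionless).
#' @return List with `fits` (data.frame: variant, parameter, value,
#'   residual) and `best` (a [representation_params()] for the
#'   lowest-residual variant).
#' @export
recover_parameters <- function(nd, pd,
                               variants = c("time", "spatial_shift", "gain",
                                            "mechanical"),
                               bounds = list(tau = c(0, 1.5),
                                             dx = c(-15, 15),
                                             g = c(0.2, 3))) {
  stopifnot(inherits(nd, "session_data"), inherits(pd, "session_data"),
            nd$task == pd$task, nd$participant == pd$participant)
  if (length(pd$trials) < 3L || length(nd$trials) < 3L)
    stop("insufficient data: at least 3 trials per session are required")
  if (nd$task %in% c("track_eight", "track_sine", "track_mixture"))
    recover_tracking(nd, pd, variants, bounds)
  else if (nd$task == "reach")
    recover_reach(nd, pd, variants, bounds)
  else stop("parameter recovery is defined for reach and tracking tasks")
}

recover_tracking <- function(nd, pd, variants, bounds) {
  # cursor estimate: the mean post-no-delay hand (the veridical hand equals
  # the imagined cursor up to noise)
  nd_x <- rowMeans(vapply(nd$trials, function(tr) tr$hand$x,
                          numeric(length(nd$trials[[1]]$hand))))
  nd_y <- rowMeans(vapply(nd$trials, function(tr) tr$hand$y,
                          numeric(length(nd$trials[[1]]$hand))))
  cursor <- traj_like(nd$trials[[1]]$hand, nd_x, nd_y)
  origin <- c(mean(cursor$x), mean(cursor$y))
  hx <- vapply(pd$trials, function(tr) tr$hand$x, numeric(length(cursor)))
  hy <- vapply(pd$trials, function(tr) tr$hand$y, numeric(length(cursor)))
  mhx <- rowMeans(hx); mhy <- rowMeans(hy)
  # baseline lag: how far the cursor estimate trails the target
  base_lag <- -target_hand_delay(cursor$y, nd$trials[[1]]$target$y,
                                 rate = cursor$rate)
  # residuals for every variant are evaluated on a common window that
  # excludes the region contaminated by the time-variant's terminal hold,
  # so per-variant residuals stay comparable
  kmax <- min(as.integer(round((bounds$tau[2] + max(base_lag, 0)) *
                                 cursor$rate)),
              length(cursor) - 2L)
  win <- seq_len(length(cursor) - kmax)
  # mean over trials of per-sample squared error decomposes into the error
  # to the mean hand plus the within-trial variance (constant in theta)
  vconst <- mean((hx[win, , drop = FALSE] - mhx[win])^2) +
    mean((hy[win, , drop = FALSE] - mhy[win])^2)
  obj <- function(variant, theta) {
    par <- switch(variant,
      none = representation_params("none"),
      time = representation_params("time", tau_hat = theta),
      spatial_shift = representation_params("spatial_shift",
                                            dx_hat = theta),
      gain = representation_params("gain", g_hat = theta),
      mechanical = representation_params("mechanical", tau_hat = theta))
    pred <- apply_representation(par, cursor, origin = origin,
                                 direction = c(0, 1))
    mean((pred$x[win] - mhx[win])^2 + (pred$y[win] - mhy[win])^2) + vconst
  }
  fit_one <- function(variant) {
    if (variant == "none")
      return(list(value = NA_real_, residual = obj("none", 0)))
    if (variant == "time") {
      # the time model advances the cursor; the represented delay is the
      # lead over the TARGET, so the baseline lag (estimated from the
      # post-no-delay session) is subtracted from the fitted advance
      taus <- (0:kmax) / cursor$rate
      res <- vapply(taus, function(th) obj("time", th), numeric(1))
      return(list(value = taus[which.min(res)] - base_lag,
                  residual = min(res)))
    }
    b <- switch(variant, spatial_shift = bounds$dx, gain = bounds$g,
                mechanical = bounds$tau)
    op <- stats::optimize(function(th) obj(variant, th), b, tol = 1e-6)
    list(value = op$minimum, residual = op$objective)
  }
  finish_recovery(c("none", setdiff(variants, "none")), fit_one)
}

recover_reach <- function(nd, pd, variants, bounds) {
  dist <- pd$gen$reach_distance
  rate <- pd$gen$rate
  targets <- reach_targets(dist)
  obs <- lapply(names(targets), function(lab) {
    sel <- pd$trials$target == lab
    c(mean(pd$trials$end_x[sel]), mean(pd$trials$end_y[sel]))
  })
  obj <- function(variant, theta) {
    par <- switch(variant,
      none = representation_params("none"),
      time = representation_params("time", tau_hat = theta),
      spatial_shift = representation_params("spatial_shift",
                                            dx_hat = theta),
      gain = representation_params("gain", g_hat = theta),
      mechanical = representation_params("mechanical", tau_hat = theta))
    pred <- lapply(targets, function(tg) {
      simulate_blind_reach(reach_spec(start = c(0, 0), target = tg,
                                      rate = rate),
                           par, noise_sd = 0)$endpoint_raw
    })
    mean(vapply(seq_along(pred),
                function(i) sum((pred[[i]] - obs[[i]])^2), numeric(1)))
  }
  fit_one <- function(variant) {
    if (variant == "none")
      return(list(value = NA_real_, residual = obj("none", 0)))
    if (variant == "time") {
      # the time model predicts on-target endpoints for any tau: the
      # objective is flat, so report tau = 0 with the common residual
      return(list(value = 0, residual = obj("time", 0)))
    }
    b <- switch(variant, spatial_shift = bounds$dx, gain = bounds$g,
                mechanical = bounds$tau)
    op <- stats::optimize(function(th) obj(variant, th), b, tol = 1e-6)
    list(value = op$minimum, residual = op$objective)
  }
  finish_recovery(c("none", setdiff(variants, "none")), fit_one)
}

finish_recovery <- function(variants, fit_one) {
  rows <- lapply(variants, function(vr) {
    f <- fit_one(vr)
    data.frame(variant = vr,
               parameter = switch(vr, none = "", time = "tau_hat",
                                  spatial_shift = "dx_hat", gain = "g_hat",
                                  mechanical = "tau_hat"),
               value = f$value, residual = f$residual,
               stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  cand <- fits[fits$variant != "none", , drop = FALSE]
  bi <- cand[which.min(cand$residual), ]
  best <- switch(bi$variant,
    time = representation_params("time", tau_hat = max(bi$value, 0)),
    spatial_shift = representation_params("spatial_shift",
                                          dx_hat = bi$value),
    gain = representation_params("gain", g_hat = bi$value),
    mechanical = representation_params("mechanical", tau_hat = bi$value))
  list(fits = fits, best = best)
}

#' Slope of the dB-difference profile between two sessions
#'
#' The model-discrimination statistic: the least-squares slope of
#' `amp_db(post) - amp_db(pre)` against frequency. Flat (about 0 dB/Hz)
#' under a gain representation, increasing under a mechanical one.
#'
#' @param pre,post [frequency_response()] objects on the same frequencies.
#' @return List with `slope` (dB/Hz) and `db_diff` (per-frequency dB
#'   difference).
#' @export
db_difference_slope <- function(pre, post) {
  stopifnot(inherits(pre, "frequency_response"),
            inherits(post, "frequency_response"),
            isTRUE(all.equal(pre$freqs, post$freqs)))
  dd <- post$amp_db - pre$amp_db
  fit <- stats::lm.fit(cbind(1, pre$freqs), dd)
  list(slope = unname(fit$coefficients[2]), db_diff = dd)
}
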