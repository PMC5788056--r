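#' Delay schedule for the pong game
#'
#' How the hand-to-paddle delay evolves over trials: `none` (always 0),
#' `abrupt` (`tau_max` from the first trial), or `gradual` (`increment` per
#' trial up to `tau_max`; the defaults reach 0.1 s at trial 25 with
#' 0.004 s/trial steps).
#'
#' @param kind `"none"`, `"abrupt"` or `"gradual"`.
#' @param tau_max Plateau delay, s (default 0.1).
#' @param increment Per-trial increment, s (gradual; default 0.004).
#' @return Object of class `delay_schedule`.
#' @export
delay_schedule <- function(kind = c("none", "abrupt", "gradual"),
                           tau_max = 0.1, increment = 0.004) {
  kind <- match.arg(kind)
  if (tau_max < 0 || increment <= 0) stop("invalid schedule parameters")
  structure(list(kind = kind, tau_max = tau_max, increment = increment),
            class = "delay_schedule")
}

#' Delay on a given trial
#'
#' @param schedule A [delay_schedule()].
#' @param trial_index Trial number, 1-based.
#' @return Delay tau, s.
#' @examples
#' schedule_tau(delay_schedule("gradual"), 1)  # 0.004
#' schedule_tau(delay_schedule("gradual"), 25) # 0.1
#' @export
schedule_tau <- function(schedule, trial_index) {
  stopifnot(inherits(schedule, "delay_schedule"), trial_index >= 1)
  switch(schedule$kind,
         none = 0,
         abrupt = schedule$tau_max,
         gradual = pmin(schedule$increment * trial_index, schedule$tau_max))
}

#' Pong game configuration
#'
#' Arena geometry and physics of the desk-scale pong simulator. The paddle
#' is a horizontal bar at the (possibly delayed) hand position; the ball
#' reflects elastically off the side and bottom walls, receives a stochastic
#' horizontal jitter at the upper wall, and is hit by the paddle only while
#' the paddle moves upward and the ball downward.
#'
#' @param arena c(width, height), cm (default 24 x 16).
#' @param dt Physics step, s (default 0.001, a 1 kHz control loop).
#' @param ball_speed0 Initial ball speed, cm/s (default 20).
#' @param ball_mass Ball mass, kg (default 0.15; used by [haptic_pulse()]).
#' @param restitution_ball Paddle-hit coefficient on the ball's own velocity
#'   (default 0.7).
#' @param paddle_coupling Paddle-hit coefficient on the paddle velocity
#'   (default 0.42).
#' @param paddle_width Frontal extent of the paddle, cm (default 4; not
#'   dictated by the physics, exposed as a parameter).
#' @param jitter_kind `"normal_angle"` (deflection angle ~ N(0, var =
#'   0.05*pi rad^2)) or `"uniform_velocity"` (jitter ~ U(-13, 13) cm/s).
#' @param jitter_scale Variance (rad^2) or half-range (cm/s) per
#'   `jitter_kind`.
#' @param delay_schedule A [delay_schedule()].
#' @param trial_duration Trial length, s (default 60).
#' @param pulse_dt Haptic force interval, s (default 0.025).
#' @return Object of class `pong_config`.
#' @export
pong_config <- function(arena = c(24, 16), dt = 0.001, ball_speed0 = 20,
                        ball_mass = 0.15, restitution_ball = 0.7,
                        paddle_coupling = 0.42, paddle_width = 4,
                        jitter_kind = c("normal_angle", "uniform_velocity"),
                        jitter_scale = NULL,
                        delay_schedule = delayrep::delay_schedule("none"),
                        trial_duration = 60, pulse_dt = 0.025) {
  jitter_kind <- match.arg(jitter_kind)
  if (is.null(jitter_scale))
    jitter_scale <- if (jitter_kind == "normal_angle") 0.05 * pi else 13
  if (dt <= 0 || any(arena <= 0) || trial_duration <= 0)
    stop("arena, dt and trial_duration must be positive")
  if (restitution_ball <= 0 || restitution_ball >= 1 ||
      paddle_coupling <= 0 || paddle_coupling >= 1)
    stop("collision coefficients must lie in (0, 1)")
  structure(list(arena = arena, dt = dt, ball_speed0 = ball_speed0,
                 ball_mass = ball_mass, restitution_ball = restitution_ball,
                 paddle_coupling = paddle_coupling,
                 paddle_width = paddle_width, jitter_kind = jitter_kind,
                 jitter_scale = jitter_scale,
                 delay_schedule = delay_schedule,
                 trial_duration = trial_duration, pulse_dt = pulse_dt),
            class = "pong_config")
}

#' Delayed paddle position from the hand buffer
#'
#' The paddle is displayed at the hand position `tau` seconds earlier,
#' read from a buffer updated at the control-loop rate. `tau/dt` is rounded
#' to the nearest step (all canonical delays are integral at 1 ms). While
#' the buffer is shorter than the delay, the earliest sample is returned.
#'
#' @param hand_history Numeric vector (or 2-column matrix) of hand samples,
#'   oldest first, up to the current step.
#' @param tau Delay, s (>= 0).
#' @param dt Buffer update interval, s.
#' @return The buffered sample `round(tau/dt)` steps back.
#' @export
delay_buffer <- function(hand_history, tau, dt) {
  if (is.matrix(hand_history)) n <- nrow(hand_history)
  else n <- length(hand_history)
  if (n == 0L) stop("empty hand buffer")
  if (tau < 0 || dt <= 0) stop("tau must be >= 0 and dt > 0")
  i <- max(1L, n - as.integer(round(tau / dt)))
  if (is.matrix(hand_history)) hand_history[i, ] else hand_history[i]
}

#' Wall reflection with upper-wall jitter
#'
#' Side and bottom walls reflect elastically (mirror the normal velocity
#' component, speed conserved). The upper wall mirrors the vertical
#' component and perturbs the horizontal one: under `normal_angle` the
#' outgoing direction is deflected by an angle alpha ~ N(0, var =
#' `jitter_scale`), adding `j = -vy_pre * tan(alpha)` to vx; under
#' `uniform_velocity`, `j ~ U(-jitter_scale, jitter_scale)` cm/s. If the
#' ball is not moving into the wall the velocity is returned unchanged with
#' a warning.
#'
#' @param vel c(vx, vy), cm/s.
#' @param wall One of `"left"`, `"right"`, `"bottom"`, `"top"`.
#' @param jitter_kind,jitter_scale See [pong_config()].
#' @param alpha Optional fixed deflection angle (rad), overriding the random
#'   draw (for testing / jitter-free runs use `alpha = 0`).
#' @return c(vx, vy) after the bounce.
#' @export
reflect_wall <- function(vel, wall = c("left", "right", "bottom", "top"),
                         jitter_kind = c("normal_angle", "uniform_velocity"),
                         jitter_scale = 0.05 * pi, alpha = NULL) {
  wall <- match.arg(wall)
  jitter_kind <- match.arg(jitter_kind)
  toward <- switch(wall,
                   left = vel[1] < 0, right = vel[1] > 0,
                   bottom = vel[2] < 0, top = vel[2] > 0)
  if (!toward) {
    warning("ball not moving toward the ", wall, " wall; no reflection")
    return(vel)
  }
  if (wall %in% c("left", "right")) return(c(-vel[1], vel[2]))
  if (wall == "bottom") return(c(vel[1], -vel[2]))
  j <- if (jitter_kind == "normal_angle") {
    if (is.null(alpha)) alpha <- stats::rnorm(1L, 0, sqrt(jitter_scale))
    -vel[2] * tan(alpha)
  } else {
    if (!is.null(alpha)) alpha else
      stats::runif(1L, -jitter_scale, jitter_scale)
  }
  c(vel[1] + j, -vel[2])
}

#' Directional paddle-ball hit
#'
#' A hit occurs only when the paddle moves upward and the ball downward;
#' otherwise the ball passes through unchanged. On a hit the outgoing
#' velocity is `vx' = 0.7 vx + 0.42 vxp`, `vy' = -0.7 vy + 0.42 vyp`, which
#' is always upward given the preconditions. Keeping the two coefficients
#' below 1 means the paddle must move at least ~0.71 |vy| upward to
#' preserve the ball's sagittal speed.
#'
#' @param ball_vel c(vx, vy) of the ball, cm/s.
#' @param paddle_vel c(vx, vy) of the paddle, cm/s.
#' @param restitution_ball,paddle_coupling Hit coefficients (defaults
#'   0.7 / 0.42).
#' @return List with `hit` (logical) and `vel` (outgoing c(vx, vy)).
#' @export
paddle_hit <- function(ball_vel, paddle_vel, restitution_ball = 0.7,
                       paddle_coupling = 0.42) {
  hit <- paddle_vel[2] > 0 && ball_vel[2] < 0
  if (!hit) return(list(hit = FALSE, vel = ball_vel))
  list(hit = TRUE,
       vel = c(restitution_ball * ball_vel[1] +
                 paddle_coupling * paddle_vel[1],
               -restitution_ball * ball_vel[2] +
                 paddle_coupling * paddle_vel[2]))
}

#' Peak haptic-pulse force at a hit
#'
#' `F = m_b * dv / dt` in SI units (the velocity change is given in cm/s
#' and converted to m/s). The triangular 0.05 s rendering profile is a
#' display detail and is not simulated.
#'
#' @param ball_mass kg.
#' @param dv Sagittal ball velocity change at the hit, cm/s.
#' @param pulse_dt Force interval, s (> 0).
#' @return Peak force, N.
#' @examples
#' haptic_pulse(0.15, 50, 0.025) # 3 N
#' @export
haptic_pulse <- function(ball_mass, dv, pulse_dt) {
  if (pulse_dt <= 0) stop("pulse_dt must be > 0")
  ball_mass * (dv / 100) / pulse_dt
}

#' Reference paddle policies
#'
#' Policies map `(t, ball_pos, ball_vel, paddle_pos)` to a commanded hand
#' velocity c(vx, vy) in cm/s, so the simulator can be exercised without a
#' human player:
#' * `policy_dead()` never moves (zero hits by construction).
#' * `policy_scripted(fx, fy)` follows scripted velocity functions of time.
#' * `policy_chaser(kp, stroke_amp, stroke_freq, lag)` tracks the ball
#'   frontally with proportional gain `kp` (1/s) and strokes vertically as
#'   a sinusoid (amplitude cm, frequency Hz), optionally reacting to the
#'   ball position `lag` seconds late.
#'
#' @param kp Frontal proportional gain, 1/s.
#' @param stroke_amp,stroke_freq Vertical stroke amplitude (cm) and
#'   frequency (Hz).
#' @param lag Reaction lag, s.
#' @param vmax Frontal speed bound, cm/s.
#' @param fx,fy Functions of time returning velocities, cm/s.
#' @return A policy function.
#' @name pong_policies
NULL

#' @rdname pong_policies
#' @export
policy_dead <- function() function(t, ball_pos, ball_vel, paddle_pos) c(0, 0)

#' @rdname pong_policies
#' @export
policy_scripted <- function(fx = function(t) 0, fy = function(t) 0) {
  function(t, ball_pos, ball_vel, paddle_pos) c(fx(t), fy(t))
}

#' @rdname pong_policies
#' @export
policy_chaser <- function(kp = 8, stroke_amp = 3, stroke_freq = 1.2,
                          lag = 0, vmax = 60) {
  memory <- new.env(parent = emptyenv())
  memory$hist_x <- numeric(0)
  function(t, ball_pos, ball_vel, paddle_pos) {
    memory$hist_x <- c(memory$hist_x, ball_pos[1])
    # react to the ball position `lag` seconds ago (buffer grows one
    # sample per control step)
    n <- length(memory$hist_x)
    bx <- memory$hist_x[max(1L, n - as.integer(round(lag * 1000)))]
    vx <- max(-vmax, min(vmax, kp * (bx - paddle_pos[1])))
    vy <- stroke_amp * 2 * pi * stroke_freq * cos(2 * pi * stroke_freq * t)
    c(vx, vy)
  }
}

#' Run one pong trial
#'
#' Steps the arena physics at `config$dt`: the policy commands a hand
#' velocity, the hand position feeds a delay buffer, the paddle is drawn at
#' the buffered position, the ball advances, wall collisions are resolved
#' first (simultaneous corner hits reflect both components), then a paddle
#' hit is tested when the ball's sagittal position crosses the paddle line
#' within the paddle's frontal extent during the step (linear interpolation
#' within the step). Deterministic given `seed`.
#'
#' @param config A [pong_config()].
#' @param policy A policy function (see [pong_policies]).
#' @param tau Hand-to-paddle delay for this trial, s; defaults to trial 1
#'   of `config$delay_schedule`.
#' @param seed Optional integer seed (upper-wall jitter).
#' @param record_rate Rate at which trajectories are recorded, Hz
#'   (default 200).
#' @param jitter Set `FALSE` to disable upper-wall jitter (bit-reproducible
#'   physics).
#' @return List with `hand`, `paddle`, `ball` trajectories, `hit_times`
#'   (s), `hit_count`, `tau`, and `config`.
#' @export
run_pong_trial <- function(config, policy, tau = NULL, seed = NULL,
                           record_rate = 200, jitter = TRUE) {
  stopifnot(inherits(config, "pong_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tau)) tau <- schedule_tau(config$delay_schedule, 1L)
  W <- config$arena[1]; H <- config$arena[2]
  dt <- config$dt
  n_steps <- round(config$trial_duration / dt)
  k_delay <- as.integer(round(tau / dt))
  half_pw <- config$paddle_width / 2
  rec_every <- max(1L, as.integer(round(1 / (record_rate * dt))))

  # state: ball starts centred moving down-left at ball_speed0; hand centred
  # at 1/4 arena height
  bx <- W / 2; by <- H / 2
  ang <- -3 * pi / 4
  vx <- config$ball_speed0 * cos(ang); vy <- config$ball_speed0 * sin(ang)
  hx <- W / 2; hy <- H / 4
  hist_x <- numeric(n_steps + 1L); hist_y <- numeric(n_steps + 1L)
  hist_x[1] <- hx; hist_y[1] <- hy
  px_prev <- hx; py_prev <- hy
  hit_times <- numeric(0)
  n_rec <- n_steps %/% rec_every + 1L
  rec <- matrix(NA_real_, n_rec, 7L)
  rec[1, ] <- c(0, hx, hy, px_prev, py_prev, bx, by)
  r <- 1L

  for (s in seq_len(n_steps)) {
    t_now <- s * dt
    cmd <- policy(t_now, c(bx, by), c(vx, vy), c(px_prev, py_prev))
    if (length(cmd) != 2L || !all(is.finite(cmd)))
      stop("policy returned a non-finite velocity command at t = ", t_now)
    hx <- min(max(hx + cmd[1] * dt, 0), W)
    hy <- min(max(hy + cmd[2] * dt, 0), H)
    hist_x[s + 1L] <- hx; hist_y[s + 1L] <- hy
    i_buf <- max(1L, s + 1L - k_delay)
    px <- hist_x[i_buf]; py <- hist_y[i_buf]
    pvx <- (px - px_prev) / dt; pvy <- (py - py_prev) / dt

    bx_new <- bx + vx * dt; by_new <- by + vy * dt
    # walls first (corner hits reflect both components)
    if (bx_new < 0 && vx < 0) {
      bx_new <- -bx_new; vx <- -vx
    } else if (bx_new > W && vx > 0) {
      bx_new <- 2 * W - bx_new; vx <- -vx
    }
    if (by_new < 0 && vy < 0) {
      by_new <- -by_new; vy <- -vy
    } else if (by_new > H && vy > 0) {
      a <- if (jitter) NULL else 0
      v2 <- reflect_wall(c(vx, vy), "top", config$jitter_kind,
                         config$jitter_scale, alpha = a)
      vx <- v2[1]; vy <- v2[2]
      by_new <- 2 * H - by_new
    }
    # paddle hit: sagittal crossing of the paddle line during the step
    if (vy < 0 && pvy > 0 && (by - py_prev) * (by_new - py) <= 0) {
      denom <- (by_new - by) - (py - py_prev)
      frac <- if (abs(denom) > 1e-12) (py_prev - by) / denom else 0
      frac <- min(max(frac, 0), 1)
      x_at <- bx + (bx_new - bx) * frac
      px_at <- px_prev + (px - px_prev) * frac
      if (abs(x_at - px_at) <= half_pw) {
        res <- paddle_hit(c(vx, vy), c(pvx, pvy),
                          config$restitution_ball, config$paddle_coupling)
        if (res$hit) {
          vx <- res$vel[1]; vy <- res$vel[2]
          by_new <- py + (1 - frac) * vy * dt
          hit_times <- c(hit_times, t_now)
        }
      }
    }
    bx <- min(max(bx_new, 0), W); by <- min(max(by_new, 0), H)
    px_prev <- px; py_prev <- py
    if (s %% rec_every == 0L) {
      r <- r + 1L
      rec[r, ] <- c(t_now, hx, hy, px, py, bx, by)
    }
  }
  rec <- rec[seq_len(r), , drop = FALSE]
  mk <- function(i, j) trajectory(x = rec[, i], y = rec[, j], t = rec[, 1])
  list(hand = mk(2L, 3L), paddle = mk(4L, 5L), ball = mk(6L, 7L),
       hit_times = hit_times, hit_count = length(hit_times),
       tau = tau, config = config)
}

#' Run a multi-trial pong session under a delay schedule
#'
#' @param config A [pong_config()].
#' @param policy A policy function.
#' @param n_trials Number of trials.
#' @param seed Integer seed; each trial uses `seed + trial - 1`.
#' @param ... Passed to [run_pong_trial()].
#' @return List of trial records (see [run_pong_trial()]); each carries its
#'   scheduled `tau`.
#' @export
simulate_pong_session <- function(config, policy, n_trials, seed = NULL,
                                  ...) {
  lapply(seq_len(n_trials), function(i) {
    run_pong_trial(config, policy,
                   tau = schedule_tau(config$delay_schedule, i),
                   seed = if (is.null(seed)) NULL else seed + i - 1L, ...)
  })
}

#' Hit rate per time bin
#'
#' Splits a trial of length `dur` into `n_bins` equal bins and
#' returns hits per second in each, so that `sum(rate * bin_width)` equals
#' the total hit count.
#'
#' @param hit_times Hit times, s.
#' @param dur Trial duration, s (> 0).
#' @param n_bins Number of bins (>= 1).
#' @return Numeric vector of rates, hits/s.
#' @export
hit_rate <- function(hit_times, dur, n_bins = 1L) {
  if (dur <= 0 || n_bins < 1L) stop("dur > 0 and n_bins >= 1 required")
  binw <- dur / n_bins
  # bins are left-open/right-closed, so a hit on an edge counts in the
  # earlier bin; a hit at exactly t = 0 falls in the first
  bin <- pmin(pmax(ceiling(hit_times / binw), 1L), n_bins)
  tabulate(bin, nbins = n_bins) / binw
}
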