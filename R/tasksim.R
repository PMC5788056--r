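#' Reach specification
#'
#' @param start Start point (x, y), cm.
#' @param target Target point (x, y), cm.
#' @param tf Movement duration, s (default 0.3).
#' @param rate Sampling frequency, Hz (default 200, the recorded-data rate).
#' @return Object of class `reach_spec`.
#' @export
reach_spec <- function(start = c(0, 0), target = c(0, 10), tf = 0.3,
                       rate = 200) {
  if (tf <= 0) stop("tf must be > 0")
  if (isTRUE(all.equal(start, target))) stop("start and target must differ")
  structure(list(start = as.numeric(start), target = as.numeric(target),
                 tf = tf, rate = rate),
            class = "reach_spec")
}

#' Tracking-path specification
#'
#' Three path kinds are supported:
#' * `figure_eight` — `x = A sin(2 pi t / T)`, `y = A sin(4 pi t / T)`:
#'   one frontal cycle per two sagittal cycles (defaults A = 8 cm, T = 5 s).
#' * `sine` — a single sagittal sine cycle `y = A sin(2 pi t / T)`, the
#'   reduced form used for tracking simulations.
#' * `sinusoid_mixture` — `y = A sum_i sin(2 pi fr_i t + phi_i)`, x
#'   constant; five components of equal amplitude by default (A = 2 cm,
#'   duration 120 s). The component values `fr` are true frequencies in Hz.
#'
#' @param path_kind `"figure_eight"`, `"sine"` or `"sinusoid_mixture"`.
#' @param A Path amplitude, cm.
#' @param T_cycle Cycle time, s (figure-eight / sine).
#' @param fr Component frequencies, Hz (mixture).
#' @param phi Component phases, rad (mixture; same length as `fr`).
#' @param center Path centre (x, y), cm.
#' @param dur Trial duration, s; defaults to one cycle (figure-eight/sine)
#'   or 120 s (mixture).
#' @param rate Sampling frequency, Hz.
#' @return Object of class `track_spec`.
#' @export
track_spec <- function(path_kind = c("figure_eight", "sine",
                                     "sinusoid_mixture"),
                       A = NULL, T_cycle = 5,
                       fr = c(0.31, 0.67, 0.23, 0.42, 0.54),
                       phi = c(0, pi / 4, pi, 3 * pi / 2, pi / 3),
                       center = c(0, 0), dur = NULL, rate = 200) {
  path_kind <- match.arg(path_kind)
  if (is.null(A)) A <- if (path_kind == "sinusoid_mixture") 2 else 8
  if (A <= 0) stop("A must be > 0")
  if (path_kind == "sinusoid_mixture") {
    if (length(fr) != length(phi))
      stop("fr and phi must have the same length")
    if (is.null(dur)) dur <- 120
  } else {
    if (T_cycle <= 0) stop("T_cycle must be > 0")
    if (is.null(dur)) dur <- T_cycle
  }
  structure(list(path_kind = path_kind, A = A, T_cycle = T_cycle,
                 fr = fr, phi = phi, center = as.numeric(center),
                 dur = dur, rate = rate),
            class = "track_spec")
}

# Uniform time grid 0..dur inclusive.
time_grid <- function(dur, rate) (0:round(dur * rate)) / rate

# Evaluate a track path analytically at arbitrary times (negative allowed),
# so lagged/advanced cursors are computed without padding artifacts.
path_eval <- function(spec, t) {
  switch(spec$path_kind,
    figure_eight = list(
      x = spec$center[1] + spec$A * sin(2 * pi * t / spec$T_cycle),
      y = spec$center[2] + spec$A * sin(4 * pi * t / spec$T_cycle)),
    sine = list(
      x = rep(spec$center[1], length(t)),
      y = spec$center[2] + spec$A * sin(2 * pi * t / spec$T_cycle)),
    sinusoid_mixture = {
      y <- rep(0, length(t))
      for (i in seq_along(spec$fr))
        y <- y + sin(2 * pi * spec$fr[i] * t + spec$phi[i])
      list(x = rep(spec$center[1], length(t)), y = spec$center[2] + spec$A * y)
    })
}

#' Minimum-jerk reach trajectory
#'
#' Point-to-point reach following the quintic profile
#' `s(u) = 10 u^3 - 15 u^4 + 6 u^5`, `u = t/tf`, per axis. Position equals
#' `start` at t = 0 and `target` at t = tf; velocity and acceleration
#' vanish at both ends; peak speed is `1.875 d / tf` for distance d.
#'
#' @param spec A [reach_spec()].
#' @return A [trajectory()].
#' @export
min_jerk <- function(spec) {
  stopifnot(inherits(spec, "reach_spec"))
  t <- time_grid(spec$tf, spec$rate)
  u <- t / spec$tf
  s <- 10 * u^3 - 15 * u^4 + 6 * u^5
  trajectory(x = spec$start[1] + (spec$target[1] - spec$start[1]) * s,
             y = spec$start[2] + (spec$target[2] - spec$start[2]) * s,
             t = t, rate = spec$rate)
}

#' Tracking target trajectory
#'
#' Generates the target path described by a [track_spec()].
#'
#' @param spec A [track_spec()].
#' @return A [trajectory()].
#' @export
target_path <- function(spec) {
  stopifnot(inherits(spec, "track_spec"))
  switch(spec$path_kind,
         figure_eight = figure_eight(spec),
         sine = sagittal_sine(spec),
         sinusoid_mixture = sinusoid_mixture(spec))
}

#' @rdname target_path
#' @export
figure_eight <- function(spec) {
  stopifnot(inherits(spec, "track_spec"), spec$path_kind == "figure_eight")
  eval_on_grid(spec)
}

#' @rdname target_path
#' @export
sagittal_sine <- function(spec) {
  stopifnot(inherits(spec, "track_spec"), spec$path_kind == "sine")
  eval_on_grid(spec)
}

#' @rdname target_path
#' @export
sinusoid_mixture <- function(spec) {
  stopifnot(inherits(spec, "track_spec"),
            spec$path_kind == "sinusoid_mixture")
  if (length(spec$fr) != length(spec$phi))
    stop("fr and phi must have the same length")
  eval_on_grid(spec)
}

eval_on_grid <- function(spec) {
  t <- time_grid(spec$dur, spec$rate)
  p <- path_eval(spec, t)
  trajectory(x = p$x, y = p$y, t = t, rate = spec$rate)
}

#' Simulate a blind reach under a representation model
#'
#' The imagined cursor performs the minimum-jerk reach to the target; the
#' hand moves so that the imagined cursor would land on the target, i.e.
#' the hand trajectory is the active model applied to the cursor
#' trajectory. The reported endpoint is the point of maximal along-reach
#' excursion of the hand over the movement (which reduces to the terminal
#' point for monotone trajectories), plus per-axis Gaussian endpoint noise.
#'
#' For the gain variant the scaling origin is the movement start; for the
#' spatial-shift variant the shift points from start to target.
#'
#' @param spec A [reach_spec()].
#' @param params A [representation_params()].
#' @param noise_sd Endpoint noise SD per axis, cm (default 1).
#' @param seed Optional integer seed for the endpoint noise.
#' @return List with `endpoint` (noisy, cm), `endpoint_raw` (pre-noise),
#'   `hand` and `cursor` trajectories.
#' @export
simulate_blind_reach <- function(spec, params, noise_sd = 1, seed = NULL) {
  stopifnot(inherits(spec, "reach_spec"),
            inherits(params, "representation_params"))
  if (!is.null(seed)) set.seed(seed)
  cursor <- min_jerk(spec)
  dirvec <- spec$target - spec$start
  dirvec <- dirvec / sqrt(sum(dirvec^2))
  hand <- apply_representation(params, cursor,
                               origin = spec$start, direction = dirvec)
  excursion <- (hand$x - spec$start[1]) * dirvec[1] +
               (hand$y - spec$start[2]) * dirvec[2]
  i <- which.max(excursion)
  endpoint_raw <- c(hand$x[i], hand$y[i])
  endpoint <- endpoint_raw + stats::rnorm(2L, 0, noise_sd)
  list(endpoint = endpoint, endpoint_raw = endpoint_raw,
       hand = hand, cursor = cursor)
}

#' Simulate blind tracking under a representation model
#'
#' The imagined cursor equals the target delayed by `baseline_lag` (the
#' hand naturally trails the target during manual tracking). Because the
#' track paths are analytic, lagged and advanced signals are obtained by
#' evaluating the path at shifted time arguments — no padding artifacts.
#' The time variant predicts a hand that precedes the target by exactly
#' `tau_hat` (the mover places the imagined cursor on the target and the
#' hand leads it by the represented delay): `hand(t) = path(t + tau_hat)`,
#' so its lead over the baseline hand is `baseline_lag + tau_hat`. The
#' state-based variants are applied pointwise to the lagged cursor; the
#' post-no-delay condition is obtained with `variant = "none"`. For the
#' gain variant the scaling origin is the path centre (mean of the cursor
#' trajectory); for the spatial-shift variant the shift is along +y
#' (sagittal).
#'
#' @param spec A [track_spec()].
#' @param params A [representation_params()].
#' @param baseline_lag Baseline target-to-hand lag, s (>= 0, default 0.2).
#' @return List with `target`, `cursor` and `hand` trajectories.
#' @export
simulate_blind_tracking <- function(spec, params, baseline_lag = 0.2) {
  stopifnot(inherits(spec, "track_spec"),
            inherits(params, "representation_params"))
  if (baseline_lag < 0) stop("baseline_lag must be >= 0")
  t <- time_grid(spec$dur, spec$rate)
  pt <- path_eval(spec, t)
  pc <- path_eval(spec, t - baseline_lag)
  target <- trajectory(x = pt$x, y = pt$y, t = t, rate = spec$rate)
  cursor <- trajectory(x = pc$x, y = pc$y, t = t, rate = spec$rate)
  hand <- if (params$variant == "time") {
    ph <- path_eval(spec, t + params$tau_hat)
    trajectory(x = ph$x, y = ph$y, t = t, rate = spec$rate)
  } else {
    origin <- c(mean(cursor$x), mean(cursor$y))
    apply_representation(params, cursor, origin = origin,
                         direction = c(0, 1))
  }
  list(target = target, cursor = cursor, hand = hand)
}

#' Predicted frequency response under each representation model
#'
#' For a target moving with baseline amplitude `At` at each frequency, the
#' predicted hand amplitude is `g_hat * At` under the gain model,
#' `At * sqrt(1 + tau^4 w^4 / 4)` under the mechanical model, and `At`
#' (unchanged) under the time and spatial-shift models. The dB difference
#' profile relative to baseline is flat for gain and rises with frequency
#' for mechanical — the model-discrimination signature.
#'
#' @param params A [representation_params()].
#' @param freqs Frequencies, Hz.
#' @param At Baseline amplitude per frequency, cm (scalar or same length
#'   as `freqs`).
#' @return A [frequency_response()] with extra fields `baseline_amp_cm`
#'   and `db_diff` (dB relative to baseline).
#' @export
frequency_response_prediction <- function(params, freqs, At) {
  stopifnot(inherits(params, "representation_params"))
  if (length(At) == 1L) At <- rep(At, length(freqs))
  if (length(At) != length(freqs))
    stop("At must be scalar or the length of freqs")
  omega <- 2 * pi * freqs
  Ah <- switch(params$variant,
    none = At,
    time = At,
    spatial_shift = At,
    gain = params$g_hat * At,
    # modulus of 1 - (M/K) w^2 + (B/K) w j; reduces to
    # sqrt(1 + tau^4 w^4 / 4) for the Taylor pairing B/K = tau, M/K = tau^2/2
    mechanical = At * sqrt((1 - params$m_over_k * omega^2)^2 +
                             (params$b_over_k * omega)^2),
    stop("unknown variant"))
  resp <- frequency_response(freqs, Ah)
  resp$baseline_amp_cm <- At
  resp$db_diff <- resp$amp_db - 10 * log10(At^2 / 2)
  resp
}
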