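#' Delay representation parameters
#'
#' Bundles the active representation model and its parameter(s). The four
#' candidate representations map a displayed-paddle / imagined-cursor
#' trajectory to the hand trajectory a mover holding that representation
#' would produce:
#'
#' * `none` — veridical mapping, hand = cursor.
#' * `time` — the delay is represented explicitly as a time lag `tau_hat`:
#'   hand(t) = cursor(t + tau_hat).
#' * `spatial_shift` — the cursor is believed to trail the hand by a fixed
#'   offset `dx_hat` (cm) along a direction: hand = cursor + dx_hat * dir.
#' * `gain` — the cursor is believed to move with smaller amplitude, so the
#'   hand scales by `g_hat` about an origin: hand = origin + g_hat * (cursor
#'   - origin). The delay-representation hypothesis predicts g_hat > 1;
#'   values in (0, 1] are accepted so that parameter recovery can return
#'   near-identity fits.
#' * `mechanical` — the cursor is believed to be a damped mass on a spring
#'   attached to the hand; to second order this is hand(t) = cursor(t) +
#'   (B/K) cursor'(t) + (M/K) cursor''(t). Choosing B/K = tau_hat and
#'   M/K = tau_hat^2/2 makes it the Taylor expansion of the time model.
#'
#' @param variant One of `"none"`, `"time"`, `"spatial_shift"`, `"gain"`,
#'   `"mechanical"`.
#' @param tau_hat Estimated delay, s (>= 0). Read by `time`; also the
#'   convenience parameter for `mechanical` when `b_over_k`/`m_over_k` are
#'   not given (then set via [taylor_params()]).
#' @param dx_hat Spatial shift, cm. Read by `spatial_shift`.
#' @param g_hat Gain, dimensionless (> 0). Read by `gain`.
#' @param b_over_k Damping/stiffness ratio B/K, s (>= 0). Read by
#'   `mechanical`.
#' @param m_over_k Mass/stiffness ratio M/K, s^2 (>= 0). Read by
#'   `mechanical`.
#' @return An object of class `representation_params`.
#' @examples
#' representation_params("gain", g_hat = 1.2)
#' representation_params("mechanical", tau_hat = 0.1)
#' @export
representation_params <- function(variant = c("none", "time", "spatial_shift",
                                              "gain", "mechanical"),
                                  tau_hat = 0, dx_hat = 0, g_hat = 1,
                                  b_over_k = NULL, m_over_k = NULL) {
  variant <- match.arg(variant)
  if (variant == "time" && (!is.finite(tau_hat) || tau_hat < 0))
    stop("tau_hat must be >= 0")
  if (variant == "gain" && (!is.finite(g_hat) || g_hat <= 0))
    stop("g_hat must be > 0")
  if (variant == "mechanical" && is.null(b_over_k)) {
    tp <- taylor_params(tau_hat)
    b_over_k <- tp$b_over_k
    m_over_k <- tp$m_over_k
  }
  if (variant == "mechanical" &&
      (b_over_k < 0 || is.null(m_over_k) || m_over_k < 0))
    stop("b_over_k and m_over_k must be >= 0")
  structure(list(variant = variant, tau_hat = tau_hat, dx_hat = dx_hat,
                 g_hat = g_hat, b_over_k = b_over_k, m_over_k = m_over_k),
            class = "representation_params")
}

#' @export
print.representation_params <- function(x, ...) {
  par_str <- switch(x$variant,
    none = "identity",
    time = sprintf("tau_hat = %g s", x$tau_hat),
    spatial_shift = sprintf("dx_hat = %g cm", x$dx_hat),
    gain = sprintf("g_hat = %g", x$g_hat),
    mechanical = sprintf("B/K = %g s, M/K = %g s^2", x$b_over_k, x$m_over_k))
  cat(sprintf("<representation_params> %s (%s)\n", x$variant, par_str))
  invisible(x)
}

#' Veridical (no-representation) mapping
#'
#' The hand is estimated as aligned with the cursor: the output equals the
#' input sample for sample. Baseline for all post-no-delay simulations.
#'
#' @param cursor A [trajectory()].
#' @return A [trajectory()] equal to `cursor`.
#' @export
identity_map <- function(cursor) {
  validate_trajectory(cursor)
  cursor
}

#' Time representation: hand leads the cursor by the estimated delay
#'
#' `hand(t) = cursor(t + tau_hat)`. The signal is advanced by
#' `round(tau_hat * rate)` samples; the vacated tail holds the cursor's
#' terminal sample (the cursor is stationary at trial end in every simulated
#' task), so the output length equals the input length.
#'
#' @param cursor A [trajectory()].
#' @param tau_hat Estimated delay, s (>= 0, at most the signal duration).
#' @return A [trajectory()].
#' @export
time_model <- function(cursor, tau_hat) {
  validate_trajectory(cursor)
  if (!is.finite(tau_hat) || tau_hat < 0)
    stop("tau_hat must be >= 0")
  if (tau_hat > duration(cursor))
    stop("tau_hat exceeds signal duration")
  shift_samples(cursor, round(tau_hat * cursor$rate))
}

#' Spatial-shift representation: constant offset along a direction
#'
#' `hand = cursor + dx_hat * direction` at every sample. The direction must
#' be a unit vector; by convention it points from movement start to target
#' for reaches and along +y (sagittal) for tracking.
#'
#' @param cursor A [trajectory()].
#' @param dx_hat Shift magnitude, cm.
#' @param direction Length-2 unit vector (frontal, sagittal).
#' @return A [trajectory()].
#' @export
spatial_shift_model <- function(cursor, dx_hat, direction = c(0, 1)) {
  validate_trajectory(cursor)
  if (length(direction) != 2L || abs(sqrt(sum(direction^2)) - 1) > 1e-8)
    stop("direction must be a 2D unit vector")
  traj_like(cursor,
            cursor$x + dx_hat * direction[1],
            cursor$y + dx_hat * direction[2])
}

#' Gain representation: amplitude scaling about an origin
#'
#' `hand = origin + g_hat * (cursor - origin)` at every sample. The origin
#' is the movement start for reaches and the path centre (mean of the
#' cursor trajectory) for tracking.
#'
#' @param cursor A [trajectory()].
#' @param g_hat Gain (> 0), dimensionless.
#' @param origin Length-2 point (cm), the fixed point of the scaling.
#' @return A [trajectory()].
#' @export
gain_model <- function(cursor, g_hat, origin = c(0, 0)) {
  validate_trajectory(cursor)
  if (!is.finite(g_hat) || g_hat <= 0) stop("g_hat must be > 0")
  traj_like(cursor,
            origin[1] + g_hat * (cursor$x - origin[1]),
            origin[2] + g_hat * (cursor$y - origin[2]))
}

# Finite-difference first and second derivatives, 2nd-order accurate:
# central in the interior, one-sided at the two endpoints.
fd_derivatives <- function(p, dt) {
  n <- length(p)
  v <- numeric(n)
  a <- numeric(n)
  i <- 2:(n - 1)
  v[i] <- (p[i + 1] - p[i - 1]) / (2 * dt)
  a[i] <- (p[i + 1] - 2 * p[i] + p[i - 1]) / dt^2
  v[1] <- (-3 * p[1] + 4 * p[2] - p[3]) / (2 * dt)
  v[n] <- (3 * p[n] - 4 * p[n - 1] + p[n - 2]) / (2 * dt)
  a[1] <- (2 * p[1] - 5 * p[2] + 4 * p[3] - p[4]) / dt^2
  a[n] <- (2 * p[n] - 5 * p[n - 1] + 4 * p[n - 2] - p[n - 3]) / dt^2
  list(v = v, a = a)
}

#' Mechanical-system representation (Taylor form)
#'
#' Second-order state-based equivalent of the time model:
#' `hand(t) = cursor(t) + (B/K) cursor'(t) + (M/K) cursor''(t)`.
#' Derivatives are 2nd-order central differences, one-sided (2nd-order) at
#' the endpoints.
#'
#' @param cursor A [trajectory()] with at least 5 samples.
#' @param b_over_k Damping/stiffness ratio, s (>= 0).
#' @param m_over_k Mass/stiffness ratio, s^2 (>= 0).
#' @return A [trajectory()].
#' @export
mechanical_model <- function(cursor, b_over_k, m_over_k) {
  validate_trajectory(cursor)
  if (length(cursor) < 5L) stop("trajectory too short for derivatives (need >= 5 samples)")
  if (!is.finite(b_over_k) || b_over_k < 0 ||
      !is.finite(m_over_k) || m_over_k < 0)
    stop("b_over_k and m_over_k must be >= 0")
  dt <- 1 / cursor$rate
  dx <- fd_derivatives(cursor$x, dt)
  dy <- fd_derivatives(cursor$y, dt)
  traj_like(cursor,
            cursor$x + b_over_k * dx$v + m_over_k * dx$a,
            cursor$y + b_over_k * dy$v + m_over_k * dy$a)
}

#' Taylor coefficients matching the mechanical model to a delay
#'
#' Choosing `B/K = tau_hat` and `M/K = tau_hat^2 / 2` makes the mechanical
#' representation the second-order Taylor expansion of
#' `cursor(t + tau_hat)`.
#'
#' @param tau_hat Delay, s (>= 0).
#' @return List with `b_over_k` (s) and `m_over_k` (s^2).
#' @examples
#' taylor_params(0.1) # B/K = 0.1 s, M/K = 0.005 s^2
#' @export
taylor_params <- function(tau_hat) {
  if (!is.finite(tau_hat) || tau_hat < 0) stop("tau_hat must be >= 0")
  list(b_over_k = tau_hat, m_over_k = tau_hat^2 / 2)
}

#' Frequency-domain amplitude gain of the mechanical representation
#'
#' The transfer function of the Taylor-form mechanical model is
#' `1 - (tau^2/2) w^2 + tau w j`, whose modulus is
#' `sqrt(1 + tau^4 w^4 / 4)`: amplitude gain grows with frequency, the
#' signature that separates the mechanical from the (frequency-flat) gain
#' representation.
#'
#' @param omega Angular frequency, rad/s (>= 0). Vectorized.
#' @param tau_hat Delay parameter, s.
#' @return Dimensionless amplitude gain, same length as `omega`.
#' @export
mechanical_amplitude_gain <- function(omega, tau_hat) {
  if (any(omega < 0)) stop("omega must be >= 0")
  sqrt(1 + tau_hat^4 * omega^4 / 4)
}

#' Apply a representation model to a cursor trajectory
#'
#' Dispatcher used by the task simulators: maps the imagined-cursor
#' trajectory to the hand trajectory under `params`.
#'
#' @param params A [representation_params()].
#' @param cursor A [trajectory()].
#' @param origin Scaling origin for the gain variant (cm).
#' @param direction Unit shift direction for the spatial-shift variant.
#' @return A [trajectory()].
#' @export
apply_representation <- function(params, cursor, origin = c(0, 0),
                                 direction = c(0, 1)) {
  stopifnot(inherits(params, "representation_params"))
  switch(params$variant,
    none = identity_map(cursor),
    time = time_model(cursor, params$tau_hat),
    spatial_shift = spatial_shift_model(cursor, params$dx_hat, direction),
    gain = gain_model(cursor, params$g_hat, origin),
    mechanical = mechanical_model(cursor, params$b_over_k, params$m_over_k))
}
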