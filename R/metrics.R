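#' Reach amplitude with velocity-threshold onset/offset
#'
#' Movement onset is the first sample at which speed exceeds
#' `onset_frac` of its maximum; movement end is `offset_hold` seconds after
#' speed first drops below `offset_frac` of its maximum following the speed
#' peak (clipped to the last sample when the hold runs past the trial end).
#' Amplitude is the Euclidean distance between the positions at onset and
#' end. Speed comes from 2nd-order finite differences of position.
#'
#' @param traj A [trajectory()] holding a single reach.
#' @param onset_frac Onset threshold as a fraction of peak speed
#'   (default 0.02).
#' @param offset_frac Offset threshold as a fraction of peak speed
#'   (default 0.05).
#' @param offset_hold Hold time after the offset threshold, s (default 0.1).
#' @return List with `onset` and `end` (sample indices), `endpoint`
#'   c(x, y) cm, and `amplitude` cm.
#' @export
reach_amplitude <- function(traj, onset_frac = 0.02, offset_frac = 0.05,
                            offset_hold = 0.1) {
  validate_trajectory(traj)
  dt <- 1 / traj$rate
  spd <- sqrt(fd_derivatives(traj$x, dt)$v^2 +
                fd_derivatives(traj$y, dt)$v^2)
  vmax <- max(spd)
  if (vmax <= 0) stop("no movement: velocity is identically zero")
  onset <- which(spd > onset_frac * vmax)[1]
  i_peak <- which.max(spd)
  below <- which(spd[i_peak:length(spd)] < offset_frac * vmax)
  i_off <- if (length(below)) i_peak + below[1] - 1L else length(spd)
  i_end <- min(i_off + as.integer(round(offset_hold * traj$rate)),
               length(spd))
  endpoint <- c(traj$x[i_end], traj$y[i_end])
  amplitude <- sqrt((endpoint[1] - traj$x[onset])^2 +
                      (endpoint[2] - traj$y[onset])^2)
  list(onset = onset, end = i_end, endpoint = endpoint,
       amplitude = amplitude)
}

#' Tracking accuracy R-squared
#'
#' `R^2 = 1 - [var(x_h - x_t) + var(y_h - y_t)] / [var(x_h) + var(y_h)]`.
#' A constant hand-target offset does not reduce the score (the variance of
#' a constant difference is zero). Trials with `R^2 < 0.6` are
#' conventionally excluded from further analysis.
#'
#' @param hand,target [trajectory()] objects on the same time base.
#' @return R-squared (dimensionless, can be negative for poor tracking).
#' @export
tracking_r2 <- function(hand, target) {
  validate_trajectory(hand); validate_trajectory(target)
  if (length(hand) != length(target))
    stop("hand and target must have equal length")
  denom <- stats::var(hand$x) + stats::var(hand$y)
  if (denom <= 0) stop("undefined metric: hand has zero variance")
  1 - (stats::var(hand$x - target$x) + stats::var(hand$y - target$y)) / denom
}

#' Target-hand delay by cross-correlation
#'
#' Finds the integer-sample lag maximizing the cross-correlation of the
#' mean-subtracted signals, searched over `[-max_lag, max_lag]`. At each
#' lag the full-overlap product sum is divided by the norms of the two
#' overlapping segments (overlap cosine); without this normalization the
#' shrinking-overlap envelope biases the argmax toward zero lag on short
#' signals. Positive values mean the hand precedes the target.
#'
#' @param hand,target Numeric 1D signals of equal length (e.g. the sagittal
#'   components), or [trajectory()] objects (then the `y` component is
#'   used).
#' @param rate Sampling frequency, Hz (taken from `hand` when it is a
#'   trajectory).
#' @param max_lag Lag search bound, s (default 2; must be below half the
#'   signal duration).
#' @return Lag, s (positive = hand leads).
#' @export
target_hand_delay <- function(hand, target, rate = NULL, max_lag = 2) {
  if (inherits(hand, "trajectory")) {
    if (is.null(rate)) rate <- hand$rate
    hand <- hand$y
  }
  if (inherits(target, "trajectory")) target <- target$y
  if (is.null(rate)) stop("rate must be supplied for plain signals")
  n <- length(hand)
  if (length(target) != n) stop("signals must have equal length")
  h <- hand - mean(hand)
  g <- target - mean(target)
  if (max(abs(h)) == 0 || max(abs(g)) == 0)
    stop("undefined lag: constant signal")
  K <- as.integer(round(max_lag * rate))
  if (K >= n) stop("max_lag must be below the signal duration")
  lags <- -K:K
  cc <- vapply(lags, function(m) {
    if (m >= 0) {
      hs <- h[seq_len(n - m)]; gs <- g[seq_len(n - m) + m]
    } else {
      hs <- h[(1 - m):n]; gs <- g[seq_len(n + m)]
    }
    den <- sqrt(sum(hs^2) * sum(gs^2))
    if (den == 0) -Inf else sum(hs * gs) / den
  }, numeric(1))
  lags[which.max(cc)] / rate
}

#' Centered moving average
#'
#' Smooths with a centred window of odd size `window`; near the edges the
#' window shrinks symmetrically so the estimate stays centred.
#'
#' @param x Numeric vector.
#' @param window Window size, samples (odd; default 101).
#' @return Smoothed vector, same length as `x`.
#' @export
moving_average <- function(x, window = 101L) {
  n <- length(x)
  hw <- (as.integer(window) - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    h <- min(hw, i - 1L, n - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
}
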