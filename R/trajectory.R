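#' Uniformly sampled 2D position time series
#'
#' The universal data container of the package: a hand, cursor, target or
#' ball path sampled at a fixed rate, with time in seconds and positions in
#' centimetres. The frontal axis is `x`, the sagittal axis is `y` (forward
#' motion has positive velocity).
#'
#' @param x Frontal position, cm.
#' @param y Sagittal position, cm. Recycled from 0 if omitted so 1D sagittal
#'   signals can be stored with a zero frontal component (and vice versa).
#' @param t Time stamps, s. If omitted, built as `(0:(n-1))/rate`.
#' @param rate Sampling frequency, Hz. If omitted, inferred from `t`.
#' @return An object of class `trajectory`: a list with elements `t`, `x`,
#'   `y` (numeric vectors of equal length) and `rate` (scalar, Hz).
#' @examples
#' tr <- trajectory(x = rep(0, 200), y = sin(2 * pi * (0:199) / 200), rate = 200)
#' duration(tr)
#' @export
trajectory <- function(x, y = NULL, t = NULL, rate = NULL) {
  x <- as.numeric(x)
  if (is.null(y)) y <- numeric(length(x))
  y <- as.numeric(y)
  if (is.null(t) && is.null(rate))
    stop("provide `t`, `rate`, or both")
  if (is.null(t)) t <- (seq_along(x) - 1) / rate
  t <- as.numeric(t)
  if (is.null(rate)) {
    dt <- diff(t)
    if (length(dt) < 1L) stop("cannot infer `rate` from fewer than 2 samples")
    rate <- 1 / stats::median(dt)
  }
  obj <- structure(list(t = t, x = x, y = y, rate = rate),
                   class = "trajectory")
  validate_trajectory(obj)
  obj
}

#' @rdname trajectory
#' @param traj Object to validate.
#' @export
validate_trajectory <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$t)
  if (n < 2L) stop("trajectory must hold at least 2 samples")
  if (length(traj$x) != n || length(traj$y) != n)
    stop("t, x, y must have identical length")
  if (!all(is.finite(traj$t)) || !all(is.finite(traj$x)) ||
      !all(is.finite(traj$y)))
    stop("trajectory values must all be finite")
  dt <- diff(traj$t)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (!is.finite(traj$rate) || traj$rate <= 0) stop("rate must be positive")
  if (max(abs(dt - 1 / traj$rate)) > 1e-9)
    stop("sampling must be uniform at 1/rate (tolerance 1e-9 s)")
  invisible(traj)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d samples @ %g Hz, %.3f s\n  x [%.2f, %.2f] cm; y [%.2f, %.2f] cm\n",
    length(x$t), x$rate, duration(x),
    min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(t_s = x$t, x_cm = x$x, y_cm = x$y)
}

#' @export
length.trajectory <- function(x) length(x$t)

#' Trajectory duration in seconds
#' @param traj A [trajectory()].
#' @return Elapsed time between first and last sample, s.
#' @export
duration <- function(traj) traj$t[length(traj$t)] - traj$t[1]

# Build a sibling trajectory sharing the time base.
traj_like <- function(traj, x, y) {
  structure(list(t = traj$t, x = x, y = y, rate = traj$rate),
            class = "trajectory")
}

#' Shift a trajectory along its own time axis
#'
#' `shift_samples` moves the signal by an integer number of samples.
#' Positive `k` advances the signal (sample i takes the value of sample
#' i + k) and the vacated tail holds the terminal sample; negative `k`
#' delays it and the vacated head holds the initial sample. Output length
#' equals input length.
#'
#' @param traj A [trajectory()].
#' @param k Integer sample shift (positive = advance).
#' @return A [trajectory()].
#' @keywords internal
shift_samples <- function(traj, k) {
  n <- length(traj$t)
  k <- as.integer(round(k))
  if (abs(k) >= n) stop("shift exceeds signal length")
  idx <- pmin(pmax(seq_len(n) + k, 1L), n)
  traj_like(traj, traj$x[idx], traj$y[idx])
}

#' Read / write trajectory CSV
#'
#' Delimited-text serialization with the fixed header `t_s,x_cm,y_cm`.
#' On read the time base is validated (strictly increasing, uniform);
#' malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @return `read_trajectory` returns a [trajectory()]; `write_trajectory`
#'   returns `path` invisibly.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 1L)
  if (!identical(trimws(hdr), "t_s,x_cm,y_cm"))
    stop("expected header `t_s,x_cm,y_cm` in ", path)
  df <- utils::read.csv(path, colClasses = "numeric")
  bad <- which(!stats::complete.cases(df) |
                 !apply(as.matrix(df), 1L, function(r) all(is.finite(r))))
  if (length(bad))
    stop("non-finite or missing values at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  dup <- which(diff(df$t_s) <= 0)
  if (length(dup))
    stop("time not strictly increasing at line ", dup[1] + 2L, " of ", path)
  trajectory(x = df$x_cm, y = df$y_cm, t = df$t_s)
}

#' @rdname read_trajectory
#' @param traj A [trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  validate_trajectory(traj)
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
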