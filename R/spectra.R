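#' Frequency response container
#'
#' Paired frequency/amplitude vectors. The dB amplitude is defined from
#' the power `pow = amp^2 / 2` as `10 log10(pow)`, so a sine of amplitude
#' A has power A^2/2 (its mean square) and `amp = sqrt(2 pow)`.
#'
#' @param freqs Frequencies, Hz (strictly increasing).
#' @param amp_cm Amplitudes, cm (same length).
#' @return Object of class `frequency_response` with `freqs`, `amp_cm`,
#'   `amp_db`.
#' @export
frequency_response <- function(freqs, amp_cm) {
  if (length(freqs) != length(amp_cm))
    stop("freqs and amp_cm must have equal length")
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  structure(list(freqs = freqs, amp_cm = amp_cm,
                 amp_db = 10 * log10(amp_cm^2 / 2)),
            class = "frequency_response")
}

#' @export
print.frequency_response <- function(x, ...) {
  cat(sprintf("<frequency_response> %d bins, %.4g-%.4g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

# Zero-padding length: at least pad_factor * L, rounded up to a
# 2-3-5-smooth integer so the mixed-radix FFT stays O(n log n) (a large
# prime length makes stats::fft quadratic).
pad_length <- function(L, pad_factor) {
  n <- as.integer(round(pad_factor * L))
  if (pad_factor <= 1) return(max(n, L))
  stats::nextn(n, c(2, 3, 5))
}

# Hann-windowed, zero-padded one-sided power spectrum scaled so that a pure
# sine of amplitude A peaks at power A^2/2.
hann_power <- function(x, rate, pad_factor) {
  L <- length(x)
  w <- signal::hanning(L)
  S0 <- sum(w)
  nfft <- pad_length(L, pad_factor)
  X <- stats::fft(c(x * w, rep(0, nfft - L)))
  half <- seq_len(nfft %/% 2L + 1L)
  pow <- 2 * Mod(X[half])^2 / S0^2
  pow[1] <- pow[1] / 2
  if (nfft %% 2L == 0L) pow[length(half)] <- pow[length(half)] / 2
  list(freqs = (half - 1L) * rate / nfft, pow = pow, window = w,
       nfft = nfft)
}

#' Periodogram amplitude spectrum (Hann window, zero padding)
#'
#' Computes the Hann-windowed periodogram of a 1D signal, zero-padded to
#' `pad_factor` times the signal length so that sharp spectral peaks are
#' sampled densely, scaled so a pure sine of amplitude A peaks at power
#' `A^2/2`. Amplitude is `sqrt(2 pow)` and dB amplitude `10 log10(pow)`.
#' When `probe_freqs` are given, the local power peak within
#' `search_halfwidth` of each probe is extracted (the default half-width is
#' the Hann main-lobe half-width, 2/duration Hz).
#'
#' @param x Numeric signal (e.g. sagittal hand position, cm), or a
#'   [trajectory()] (then `y` is used).
#' @param rate Sampling frequency, Hz.
#' @param pad_factor Zero-padding factor (default 25, e.g. 24,000 samples
#'   padded to 600,000).
#' @param probe_freqs Optional frequencies (Hz) at which to report local
#'   peak amplitudes; must be below the Nyquist frequency.
#' @param search_halfwidth Half-width of the local peak search band, Hz.
#' @return A [frequency_response()]; when probing, `freqs` are the probe
#'   frequencies (sorted).
#' @export
periodogram_amplitude <- function(x, rate = NULL, pad_factor = 25,
                                  probe_freqs = NULL,
                                  search_halfwidth = NULL) {
  if (inherits(x, "trajectory")) {
    if (is.null(rate)) rate <- x$rate
    x <- x$y
  }
  if (is.null(rate)) stop("rate must be supplied for plain signals")
  if (length(x) < 2 * rate) stop("need at least 2 s of signal")
  ps <- hann_power(x, rate, pad_factor)
  if (is.null(probe_freqs))
    return(frequency_response(ps$freqs, sqrt(2 * ps$pow)))
  if (any(probe_freqs >= rate / 2))
    stop("probe frequency at or above Nyquist")
  probe_freqs <- sort(probe_freqs)
  if (is.null(search_halfwidth))
    search_halfwidth <- 2 * rate / length(x)
  amp <- vapply(probe_freqs, function(f0) {
    sel <- ps$freqs >= f0 - search_halfwidth &
      ps$freqs <= f0 + search_halfwidth
    sqrt(2 * max(ps$pow[sel]))
  }, numeric(1))
  frequency_response(probe_freqs, amp)
}

#' FFT amplitude spectrum
#'
#' `A(f) = 2 |FFT(padded signal)| / L` with `L` the unpadded signal length,
#' over the one-sided frequency grid; dB amplitude is `10 log10(A^2/2)`.
#'
#' @inheritParams periodogram_amplitude
#' @return A [frequency_response()] over the full one-sided grid.
#' @export
fft_amplitude <- function(x, rate = NULL, pad_factor = 25) {
  if (inherits(x, "trajectory")) {
    if (is.null(rate)) rate <- x$rate
    x <- x$y
  }
  if (is.null(rate)) stop("rate must be supplied for plain signals")
  L <- length(x)
  nfft <- pad_length(L, pad_factor)
  X <- stats::fft(c(x, rep(0, nfft - L)))
  half <- seq_len(nfft %/% 2L + 1L)
  frequency_response((half - 1L) * rate / nfft, 2 * Mod(X[half]) / L)
}

#' Dominant frequency of a smoothed dB spectrum
#'
#' Smooths the dB amplitude profile with a centred moving average and
#' returns the frequency of its maximum within `band`, with ties broken
#' toward the lowest frequency. Mirrors the restriction of pong-movement
#' analysis to the 0.5-1.5 Hz band (excluding the low-frequency pause
#' peak).
#'
#' @param resp A [frequency_response()].
#' @param band c(low, high), Hz.
#' @param smooth_window Moving-average window, samples (default 101).
#' @return List with `freq` (Hz) and `peak_db` (smoothed dB value).
#' @export
dominant_frequency <- function(resp, band = c(0.5, 1.5),
                               smooth_window = 101L) {
  stopifnot(inherits(resp, "frequency_response"))
  sm <- moving_average(resp$amp_db, smooth_window)
  sel <- which(resp$freqs >= band[1] & resp$freqs <= band[2])
  if (!length(sel)) stop("band contains no frequency bins")
  i <- sel[which.max(sm[sel])] # which.max takes the first (lowest) on ties
  list(freq = resp$freqs[i], peak_db = sm[i])
}
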