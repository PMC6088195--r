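#' Zero-phase band-pass filter
#'
#' Filters a real-valued time series to a frequency band with a 4th-order
#' Butterworth filter applied forward and backward ([signal::filtfilt()]), so
#' the output has zero phase distortion -- a requirement for phase-based
#' connectivity estimation downstream.
#'
#' @param x Numeric vector.
#' @param band A [bandSpec()].
#' @param fs Sampling rate in Hz; must exceed `2 * f_high`.
#' @param order Butterworth order per pass (default 4).
#' @return Filtered series of the same length.
#' @export
bandpass <- function(x, band, fs, order = 4L) {
  stopifnot_scalar(fs, "fs")
  if (fs <= 2 * band$f_high)
    stop(sprintf("fs = %g Hz violates Nyquist for band up to %g Hz", fs, band$f_high),
         call. = FALSE)
  if (!is.numeric(x) || length(x) < 8L)
    stop("x must be a numeric vector with at least 8 samples", call. = FALSE)
  bf <- signal::butter(order, c(band$f_low, band$f_high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Analytic signal via the frequency-domain construction: double positive
# frequencies, zero negative ones. Returns complex vector of same length.
analyticSignal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase and envelope of a band-limited series
#'
#' Computes the analytic signal (frequency-domain Hilbert construction) of a
#' band-limited input and returns its instantaneous phase, wrapped to
#' `(-pi, pi]`, and nonnegative amplitude envelope.
#'
#' @param x Band-limited numeric vector (see [bandpass()]); all-zero input is
#'   rejected.
#' @param band A [bandSpec()] describing the band of `x`.
#' @param fs Sampling rate in Hz.
#' @return An `AnalyticSeries`: list with `phase`, `envelope`, `analytic`
#'   (complex), `band`, `fs`.
#' @export
analyticSeries <- function(x, band, fs) {
  if (all(x == 0)) stop("all-zero input has no defined phase", call. = FALSE)
  z <- analyticSignal(x)
  structure(list(phase = Arg(z), envelope = Mod(z), analytic = z,
                 band = band, fs = fs),
            class = "AnalyticSeries")
}

# Moving-average low-pass used to smooth envelopes before correlation.
smoothEnvelope <- function(env, width) {
  width <- max(1L, as.integer(width))
  if (width <= 1L) return(env)
  k <- rep(1 / width, width)
  as.numeric(stats::filter(env, k, sides = 2, circular = TRUE))
}
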