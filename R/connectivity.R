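#' Imaginary part of the phase-locking value
#'
#' `iplv = (1/T) * |Im sum_t exp(i (phi_a(t) - phi_b(t)))|`. Being the
#' imaginary component only, it vanishes for zero-lag (instantaneous)
#' coupling, making it resistant to field-spread/leakage self-interactions.
#'
#' @param a,b [analyticSeries()] objects (or numeric phase vectors) of equal
#'   length `T >= 2`.
#' @return Scalar in `[0, 1]`.
#' @export
iplv <- function(a, b) {
  pa <- if (inherits(a, "AnalyticSeries")) a$phase else a
  pb <- if (inherits(b, "AnalyticSeries")) b$phase else b
  if (length(pa) != length(pb)) stop("phase series lengths differ", call. = FALSE)
  if (length(pa) < 2) stop("need at least 2 samples", call. = FALSE)
  abs(Im(sum(exp(1i * (pa - pb))))) / length(pa)
}

# Envelope correlation of an orthogonalized pair, from band-limited signals
# and their analytic transforms. One direction: regress y on x, correlate the
# residual's envelope with x's envelope.
corenvPair <- function(bx, by, ax, ay, smooth_samples) {
  dir1 <- corenvDirected(bx, by, ax, ay, smooth_samples)
  dir2 <- corenvDirected(by, bx, ay, ax, smooth_samples)
  (dir1 + dir2) / 2
}

corenvDirected <- function(bx, by, ax, ay, smooth_samples) {
  b <- sum(by * bx) / sum(bx * bx)
  res_a <- ay - b * ax                    # Hilbert transform is linear
  if (max(Mod(res_a)) <= 1e-7 * max(Mod(ay))) {
    warning("zero-variance residual after orthogonalization; returning 0")
    return(0)
  }
  env_r <- smoothEnvelope(Mod(res_a), smooth_samples)
  env_x <- smoothEnvelope(Mod(ax), smooth_samples)
  if (sd(env_r) < 1e-12 || sd(env_x) < 1e-12) {
    warning("zero-variance envelope after orthogonalization; returning 0")
    return(0)
  }
  cor(env_r, env_x)
}

#' Orthogonalized amplitude-envelope correlation
#'
#' Corrects for linear signal leakage with the pairwise (bivariate)
#' orthogonalization: each band-limited signal is regressed on the other, the
#' residual's amplitude envelope is correlated with the partner's envelope,
#' and the two directed values are averaged. A signal that is an exact scalar
#' multiple of the other therefore yields 0.
#'
#' @param x,y Numeric time series of equal length.
#' @param band A [bandSpec()].
#' @param fs Sampling rate in Hz.
#' @param smooth_samples Moving-average width applied to the envelopes before
#'   correlation (default 0.5 s of samples, i.e. roughly a 2-Hz low-pass, the
#'   conventional envelope-correlation setting); `1` disables smoothing.
#' @return Scalar correlation in `[-1, 1]`.
#' @export
corenv <- function(x, y, band, fs,
                   smooth_samples = max(1L, round(fs / 2))) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  bx <- bandpass(x, band, fs); by <- bandpass(y, band, fs)
  corenvPair(bx, by, analyticSignal(bx), analyticSignal(by), smooth_samples)
}

#' Sliding-window specification in band cycles
#'
#' @param width_cycles,step_cycles Window width and step, in cycles of the
#'   band's reference frequency; `width_cycles > step_cycles > 0`.
#' @param cycle_freq_rule Which frequency a "cycle" refers to
#'   (see [bandCycleFreq()]).
#' @return A `WindowSpec` list.
#' @export
windowSpec <- function(width_cycles, step_cycles,
                       cycle_freq_rule = "band_center_arithmetic") {
  if (!(width_cycles > step_cycles && step_cycles > 0))
    stop("need width_cycles > step_cycles > 0", call. = FALSE)
  structure(list(width_cycles = width_cycles, step_cycles = step_cycles,
                 cycle_freq_rule = cycle_freq_rule), class = "WindowSpec")
}

#' Plan sliding windows over a recording
#'
#' Converts a cycle-based [windowSpec()] to samples using the band's reference
#' frequency and tiles the recording with overlapping windows:
#' `count = floor((n_samples - width) / step) + 1`.
#'
#' @param n_samples Recording length in samples.
#' @param fs Sampling rate in Hz.
#' @param spec A [windowSpec()], or `NULL` to pass `width`/`step` in samples
#'   directly.
#' @param band A [bandSpec()] (required with a cycle-based spec).
#' @param width,step Window width/step in samples (used when `spec` is NULL).
#' @return List with `starts` (1-based), `width`, `step` (samples), `count`.
#' @export
windowPlan <- function(n_samples, fs, spec = NULL, band = NULL,
                       width = NULL, step = NULL) {
  if (!is.null(spec)) {
    f_ref <- bandCycleFreq(band, spec$cycle_freq_rule)
    width <- max(2L, round(spec$width_cycles / f_ref * fs))
    step <- max(1L, round(spec$step_cycles / f_ref * fs))
  }
  width <- as.integer(width); step <- as.integer(step)
  if (width > n_samples)
    stop("window width exceeds recording length", call. = FALSE)
  count <- (n_samples - width) %/% step + 1L
  list(starts = 1L + (seq_len(count) - 1L) * step,
       width = width, step = step, count = count)
}

# Band-limit every column and return list(filtered matrix, analytic matrix).
prepareRoiSignals <- function(roi_ts, band, fs) {
  if (any(!is.finite(roi_ts))) stop("non-finite values in input", call. = FALSE)
  filt <- apply(roi_ts, 2, bandpass, band = band, fs = fs)
  anl <- apply(filt, 2, analyticSignal)
  list(filtered = filt, analytic = matrix(anl, nrow = nrow(roi_ts)))
}

# All-pairs iPLV from a complex unit-phasor matrix (T x n).
iplvMatrix <- function(z) {
  m <- abs(Im(crossprod(Conj(z), z))) / nrow(z)
  cleanGraphMatrix(m)
}

corenvMatrix <- function(filt, anl, smooth_samples) {
  n <- ncol(filt)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- corenvPair(filt[, i], filt[, j],
                                     anl[, i], anl[, j], smooth_samples)
  }
  m
}

#' Static functional connectivity graph
#'
#' Computes all pairwise couplings over the whole recording with the chosen
#' estimator, yielding a symmetric zero-diagonal weighted graph.
#'
#' @param roi_ts `samples x n_rois` numeric matrix.
#' @param band A [bandSpec()].
#' @param estimator `"iplv"` or `"corenv"`.
#' @param fs Sampling rate in Hz.
#' @param smooth_samples Envelope smoothing for `"corenv"` (see [corenv()]).
#' @return An [FCGraph-class].
#' @export
staticFCG <- function(roi_ts, band, estimator = c("iplv", "corenv"), fs,
                      smooth_samples = max(1L, round(fs / 2))) {
  estimator <- match.arg(estimator)
  if (ncol(roi_ts) < 2) stop("need at least 2 ROIs", call. = FALSE)
  pre <- prepareRoiSignals(roi_ts, band, fs)
  w <- if (estimator == "iplv") {
    iplvMatrix(exp(1i * Arg(pre$analytic)))
  } else {
    corenvMatrix(pre$filtered, pre$analytic, smooth_samples)
  }
  FCGraph(w, estimator, band, fs)
}

#' Sliding-window dynamic functional connectivity graph
#'
#' Re-estimates the connectivity graph within each sliding window, producing a
#' `windows x n x n` tensor. Phases/envelopes are derived once from the
#' full-length analytic signal and sliced per window, so each slice equals the
#' static estimate on that window's samples up to filter edge effects.
#'
#' @inheritParams staticFCG
#' @param spec A [windowSpec()], or `NULL` with explicit `width`/`step`.
#' @param width,step Window width/step in samples (when `spec` is NULL).
#' @return A [DynamicFCGraph-class].
#' @export
dynamicFCG <- function(roi_ts, band, estimator = c("iplv", "corenv"), fs,
                       spec = NULL, width = NULL, step = NULL,
                       smooth_samples = NULL) {
  estimator <- match.arg(estimator)
  plan <- windowPlan(nrow(roi_ts), fs, spec, band, width, step)
  pre <- prepareRoiSignals(roi_ts, band, fs)
  n <- ncol(roi_ts)
  if (is.null(smooth_samples))
    smooth_samples <- max(1L, min(round(fs / 2), plan$width %/% 4L))
  z <- exp(1i * Arg(pre$analytic))
  tens <- array(0, c(plan$count, n, n))
  for (wi in seq_len(plan$count)) {
    idx <- plan$starts[wi]:(plan$starts[wi] + plan$width - 1L)
    tens[wi, , ] <- if (estimator == "iplv") {
      iplvMatrix(z[idx, , drop = FALSE])
    } else {
      corenvMatrix(pre$filtered[idx, , drop = FALSE],
                   pre$analytic[idx, , drop = FALSE], smooth_samples)
    }
  }
  new("DynamicFCGraph", tensor = tens, windowStarts = as.integer(plan$starts),
      width = plan$width, step = plan$step, estimator = estimator,
      band = unclass(band), fs = fs)
}
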