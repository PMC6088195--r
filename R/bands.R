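#' Define a frequency band
#'
#' A band is a named frequency interval in Hz. The eight canonical
#' electrophysiological rhythms used throughout the package are available from
#' [defaultBands()].
#'
#' @param name Band label, e.g. `"alpha1"`.
#' @param f_low,f_high Band edges in Hz, `0 < f_low < f_high`.
#' @return A `BandSpec`: a named list with elements `name`, `f_low`, `f_high`.
#' @examples
#' bandSpec("alpha1", 8, 10)
#' @export
bandSpec <- function(name, f_low, f_high) {
  stopifnot_scalar(f_low, "f_low")
  stopifnot_scalar(f_high, "f_high")
  if (f_low >= f_high) stop("f_low must be strictly below f_high", call. = FALSE)
  structure(list(name = as.character(name), f_low = f_low, f_high = f_high),
            class = "BandSpec")
}

#' Canonical frequency-band registry
#'
#' The eight rhythms conventionally studied in resting-state
#' electrophysiology: delta 0.5-4, theta 4-8, alpha1 8-10, alpha2 10-13,
#' beta1 13-20, beta2 20-30, gamma1 30-45 and gamma2 55-90 Hz.
#'
#' @return Named list of [bandSpec()] objects.
#' @export
defaultBands <- function() {
  defs <- list(
    delta  = c(0.5, 4), theta  = c(4, 8),  alpha1 = c(8, 10),
    alpha2 = c(10, 13), beta1  = c(13, 20), beta2  = c(20, 30),
    gamma1 = c(30, 45), gamma2 = c(55, 90))
  out <- lapply(names(defs), function(nm) bandSpec(nm, defs[[nm]][1], defs[[nm]][2]))
  names(out) <- names(defs)
  out
}

#' Reference frequency of a band for cycle-based window sizing
#'
#' Sliding-window widths and steps are expressed in cycles of a band; this
#' maps a band to the frequency whose cycle is meant. The default is the
#' arithmetic band centre.
#'
#' @param band A [bandSpec()].
#' @param rule One of `"band_center_arithmetic"`, `"band_low"`, `"band_high"`.
#' @return Frequency in Hz.
#' @export
bandCycleFreq <- function(band, rule = c("band_center_arithmetic", "band_low", "band_high")) {
  rule <- match.arg(rule)
  switch(rule,
         band_center_arithmetic = (band$f_low + band$f_high) / 2,
         band_low = band$f_low,
         band_high = band$f_high)
}

#' @export
print.BandSpec <- function(x, ...) {
  cat(sprintf("<BandSpec> %s: %g-%g Hz\n", x$name, x$f_low, x$f_high))
  invisible(x)
}
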