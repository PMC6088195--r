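#' @import methods
NULL

# ---- FCGraph -----------------------------------------------------------------

#' Static functional connectivity graph
#'
#' An `FCGraph` holds one symmetric weighted connectivity matrix for one
#' recording, band and estimator. The diagonal is zero by construction;
#' imaginary phase-locking (`"iplv"`) weights lie in \[0, 1\].
#'
#' @slot w Symmetric numeric matrix with zero diagonal.
#' @slot estimator `"iplv"` or `"corenv"`.
#' @slot band A [bandSpec()] (stored as list).
#' @slot fs Sampling rate in Hz.
#' @export
setClass("FCGraph", representation(
  w = "matrix", estimator = "character", band = "list", fs = "numeric"))

setValidity("FCGraph", function(object) {
  w <- object@w
  if (!is.numeric(w) || nrow(w) != ncol(w)) return("w must be a square numeric matrix")
  if (!isSymmetricTol(w)) return("w must be symmetric within 1e-12")
  if (any(abs(diag(w)) > 1e-12)) return("diagonal of w must be zero")
  if (length(object@estimator) != 1L ||
      !object@estimator %in% c("iplv", "corenv"))
    return("estimator must be 'iplv' or 'corenv'")
  if (object@estimator == "iplv" && (min(w) < -1e-12 || max(w) > 1 + 1e-12))
    return("iplv weights must lie in [0, 1]")
  TRUE
})

#' Construct an FCGraph
#' @param w Symmetric weight matrix, zero diagonal.
#' @param estimator `"iplv"` or `"corenv"`.
#' @param band A [bandSpec()].
#' @param fs Sampling rate (Hz).
#' @return An [FCGraph-class] object.
#' @export
FCGraph <- function(w, estimator, band, fs) {
  new("FCGraph", w = cleanGraphMatrix(w), estimator = estimator,
      band = unclass(band), fs = fs)
}

#' @describeIn FCGraph-class connectivity matrix accessor
#' @param x,object An `FCGraph`.
#' @export
setGeneric("connMatrix", function(x) standardGeneric("connMatrix"))

#' @rdname FCGraph-class
#' @export
setMethod("connMatrix", "FCGraph", function(x) x@w)

#' @rdname FCGraph-class
#' @export
setGeneric("estimatorName", function(x) standardGeneric("estimatorName"))

#' @rdname FCGraph-class
#' @export
setMethod("estimatorName", "FCGraph", function(x) x@estimator)

setMethod("show", "FCGraph", function(object) {
  cat(sprintf("<FCGraph> %d nodes, estimator %s, band %s (%g-%g Hz)\n",
              nrow(object@w), object@estimator,
              object@band$name, object@band$f_low, object@band$f_high))
  cat(sprintf("  mean |edge| = %.4g, density(nonzero) = %.2f\n",
              mean(abs(upperTriVals(object@w))),
              mean(upperTriVals(object@w) != 0)))
})

# ---- DynamicFCGraph ----------------------------------------------------------

#' Sliding-window dynamic functional connectivity graph
#'
#' A `DynamicFCGraph` is a windows x n x n tensor of connectivity snapshots
#' plus the window plan (starts, width, step, all in samples). Each slice
#' satisfies the [FCGraph-class] invariants.
#'
#' @slot tensor Numeric array `n_windows x n x n`.
#' @slot windowStarts Integer vector of 1-based window start samples,
#'   strictly increasing with constant step.
#' @slot width,step Window width and step in samples.
#' @slot estimator,band,fs As in [FCGraph-class].
#' @export
setClass("DynamicFCGraph", representation(
  tensor = "array", windowStarts = "integer", width = "integer",
  step = "integer", estimator = "character", band = "list", fs = "numeric"))

setValidity("DynamicFCGraph", function(object) {
  d <- dim(object@tensor)
  if (length(d) != 3L || d[2] != d[3]) return("tensor must be n_windows x n x n")
  if (length(object@windowStarts) != d[1]) return("windowStarts length must match tensor")
  if (d[1] > 1) {
    df <- diff(object@windowStarts)
    if (any(df <= 0) || any(df != df[1]))
      return("windowStarts must be strictly increasing with constant step")
  }
  TRUE
})

#' @rdname DynamicFCGraph-class
#' @param x A `DynamicFCGraph`.
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' @rdname DynamicFCGraph-class
#' @export
setMethod("nWindows", "DynamicFCGraph", function(x) dim(x@tensor)[1])

#' @rdname DynamicFCGraph-class
#' @param w Window index.
#' @export
setGeneric("graphSlice", function(x, w) standardGeneric("graphSlice"))

#' @rdname DynamicFCGraph-class
#' @export
setMethod("graphSlice", "DynamicFCGraph", function(x, w) {
  m <- x@tensor[w, , , drop = TRUE]
  dim(m) <- dim(x@tensor)[2:3]
  m
})

setMethod("show", "DynamicFCGraph", function(object) {
  d <- dim(object@tensor)
  cat(sprintf("<DynamicFCGraph> %d windows x %d nodes, estimator %s, band %s\n",
              d[1], d[2], object@estimator, object@band$name))
  cat(sprintf("  width %d samples, step %d samples, fs %g Hz\n",
              object@width, object@step, object@fs))
})

# ---- Codebook ----------------------------------------------------------------

#' Microstate codebook from neural-gas vector quantization
#'
#' Prototype vectors over Laplacian eigenspectrum features, the hard
#' assignment of every pooled window to its nearest prototype, and the
#' relative reconstruction error E (percent).
#'
#' @slot prototypes `k x p` matrix of code vectors.
#' @slot assignments Integer vector, one label in `1..k` per pooled window.
#' @slot reconError Reconstruction error E in percent.
#' @slot seed Seed used for the fit.
#' @slot params Neural-gas hyperparameters.
#' @export
setClass("Codebook", representation(
  prototypes = "matrix", assignments = "integer", reconError = "numeric",
  seed = "numeric", params = "list"))

setValidity("Codebook", function(object) {
  if (length(object@assignments) &&
      (min(object@assignments) < 1L ||
       max(object@assignments) > nrow(object@prototypes)))
    return("assignments must index prototype rows")
  if (object@reconError < 0) return("reconstruction error must be >= 0")
  TRUE
})

#' @rdname Codebook-class
#' @param x A `Codebook`.
#' @export
setGeneric("prototypes", function(x) standardGeneric("prototypes"))

#' @rdname Codebook-class
#' @export
setMethod("prototypes", "Codebook", function(x) x@prototypes)

#' @rdname Codebook-class
#' @export
setGeneric("stateAssignments", function(x) standardGeneric("stateAssignments"))

#' @rdname Codebook-class
#' @export
setMethod("stateAssignments", "Codebook", function(x) x@assignments)

#' @rdname Codebook-class
#' @export
setGeneric("reconError", function(x) standardGeneric("reconError"))

#' @rdname Codebook-class
#' @export
setMethod("reconError", "Codebook", function(x) x@reconError)

#' @rdname Codebook-class
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @rdname Codebook-class
#' @export
setMethod("nStates", "Codebook", function(x) nrow(x@prototypes))

setMethod("show", "Codebook", function(object) {
  cat(sprintf("<Codebook> k = %d prototypes of dim %d, E = %.3f%%, %d windows assigned\n",
              nrow(object@prototypes), ncol(object@prototypes),
              object@reconError, length(object@assignments)))
})

# ---- Cohort ------------------------------------------------------------------

#' Synthetic multi-subject two-session cohort
#'
#' Band-limited ROI time series for `n_subjects x n_sessions x bands`, plus the
#' planted ground truth (state labels per analysis window, transition rates,
#' occupancy vectors and the state coupling templates) that the generator
#' embedded.
#'
#' @slot signals Nested list `signals[[subject]][[session]][[band]]`, each a
#'   `samples x n_rois` numeric matrix.
#' @slot config The [cohortConfig()] used.
#' @slot truth Ground-truth list (see [generateCohort()]).
#' @export
setClass("Cohort", representation(
  signals = "list", config = "list", truth = "list"))

#' @rdname Cohort-class
#' @param x A `Cohort`.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname Cohort-class
#' @export
setMethod("nSubjects", "Cohort", function(x) length(x@signals))

#' @rdname Cohort-class
#' @export
setGeneric("nSessions", function(x) standardGeneric("nSessions"))

#' @rdname Cohort-class
#' @export
setMethod("nSessions", "Cohort", function(x) length(x@signals[[1]]))

#' @rdname Cohort-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname Cohort-class
#' @export
setMethod("groundTruth", "Cohort", function(x) x@truth)

#' Extract one recording from a cohort
#' @param x A [Cohort-class].
#' @param subject,session,band Indices (band may be name or index).
#' @return `samples x n_rois` matrix.
#' @export
recordingMatrix <- function(x, subject, session, band = 1L) {
  x@signals[[subject]][[session]][[band]]
}

setMethod("show", "Cohort", function(object) {
  cfg <- object@config
  cat(sprintf("<Cohort> %d subjects x %d sessions, %d ROIs, %g s @ %g Hz, %d band(s), %d planted state(s)\n",
              length(object@signals), length(object@signals[[1]]),
              cfg$n_rois, cfg$duration, cfg$fs, length(cfg$bands),
              cfg$state_count))
})
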