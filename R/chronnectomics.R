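#' Transition rate of a microstate sequence
#'
#' Fraction of consecutive window pairs in which the state label changes:
#' `TR = transitions / (slides - 1)`.
#'
#' @param labels Integer state sequence (length `>= 2`).
#' @return Scalar in `[0, 1]`.
#' @export
transitionRate <- function(labels) {
  if (length(labels) < 2) stop("sequence must have length >= 2", call. = FALSE)
  sum(diff(as.integer(labels)) != 0) / (length(labels) - 1)
}

#' Occupancy times of the microstates
#'
#' Fraction of windows spent in each state; sums to 1.
#'
#' @param labels Integer state sequence.
#' @param k Number of states (`>= max(labels)`).
#' @return Numeric vector of length `k`.
#' @export
occupancy <- function(labels, k) {
  if (!length(labels)) stop("empty sequence", call. = FALSE)
  if (max(labels) > k) stop("labels exceed k", call. = FALSE)
  tabulate(as.integer(labels), k) / length(labels)
}

#' Test-retest correlation of a cohort metric
#'
#' Pearson (default) correlation between the per-subject values of the two
#' scan sessions, with its two-sided p-value. A Spearman switch exists.
#'
#' @param v1,v2 Paired per-subject vectors (length `>= 3`).
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r`, `p`, `n`; `r` is `NA` with a warning when either
#'   vector has zero variance.
#' @export
testRetest <- function(v1, v2, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(v1) != length(v2) || length(v1) < 3)
    stop("need paired vectors of length >= 3", call. = FALSE)
  if (sd(v1) == 0 || sd(v2) == 0) {
    warning("zero variance in a session vector; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(v1)))
  }
  ct <- suppressWarnings(cor.test(v1, v2, method = method))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(v1))
}

#' Per-ROI test-retest reliability of nodal metrics
#'
#' One correlation per ROI between the cohort's session-1 and session-2
#' values.
#'
#' @param s1,s2 `subjects x ROIs` matrices for the two sessions.
#' @param method Correlation type (see [testRetest()]).
#' @return List with `r` and `p` vectors of length `n_rois`.
#' @export
nodalReliability <- function(s1, s2, method = "pearson") {
  if (!all(dim(s1) == dim(s2)))
    stop("both sessions must cover the same subjects and ROIs", call. = FALSE)
  res <- lapply(seq_len(ncol(s1)), function(j) {
    if (sd(s1[, j]) == 0 || sd(s2[, j]) == 0)
      return(list(r = NA_real_, p = NA_real_))
    ct <- suppressWarnings(cor.test(s1[, j], s2[, j], method = method))
    list(r = unname(ct$estimate), p = ct$p.value)
  })
  list(r = vapply(res, `[[`, numeric(1), "r"),
       p = vapply(res, `[[`, numeric(1), "p"))
}

# OMST-filter every slice of a dynamic tensor. A statistically filtered slice
# that lost connectivity falls back to the unfiltered slice for the tree
# extraction (the trees need a connected support).
omstTensor <- function(tens, raw_tens = tens) {
  out <- tens
  for (w in seq_len(dim(tens)[1])) {
    Wm <- tens[w, , ]
    if (all(Wm == 0) || igraph::components(graphFromW(Wm))$no > 1)
      Wm <- raw_tens[w, , ]
    out[w, , ] <- omst(Wm)$w_filtered
  }
  out
}

#' Dynamic-branch chronnectomics for a whole cohort
#'
#' Runs the dynamic pipeline for one band and estimator on every recording:
#' sliding-window graphs, optional surrogate statistical filtering, OMST
#' topological filtering per window, Laplacian eigenspectrum features pooled
#' across subjects per session, per-session neural-gas codebooks (state count
#' selected on session 1 by the reconstruction-error criterion and reused for
#' session 2), cross-session codebook matching, and per-recording transition
#' rate, occupancy and transition matrices.
#'
#' @param cohort A [Cohort-class].
#' @param band_name Which band of the cohort to analyse.
#' @param estimator `"iplv"` or `"corenv"`.
#' @param width,step Window width/step in samples (default: the cohort's
#'   planted segment grid, so windows align with planted labels).
#' @param scheme Optional [surrogateScheme()]; `NULL` skips statistical
#'   filtering.
#' @param q FDR level for the statistical filter.
#' @param k_range,e_threshold State-count selection (see [selectK()]).
#' @param ng_params Neural-gas hyperparameters.
#' @param seed Seed for the codebook fits.
#' @return List: `tr` (`subjects x sessions`), `oc`
#'   (`subjects x sessions x k`), `labels` (nested), `codebooks`, `k`,
#'   `e_curve`, `perm` (session-2 state matching).
#' @export
dynamicChronnectomics <- function(cohort, band_name = 1L,
                                  estimator = "iplv",
                                  width = NULL, step = NULL,
                                  scheme = NULL, q = 0.01,
                                  k_range = 1:4, e_threshold = 4,
                                  ng_params = list(), seed = 1L) {
  cfg <- cohort@config
  band <- cfg$bands[[band_name]]
  if (is.null(width)) width <- cfg$segment_samples
  if (is.null(step)) step <- width
  ns <- nSubjects(cohort); ne <- nSessions(cohort)
  feats <- vector("list", ns)
  nw <- NULL
  for (s in seq_len(ns)) {
    feats[[s]] <- vector("list", ne)
    for (e in seq_len(ne)) {
      ts <- recordingMatrix(cohort, s, e, band_name)
      dfc <- dynamicFCG(ts, band, estimator, cfg$fs, width = width, step = step)
      tens <- dfc@tensor
      if (!is.null(scheme)) {
        filt <- statisticalFilter(dfc, ts, scheme, q)
        tens <- omstTensor(abs(filt$graph@tensor), abs(dfc@tensor))
      } else {
        tens <- omstTensor(abs(tens))
      }
      feats[[s]][[e]] <- eigenFeatures(tens)
      nw <- nrow(feats[[s]][[e]])
    }
  }
  pool <- function(e) do.call(rbind, lapply(feats, `[[`, e))
  X1 <- pool(1)
  sel <- selectK(X1, k_range, e_threshold, ng_params, seed = mixSeed(seed, 101L))
  k <- sel$k
  cbs <- vector("list", ne)
  cbs[[1]] <- sel$codebook
  if (ne > 1) for (e in 2:ne)
    cbs[[e]] <- neuralGasFit(pool(e), k, ng_params, seed = mixSeed(seed, 100L + e))
  perm <- if (ne > 1) matchCodebooks(cbs[[1]], cbs[[2]]) else seq_len(k)
  labels <- vector("list", ns)
  tr <- matrix(NA_real_, ns, ne)
  oc <- array(NA_real_, c(ns, ne, k))
  for (s in seq_len(ns)) {
    labels[[s]] <- vector("list", ne)
    for (e in seq_len(ne)) {
      lab <- assignSymbols(feats[[s]][[e]], cbs[[e]])
      if (e > 1) lab <- perm[lab]          # express in session-1 state space
      labels[[s]][[e]] <- lab
      tr[s, e] <- transitionRate(lab)
      oc[s, e, ] <- occupancy(lab, k)
    }
  }
  list(tr = tr, oc = oc, labels = labels, codebooks = cbs, k = k,
       e_curve = sel$e_curve, perm = perm, n_windows = nw,
       features = feats)
}

#' Static-branch nodal metrics and distances for a whole cohort
#'
#' Static graph per recording, optional statistical filter, OMST, nodal
#' metrics (global/local efficiency, strength, shortest-path passage
#' probability), plus the pairwise graph diffusion distance matrix over all
#' recordings and its 2D MDS projection.
#'
#' @inheritParams dynamicChronnectomics
#' @param passage Compute the random-walk passage metric (default TRUE).
#' @return List: `metrics[[metric]]` as `subjects x sessions x ROIs` arrays,
#'   `gdd` distance matrix (recordings ordered subject-major), `mds`
#'   embedding, `graphs` (filtered static matrices).
#' @export
staticCohortMetrics <- function(cohort, band_name = 1L, estimator = "iplv",
                                scheme = NULL, q = 0.01, passage = TRUE) {
  cfg <- cohort@config
  band <- cfg$bands[[band_name]]
  ns <- nSubjects(cohort); ne <- nSessions(cohort)
  n <- cfg$n_rois
  metrics <- list(ge = array(NA_real_, c(ns, ne, n)),
                  le = array(NA_real_, c(ns, ne, n)),
                  strength = array(NA_real_, c(ns, ne, n)))
  if (passage) metrics$passage <- array(NA_real_, c(ns, ne, n))
  graphs <- list()
  for (s in seq_len(ns)) for (e in seq_len(ne)) {
    ts <- recordingMatrix(cohort, s, e, band_name)
    g <- staticFCG(ts, band, estimator, cfg$fs)
    w <- abs(connMatrix(g))
    if (!is.null(scheme)) {
      wf <- abs(connMatrix(statisticalFilter(g, ts, scheme, q)$graph))
      if (any(wf > 0) && igraph::components(graphFromW(wf))$no == 1) w <- wf
    }
    w <- omst(w)$w_filtered
    nm <- nodalMetrics(w)
    metrics$ge[s, e, ] <- nm$ge
    metrics$le[s, e, ] <- nm$le
    metrics$strength[s, e, ] <- nm$strength
    if (passage) {
      pp <- passageProbability(w)
      metrics$passage[s, e, ] <- rowSums(pp$pi) / (n - 1)
    }
    graphs[[sprintf("sub%d_ses%d", s, e)]] <- w
  }
  D <- gddMatrix(graphs)
  list(metrics = metrics, gdd = D, mds = mdsEmbed(D), graphs = graphs)
}

#' Optimize sliding-window width and step by transition-rate reliability
#'
#' Evaluates an objective (by default: run the dynamic pipeline and return
#' the cohort's test-retest correlation of the transition rate) over a grid
#' of window widths and steps expressed in band cycles, and returns the
#' argmax; ties break toward the smaller width, then the smaller step. The
#' default grid is widths 1-10 cycles in 0.5 steps (19) by steps 0.1-2
#' cycles in 0.1 steps (20), i.e. 380 evaluations.
#'
#' @param cohort A [Cohort-class] (ignored when `objective` is supplied).
#' @param band_name,estimator Passed to the pipeline objective.
#' @param widths,steps Grid values in band cycles.
#' @param objective Optional `function(width_cycles, step_cycles)`
#'   returning the scalar to maximize; the default runs
#'   [dynamicChronnectomics()] with the cycle values converted to samples.
#' @param ... Passed to [dynamicChronnectomics()] in the default objective.
#' @return List with `width_cycles`, `step_cycles`, and the full `surface`
#'   (widths x steps matrix of objective values).
#' @export
optimizeWindow <- function(cohort = NULL, band_name = 1L, estimator = "iplv",
                           widths = seq(1, 10, by = 0.5),
                           steps = seq(0.1, 2, by = 0.1),
                           objective = NULL, ...) {
  if (is.null(objective)) {
    cfg <- cohort@config
    band <- cfg$bands[[band_name]]
    f_ref <- bandCycleFreq(band)
    n_samp <- round(cfg$duration * cfg$fs)
    objective <- function(wc, sc) {
      w <- max(2L, round(wc / f_ref * cfg$fs))
      st <- max(1L, round(sc / f_ref * cfg$fs))
      if (w > n_samp || st >= w) return(NA_real_)
      res <- dynamicChronnectomics(cohort, band_name, estimator,
                                   width = w, step = st, ...)
      testRetest(res$tr[, 1], res$tr[, 2])$r
    }
  }
  surface <- matrix(NA_real_, length(widths), length(steps),
                    dimnames = list(widths, steps))
  for (i in seq_along(widths)) for (j in seq_along(steps))
    surface[i, j] <- objective(widths[i], steps[j])
  best <- which(surface == max(surface, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(width_cycles = widths[best[1]], step_cycles = steps[best[2]],
       surface = surface)
}

#' Run the full static + dynamic reliability study on a cohort
#'
#' Orchestrates both branches for each requested band and estimator and
#' collates a reliability report: per-ROI test-retest correlations of the
#' nodal metrics, the graph-diffusion-distance MDS projection of all static
#' graphs, and the chronnectomic reliabilities (transition rate and
#' per-matched-state occupancy).
#'
#' @param cohort A [Cohort-class] (or a [cohortConfig()] to synthesize one).
#' @param bands Band names/indices to analyse (default: all in the cohort).
#' @param estimators Estimators to run (default `"iplv"`).
#' @param scheme Optional [surrogateScheme()] for statistical filtering.
#' @param q FDR level.
#' @param static Run the static branch (default TRUE).
#' @param ... Passed to [dynamicChronnectomics()].
#' @param seed Seed for the codebook fits.
#' @return A `ReliabilityReport` list (see Details) with per band x estimator
#'   entries and provenance (config, seed).
#' @export
runStudy <- function(cohort, bands = NULL, estimators = "iplv",
                     scheme = NULL, q = 0.01, static = TRUE, seed = 1L, ...) {
  if (inherits(cohort, "CohortConfig")) cohort <- generateCohort(cohort)
  cfg <- cohort@config
  if (is.null(bands)) bands <- seq_along(cfg$bands)
  report <- list(results = list(),
                 provenance = list(
                   n_subjects = nSubjects(cohort), n_sessions = nSessions(cohort),
                   n_rois = cfg$n_rois, fs = cfg$fs, duration = cfg$duration,
                   seed = seed))
  for (b in bands) for (est in estimators) {
    bn <- cfg$bands[[b]]$name
    key <- paste(bn, est, sep = ".")
    entry <- list(band = bn, estimator = est)
    dyn <- dynamicChronnectomics(cohort, b, est, scheme = scheme, q = q,
                                 seed = seed, ...)
    entry$k <- dyn$k
    entry$e_curve <- dyn$e_curve
    entry$tr <- dyn$tr
    entry$oc <- dyn$oc
    entry$tr_reliability <- testRetest(dyn$tr[, 1], dyn$tr[, 2])
    entry$oc_reliability <- lapply(seq_len(dyn$k), function(st)
      testRetest(dyn$oc[, 1, st], dyn$oc[, 2, st]))
    if (static) {
      st <- staticCohortMetrics(cohort, b, est, scheme = scheme, q = q)
      entry$nodal_reliability <- lapply(st$metrics, function(m)
        nodalReliability(m[, 1, ], m[, 2, ]))
      entry$mds_stress <- st$mds$stress
      entry$gdd_mean <- mean(st$gdd[upper.tri(st$gdd)])
    }
    report$results[[key]] <- entry
  }
  class(report) <- "ReliabilityReport"
  report
}
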