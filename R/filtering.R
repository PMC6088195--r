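#' Single-cut surrogate scheme
#'
#' Surrogates are generated by cutting the original series at one random
#' point and exchanging the two resulting blocks, which preserves the sample
#' multiset and minimally distorts the phase dynamics. Cut points are drawn
#' uniformly from a window of `cut_halfwidth` seconds on either side of the
#' recording midpoint.
#'
#' @param n_surrogates Number of surrogates (default 200; the conventional
#'   large-cohort setting of 1000 is selectable).
#' @param cut_halfwidth Half-width of the cut window in seconds (default 10).
#' @param seed Seed for the cut draws.
#' @return A `SurrogateScheme` list.
#' @export
surrogateScheme <- function(n_surrogates = 200L, cut_halfwidth = 10, seed = 1L) {
  if (n_surrogates < 19) stop("need at least 19 surrogates", call. = FALSE)
  if (cut_halfwidth <= 0) stop("cut_halfwidth must be positive", call. = FALSE)
  structure(list(n_surrogates = as.integer(n_surrogates),
                 cut_halfwidth = cut_halfwidth, seed = as.integer(seed)),
            class = "SurrogateScheme")
}

# Cut points (in samples) for all draws of a scheme, reproducible.
surrogateCuts <- function(scheme, n_samples, fs) {
  hw <- round(scheme$cut_halfwidth * fs)
  mid <- n_samples %/% 2
  lo <- mid - hw; hi <- mid + hw
  if (lo < 1 || hi >= n_samples)
    stop("cut window does not fit within the recording", call. = FALSE)
  withSeed(scheme$seed, sample(lo:hi, scheme$n_surrogates, replace = TRUE))
}

#' One single-cut surrogate of a time series
#'
#' @param x Numeric vector.
#' @param scheme A [surrogateScheme()].
#' @param draw Which surrogate draw (1-based index into the scheme's cuts).
#' @param fs Sampling rate in Hz (to convert the cut window to samples).
#' @return Numeric vector: the two blocks of `x` around the drawn cut point,
#'   exchanged. The sample multiset is preserved.
#' @export
surrogateSeries <- function(x, scheme, draw = 1L, fs) {
  cuts <- surrogateCuts(scheme, length(x), fs)
  cut <- cuts[draw]
  c(x[(cut + 1L):length(x)], x[seq_len(cut)])
}

#' One-sided surrogate p-value for an edge
#'
#' `p = #\{surrogate >= observed\} / n_surrogates`; ties count against the
#' observed value.
#'
#' @param observed Observed coupling value.
#' @param surrogate_values Numeric vector of at least 19 surrogate values.
#' @return p-value in `[0, 1]`.
#' @export
edgePValue <- function(observed, surrogate_values) {
  if (length(surrogate_values) < 19)
    stop("need at least 19 surrogate values", call. = FALSE)
  mean(surrogate_values >= observed)
}

#' Benjamini-Hochberg keep-mask
#'
#' Step-up false-discovery-rate control at level `q` over one graph
#' snapshot's edge set (wraps [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values.
#' @param q FDR level (default 0.01).
#' @return Logical keep-mask of the same length.
#' @export
fdrBH <- function(p_values, q = 0.01) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values outside [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH") <= q
}

# Per-edge surrogate coupling distributions from the full-length recording.
# For iPLV all cuts are obtained at once per pair via the circular
# cross-correlation of the unit phasors (a block exchange is a circular
# rotation); for CorEnv each cut rotates the band-limited driver and the
# estimator is re-evaluated.
surrogateEdgeDistributions <- function(pre, estimator, cuts, smooth_samples) {
  n <- ncol(pre$filtered)
  T_len <- nrow(pre$filtered)
  n_pairs <- n * (n - 1) / 2
  out <- matrix(0, length(cuts), n_pairs)
  pair <- 0L
  if (estimator == "iplv") {
    z <- exp(1i * Arg(pre$analytic))
    Fz <- stats::mvfft(z)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      pair <- pair + 1L
      r <- fft(Fz[, i] * Conj(Fz[, j]), inverse = TRUE) / T_len
      out[, pair] <- abs(Im(r[cuts + 1L])) / T_len
    }
  } else {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      pair <- pair + 1L
      for (s in seq_along(cuts)) {
        idx <- c((cuts[s] + 1L):T_len, seq_len(cuts[s]))
        out[s, pair] <- corenvPair(pre$filtered[idx, i], pre$filtered[, j],
                                   pre$analytic[idx, i], pre$analytic[, j],
                                   smooth_samples)
      }
    }
  }
  out
}

#' Statistical filtering of connectivity graphs by surrogate testing
#'
#' Computes, once per recording, a per-edge null distribution of coupling
#' values from single-cut surrogates of the full-length series, derives a
#' one-sided p-value for every edge of every snapshot, applies
#' Benjamini-Hochberg FDR at level `q` within each snapshot, and zeroes
#' non-significant edges. For dynamic graphs the same full-recording null is
#' reused across all windows.
#'
#' @param graph An [FCGraph-class] or [DynamicFCGraph-class].
#' @param roi_ts The `samples x n_rois` series the graph was estimated from.
#' @param scheme A [surrogateScheme()].
#' @param q FDR level (default 0.01).
#' @param smooth_samples Envelope smoothing for `"corenv"`.
#' @return List with `graph` (same class, non-significant edges zeroed),
#'   `p` (edge p-value matrix, or `windows x n x n` array), and
#'   `test` metadata (one-sided on the signed value).
#' @export
statisticalFilter <- function(graph, roi_ts, scheme, q = 0.01,
                              smooth_samples = NULL) {
  band <- do.call(bandSpec, graph@band[c("name", "f_low", "f_high")])
  fs <- graph@fs
  pre <- prepareRoiSignals(roi_ts, band, fs)
  cuts <- surrogateCuts(scheme, nrow(roi_ts), fs)
  if (is.null(smooth_samples)) smooth_samples <- max(1L, round(fs / 2))
  sur <- surrogateEdgeDistributions(pre, graph@estimator, cuts, smooth_samples)
  n <- ncol(roi_ts)
  ut <- which(upper.tri(matrix(0, n, n)))
  if (is(graph, "FCGraph")) {
    w <- graph@w
    p_vec <- vapply(seq_along(ut), function(k)
      mean(sur[, k] >= w[ut[k]]), numeric(1))
    keep <- fdrBH(p_vec, q)
    w_f <- matrix(0, n, n)
    w_f[ut] <- ifelse(keep, w[ut], 0)
    w_f <- w_f + t(w_f)
    p_m <- matrix(0, n, n); p_m[ut] <- p_vec; p_m <- p_m + t(p_m)
    out_g <- FCGraph(w_f, graph@estimator, band, fs)
    return(list(graph = out_g, p = p_m,
                test = list(sided = "one-sided-signed", q = q,
                            n_surrogates = scheme$n_surrogates)))
  }
  tens <- graph@tensor
  p_arr <- array(0, dim(tens))
  for (wi in seq_len(dim(tens)[1])) {
    slice <- tens[wi, , ]
    p_vec <- vapply(seq_along(ut), function(k)
      mean(sur[, k] >= slice[ut[k]]), numeric(1))
    keep <- fdrBH(p_vec, q)
    w_f <- matrix(0, n, n)
    w_f[ut] <- ifelse(keep, slice[ut], 0)
    tens[wi, , ] <- w_f + t(w_f)
    p_m <- matrix(0, n, n); p_m[ut] <- p_vec
    p_arr[wi, , ] <- p_m + t(p_m)
  }
  out_g <- new("DynamicFCGraph", tensor = tens,
               windowStarts = graph@windowStarts, width = graph@width,
               step = graph@step, estimator = graph@estimator,
               band = graph@band, fs = fs)
  list(graph = out_g, p = p_arr,
       test = list(sided = "one-sided-signed", q = q,
                   n_surrogates = scheme$n_surrogates))
}

graphFromW <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# Global efficiency of a weight matrix: mean over ordered pairs of 1/d with
# shortest-path distances on 1/w; disconnected pairs contribute 0.
globalEfficiencyW <- function(W) {
  if (all(W == 0)) return(0)
  g <- graphFromW(W)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  mean(inv[row(inv) != col(inv)])
}

#' Topological filtering by orthogonal minimal spanning trees
#'
#' Iteratively extracts edge-disjoint maximum-weight spanning trees
#' (minimum-distance trees on `1/w`), accumulating them into a selection, and
#' after each round evaluates the quality function `J = GE - Cost`, where `GE`
#' is the selection's global efficiency (distances `1/w`) and `Cost` is the
#' ratio of selected to total edge weight. The returned selection is the
#' cumulative prefix of rounds maximizing `J`; it is always connected.
#'
#' @param W Nonnegative symmetric weight matrix, connected on its nonzero
#'   support.
#' @param max_rounds Optional cap on the number of tree rounds.
#' @return List: `w_filtered` (selected weights), `rounds_used`, `j_curve`
#'   (J per candidate round), `ge`, `cost`.
#' @export
omst <- function(W, max_rounds = Inf) {
  if (!isSymmetricTol(W, 1e-9)) stop("input must be symmetric", call. = FALSE)
  if (any(W < 0)) stop("weights must be nonnegative", call. = FALSE)
  W <- cleanGraphMatrix(W)
  n <- nrow(W)
  comp <- igraph::components(graphFromW(W))
  if (comp$no > 1)
    stop(sprintf("input graph is disconnected (%d components of sizes %s)",
                 comp$no, paste(comp$csize, collapse = ", ")), call. = FALSE)
  total <- sum(W) / 2
  Wrem <- W
  sel <- matrix(0, n, n)
  j_curve <- ge_curve <- cost_curve <- numeric(0)
  round_edges <- list()
  r <- 0L
  repeat {
    if (r >= max_rounds) break
    g <- graphFromW(Wrem)
    if (igraph::components(g)$no > 1 || igraph::ecount(g) < n - 1) break
    tree <- igraph::mst(g, weights = 1 / igraph::E(g)$weight)
    el <- igraph::as_edgelist(tree, names = FALSE)
    r <- r + 1L
    round_edges[[r]] <- el
    for (k in seq_len(nrow(el))) {
      i <- el[k, 1]; j <- el[k, 2]
      sel[i, j] <- sel[j, i] <- W[i, j]
      Wrem[i, j] <- Wrem[j, i] <- 0
    }
    ge_r <- globalEfficiencyW(sel)
    cost_r <- sum(sel) / 2 / total
    ge_curve <- c(ge_curve, ge_r)
    cost_curve <- c(cost_curve, cost_r)
    j_curve <- c(j_curve, ge_r - cost_r)
  }
  if (r == 0L) stop("no spanning tree could be extracted", call. = FALSE)
  best <- which.max(j_curve)
  w_f <- matrix(0, n, n)
  for (rr in seq_len(best)) {
    el <- round_edges[[rr]]
    for (k in seq_len(nrow(el))) {
      i <- el[k, 1]; j <- el[k, 2]
      w_f[i, j] <- w_f[j, i] <- W[i, j]
    }
  }
  list(w_filtered = w_f, rounds_used = best, j_curve = j_curve,
       ge = ge_curve[best], cost = cost_curve[best])
}
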