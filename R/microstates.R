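#' Graph Laplacian
#'
#' `L = D - A`, where `D` is the diagonal strength (weighted degree) matrix
#' of the symmetric nonnegative adjacency `A`. Row sums are zero and the
#' matrix is positive semidefinite.
#'
#' @param W Symmetric nonnegative weight matrix.
#' @return `n x n` Laplacian matrix.
#' @export
laplacianMatrix <- function(W) {
  if (!isSymmetricTol(W, 1e-9)) stop("input must be symmetric", call. = FALSE)
  W <- cleanGraphMatrix(W)
  diag(rowSums(W)) - W
}

#' Laplacian eigenspectrum features of a dynamic graph
#'
#' One ascending-sorted Laplacian eigenvalue vector per window. Spectra are
#' invariant under node permutations, which is what makes them a compact,
#' alignment-free descriptor of the evolving network topology. Each snapshot
#' must be connected (guaranteed after OMST filtering).
#'
#' @param dfc A [DynamicFCGraph-class], or a `windows x n x n` array.
#' @return `n_windows x n` matrix of sorted eigenvalues.
#' @export
eigenFeatures <- function(dfc) {
  tens <- if (is(dfc, "DynamicFCGraph")) dfc@tensor else dfc
  nw <- dim(tens)[1]; n <- dim(tens)[2]
  X <- matrix(0, nw, n)
  for (w in seq_len(nw)) {
    Wm <- tens[w, , ]
    if (igraph::components(graphFromW(Wm))$no > 1)
      stop(sprintf("window %d snapshot is disconnected", w), call. = FALSE)
    X[w, ] <- sort(eigen(laplacianMatrix(Wm), symmetric = TRUE,
                         only.values = TRUE)$values)
  }
  X
}

#' Neural-gas vector quantization of pooled window features
#'
#' Fits `k` prototype vectors to the pooled feature rows with the neural-gas
#' learning rule: for each presented sample all prototypes are ranked by
#' distance and moved toward it with a soft-max factor `exp(-rank/lambda)`,
#' with neighborhood range `lambda` and step size `eps` decaying
#' exponentially over the run. Deterministic under a fixed seed.
#'
#' @param X `n_windows x p` feature matrix (windows pooled across subjects).
#' @param k Number of prototypes (`1 <= k <= n_windows`).
#' @param params Hyperparameters: `epochs` (50), `lambda0` (10), `lambdaF`
#'   (0.01), `eps0` (0.5), `epsF` (0.005), `polish` (TRUE).
#' @param seed Seed for initialization and presentation order.
#' @details After the annealed gas run, a deterministic centroid (Lloyd)
#'   polish is applied by default: prototypes move to the mean of their
#'   assigned rows, and a prototype left without members is relocated to the
#'   currently worst-reconstructed row, until assignments stabilize. This is
#'   the standard finishing step for vector quantization; it makes exactly
#'   representable configurations (e.g. `k` zero-variance clusters) exact
#'   and never increases the reconstruction error. Disable with
#'   `params$polish = FALSE` to inspect the raw gas solution.
#' @return A [Codebook-class] with prototypes, hard assignments and the
#'   reconstruction error E (percent).
#' @export
neuralGasFit <- function(X, k, params = list(), seed = 1L) {
  X <- as.matrix(X)
  nw <- nrow(X)
  if (k < 1 || k > nw) stop("k must lie in [1, n_windows]", call. = FALSE)
  p <- modifyList(list(epochs = 50L, lambda0 = 10, lambdaF = 0.01,
                       eps0 = 0.5, epsF = 0.005, polish = TRUE), params)
  withSeed(seed, {
    P <- X[sample.int(nw, k), , drop = FALSE]
    tmax <- p$epochs * nw
    step <- 0
    for (ep in seq_len(p$epochs)) {
      ord <- sample.int(nw)
      for (i in ord) {
        frac <- step / tmax
        lambda <- p$lambda0 * (p$lambdaF / p$lambda0)^frac
        eps <- p$eps0 * (p$epsF / p$eps0)^frac
        x <- X[i, ]
        d2 <- rowSums((P - matrix(x, k, ncol(P), byrow = TRUE))^2)
        ranks <- rank(d2, ties.method = "first") - 1
        h <- eps * exp(-ranks / lambda)
        P <- P + h * (matrix(x, k, ncol(P), byrow = TRUE) - P)
        step <- step + 1
      }
    }
    if (isTRUE(p$polish)) P <- lloydPolish(X, P)
    assign <- nearestPrototype(X, P)
    cb <- new("Codebook", prototypes = P, assignments = assign,
              reconError = 0, seed = as.numeric(seed), params = p)
    cb@reconError <- reconstructionError(X, cb)
    cb
  })
}

# Deterministic centroid refinement with empty-unit repair.
lloydPolish <- function(X, P, maxit = 25L) {
  k <- nrow(P)
  prev <- integer(0)
  for (it in seq_len(maxit)) {
    assign <- nearestPrototype(X, P)
    err <- rowSums((X - P[assign, , drop = FALSE])^2)
    for (j in seq_len(k)) {
      if (!any(assign == j)) {           # dead unit -> worst-served row
        worst <- which.max(err)
        P[j, ] <- X[worst, ]
        assign[worst] <- j
        err[worst] <- -Inf               # not available to another dead unit
      }
    }
    for (j in seq_len(k))
      if (any(assign == j))
        P[j, ] <- colMeans(X[assign == j, , drop = FALSE])
    if (identical(assign, prev)) break
    prev <- assign
  }
  P
}

nearestPrototype <- function(X, P) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(P))) - 2 * X %*% t(P) +
    outer(rep(1, nrow(X)), rowSums(P^2))
  max.col(-d2, ties.method = "first")
}

#' Reconstruction error of a codebook
#'
#' `E = 100 * ||X - Xhat||_F / ||X||_F`, where `Xhat` replaces every feature
#' row by its assigned prototype. The percentage quantifies how much of the
#' dynamic repertoire the `k` microstates fail to capture.
#'
#' @param X Feature matrix.
#' @param codebook A [Codebook-class] with assignments for the rows of `X`.
#' @return E in percent.
#' @export
reconstructionError <- function(X, codebook) {
  X <- as.matrix(X)
  nx <- sqrt(sum(X^2))
  if (nx == 0) stop("zero-norm feature matrix", call. = FALSE)
  Xhat <- prototypes(codebook)[stateAssignments(codebook), , drop = FALSE]
  100 * sqrt(sum((X - Xhat)^2)) / nx
}

#' Select the number of microstates by the reconstruction-error criterion
#'
#' Fits codebooks for increasing `k` and returns the smallest `k` whose
#' reconstruction error falls below `e_threshold` percent (default 4). The
#' full E-vs-k curve is returned for plateau inspection; if no `k` satisfies
#' the criterion the largest is returned with a warning.
#'
#' @param X Feature matrix.
#' @param k_range Candidate state counts (default `1:6`).
#' @param e_threshold Error threshold in percent (default 4).
#' @param params,seed Passed to [neuralGasFit()].
#' @return List with `k`, `codebook`, and `e_curve` (named by k).
#' @export
selectK <- function(X, k_range = 1:6, e_threshold = 4, params = list(), seed = 1L) {
  if (!length(k_range)) stop("k_range must be nonempty", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  e_curve <- numeric(0)
  books <- list()
  chosen <- NULL
  for (k in k_range) {
    cb <- neuralGasFit(X, k, params, seed = mixSeed(seed, k))
    e_curve[as.character(k)] <- reconError(cb)
    books[[as.character(k)]] <- cb
    if (is.null(chosen) && reconError(cb) < e_threshold) chosen <- k
  }
  if (is.null(chosen)) {
    warning("no k in k_range meets the reconstruction-error criterion; returning the largest")
    chosen <- max(k_range)
  }
  list(k = chosen, codebook = books[[as.character(chosen)]], e_curve = e_curve)
}

#' Assign windows to microstates
#'
#' Nearest-prototype (Euclidean) labels for new feature rows; ties go to the
#' lowest prototype index.
#'
#' @param X Feature matrix (`p` must match the codebook).
#' @param codebook A [Codebook-class].
#' @return Integer vector of state labels in `1..k`.
#' @export
assignSymbols <- function(X, codebook) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(prototypes(codebook)))
    stop("feature dimension does not match the codebook", call. = FALSE)
  nearestPrototype(X, prototypes(codebook))
}

#' Match the states of two codebooks
#'
#' Finds the permutation of the second codebook's states minimizing the total
#' Euclidean distance between matched prototypes (exhaustive over
#' permutations, `k <= 8`). Needed to compare per-state quantities across
#' independently fitted codebooks (e.g. session 1 vs session 2).
#'
#' @param cb1,cb2 [Codebook-class] objects with equal `k`.
#' @return Integer permutation `perm` such that state `j` of `cb2` matches
#'   state `perm[j]` of `cb1`... i.e. `prototypes(cb2)[j, ]` corresponds to
#'   `prototypes(cb1)[perm[j], ]`.
#' @export
matchCodebooks <- function(cb1, cb2) {
  k <- nStates(cb1)
  if (k != nStates(cb2)) stop("codebooks have different k", call. = FALSE)
  if (k > 8) stop("exhaustive matching supports k <= 8", call. = FALSE)
  P1 <- prototypes(cb1); P2 <- prototypes(cb2)
  best <- NULL; best_cost <- Inf
  for (perm in allPermutations(k)) {
    cost <- sum(sqrt(rowSums((P2 - P1[perm, , drop = FALSE])^2)))
    if (cost < best_cost) { best_cost <- cost; best <- perm }
  }
  best
}

#' First-order transition-probability matrix of a state sequence
#'
#' Counts consecutive label pairs and row-normalizes. The diagonal is the
#' persistence probability (fraction of windows in which the state is
#' retained); rows of states never visited are left as zero and flagged.
#'
#' @param labels Integer state sequence (length `>= 2`).
#' @param k Number of states (`>= max(labels)`).
#' @return List with `tp` (`k x k` matrix) and `visited` (logical per state).
#' @export
transitionMatrixOf <- function(labels, k) {
  if (length(labels) < 2) stop("sequence must have length >= 2", call. = FALSE)
  if (max(labels) > k) stop("labels exceed k", call. = FALSE)
  counts <- matrix(0, k, k)
  for (i in seq_len(length(labels) - 1))
    counts[labels[i], labels[i + 1]] <- counts[labels[i], labels[i + 1]] + 1
  rs <- rowSums(counts)
  tp <- counts
  for (r in seq_len(k)) if (rs[r] > 0) tp[r, ] <- counts[r, ] / rs[r]
  list(tp = tp, visited = rs > 0)
}

#' Per-state mean connectivity topology
#'
#' Element-wise mean of the dynamic graph slices assigned to each state: the
#' prototypical network configuration of each microstate.
#'
#' @param dfc A [DynamicFCGraph-class] or `windows x n x n` array.
#' @param labels State label per window.
#' @param k Number of states.
#' @return List of `k` symmetric mean matrices (zero with a warning for
#'   states that own no window).
#' @export
prototypeTopologies <- function(dfc, labels, k = max(labels)) {
  tens <- if (is(dfc, "DynamicFCGraph")) dfc@tensor else dfc
  if (dim(tens)[1] != length(labels))
    stop("label count must match window count", call. = FALSE)
  n <- dim(tens)[2]
  lapply(seq_len(k), function(s) {
    idx <- which(labels == s)
    if (!length(idx)) {
      warning(sprintf("state %d owns no window; returning zero graph", s))
      return(matrix(0, n, n))
    }
    m <- apply(tens[idx, , , drop = FALSE], c(2, 3), mean)
    cleanGraphMatrix(m)
  })
}

#' Aggregate a ROI graph into a network-of-networks matrix
#'
#' Sums edge weights within and between canonical resting-state networks
#' (e.g. DMN, FPN, occipital, sensorimotor, cingulo-opercular): the diagonal
#' holds summed within-network strength, off-diagonals summed
#' between-network strength; every undirected edge is counted once, so the
#' cells sum to the graph's total edge weight.
#'
#' @param W Symmetric weight matrix.
#' @param partition Factor/character vector mapping every ROI to a network.
#'   An editable synthetic example partition for a 90-ROI atlas ships as
#'   `system.file("extdata", "network_partition_synthetic.tsv",
#'   package = "chronconn")` (two columns: roi_label, network); real analyses
#'   should substitute their atlas's mapping.
#' @return `m x m` symmetric aggregate matrix with network names.
#' @export
aggregateNetworks <- function(W, partition) {
  if (length(partition) != nrow(W))
    stop("every ROI must be mapped to a network", call. = FALSE)
  if (anyNA(partition)) stop("unmapped ROI in partition", call. = FALSE)
  nets <- sort(unique(as.character(partition)))
  m <- length(nets)
  agg <- matrix(0, m, m, dimnames = list(nets, nets))
  idx <- match(as.character(partition), nets)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  for (k in seq_len(nrow(ut))) {
    a <- idx[ut[k, 1]]; b <- idx[ut[k, 2]]
    if (a == b) agg[a, a] <- agg[a, a] + W[ut[k, 1], ut[k, 2]]
    else {
      agg[a, b] <- agg[a, b] + W[ut[k, 1], ut[k, 2]]
      agg[b, a] <- agg[a, b]
    }
  }
  agg
}

#' Normalize a collection of aggregate matrices to a common maximum of 1
#'
#' @param aggs List of matrices from [aggregateNetworks()] (e.g. across bands
#'   and microstates).
#' @return List of matrices scaled by the collection-wide maximum.
#' @export
normalizeAggregates <- function(aggs) {
  mx <- max(vapply(aggs, max, numeric(1)))
  if (mx <= 0) return(aggs)
  lapply(aggs, function(a) a / mx)
}
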