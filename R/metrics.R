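#' Nodal and global efficiency and strength of a weighted graph
#'
#' Shortest paths use the edge-to-distance map `1/w`. Nodal global efficiency
#' of node i is the mean of `1/d_ij` over the other nodes; nodal local
#' efficiency is the efficiency of the subgraph induced by i's first
#' neighbors; strength is the row sum of weights. Disconnected pairs
#' contribute `1/Inf = 0`.
#'
#' @param W Nonnegative symmetric weight matrix (`n >= 2`).
#' @return List with `ge` (per-node), `le` (per-node), `strength`, and the
#'   global means `ge_global`, `le_global`.
#' @export
nodalMetrics <- function(W) {
  if (any(W < 0)) stop("negative weights are not allowed", call. = FALSE)
  if (!isSymmetricTol(W, 1e-9)) stop("input must be symmetric", call. = FALSE)
  W <- cleanGraphMatrix(W)
  n <- nrow(W)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  g <- graphFromW(W)
  wts <- igraph::E(g)$weight
  d <- if (length(wts)) igraph::distances(g, weights = 1 / wts) else
    matrix(Inf, n, n)
  inv <- 1 / d; diag(inv) <- 0
  ge <- rowSums(inv) / (n - 1)
  le <- vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    k_i <- length(nb)
    if (k_i < 2) return(0)
    sub <- W[nb, nb, drop = FALSE]
    gs <- graphFromW(sub)
    ws <- igraph::E(gs)$weight
    ds <- if (length(ws)) igraph::distances(gs, weights = 1 / ws) else
      matrix(Inf, k_i, k_i)
    invs <- 1 / ds; diag(invs) <- 0
    sum(invs) / (k_i * (k_i - 1))
  }, numeric(1))
  list(ge = ge, le = le, strength = rowSums(W),
       ge_global = mean(ge), le_global = mean(le))
}

# Hop counts along minimal-1/w-distance paths, ties broken toward fewer hops:
# the smallest L such that a path of <= L edges attains the weighted shortest
# distance (min-plus dynamic programme).
shortestPathHops <- function(W) {
  n <- nrow(W)
  A <- ifelse(W > 0, 1 / W, Inf); diag(A) <- 0
  g <- graphFromW(W)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  hops <- matrix(NA_integer_, n, n); diag(hops) <- 0L
  Dk <- A
  tol <- 1e-10
  for (L in seq_len(n - 1)) {
    done <- !is.na(hops)
    newly <- !done & (Dk <= D + tol)
    hops[newly] <- L
    if (all(!is.na(hops))) break
    # min-plus product: paths of <= L+1 edges
    Dk <- vapply(seq_len(n), function(j)
      apply(Dk + rep(A[, j], each = n), 1, min), numeric(n))
    Dk <- pmin(Dk, A)
  }
  hops
}

#' Shortest-path arrival probabilities of a random walk
#'
#' For a walker starting at node i with the row-normalized weight matrix as
#' transition probabilities, `pi_ij` is the probability of reaching node j
#' within `phi_ij` steps, where `phi_ij` is the hop count of the weighted
#' (`1/w`-distance) shortest path: `pi_ij = 1 - sum_v [B_j^phi_ij]_iv` with
#' `B_j` the transition matrix with column j zeroed (j absorbing). The
#' scalar summary `pi_spl` is the mean over the off-diagonal entries.
#'
#' @param W Connected nonnegative symmetric weight matrix.
#' @return List with `pi` (n x n), `pi_spl`, `spl` (hop counts),
#'   `transition` (row-stochastic P).
#' @export
passageProbability <- function(W) {
  if (any(W < 0)) stop("negative weights are not allowed", call. = FALSE)
  W <- cleanGraphMatrix(W)
  n <- nrow(W)
  if (igraph::components(graphFromW(W))$no > 1)
    stop("graph must be connected for passage probabilities", call. = FALSE)
  P <- W / rowSums(W)
  hops <- shortestPathHops(W)
  piM <- matrix(0, n, n)
  for (j in seq_len(n)) {
    B <- P; B[, j] <- 0
    maxL <- max(hops[-j, j])
    Bp <- diag(n)
    surv <- matrix(0, n, maxL)   # survival prob (never hit j) after L steps
    for (L in seq_len(maxL)) {
      Bp <- Bp %*% B
      surv[, L] <- rowSums(Bp)
    }
    for (i in seq_len(n)) if (i != j) piM[i, j] <- 1 - surv[i, hops[i, j]]
  }
  list(pi = piM, pi_spl = mean(piM[row(piM) != col(piM)]),
       spl = hops, transition = P)
}

# Squared Frobenius discrepancy of the heat kernels at diffusion time t,
# from the spectral decompositions of the two Laplacians.
gddXi <- function(t, e1, e2) {
  K1 <- e1$vectors %*% (exp(-t * e1$values) * t(e1$vectors))
  K2 <- e2$vectors %*% (exp(-t * e2$values) * t(e2$vectors))
  sum((K1 - K2)^2)
}

#' Graph diffusion distance
#'
#' Compares two graphs through their Laplacian heat kernels:
#' `d^2 = max_t ||exp(-t L1) - exp(-t L2)||_F^2`, with the matrix
#' exponentials evaluated spectrally and the diffusion time searched on a
#' log-spaced grid refined by golden-section search.
#'
#' @param W1,W2 Symmetric weight matrices of the same size.
#' @param t_grid Candidate diffusion times (default 60 log-spaced points in
#'   `[1e-3, 10]`).
#' @return List with `d` (the distance), `d2` (its square, the maximized
#'   discrepancy), `t_star`, and the Laplacian spectra.
#' @export
gdd <- function(W1, W2, t_grid = 10^seq(-3, 1, length.out = 60)) {
  if (!all(dim(W1) == dim(W2))) stop("graphs must have the same node count", call. = FALSE)
  if (!isSymmetricTol(W1, 1e-9) || !isSymmetricTol(W2, 1e-9))
    stop("inputs must be symmetric", call. = FALSE)
  L1 <- laplacianMatrix(W1); L2 <- laplacianMatrix(W2)
  e1 <- eigen(L1, symmetric = TRUE); e2 <- eigen(L2, symmetric = TRUE)
  if (max(abs(L1 - L2)) == 0)
    return(list(d = 0, d2 = 0, t_star = t_grid[1], spectra = list(e1, e2)))
  xi <- vapply(t_grid, gddXi, numeric(1), e1 = e1, e2 = e2)
  b <- which.max(xi)
  lo <- t_grid[max(1, b - 1)]; hi <- t_grid[min(length(t_grid), b + 1)]
  opt <- stats::optimize(gddXi, c(lo, hi), e1 = e1, e2 = e2, maximum = TRUE)
  d2 <- max(opt$objective, xi[b])
  t_star <- if (opt$objective >= xi[b]) opt$maximum else t_grid[b]
  list(d = sqrt(d2), d2 = d2, t_star = t_star, spectra = list(e1, e2))
}

#' Pairwise graph diffusion distance matrix
#'
#' @param graphs List of symmetric weight matrices of equal size (e.g. one
#'   per subject x session).
#' @param ... Passed to [gdd()].
#' @return Symmetric zero-diagonal distance matrix.
#' @export
gddMatrix <- function(graphs, ...) {
  m <- length(graphs)
  D <- matrix(0, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    D[i, j] <- D[j, i] <- gdd(graphs[[i]], graphs[[j]], ...)$d
  D
}

#' Classical multidimensional scaling with stress
#'
#' Projects a distance matrix into a low-dimensional common space by
#' classical MDS (eigendecomposition of the double-centered squared
#' distances, [stats::cmdscale()]) and reports the stress-1 loss between
#' input and embedded distances.
#'
#' @param D Symmetric nonnegative distance matrix with zero diagonal.
#' @param dim Embedding dimension (default 2).
#' @return List with `coords` (`m x dim`) and `stress` (stress-1 in `[0, 1]`).
#' @export
mdsEmbed <- function(D, dim = 2L) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be square", call. = FALSE)
  if (any(D < 0) || any(abs(diag(D)) > 1e-12))
    stop("D must be nonnegative with zero diagonal", call. = FALSE)
  co <- cmdscale(as.dist(D), k = dim)
  if (is.null(dim(co))) co <- matrix(co, ncol = 1)
  emb <- as.matrix(dist(co))
  num <- sum((D - emb)^2) / 2
  den <- sum(D^2) / 2
  list(coords = co, stress = if (den > 0) sqrt(num / den) else 0)
}
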