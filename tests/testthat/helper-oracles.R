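# Independent oracles and shared fixtures for the test suite. These are
# deliberately naive re-implementations, kept separate from the package code
# paths they check.

ALPHA <- bandSpec("alpha", 8, 12)

# Floyd-Warshall all-pairs shortest paths on distances 1/w.
fwDistances <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Nodal/global efficiency and strength straight from the definitions.
oracleMetrics <- function(W) {
  n <- nrow(W)
  D <- fwDistances(W)
  inv <- 1 / D
  diag(inv) <- 0
  ge <- rowSums(inv) / (n - 1)
  le <- sapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    Ds <- fwDistances(W[nb, nb, drop = FALSE])
    invs <- 1 / Ds
    diag(invs) <- 0
    sum(invs) / (length(nb) * (length(nb) - 1))
  })
  list(ge = ge, le = le, strength = rowSums(W), ge_global = mean(ge))
}

# Kruskal maximum-weight spanning forest (union-find), independent of igraph.
kruskalMaxTree <- function(W) {
  n <- nrow(W)
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  ord <- order(W[upper.tri(W) & W > 0], decreasing = TRUE)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  sel <- matrix(0, n, n)
  for (k in ord) {
    i <- ut[k, 1]; j <- ut[k, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      sel[i, j] <- sel[j, i] <- W[i, j]
    }
  }
  sel
}

# Planted constant-lag pair on a band-noise carrier (aperiodic, so single-cut
# surrogates genuinely destroy the coupling, unlike a pure sinusoid).
noisyLagPair <- function(duration, fs, lag, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  w <- rnorm(duration * fs)
  x <- bandpass(w, ALPHA, fs)
  x <- x / sd(x)
  z <- chronconn:::analyticSignal(x)
  y <- Re(z * exp(-1i * lag)) + rnorm(length(x), sd = noise_sd)
  list(x = x + rnorm(length(x), sd = noise_sd), y = y)
}

# Quality J = GE - Cost of a selection, from the oracle's own pieces.
oracleJ <- function(sel, W_total) {
  inv <- 1 / fwDistances(sel)
  diag(inv) <- 0
  ge <- mean(inv[row(inv) != col(inv)])
  ge - sum(sel) / sum(W_total)
}

# Random connected weighted graph (keeps drawing until connected).
randomConnectedGraph <- function(n, p = 0.6) {
  repeat {
    W <- matrix(0, n, n)
    ut <- which(upper.tri(W))
    on <- ut[runif(length(ut)) < p]
    W[on] <- runif(length(on), 0.2, 1)
    W <- W + t(W)
    D <- fwDistances(W)
    if (all(is.finite(D))) return(W)
  }
}

# Monte-Carlo absorption estimate of the shortest-path passage probability:
# `walkers` random walks of exactly hops[i, j] steps from i, absorbed at j.
mcPassage <- function(W, walkers = 1e4) {
  n <- nrow(W)
  P <- W / rowSums(W)
  hops <- chronconn:::shortestPathHops(W)
  piM <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    state <- rep(i, walkers)
    hit <- rep(FALSE, walkers)
    for (step in seq_len(hops[i, j])) {
      alive <- which(!hit)
      if (!length(alive)) break
      cur <- state[alive]                 # snapshot before any group moves
      for (s in unique(cur)) {
        idx <- alive[cur == s]
        state[idx] <- sample.int(n, length(idx), replace = TRUE, prob = P[s, ])
      }
      hit[alive] <- state[alive] == j
    }
    piM[i, j] <- mean(hit)
  }
  piM
}

# Best assignment accuracy over all state-label permutations.
labelAccuracy <- function(lab, truth, k = max(truth, lab)) {
  best <- 0
  for (perm in chronconn:::allPermutations(k))
    best <- max(best, mean(perm[lab] == truth))
  best
}

# Small desk-scale planted cohort shared by pipeline tests.
smallCohort <- function(n_subjects = 4, duration = 120, seed = 7,
                        jitter = 0.02, n_rois = 10, fs = 80) {
  generateCohort(cohortConfig(
    n_subjects = n_subjects, duration = duration, fs = fs, n_rois = n_rois,
    bands = list(ALPHA), state_count = 2, session_jitter = jitter,
    noise_sd = 0.1, segment_samples = 2 * fs, seed = seed))
}

plantedTR <- function(cohort, session = 1) {
  gt <- groundTruth(cohort)
  ns <- nSubjects(cohort)
  vapply(seq_len(ns), function(s)
    gt$per_recording[[sprintf("sub%d_ses%d", s, session)]]$planted_tr,
    numeric(1))
}
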