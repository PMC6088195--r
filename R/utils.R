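#' @importFrom methods new validObject is slot
#' @importFrom stats cor cor.test fft p.adjust runif rnorm sd var cmdscale
#' @importFrom utils head tail write.table read.table modifyList
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Counter-based sub-seed scheme: folds integer tags into one global seed so
# per-subject/session/ROI streams are reproducible and independent of the
# order of generation. Result always in [0, 2^31 - 2].
mixSeed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed) %% 2147483647
  for (t in tags) {
    h <- (h * 48271 + as.double(t) * 16807 + 12345) %% 2147483647
  }
  as.integer(h)
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}

isSymmetricTol <- function(m, tol = 1e-12) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

# Symmetrize tiny numerical asymmetries and zero the diagonal.
cleanGraphMatrix <- function(m) {
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

upperTriVals <- function(m) m[upper.tri(m)]

# All permutations of 1..k (k small; used for codebook matching).
allPermutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- allPermutations(k - 1L)
    for (p in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(k), i)[p])
  }
  out
}
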