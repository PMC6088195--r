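test_that("the Laplacian has zero row sums and a nonnegative spectrum", {
  W <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(laplacianMatrix(W), matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(laplacianMatrix(matrix(0, 3, 3)), matrix(0, 3, 3))
  set.seed(30)
  Wr <- randomConnectedGraph(6)
  L <- laplacianMatrix(Wr)
  expect_equal(rowSums(L), rep(0, 6), tolerance = 1e-12)
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(min(abs(ev)), 0, tolerance = 1e-10)
  expect_error(laplacianMatrix(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("eigen features are per-window spectra, permutation-invariant", {
  set.seed(31)
  W <- randomConnectedGraph(5)
  tens <- array(0, c(3, 5, 5))
  for (w in 1:3) tens[w, , ] <- W
  X <- eigenFeatures(tens)
  expect_equal(X[1, ], X[3, ])
  perm <- sample(5)
  tens[2, , ] <- W[perm, perm]
  Xp <- eigenFeatures(tens)
  expect_equal(Xp[2, ], Xp[1, ], tolerance = 1e-9)
  tens[2, , ] <- 0; tens[2, 1, 2] <- tens[2, 2, 1] <- 1
  expect_error(eigenFeatures(tens), "window 2")
})

test_that("neural gas nails zero-variance clusters and distinct rows", {
  X <- rbind(matrix(rep(c(1, 0, 0), 10), ncol = 3, byrow = TRUE),
             matrix(rep(c(0, 0, 5), 10), ncol = 3, byrow = TRUE))
  cb <- neuralGasFit(X, 2, seed = 1)
  P <- prototypes(cb)[order(prototypes(cb)[, 1]), ]
  expect_equal(P[1, ], c(0, 0, 5), tolerance = 1e-6)
  expect_equal(P[2, ], c(1, 0, 0), tolerance = 1e-6)
  expect_equal(reconError(cb), 0, tolerance = 1e-4)
  # k equal to the number of distinct rows reaches zero error
  X3 <- rbind(c(1, 0), c(0, 1), c(4, 4))[rep(1:3, 5), ]
  expect_equal(reconError(neuralGasFit(X3, 3, seed = 2)), 0, tolerance = 1e-4)
  expect_error(neuralGasFit(X3, 100, seed = 1), "k must")
})

test_that("well-separated Gaussian clusters are recovered across seeds", {
  ok <- 0
  for (s in 1:20) {
    set.seed(s)
    X <- rbind(matrix(rnorm(40 * 3, mean = 0), ncol = 3),
               matrix(rnorm(40 * 3, mean = 10), ncol = 3))
    truth <- rep(1:2, each = 40)
    cb <- neuralGasFit(X, 2, seed = s)
    if (labelAccuracy(stateAssignments(cb), truth) >= 0.99) ok <- ok + 1
  }
  expect_gte(ok, 20 * 0.99 - 1)   # >= 19 of 20
})

test_that("reconstruction error follows its closed form and decreases in k", {
  # two zero-variance clusters at +-c collapsed to one prototype at the mean
  cval <- 3
  X <- rbind(c(cval, 0), c(-cval, 0))
  cb1 <- neuralGasFit(X, 1, seed = 3)
  expect_equal(reconError(cb1),
               100 * sqrt(sum((X - rbind(c(0, 0), c(0, 0)))^2)) / sqrt(sum(X^2)),
               tolerance = 1e-4)
  set.seed(33)
  Xr <- rbind(matrix(rnorm(60, 0, 1), ncol = 2),
              matrix(rnorm(60, 6, 1), ncol = 2))
  es <- vapply(1:5, function(k) reconError(neuralGasFit(Xr, k, seed = 5)), numeric(1))
  expect_true(all(diff(es) < 1e-6 + 0.05 * es[-5]))   # non-increasing up to jitter
  expect_error(reconstructionError(matrix(0, 2, 2), cb1), "zero-norm")
})

test_that("selectK applies the error criterion and falls back with a warning", {
  X <- matrix(rep(c(1, 2, 3), 12), ncol = 3, byrow = TRUE)
  sel <- selectK(X, 1:3, seed = 4)
  expect_equal(sel$k, 1L)
  set.seed(34)
  X2 <- rbind(matrix(rnorm(40, 0, 0.01), ncol = 2),
              matrix(rnorm(40, 8, 0.01), ncol = 2))
  sel2 <- selectK(X2, 1:3, seed = 5)
  expect_equal(sel2$k, 2L)
  expect_gt(sel2$e_curve["1"], 4)
  Xn <- matrix(rnorm(200), ncol = 2)
  expect_warning(sel3 <- selectK(Xn, 1:2, e_threshold = 0.001, seed = 6),
                 "criterion")
  expect_equal(sel3$k, 2L)
  expect_error(selectK(Xn, integer(0)), "nonempty")
})

test_that("symbol assignment is nearest-prototype with low-index ties", {
  P <- rbind(c(0, 0), c(4, 4))
  cb <- new("Codebook", prototypes = P, assignments = c(1L, 2L),
            reconError = 0, seed = 1, params = list())
  expect_equal(assignSymbols(P, cb), c(1L, 2L))
  expect_equal(assignSymbols(matrix(c(2, 2), 1), cb), 1L)  # tie -> lowest index
  expect_equal(assignSymbols(matrix(c(3.9, 4.1), 1), cb), 2L)
  expect_length(assignSymbols(matrix(c(0, 1), 1), cb), 1L)
  expect_error(assignSymbols(matrix(0, 1, 3), cb), "dimension")
})

test_that("codebook matching recovers permutations exactly and under noise", {
  set.seed(35)
  P <- matrix(rnorm(12), 4, 3)
  cb1 <- new("Codebook", prototypes = P, assignments = integer(0),
             reconError = 0, seed = 1, params = list())
  mk <- function(M) new("Codebook", prototypes = M, assignments = integer(0),
                        reconError = 0, seed = 1, params = list())
  expect_equal(matchCodebooks(cb1, cb1), 1:4)
  perm <- c(3, 1, 4, 2)
  cb2 <- mk(P[perm, ])
  expect_equal(matchCodebooks(cb1, cb2), perm)
  ok <- TRUE
  for (s in 1:20) {
    set.seed(s)
    prm <- sample(4)
    noisy <- mk(P[prm, ] + matrix(rnorm(12, sd = 0.05), 4, 3))
    ok <- ok && identical(matchCodebooks(cb1, noisy), prm)
  }
  expect_true(ok)
  expect_error(matchCodebooks(cb1, mk(P[1:3, ])), "different k")
})

test_that("transition matrices count consecutive pairs", {
  expect_equal(transitionMatrixOf(c(1, 2, 1, 2, 1), 2)$tp,
               matrix(c(0, 1, 1, 0), 2, 2))
  t2 <- transitionMatrixOf(c(1, 1, 1), 2)
  expect_equal(t2$tp[1, ], c(1, 0))
  expect_equal(t2$visited, c(TRUE, FALSE))
  t3 <- transitionMatrixOf(c(1, 1, 2, 1, 2, 2), 2)
  expect_equal(t3$tp[1, ], c(1 / 3, 2 / 3))
  expect_equal(t3$tp[2, ], c(1 / 2, 1 / 2))
  expect_error(transitionMatrixOf(c(1, 3), 2), "exceed")
  expect_error(transitionMatrixOf(1L, 2), "length")
})

test_that("prototype topologies average the slices of each state", {
  set.seed(36)
  tens <- array(0, c(4, 3, 3))
  A <- randomConnectedGraph(3); B <- randomConnectedGraph(3)
  tens[1, , ] <- A; tens[2, , ] <- B; tens[3, , ] <- A; tens[4, , ] <- B
  tops <- prototypeTopologies(tens, c(1, 2, 1, 2), 2)
  expect_equal(tops[[1]], A)
  expect_equal(tops[[2]], B)
  one <- prototypeTopologies(tens, rep(1, 4), 1)
  expect_equal(one[[1]], apply(tens, c(2, 3), mean))
  expect_warning(tt <- prototypeTopologies(tens, c(1, 1, 1, 1), 2), "no window")
  expect_equal(tt[[2]], matrix(0, 3, 3))
  for (t in tops) {
    expect_equal(t, t(t))
    expect_equal(diag(t), rep(0, 3))
  }
})

test_that("network aggregation conserves total edge weight", {
  set.seed(37)
  W <- randomConnectedGraph(10)
  part <- rep(c("DMN", "FPN", "O", "SM", "CO"), each = 2)
  agg <- aggregateNetworks(W, part)
  expect_equal(sum(agg[upper.tri(agg)]) + sum(diag(agg)), sum(W) / 2,
               tolerance = 1e-12)
  # edges only inside one network touch only that diagonal cell
  Wd <- matrix(0, 10, 10); Wd[1, 2] <- Wd[2, 1] <- 2.5
  aggd <- aggregateNetworks(Wd, part)
  expect_equal(aggd["DMN", "DMN"], 2.5)
  expect_equal(sum(aggd != 0), 1)
  norm <- normalizeAggregates(list(agg, aggd))
  expect_equal(max(vapply(norm, max, numeric(1))), 1)
  expect_error(aggregateNetworks(W, part[-1]), "mapped")
  expect_error(aggregateNetworks(W, replace(part, 3, NA)), "nmapped")
  # the shipped synthetic partition fixture maps a 90-ROI layout to 5 networks
  pf <- read.table(system.file("extdata", "network_partition_synthetic.tsv",
                               package = "chronconn"),
                   header = TRUE, sep = "\t")
  expect_equal(nrow(pf), 90)
  expect_setequal(unique(pf$network), c("DMN", "FPN", "O", "SM", "CO"))
  set.seed(38)
  W90 <- matrix(0, 90, 90)
  W90[upper.tri(W90)] <- runif(90 * 89 / 2)
  W90 <- W90 + t(W90)
  agg90 <- aggregateNetworks(W90, pf$network)
  expect_equal(dim(agg90), c(5L, 5L))
  expect_equal(sum(agg90[upper.tri(agg90)]) + sum(diag(agg90)),
               sum(W90) / 2, tolerance = 1e-9)
})
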