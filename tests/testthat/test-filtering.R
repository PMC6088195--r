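test_that("single-cut surrogates are block exchanges of the original", {
  sch <- surrogateScheme(20, cut_halfwidth = 2, seed = 1)
  x <- rnorm(64 * 20)
  s1 <- surrogateSeries(x, sch, 1, fs = 64)
  expect_equal(sort(s1), sort(x))
  expect_false(identical(s1, x))
  # a cut exactly at the midpoint of an even-length series swaps the halves
  y <- seq_len(100)
  swapped <- c(y[51:100], y[1:50])
  expect_equal(c(y[(50 + 1):100], y[1:50]), swapped)
  expect_error(surrogateScheme(10), "19")
  expect_error(surrogateSeries(rnorm(50), sch, 1, fs = 64), "fit")
})

test_that("surrogates destroy a planted lag", {
  fs <- 64
  p <- noisyLagPair(20, fs, pi / 2, noise_sd = 0.3, seed = 2)
  bx <- bandpass(p$x, ALPHA, fs)
  ay <- analyticSeries(bandpass(p$y, ALPHA, fs), ALPHA, fs)
  obs <- iplv(analyticSeries(bx, ALPHA, fs), ay)
  sch <- surrogateScheme(100, cut_halfwidth = 5, seed = 3)
  sur <- vapply(1:100, function(d) {
    sx <- surrogateSeries(bx, sch, d, fs = fs)
    iplv(analyticSeries(sx, ALPHA, fs), ay)
  }, numeric(1))
  expect_gte(mean(sur < obs), 0.99)
})

test_that("edge p-values are one-sided proportions", {
  sur <- seq(0.01, 1, length.out = 100)
  expect_equal(edgePValue(2, sur), 0)
  expect_equal(edgePValue(0.505, sur), 0.5)
  expect_equal(edgePValue(0, sur), 1)
  expect_error(edgePValue(1, numeric(0)), "19")
})

test_that("the BH keep-mask reproduces the step-up rule", {
  expect_true(all(fdrBH(rep(0.001, 10), 0.01)))
  expect_false(any(fdrBH(rep(0.5, 10), 0.01)))
  keep <- fdrBH(c(0.001, 0.002, 0.005, 0.02, 0.2), 0.05)
  expect_equal(keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_error(fdrBH(c(0.5, 1.2)), "outside")
})

test_that("statistical filtering keeps a planted edge and respects q = 1", {
  fs <- 64
  set.seed(4)
  p <- noisyLagPair(30, fs, pi / 2, noise_sd = 0.3, seed = 5)
  ts <- cbind(p$x, p$y, bandpass(rnorm(fs * 30), ALPHA, fs),
              bandpass(rnorm(fs * 30), ALPHA, fs))
  g <- staticFCG(ts, ALPHA, "iplv", fs)
  sch <- surrogateScheme(100, cut_halfwidth = 5, seed = 6)
  filt <- statisticalFilter(g, ts, sch, q = 0.01)
  expect_gt(connMatrix(filt$graph)[1, 2], 0)
  # filtering never increases a weight; zeros stay zero
  expect_true(all(connMatrix(filt$graph) <= connMatrix(g) + 1e-12))
  all_kept <- statisticalFilter(g, ts, sch, q = 1)
  expect_equal(connMatrix(all_kept$graph), connMatrix(g))
})

test_that("statistical filtering of a dynamic graph reuses one null per edge", {
  fs <- 64
  set.seed(7)
  ts <- sapply(1:4, function(i) rnorm(fs * 30))
  dfc <- dynamicFCG(ts, ALPHA, "iplv", fs, width = fs * 5, step = fs * 5)
  sch <- surrogateScheme(50, cut_halfwidth = 5, seed = 8)
  filt <- statisticalFilter(dfc, ts, sch, q = 0.01)
  expect_s4_class(filt$graph, "DynamicFCGraph")
  expect_equal(dim(filt$p), dim(dfc@tensor))
  expect_true(all(filt$graph@tensor <= dfc@tensor + 1e-12))
})

test_that("omst returns a tree unchanged and matches the greedy tree oracle", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 2; W[3, 4] <- W[4, 3] <- 1.5
  o <- omst(W)
  expect_equal(o$rounds_used, 1L)
  expect_equal(o$w_filtered, W)
  expect_equal(o$cost, 1)
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    Wc <- matrix(0, n, n)
    Wc[upper.tri(Wc)] <- runif(n * (n - 1) / 2, 0.1, 1)
    Wc <- Wc + t(Wc)
    first_round <- omst(Wc, max_rounds = 1)$w_filtered
    expect_equal(first_round, kruskalMaxTree(Wc))
  }
})

test_that("omst maximizes J over cumulative rounds (brute-force oracle)", {
  set.seed(10)
  for (rep in 1:8) {
    n <- sample(4:6, 1)
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- runif(n * (n - 1) / 2, 0.1, 1)
    W <- W + t(W)
    o <- omst(W)
    # oracle: rebuild the cumulative selections round by round independently
    Wrem <- W
    sel <- matrix(0, n, n)
    js <- numeric(0)
    repeat {
      D <- fwDistances(Wrem)
      if (any(!is.finite(D))) break
      tree <- kruskalMaxTree(Wrem)
      sel <- sel + tree
      Wrem[tree > 0] <- 0
      js <- c(js, oracleJ(sel, W))
    }
    expect_equal(length(o$j_curve), length(js))
    expect_equal(o$j_curve, js, tolerance = 1e-9)
    expect_equal(max(o$j_curve), o$ge - o$cost, tolerance = 1e-12)
    expect_equal(which.max(js), o$rounds_used)
    # output connected, cost in (0, 1]
    expect_true(all(is.finite(fwDistances(o$w_filtered))))
    expect_gt(o$cost, 0); expect_lte(o$cost, 1)
  }
  Wd <- matrix(0, 4, 4); Wd[1, 2] <- Wd[2, 1] <- 1; Wd[3, 4] <- Wd[4, 3] <- 1
  expect_error(omst(Wd), "disconnected")
})

test_that("null edge p-values are approximately uniform", {
  fs <- 64
  set.seed(11)
  pvals <- c()
  for (run in 1:3) {
    ts <- sapply(1:15, function(r) rnorm(fs * 20))
    g <- staticFCG(ts, ALPHA, "iplv", fs)
    sf <- statisticalFilter(g, ts, surrogateScheme(200, cut_halfwidth = 4,
                                                   seed = run), q = 0.01)
    pvals <- c(pvals, sf$p[upper.tri(sf$p)])
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})
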