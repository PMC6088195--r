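test_that("bandpass preserves the passband and attenuates the stopband", {
  fs <- 64
  t <- (0:(fs * 10 - 1)) / fs
  tone_in <- sin(2 * pi * 10 * t)
  expect_equal(sd(bandpass(tone_in, ALPHA, fs)) / sd(tone_in), 1, tolerance = 0.05)
  tone_out <- sin(2 * pi * 20 * t)   # one octave above band centre
  atten <- 20 * log10(sd(bandpass(tone_out, ALPHA, fs)) / sd(tone_out))
  expect_lt(atten, -20)
  set.seed(2)
  y <- bandpass(rnorm(fs * 30), ALPHA, fs)
  sp <- spec.pgram(ts(y, frequency = fs), plot = FALSE, taper = 0)
  inband <- sum(sp$spec[sp$freq >= 8 & sp$freq <= 12]) / sum(sp$spec)
  expect_gt(inband, 0.9)
  expect_error(bandpass(rnorm(100), bandSpec("g", 30, 40), fs = 60), "Nyquist")
})

test_that("the analytic construction recovers phase and envelope", {
  fs <- 64
  t <- (0:(fs * 10 - 1)) / fs
  a <- analyticSeries(cos(2 * pi * 10 * t), ALPHA, fs)
  mid <- (fs * 2):(fs * 8)
  expect_lt(max(abs(a$envelope[mid] - 1)), 0.02)
  b <- analyticSeries(sin(2 * pi * 10 * t), ALPHA, fs)
  dphi <- Arg(exp(1i * (a$phase[mid] - b$phase[mid])))
  expect_equal(mean(dphi), pi / 2, tolerance = 1e-3)
  am <- (1 + 0.5 * cos(2 * pi * 0.5 * t)) * cos(2 * pi * 10 * t)
  e <- analyticSeries(am, ALPHA, fs)$envelope[mid]
  expect_lt(sqrt(mean((e - (1 + 0.5 * cos(2 * pi * 0.5 * t[mid])))^2)), 0.03)
  expect_error(analyticSeries(rep(0, 100), ALPHA, fs), "all-zero")
})

test_that("iPLV is a lag detector blind to zero-lag coupling", {
  phi <- runif(500, -pi, pi)
  expect_equal(iplv(phi + pi / 2, phi), 1, tolerance = 1e-12)
  expect_equal(iplv(phi, phi), 0, tolerance = 1e-12)
  # invariance to a common phase constant and to swapping inputs
  psi <- runif(500, -pi, pi)
  expect_equal(iplv(phi, psi), iplv(phi + 1.3, psi + 1.3), tolerance = 1e-12)
  expect_equal(iplv(phi, psi), iplv(psi, phi), tolerance = 1e-12)
  expect_error(iplv(phi, psi[-1]), "lengths")
  # independent uniform phases concentrate near zero
  set.seed(9)
  nulls <- vapply(1:100, function(i)
    iplv(runif(1e4, -pi, pi), runif(1e4, -pi, pi)), numeric(1))
  expect_gte(mean(nulls < 0.05), 0.95)
})

test_that("corenv vanishes on scaled copies and is symmetric", {
  fs <- 64
  set.seed(3)
  x <- bandpass(rnorm(fs * 30), ALPHA, fs)
  expect_equal(suppressWarnings(corenv(x, 2.5 * x, ALPHA, fs)), 0)
  y <- bandpass(rnorm(fs * 30), ALPHA, fs)
  expect_equal(corenv(x, y, ALPHA, fs), corenv(y, x, ALPHA, fs))
})

test_that("corenv null stays small and planted coupling is recovered", {
  fs <- 64
  set.seed(10)
  nulls <- vapply(1:30, function(i) {
    x <- bandpass(rnorm(fs * 60), ALPHA, fs)
    y <- bandpass(rnorm(fs * 60), ALPHA, fs)
    corenv(x, y, ALPHA, fs)
  }, numeric(1))
  expect_gte(mean(abs(nulls) < 0.15), 0.9)
  planted <- vapply(1:15, function(s) {
    p <- generateEnvelopeCoupledPair(60, fs, ALPHA, 0.8, seed = s)
    corenv(p$x, p$y, ALPHA, fs)
  }, numeric(1))
  expect_lt(abs(mean(planted) - 0.8), 0.15)
})

test_that("window plans tile the recording as specified", {
  wp <- windowPlan(1000, 100, width = 100, step = 50)
  expect_equal(wp$count, 19L)
  expect_equal(wp$starts[1:3], c(1L, 51L, 101L))
  expect_equal(windowPlan(500, 100, width = 500, step = 100)$count, 1L)
  expect_error(windowPlan(100, 100, width = 200, step = 50), "width")
  # delta-band setting: 2-cycle window, 0.5-cycle step at the band centre
  delta <- defaultBands()$delta
  wp_d <- windowPlan(300 * 600, 600, spec = windowSpec(2, 0.5), band = delta)
  f_ref <- bandCycleFreq(delta)
  expect_equal(wp_d$width, round(2 / f_ref * 600))
  expect_equal(wp_d$step, round(0.5 / f_ref * 600))
  expect_error(windowSpec(0.5, 1), "width_cycles")
})

test_that("static graphs match pairwise estimates and reject bad input", {
  fs <- 200
  p <- generatePhaseCoupledPair(10, fs, 10, pi / 2)
  g <- staticFCG(cbind(p$x, p$y), ALPHA, "iplv", fs)
  # the graph path re-filters, so filter edge effects bound the accuracy
  expect_equal(connMatrix(g)[1, 2], 1, tolerance = 0.01)
  expect_equal(diag(connMatrix(g)), c(0, 0))
  set.seed(12)
  z <- matrix(rep(bandpass(rnorm(fs * 5), ALPHA, fs), 3), ncol = 3)
  expect_lt(max(connMatrix(staticFCG(z, ALPHA, "iplv", fs))), 1e-12)
  ts3 <- cbind(p$x, p$y, bandpass(rnorm(fs * 10), ALPHA, fs))
  g3 <- staticFCG(ts3, ALPHA, "iplv", fs)
  a <- lapply(seq_len(3), function(j) analyticSeries(bandpass(ts3[, j], ALPHA, fs), ALPHA, fs))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(connMatrix(g3)[i, j], iplv(a[[i]], a[[j]]), tolerance = 1e-9)
  ts3[5, 2] <- NA
  expect_error(staticFCG(ts3, ALPHA, "iplv", fs), "finite")
})

test_that("dynamic graphs collapse to the static graph for one window", {
  fs <- 64
  set.seed(13)
  ts <- sapply(1:4, function(i) rnorm(fs * 10))
  dfc <- dynamicFCG(ts, ALPHA, "iplv", fs, width = fs * 10, step = fs)
  expect_equal(nWindows(dfc), 1L)
  g <- staticFCG(ts, ALPHA, "iplv", fs)
  expect_equal(graphSlice(dfc, 1), connMatrix(g), tolerance = 1e-9)
})

test_that("dynamic graphs resolve a planted regime switch at the midpoint", {
  fs <- 200
  half <- fs * 10
  p1 <- generatePhaseCoupledPair(10, fs, 10, pi / 2, seed = 1)
  p2 <- generatePhaseCoupledPair(10, fs, 10, pi / 2, seed = 2)
  set.seed(14)
  ind1 <- bandpass(rnorm(half), ALPHA, fs); ind2 <- bandpass(rnorm(half), ALPHA, fs)
  # regime 1: ROIs 1-2 coupled; regime 2: ROIs 2-3 coupled
  ts <- rbind(cbind(p1$x, p1$y, ind1), cbind(ind2, p2$x, p2$y))
  dfc <- dynamicFCG(ts, ALPHA, "iplv", fs, width = fs * 2, step = fs * 2)
  g1 <- staticFCG(ts[1:half, ], ALPHA, "iplv", fs)
  g2 <- staticFCG(ts[(half + 1):(2 * half), ], ALPHA, "iplv", fs)
  v <- function(m) m[upper.tri(m)]
  for (w in seq_len(nWindows(dfc))) {
    own <- if (w <= 5) g1 else g2
    other <- if (w <= 5) g2 else g1
    expect_gt(cor(v(graphSlice(dfc, w)), v(connMatrix(own))), 0.8)
    expect_gt(cor(v(graphSlice(dfc, w)), v(connMatrix(own))),
              cor(v(graphSlice(dfc, w)), v(connMatrix(other))))
  }
})

test_that("non-overlapping windows partition the recording", {
  wp <- windowPlan(1050, 100, width = 100, step = 100)
  expect_equal(wp$count, 10L)
  covered <- unlist(lapply(wp$starts, function(s) s:(s + wp$width - 1)))
  expect_false(any(duplicated(covered)))
  expect_lte(max(covered), 1050)
})

test_that("FCGraph validity catches malformed matrices", {
  m <- matrix(c(0, 1, 0.5, 0), 2, 2)
  expect_error(new("FCGraph", w = m, estimator = "iplv",
                   band = unclass(ALPHA), fs = 64), "symmetric")
  m2 <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_error(new("FCGraph", w = m2, estimator = "iplv",
                   band = unclass(ALPHA), fs = 64), "\\[0, 1\\]")
  expect_s4_class(FCGraph(matrix(c(0, .5, .5, 0), 2, 2), "iplv", ALPHA, 64),
                  "FCGraph")
})
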