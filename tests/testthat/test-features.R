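# Differential entropy and the per-segment feature grid.

test_that("DE of Gaussian noise matches the closed form", {
  # oracle: 0.5 * log2(2*pi*e*sigma^2) evaluated at the true sigma
  set.seed(12)
  for (sigma in c(0.5, 1, 2)) {
    est <- differentialEntropy(rnorm(5000, sd = sigma))
    expect_equal(est, 0.5 * log2(2 * pi * exp(1) * sigma^2),
                 tolerance = 0.05)
  }
})

test_that("doubling the amplitude adds one bit", {
  set.seed(13)
  x <- rnorm(4000)
  expect_equal(differentialEntropy(2 * x) - differentialEntropy(x), 1,
               tolerance = 1e-9)  # exact scale property of the estimator
})

test_that("degenerate windows are rejected", {
  expect_error(differentialEntropy(rep(3, 100)), "degenerate")
  expect_error(differentialEntropy(c(1)), "length")
})

test_that("DE estimator bias vanishes as the window grows", {
  truth <- 0.5 * log2(2 * pi * exp(1))
  set.seed(14)
  bias <- vapply(c(100, 1000, 10000), function(n) {
    abs(mean(vapply(1:40, function(i) differentialEntropy(rnorm(n)), 1)) -
        truth)
  }, 1)
  expect_true(all(diff(bias) < 0))
  expect_lt(bias[3], 0.005)
})

test_that("the sub-window grid spans the segment as specified", {
  g <- featureGrid(T = 10, M = 32, subwindowLength = 1)
  expect_equal(nrow(g), 32L)
  expect_equal(unname(g[1, "start"]), 0)
  expect_equal(unname(g[32, "start"]), 9)    # last window ends at T
  expect_equal(unname(diff(g[, "start"])[1]), 9 / 31)

  halves <- featureGrid(T = 10, M = 2, subwindowLength = 5)
  expect_equal(unname(halves[, "start"]), c(0, 5))  # two disjoint halves
})

test_that("nodeFeatures computes per-sub-window DE values", {
  spec <- lightSpec(nAD = 1, nHC = 1, seed = 19)
  rec <- generateSubject(spec, "HC", 1)
  bs <- bandpassDecompose(rec)
  segs <- segmentWindows(bs)
  nf <- nodeFeatures(segs, M = 8, subwindowLength = 1)
  expect_length(nf$values, 10L)
  arr <- nf$values[[1]]
  expect_identical(dim(arr), c(19L, 8L, 5L))
  expect_true(all(is.finite(arr)))
  expect_identical(dimnames(arr)[[3]], bandNames())

  # closed-form oracle on one (channel, band, sub-window) cell
  fs <- samplingRate(segs)
  i0 <- round(nf$grid[3, "start"] * fs)
  w <- segs@segments[[1]]$alpha[7, (i0 + 1):(i0 + fs)]
  expect_equal(arr[7, 3, "alpha"], 0.5 * log2(2 * pi * exp(1) * var(w)),
               tolerance = 1e-12)
})

test_that("DE spread across sub-windows shrinks with longer sub-windows", {
  spec <- cohortSpec(nAD = 1, nHC = 1, duration = 60, samplingRate = 128,
                     seed = 23)
  rec <- generateSubject(spec, "HC", 1)
  bs <- bandpassDecompose(rec, bandDefinitions("alpha"))
  segs <- segmentWindows(bs, T = 30, overlap = 0.5, mode = "dense")
  spread <- function(w) {
    nf <- nodeFeatures(segs, M = 8, subwindowLength = w)
    mean(apply(nf$values[[1]][, , 1], 1, var))
  }
  expect_lt(spread(8), spread(0.5))
})

test_that("z-score normalization satisfies its identities", {
  set.seed(31)
  X <- array(rnorm(4 * 6 * 2 * 25, mean = 3, sd = 2), c(4, 6, 2, 25))
  st <- fitNormalization(X)
  Z <- applyNormalization(st, X)
  mu <- apply(Z, 1:3, mean)
  sg <- apply(Z, 1:3, sd)
  expect_lt(max(abs(mu)), 1e-9)
  expect_lt(max(abs(sg - 1)), 1e-9)

  # constant coordinate: sd floored, output 0
  X[2, 2, 1, ] <- 7
  st2 <- fitNormalization(X)
  Z2 <- applyNormalization(st2, X)
  expect_true(all(Z2[2, 2, 1, ] == 0))

  expect_error(fitNormalization(list()), "4-d|empty")
})

test_that("stats fitted on train do not recentre a shifted test set", {
  set.seed(32)
  train <- array(rnorm(3 * 4 * 1 * 30), c(3, 4, 1, 30))
  test <- array(rnorm(3 * 4 * 1 * 30, mean = 1.5), c(3, 4, 1, 30))
  st <- fitNormalization(train)
  Ztest <- applyNormalization(st, test)
  expect_gt(mean(Ztest), 1)  # leakage sentinel: shift survives
})
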