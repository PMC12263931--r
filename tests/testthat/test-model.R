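# GCN layer, forward pass, parameter accounting and the training loop.

test_that("gcnLayer reduces to identity propagation", {
  X <- matrix(abs(rnorm(12)), 4)
  out <- gcnLayer(X, diag(4), diag(3))
  expect_equal(unname(as.matrix(out)), unname(X))
  expect_equal(gcnLayer(matrix(0, 4, 3), randomNormAdjacency(4),
                        matrix(rnorm(6), 3, 2)),
               matrix(0, 4, 2), ignore_attr = TRUE)
  expect_error(gcnLayer(X, diag(3), diag(3)), "shape")
})

test_that("gcnLayer matches the per-node aggregation oracle", {
  set.seed(51)
  for (i in 1:5) {
    Anorm <- randomNormAdjacency(4)
    X <- matrix(rnorm(4 * 6), 4)
    W <- matrix(rnorm(6 * 3), 6)
    expect_equal(unname(as.matrix(gcnLayer(X, Anorm, W))),
                 loopGcnLayer(X, Anorm, W), tolerance = 1e-10)
  }
})

smallInputs <- function(N = 3, M = 4, J = 2, seed = 52) {
  set.seed(seed)
  X <- array(rnorm(N * M * J), c(N, M, J))
  A1 <- array(0, c(N, N, J))
  for (j in seq_len(J)) A1[, , j] <- unclass(randomNormAdjacency(N))
  A2 <- unclass(randomNormAdjacency(N))
  arch <- architectureConfig(nodes = N, inputFeatures = M, gcnHidden = 3,
                             gcnOutput = 2, bands = J, fcHidden1 = 6,
                             fcHidden2 = 4)
  params <- initParameters(arch)
  list(X = X, A1 = A1, A2 = A2, arch = arch, params = params)
}

test_that("forward pass matches the layer-by-layer composition oracle", {
  inp <- smallInputs()
  got <- forwardPass(inp$X, inp$A1, inp$A2, inp$params)
  flat <- unlist(lapply(1:2, function(j) {
    H1 <- loopGcnLayer(inp$X[, , j], inp$A1[, , j], inp$params$W0[[j]])
    as.vector(loopGcnLayer(H1, inp$A2, inp$params$W1[[j]]))
  }))
  z1 <- pmax(as.vector(flat %*% inp$params$Wf1), 0)
  z2 <- pmax(as.vector(z1 %*% inp$params$Wf2), 0)
  sc <- as.vector(z2 %*% inp$params$Wf3)
  expect_equal(got$scores, sc, tolerance = 1e-8)
  expect_equal(sum(got$probs), 1, tolerance = 1e-9)
  expect_true(all(got$probs >= 0))
})

test_that("forward pass is equivariant to channel permutation", {
  inp <- smallInputs(N = 4, seed = 53)
  p <- c(3, 1, 4, 2)
  # permute channels everywhere and adapt each band's flatten block by
  # permuting its rows through the FC input weights
  Xp <- inp$X[p, , ]
  A1p <- inp$A1[p, p, ]
  A2p <- inp$A2[p, p]
  paramsP <- inp$params
  N <- 4; L <- inp$arch@gcnOutput
  rowPerm <- unlist(lapply(seq_len(inp$arch@bands), function(j)
    (j - 1) * N * L + as.vector(outer(p, (seq_len(L) - 1) * N, "+"))))
  paramsP$Wf1 <- inp$params$Wf1[rowPerm, , drop = FALSE]
  expect_equal(forwardPass(Xp, A1p, A2p, paramsP)$scores,
               forwardPass(inp$X, inp$A1, inp$A2, inp$params)$scores,
               tolerance = 1e-10)
})

test_that("zeroing one band's features and weights isolates its block", {
  inp <- smallInputs(J = 3, seed = 54)
  X0 <- inp$X; X0[, , 2] <- 0
  p0 <- inp$params
  p0$W0[[2]][] <- 0
  s1 <- forwardPass(X0, inp$A1, inp$A2, inp$params)$scores
  s2 <- forwardPass(X0, inp$A1, inp$A2, p0)$scores
  expect_equal(s1, s2, tolerance = 1e-10)  # zero input already kills band 2
})

test_that("compiled forward agrees with the R reference", {
  ds <- .tinyDataset()
  arch <- tinyArch(ds)
  plan <- subjectSplit(ds, 0.25, seed = 2)
  model <- trainModel(ds, segmentIndices(ds, plan, "train"),
                      arch = arch, tc = trainConfig(epochs = 3, seed = 9))
  idx <- segmentIndices(ds, plan, "test")
  probs <- predictProbs(model, ds, idx)
  Xn <- applyNormalization(model@normStats, ds@features)
  for (i in seq_along(idx)[1:3]) {
    s <- idx[i]
    A1n <- array(0, dim(ds@adjacency)[1:3])
    for (j in seq_len(dim(A1n)[3]))
      A1n[, , j] <- unclass(normalizeAdjacency(ds@adjacency[, , j, s]))
    ref <- forwardPass(Xn[, , , s], A1n,
                       unclass(normalizeAdjacency(ds@structural)),
                       model@params)
    expect_equal(unname(probs[i, ]), ref$probs, tolerance = 1e-10)
  }
})

test_that("parameter count follows the shape arithmetic", {
  arch <- architectureConfig()
  # 5*(32*16) + 5*(16*2) + (190*128 + 128) + (128*32 + 32) + (32*2 + 2)
  expect_identical(countParameters(arch), 31362L)
  expect_identical(countParameters(initParameters(arch)),
                   countParameters(arch))

  tinyShared <- architectureConfig(nodes = 1, inputFeatures = 1,
                                   gcnHidden = 1, gcnOutput = 1, bands = 1,
                                   fcHidden1 = 1, fcHidden2 = 1, classes = 2,
                                   weightSharing = "shared")
  # W0 1 + W1 1 + (1*1+1) + (1*1+1) + (1*2+2)
  expect_identical(countParameters(tinyShared), 10L)

  k2 <- architectureConfig(gcnHidden = 32)
  d <- countParameters(k2) - countParameters(arch)
  expect_identical(d, 5L * (32L * 16L + 16L * 2L))  # only GCN terms move
})

test_that("training is reproducible and inert at zero learning rate", {
  ds <- .tinyDataset()
  arch <- tinyArch(ds)
  plan <- subjectSplit(ds, 0.25, seed = 4)
  tr <- segmentIndices(ds, plan, "train")

  m1 <- trainModel(ds, tr, arch = arch, tc = trainConfig(epochs = 5, seed = 11))
  m2 <- trainModel(ds, tr, arch = arch, tc = trainConfig(epochs = 5, seed = 11))
  expect_identical(m1@params, m2@params)
  expect_identical(m1@lossCurves, m2@lossCurves)

  m0 <- trainModel(ds, tr, arch = arch,
                   tc = trainConfig(learningRate = 0, epochs = 4, seed = 11))
  set.seed(11)
  expect_equal(m0@params$Wf1, initParameters(arch)$Wf1, tolerance = 0)
  expect_lt(diff(range(m0@lossCurves$train)), 1e-12)
})

test_that("training separates a strongly contrasted cohort on every seed", {
  ds <- .strongDataset()
  for (s in 1:3) {
    plan <- subjectSplit(ds, 0.25, seed = s)
    res <- evaluateSplit(ds, plan, arch = tinyArch(ds),
                         tc = trainConfig(epochs = 200, seed = s))
    expect_gte(res$metrics@accuracy, 90)
    expect_true(all(abs(rowSums(res$probs) - 1) < 1e-9))
    # smoothed training loss trends monotonically downward
    lc <- lossCurves(res$model)$train
    bins <- vapply(split(lc, cut(seq_along(lc), 4)), mean, 1)
    expect_true(all(diff(bins) < 0))
  }
})

test_that("shuffled labels collapse accuracy to chance", {
  ds <- .tinyDataset()
  set.seed(99)
  shuffled <- ds
  # permute labels across subjects, keeping segment grouping intact
  subj <- unique(ds@meta$subject_id)
  newLab <- setNames(sample(ds@meta$label[!duplicated(ds@meta$subject_id)]),
                     subj)
  shuffled@meta$label <- unname(newLab[shuffled@meta$subject_id])
  accs <- vapply(1:3, function(s) {
    plan <- subjectSplit(shuffled, 0.25, seed = s)
    evaluateSplit(shuffled, plan, arch = tinyArch(ds),
                  tc = trainConfig(epochs = 30, seed = s))$metrics@accuracy
  }, 1)
  expect_lt(mean(accs), 80)  # far from the separable-case performance
})

test_that("degenerate training inputs raise errors", {
  ds <- .tinyDataset()
  expect_error(trainModel(ds, integer(0)), "empty")
  adOnly <- which(ds@meta$label == "AD")
  expect_error(trainModel(ds, adOnly, arch = tinyArch(ds)), "single class")
})
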