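# Shared fixtures. Unit tests run on small cohorts (low sampling rate,
# short recordings) built once per session; all generation is seeded.

# A light cohort: 128 Hz keeps every band edge below Nyquist while making
# filtering cheap; 20 s is enough for the tenfold windowing (10 windows of
# 10 s at 1 s steps needs 19 s).
lightSpec <- function(nAD = 3, nHC = 3, seed = 101, ...) {
  cohortSpec(nAD = nAD, nHC = nHC, duration = 20, samplingRate = 128,
             seed = seed, ...)
}

# Small graph dataset shared across model/evaluation tests (M = 8 features
# keeps tensors small; the architecture scales with it).
.tinyDataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- buildGraphDataset(lightSpec(nAD = 4, nHC = 4, seed = 77),
                                  M = 8)
    cache
  }
})

# Strongly separable cohort: large band-variance contrast, low
# between-subject variability, wide connectivity gap.
.strongDataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      prof <- cbind(AD = c(2.5, 2.5, 0.25, 1, 1), HC = rep(1, 5))
      rownames(prof) <- bandNames()
      cache <<- buildGraphDataset(
        cohortSpec(nAD = 8, nHC = 8, duration = 20, samplingRate = 128,
                   bandVarianceProfile = prof, subjectLogSd = 0.08,
                   connectivityStrength = c(AD = 0.25, HC = 0.65),
                   seed = 55), M = 8)
    }
    cache
  }
})

tinyArch <- function(dataset, ...) {
  d <- dim(dataset@features)
  architectureConfig(nodes = d[1], inputFeatures = d[2], bands = d[3], ...)
}

# Direct brute-force GCN layer: per-node aggregation loop, independent of
# the matrix implementation.
loopGcnLayer <- function(X, Anorm, W) {
  N <- nrow(X); dout <- ncol(W)
  agg <- matrix(0, N, ncol(X))
  for (i in seq_len(N))
    for (j in seq_len(N))
      agg[i, ] <- agg[i, ] + Anorm[i, j] * X[j, ]
  out <- matrix(0, N, dout)
  for (i in seq_len(N))
    for (k in seq_len(dout))
      out[i, k] <- max(sum(agg[i, ] * W[, k]), 0)
  out
}

# Random normalized adjacency for oracle tests.
randomNormAdjacency <- function(n) {
  A <- matrix(runif(n * n), n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  normalizeAdjacency(A)
}
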