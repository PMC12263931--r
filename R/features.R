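# Differential-entropy node features. EEG band signals are approximately
# Gaussian, for which the differential entropy has the closed form
#   DE = 1/2 * log2(2 * pi * e * sigma^2)   (bits),
# with sigma^2 estimated by the unbiased sample variance. Each T-second
# segment yields M features per channel and band: DE over M evenly spaced,
# overlapping sub-windows.

#' Differential entropy of a signal window (Gaussian closed form, bits)
#'
#' Returns \code{0.5 * log2(2 * pi * e * var(x))} with the unbiased sample
#' variance. Monotone increasing in the variance; doubling the amplitude
#' adds exactly 1 bit.
#'
#' @param x numeric signal window, length >= 2.
#' @param varianceFloor windows whose sample variance falls below this floor
#'   are rejected (a constant window has DE diverging to -Inf).
#' @return differential entropy in bits.
#' @export
#' @examples
#' set.seed(1)
#' differentialEntropy(rnorm(5000))     # ~ 0.5 * log2(2 * pi * e) = 2.05
differentialEntropy <- function(x, varianceFloor = 1e-12) {
  if (length(x) < 2L) stop("window length must be >= 2")
  v <- var(x)
  if (!is.finite(v) || v < varianceFloor)
    stop("degenerate window: sample variance below the floor (",
         varianceFloor, ")")
  0.5 * log2(2 * pi * exp(1) * v)
}

#' Sub-window grid for per-segment feature extraction
#'
#' M sub-windows of length \code{w} seconds, evenly spaced over a T-second
#' segment: sub-window m starts at \code{m * (T - w) / (M - 1)} seconds,
#' m = 0 ... M-1 (for M = 1 a single window at 0).
#'
#' @param T segment length (seconds).
#' @param M number of sub-windows (default 32).
#' @param subwindowLength sub-window length \code{w} in seconds (default 1).
#' @return M x 2 matrix with columns \code{start}, \code{length} (seconds).
#' @export
featureGrid <- function(T, M = 32, subwindowLength = 1) {
  stopifnot(M >= 2 || (M == 1 && subwindowLength <= T))
  if (subwindowLength > T)
    stop("sub-window length exceeds the segment length")
  starts <- if (M == 1L) 0 else (seq_len(M) - 1L) * (T - subwindowLength) / (M - 1L)
  cbind(start = starts, length = rep(subwindowLength, M))
}

# Unbiased row variances of a channels x samples matrix.
.rowVars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  (rowMeans(m * m) - mu * mu) * n / (n - 1)
}

#' Differential-entropy node features of a segmented recording
#'
#' For every segment, channel, band and sub-window of the feature grid,
#' computes the differential entropy, giving one channels x M x bands array
#' per segment.
#'
#' @param segs a \linkS4class{SegmentSet}.
#' @param M number of sub-window features per node (default 32; must be
#'   >= 2 so that Pearson correlation over features is defined).
#' @param subwindowLength sub-window length in seconds (default 1).
#' @param varianceFloor passed to the variance check; a degenerate
#'   sub-window raises an error naming the (segment, channel, band).
#' @return list with \code{values} (list of channels x M x bands arrays,
#'   one per segment) and \code{grid} (the [featureGrid()] used).
#' @export
nodeFeatures <- function(segs, M = 32, subwindowLength = 1,
                         varianceFloor = 1e-12) {
  stopifnot(is(segs, "SegmentSet"), M >= 2)
  fs <- segs@samplingRate
  grid <- featureGrid(segs@windowLength, M, subwindowLength)
  wlen <- as.integer(round(subwindowLength * fs))
  if (wlen < 2L) stop("sub-window shorter than 2 samples")
  i0 <- as.integer(round(grid[, "start"] * fs))
  bands <- names(segs@segments[[1L]])
  nch <- length(segs@channelNames)
  const <- log2(2 * pi * exp(1))

  values <- lapply(seq_along(segs@segments), function(si) {
    seg <- segs@segments[[si]]
    arr <- array(NA_real_, c(nch, M, length(bands)),
                 dimnames = list(segs@channelNames, NULL, bands))
    for (b in seq_along(bands)) {
      mat <- seg[[b]]
      for (m in seq_len(M)) {
        v <- .rowVars(mat[, (i0[m] + 1L):(i0[m] + wlen), drop = FALSE])
        bad <- which(!is.finite(v) | v < varianceFloor)
        if (length(bad))
          stop(sprintf(
            "degenerate window in segment %d, channel %s, band %s, sub-window %d",
            si, segs@channelNames[bad[1L]], bands[b], m))
        arr[, m, b] <- 0.5 * (const + log2(v))
      }
    }
    arr
  })
  list(values = values, grid = grid)
}

#' Fit per-coordinate z-score statistics on training feature tensors
#'
#' Mean and standard deviation per (channel, feature, band) coordinate,
#' estimated over the supplied tensors only — fit this on the training
#' split alone and apply it everywhere to avoid leaking test statistics.
#'
#' @param trainFeatures channels x features x bands x samples array, or a
#'   list of channels x features x bands arrays.
#' @param sdFloor floor applied to the standard deviation so constant
#'   coordinates normalize to 0 (default 1e-8).
#' @return a \linkS4class{NormalizationStats}.
#' @export
fitNormalization <- function(trainFeatures, sdFloor = 1e-8) {
  if (is.list(trainFeatures))
    trainFeatures <- simplify2array(trainFeatures)
  if (length(dim(trainFeatures)) != 4L)
    stop("expected a 4-d array or list of 3-d arrays")
  if (dim(trainFeatures)[4L] < 1L) stop("empty training feature set")
  mu <- apply(trainFeatures, 1:3, mean)
  sg <- apply(trainFeatures, 1:3, sd)
  if (dim(trainFeatures)[4L] == 1L) sg[] <- 0
  sg <- pmax(sg, sdFloor)
  new("NormalizationStats", mean = mu, sd = sg, floor = sdFloor)
}

#' Apply fitted z-score statistics to feature tensors
#'
#' @param stats a \linkS4class{NormalizationStats} from
#'   [fitNormalization()].
#' @param features a channels x features x bands array (one sample) or a
#'   4-d array with samples in the last dimension.
#' @return normalized array of the same shape.
#' @export
applyNormalization <- function(stats, features) {
  stopifnot(is(stats, "NormalizationStats"))
  d <- dim(features)
  if (length(d) == 3L) {
    if (!identical(d, dim(stats@mean))) stop("shape mismatch with stats")
    return((features - stats@mean) / stats@sd)
  }
  if (length(d) != 4L || !identical(d[1:3], dim(stats@mean)))
    stop("shape mismatch with stats")
  sweep(sweep(features, 1:3, stats@mean, "-"), 1:3, stats@sd, "/")
}
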