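# Band decomposition, fixed-duration selection and sliding-window
# segmentation.

.bandTable <- data.frame(
  name = c("delta", "theta", "alpha", "beta", "gamma"),
  low  = c(0.5, 4, 8, 13, 25),
  high = c(4, 8, 13, 25, 45),
  stringsAsFactors = FALSE)

#' Canonical band names in pipeline order
#'
#' @return \code{c("delta", "theta", "alpha", "beta", "gamma")}. Band order
#'   is fixed across the whole pipeline and always asserted by name.
#' @export
bandNames <- function() .bandTable$name

#' EEG frequency band definitions
#'
#' The five canonical bands: delta 0.5-4 Hz, theta 4-8 Hz, alpha 8-13 Hz,
#' beta 13-25 Hz, gamma 25-45 Hz. A subset or custom table can be passed to
#' the decomposition for band-restricted analyses.
#'
#' @param names which bands to return (defaults to all five, canonical
#'   order).
#' @return data.frame with columns \code{name}, \code{low}, \code{high}
#'   (Hz).
#' @export
#' @examples
#' bandDefinitions()
#' bandDefinitions(c("alpha", "beta"))
bandDefinitions <- function(names = bandNames()) {
  unknown <- setdiff(names, .bandTable$name)
  if (length(unknown))
    stop("unknown band name(s): ", paste(unknown, collapse = ", "))
  out <- .bandTable[match(names, .bandTable$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select a fixed-duration leading portion of a recording
#'
#' Recordings of unequal length are unified by keeping `duration` seconds
#' (by default from the start; `offset` shifts the selection window).
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param duration seconds to keep.
#' @param offset start offset in seconds (default 0).
#' @return an \linkS4class{EEGRecording} of exactly
#'   \code{duration * samplingRate} samples, channel order preserved.
#' @export
selectFixedDuration <- function(rec, duration, offset = 0) {
  stopifnot(is(rec, "EEGRecording"), duration > 0, offset >= 0)
  fs <- rec@samplingRate
  n <- round(duration * fs)
  i0 <- round(offset * fs)
  if (i0 + n > ncol(rec@data))
    stop(sprintf(
      "recording for subject '%s' is shorter (%.1f s) than the requested %g s selection",
      rec@subjectId, ncol(rec@data) / fs - offset, duration))
  new("EEGRecording", subjectId = rec@subjectId, label = rec@label,
      channelNames = rec@channelNames, samplingRate = fs,
      data = rec@data[, (i0 + 1L):(i0 + n), drop = FALSE])
}

# Squared magnitude response |H|^2 of a 4th-order Butterworth bandpass
# (butter(2, band) yields an order-4 transfer function) on the FFT grid of
# an n-sample signal. Applying |H|^2 spectrally equals running the filter
# forward and backward (zero phase), with circular rather than zero-padded
# boundaries; one FFT pair per channel makes whole-cohort decomposition
# cheap.
.mag2Cache <- new.env(parent = emptyenv())

.butterMag2 <- function(n, fs, low, high) {
  key <- paste(n, fs, low, high, sep = "|")
  hit <- .mag2Cache[[key]]
  if (!is.null(hit)) return(hit)
  if (high >= fs / 2)
    stop(sprintf("band edge %g Hz is at or above the Nyquist frequency (%g Hz)",
                 high, fs / 2))
  bf <- signal::butter(2, c(low, high) / (fs / 2), type = "pass")
  e <- exp(complex(imaginary = -2 * pi * seq(0, n - 1) / n))
  horner <- function(cf) {
    acc <- rep(complex(real = cf[length(cf)]), n)
    for (k in rev(seq_len(length(cf) - 1L))) acc <- acc * e + cf[k]
    acc
  }
  mag2 <- Mod(horner(bf$b) / horner(bf$a))^2
  .mag2Cache[[key]] <- mag2
  mag2
}

# Zero-phase 4th-order Butterworth bandpass of a channels x samples matrix.
# Channels are demeaned first: DC lies outside every band, and removing it
# up front avoids leakage through the circular boundary.
.bandpassMatrix <- function(mat, fs, low, high) {
  n <- ncol(mat)
  mag2 <- .butterMag2(n, fs, low, high)
  X <- stats::mvfft(t(mat - rowMeans(mat)))
  t(Re(stats::mvfft(X * mag2, inverse = TRUE))) / n
}

# All bands of one matrix, reusing the forward transform across bands.
.bandpassMulti <- function(mat, fs, bands) {
  n <- ncol(mat)
  X <- stats::mvfft(t(mat - rowMeans(mat)))
  out <- lapply(seq_len(nrow(bands)), function(b) {
    mag2 <- .butterMag2(n, fs, bands$low[b], bands$high[b])
    t(Re(stats::mvfft(X * mag2, inverse = TRUE))) / n
  })
  names(out) <- bands$name
  out
}

#' Decompose a recording into frequency-band signals
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth bandpass
#' per band. Output length equals input length; the bands do not partition
#' the full spectrum (content below 0.5 Hz and above 45 Hz is discarded), so
#' summed band variance need not equal input variance.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param bands band table as from [bandDefinitions()].
#' @return a \linkS4class{BandSignals} object.
#' @export
bandpassDecompose <- function(rec, bands = bandDefinitions()) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@samplingRate
  sig <- .bandpassMulti(rec@data, fs, bands)
  new("BandSignals", subjectId = rec@subjectId, label = rec@label,
      channelNames = rec@channelNames, samplingRate = fs, signals = sig)
}

#' Segment band signals into overlapping sliding windows
#'
#' Windows of length \code{T} seconds advance by \code{T * (1 - overlap)}
#' seconds. \code{mode = "tenfold"} keeps exactly the first 10 windows —
#' the augmentation that expands an n-subject cohort to 10 n segments —
#' while \code{mode = "dense"} keeps every window that fits the recording.
#'
#' @param bs a \linkS4class{BandSignals} object.
#' @param T window length in seconds (default 10).
#' @param overlap overlap fraction in [0, 1) (default 0.9).
#' @param mode \code{"tenfold"} (default) or \code{"dense"}.
#' @return a \linkS4class{SegmentSet}.
#' @export
#' @examples
#' # a 300 s recording with T = 10, overlap 0.9 yields windows starting at
#' # 0, 1, 2, ... s; tenfold keeps the first 10, dense keeps all 291.
segmentWindows <- function(bs, T = 10, overlap = 0.9,
                           mode = c("tenfold", "dense")) {
  stopifnot(is(bs, "BandSignals"))
  mode <- match.arg(mode)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  fs <- bs@samplingRate
  win <- T * fs
  if (abs(win - round(win)) > 1e-8)
    stop("T * samplingRate must be an integer sample count")
  win <- as.integer(round(win))
  nsamp <- ncol(bs@signals[[1L]])
  if (win > nsamp) stop("window length T exceeds the recording length")
  step <- as.integer(round(T * (1 - overlap) * fs))
  if (step < 1L) stop("T * (1 - overlap) is below one sample")
  startIdx <- seq.int(0L, nsamp - win, by = step)
  if (mode == "tenfold") {
    if (length(startIdx) < 10L)
      stop("recording too short for the tenfold augmentation (needs 10 windows)")
    startIdx <- startIdx[1:10]
  }
  segments <- lapply(startIdx, function(i0)
    lapply(bs@signals, function(m) m[, (i0 + 1L):(i0 + win), drop = FALSE]))
  new("SegmentSet", subjectId = bs@subjectId, label = bs@label,
      channelNames = bs@channelNames, samplingRate = fs,
      windowLength = T, overlap = overlap,
      starts = startIdx / fs, segments = segments)
}
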