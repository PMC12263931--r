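# Band decomposition, fixed-duration selection and windowing.

makeRec <- function(data, fs, id = "sub-x", label = "HC") {
  rownames(data) <- montage1020()[seq_len(nrow(data))]
  new("EEGRecording", subjectId = id, label = label,
      channelNames = rownames(data), samplingRate = fs, data = data)
}

test_that("band definitions carry the canonical edges", {
  b <- bandDefinitions()
  expect_identical(b$name, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_identical(b$low, c(0.5, 4, 8, 13, 25))
  expect_identical(b$high, c(4, 8, 13, 25, 45))
  expect_error(bandDefinitions("mu"), "unknown band")
})

test_that("fixed-duration selection keeps the leading samples", {
  fs <- 100
  rec <- makeRec(matrix(seq_len(2 * 810 * fs) * 1.0, nrow = 2,
                        byrow = TRUE), fs)  # 13.5 min
  sel <- selectFixedDuration(rec, 300)
  expect_identical(ncol(sel@data), 300L * 100L)
  expect_identical(sel@data[, 1:5], rec@data[, 1:5])
  expect_identical(channelNames(sel), channelNames(rec))

  full <- selectFixedDuration(rec, 810)
  expect_identical(full@data, rec@data)

  short <- makeRec(matrix(rnorm(2 * 300 * fs), 2), fs)
  expect_error(selectFixedDuration(short, 301), "sub-x")
  off <- selectFixedDuration(rec, 10, offset = 2)
  expect_identical(off@data[, 1], rec@data[, 2 * fs + 1])
})

test_that("a pure alpha tone lands almost entirely in the alpha band", {
  fs <- 128
  tt <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * tt)
  rec <- makeRec(rbind(x, x), fs)
  bs <- bandpassDecompose(rec)
  # FFT-free oracle: output energy per band relative to input energy
  eIn <- sum(x^2)
  eOut <- vapply(bs@signals, function(m) sum(m[1, ]^2), 1)
  expect_gt(eOut[["alpha"]] / eIn, 0.95)
  for (b in c("delta", "theta", "beta", "gamma"))
    expect_lt(eOut[[b]] / eIn, 0.02)
})

test_that("DC input produces near-zero output in every band", {
  fs <- 128
  rec <- makeRec(matrix(5, 1, 10 * fs), fs)
  bs <- bandpassDecompose(rec)
  for (b in bandNames())
    expect_lt(max(abs(bs@signals[[b]])), 1e-6)
})

test_that("alpha filter bandwidth is close to its design edges", {
  fs <- 256
  set.seed(4)
  x <- rnorm(200 * fs)
  rec <- makeRec(matrix(x, 1), fs)
  bs <- bandpassDecompose(rec, bandDefinitions("alpha"))
  # periodogram oracle: -3 dB points of the smoothed output spectrum
  sp <- stats::spec.pgram(ts(bs@signals$alpha[1, ], frequency = fs),
                          spans = 51, plot = FALSE, taper = 0)
  peak <- max(sp$spec)
  inBand <- range(sp$freq[sp$spec >= peak / 2])
  expect_true(inBand[1] >= 7 && inBand[1] <= 9)
  expect_true(inBand[2] >= 12 && inBand[2] <= 14)
})

test_that("decomposition is linear in the input", {
  fs <- 128
  set.seed(8)
  x <- matrix(rnorm(2 * 10 * fs), 2)
  r1 <- bandpassDecompose(makeRec(x, fs), bandDefinitions("theta"))
  r2 <- bandpassDecompose(makeRec(3.5 * x, fs), bandDefinitions("theta"))
  expect_equal(3.5 * r1@signals$theta, r2@signals$theta, tolerance = 1e-10)
})

test_that("band edges above Nyquist are rejected", {
  fs <- 64  # gamma high edge 45 > 32
  rec <- makeRec(matrix(rnorm(fs * 10), 1), fs)
  expect_error(bandpassDecompose(rec), "Nyquist")
})

test_that("windowing reproduces the tenfold and dense counts", {
  fs <- 50
  oneBand <- bandDefinitions("delta")
  rec <- makeRec(matrix(rnorm(300 * fs), 1), fs)
  bs <- bandpassDecompose(rec, oneBand)

  tenfold <- segmentWindows(bs, T = 10, overlap = 0.9, mode = "tenfold")
  expect_length(tenfold@segments, 10L)
  expect_equal(tenfold@starts, 0:9)

  dense <- segmentWindows(bs, T = 10, overlap = 0.9, mode = "dense")
  expect_length(dense@segments, 291L)  # floor((300 - 10)/1) + 1

  non <- segmentWindows(
    bandpassDecompose(makeRec(matrix(rnorm(30 * fs), 1), fs), oneBand),
    T = 10, overlap = 0, mode = "dense")
  expect_length(non@segments, 3L)
  expect_equal(non@starts, c(0, 10, 20))

  expect_error(segmentWindows(bs, T = 10, overlap = 1), "overlap")
  expect_error(segmentWindows(bs, T = 400, overlap = 0.9), "exceeds")
})

test_that("every window lies inside the recording", {
  fs <- 50
  rec <- makeRec(matrix(rnorm(47 * fs), 1), fs)
  bs <- bandpassDecompose(rec, bandDefinitions("delta"))
  segs <- segmentWindows(bs, T = 10, overlap = 0.75, mode = "dense")
  win <- segs@windowLength
  expect_true(all(segs@starts + win <= 47))
  expect_true(all(vapply(segs@segments,
                         function(s) ncol(s$delta) == win * fs, TRUE)))
})
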