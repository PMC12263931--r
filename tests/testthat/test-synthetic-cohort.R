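# Synthetic cohort generator: determinism, shapes, class structure and the
# connectivity dial.

test_that("cohort generation is a pure function of the spec", {
  spec <- lightSpec(nAD = 2, nHC = 2, seed = 5)
  a <- generateSubject(spec, "AD", 1)
  b <- generateSubject(spec, "AD", 1)
  expect_identical(a@data, b@data)

  other <- generateSubject(lightSpec(nAD = 2, nHC = 2, seed = 6), "AD", 1)
  expect_false(identical(a@data, other@data))
  expect_identical(dim(a@data), dim(other@data))
})

test_that("generateCohort honors requested counts, labels and ids", {
  cohort <- generateCohort(lightSpec(nAD = 3, nHC = 2, seed = 9))
  expect_length(cohort, 5L)
  labs <- vapply(cohort, classLabel, "")
  expect_identical(sum(labs == "AD"), 3L)
  expect_identical(sum(labs == "HC"), 2L)
  ids <- vapply(cohort, subjectId, "")
  expect_false(anyDuplicated(ids) > 0)
  for (rec in cohort) expect_true(validObject(rec))
})

test_that("invalid labels and degenerate durations are rejected", {
  spec <- lightSpec()
  expect_error(generateSubject(spec, "MCI", 1), "label")
  expect_error(cohortSpec(nAD = 0), "nAD")
  expect_error(cohortSpec(duration = -10))
  expect_error(cohortSpec(duration = 10.37, samplingRate = 128), "integer")
})

test_that("zero connectivity yields nearly uncorrelated channels", {
  spec <- cohortSpec(nAD = 1, nHC = 1, duration = 300, samplingRate = 128,
                     connectivityStrength = c(AD = 0, HC = 0), seed = 21)
  rec <- generateSubject(spec, "HC", 1)
  C <- cor(t(rec@data))
  offdiag <- abs(C[upper.tri(C)])
  expect_lt(mean(offdiag), 0.1)
})

test_that("planted alpha suppression shows up in bandpassed variance", {
  # oracle: bandpass + windowed variance on the generated signals,
  # independent of the feature pipeline
  prof <- cbind(AD = c(1, 1, 0.5, 1, 1), HC = rep(1, 5))
  rownames(prof) <- bandNames()
  spec <- cohortSpec(nAD = 20, nHC = 20, duration = 20, samplingRate = 128,
                     bandVarianceProfile = prof, subjectLogSd = 0.15,
                     seed = 33)
  alphaVar <- function(label, i) {
    rec <- generateSubject(spec, label, i)
    bs <- bandpassDecompose(rec, bandDefinitions("alpha"))
    mean(apply(bs@signals$alpha, 1, var))
  }
  vAD <- vapply(1:20, function(i) alphaVar("AD", i), 1)
  vHC <- vapply(1:20, function(i) alphaVar("HC", i), 1)
  expect_gt(mean(vAD) / mean(vHC), 0.35)
  expect_lt(mean(vAD) / mean(vHC), 0.7)
})

test_that("mean functional adjacency rises with connectivity strength", {
  meanAdj <- function(w) {
    spec <- cohortSpec(nAD = 1, nHC = 2, duration = 20, samplingRate = 128,
                       connectivityStrength = c(AD = w, HC = w),
                       connectivitySd = 0, seed = 50)
    ds <- buildGraphDataset(spec, M = 8)
    A <- ds@adjacency
    mean(vapply(seq_len(dim(A)[4]), function(s) {
      m <- A[, , "alpha", s]
      mean(m[upper.tri(m)])
    }, 1))
  }
  vals <- vapply(c(0, 0.3, 0.6, 0.9), meanAdj, 1)
  expect_true(all(diff(vals) >= 0))
})

test_that("DE group contrast follows the configured band profile", {
  # default profile: AD > HC in delta/theta, AD < HC in alpha
  ds <- buildGraphDataset(lightSpec(nAD = 20, nHC = 20, seed = 61), M = 8)
  subj <- !duplicated(ds@meta$subject_id)
  meanDE <- function(band, lab) {
    idx <- which(ds@meta$label == lab)
    mean(ds@features[, , band, idx])
  }
  expect_gt(meanDE("delta", "AD"), meanDE("delta", "HC"))
  expect_gt(meanDE("theta", "AD"), meanDE("theta", "HC"))
  expect_lt(meanDE("alpha", "AD"), meanDE("alpha", "HC"))
})
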