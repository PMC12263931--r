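# Synthetic EEG cohort generator. Each channel is, per band, a mixture of a
# band-limited shared source and band-limited private noise:
#   x_ch = sum_bands sd_band * (sqrt(w) * s_shared + sqrt(1 - w) * p_ch)
# so band variance and inter-channel correlation are both analytically
# controllable. Class structure enters through the per-class band-variance
# profile (AD: elevated delta/theta, suppressed alpha) and through the
# shared-source weight w (AD: weakened connectivity).

# Baseline per-band signal scale (microvolt sd) of the HC profile; resting
# eyes-closed EEG is dominated by low-frequency and alpha activity.
.baseBandSd <- c(delta = 20, theta = 15, alpha = 20, beta = 10, gamma = 5)

# Default class contrast: variance multipliers follow the AD pattern —
# slowing (elevated delta/theta), suppressed mid/high bands with alpha the
# strongest single discriminator. Jointly with the between-subject
# log-variance sd (0.25) the magnitudes put each single band well below
# the five-band combination. See the methods vignette for the calibration.
.defaultProfile <- function() {
  m <- cbind(AD = c(1.5, 1.5, 0.55, 0.75, 0.75),
             HC = c(1.0, 1.0, 1.0, 1.0, 1.0))
  rownames(m) <- bandNames()
  m
}

#' Specify a synthetic EEG cohort
#'
#' Builds a validated \linkS4class{CohortSpec}. The defaults emulate a
#' 36 AD / 29 HC resting-state cohort: 19 channels of the 10-20 montage,
#' 500 Hz, 300 s per subject, AD-elevated delta/theta variance, AD-suppressed
#' alpha variance, and AD-weakened inter-channel connectivity.
#'
#' @param nAD,nHC subjects per class (defaults 36 and 29).
#' @param nChannels montage size; the first \code{nChannels} labels of
#'   [montage1020()] are used.
#' @param samplingRate Hz (default 500).
#' @param duration seconds per subject (default 300).
#' @param bandVarianceProfile 5 x 2 multiplier matrix (bands x AD/HC); see
#'   \linkS4class{CohortSpec}.
#' @param connectivityStrength named \code{c(AD=, HC=)} shared-source weight
#'   in [0, 1]; the default weakens AD connectivity (0.3 vs 0.6).
#' @param subjectLogSd between-subject log-variance sd per band (default
#'   0.25).
#' @param connectivitySd between-subject logit-scale sd of the connectivity
#'   weight (default 0.35).
#' @param effectChannels optional channels carrying the class contrast (see
#'   \linkS4class{CohortSpec}); empty means all channels.
#' @param seed integer root seed.
#' @return a \linkS4class{CohortSpec}.
#' @export
#' @examples
#' spec <- cohortSpec(nAD = 2, nHC = 2, duration = 20, samplingRate = 128)
#' spec
cohortSpec <- function(nAD = 36, nHC = 29, nChannels = 19,
                       samplingRate = 500, duration = 300,
                       bandVarianceProfile = .defaultProfile(),
                       connectivityStrength = c(AD = 0.3, HC = 0.6),
                       subjectLogSd = 0.25, connectivitySd = 0.35,
                       effectChannels = character(0), seed = 1L) {
  new("CohortSpec", nAD = as.integer(nAD), nHC = as.integer(nHC),
      nChannels = as.integer(nChannels),
      samplingRate = samplingRate, duration = duration,
      bandVarianceProfile = bandVarianceProfile,
      connectivityStrength = connectivityStrength[c("AD", "HC")],
      subjectLogSd = subjectLogSd, connectivitySd = connectivitySd,
      effectChannels = effectChannels, seed = as.integer(seed))
}

# Deterministic per-subject seed derived from (root seed, label, index) so
# cohorts are reproducible subject by subject.
.subjectSeed <- function(seed, label, index) {
  lab <- if (label == "AD") 1 else 2
  as.integer((as.double(seed) + lab * 1000003 + index * 9973) %% 2147483647)
}

# Unit-variance band-limited noise, one row per source.
.bandNoiseRows <- function(rows, n, fs, low, high) {
  x <- .bandpassMatrix(matrix(rnorm(rows * n), rows), fs, low, high)
  x / sqrt(.rowVars(x))
}

#' Generate one synthetic subject
#'
#' Deterministic given \code{(spec@seed, label, subjectIndex)}. Per band,
#' the subject's variance multiplier is the class profile value perturbed by
#' a log-normal between-subject factor; channels mix a shared band-limited
#' source (weight \code{w}, the class connectivity strength on the logit
#' scale plus subject noise) with private band-limited noise.
#'
#' When \code{spec@effectChannels} is non-empty, only those channels carry
#' the class variance contrast (all others use the HC profile) and the
#' connectivity weight follows the HC value for both classes, so the planted
#' class signal is confined to the named channels.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param label \code{"AD"} or \code{"HC"}.
#' @param subjectIndex 1-based index within the class.
#' @return an \linkS4class{EEGRecording}.
#' @export
generateSubject <- function(spec, label, subjectIndex) {
  validObject(spec)
  if (!label %in% c("AD", "HC")) stop("label must be 'AD' or 'HC'")
  stopifnot(subjectIndex >= 1)
  fs <- spec@samplingRate
  n <- as.integer(round(spec@duration * fs))
  nch <- spec@nChannels
  channels <- montage1020()[seq_len(nch)]
  bands <- bandDefinitions()
  planted <- length(spec@effectChannels) > 0L

  set.seed(.subjectSeed(spec@seed, label, subjectIndex))
  subjFactor <- exp(rnorm(nrow(bands), 0, spec@subjectLogSd))
  wClass <- if (planted) spec@connectivityStrength[["HC"]] else
    spec@connectivityStrength[[label]]
  w <- plogis(qlogis(wClass) + rnorm(1L, 0, spec@connectivitySd))
  if (wClass == 0) w <- 0
  if (wClass == 1) w <- 1

  data <- matrix(0, nch, n)
  for (b in seq_len(nrow(bands))) {
    bname <- bands$name[b]
    # row 1: shared source; rows 2..nch+1: private noise per channel
    src <- .bandNoiseRows(nch + 1L, n, fs, bands$low[b], bands$high[b])
    mult <- rep(spec@bandVarianceProfile[bname, label], nch)
    if (planted)
      mult[!channels %in% spec@effectChannels] <-
        spec@bandVarianceProfile[bname, "HC"]
    sdCh <- .baseBandSd[[bname]] * sqrt(mult * subjFactor[b])
    mix <- sqrt(w) * matrix(src[1L, ], nch, n, byrow = TRUE) +
      sqrt(1 - w) * src[-1L, , drop = FALSE]
    data <- data + sdCh * mix
  }
  rownames(data) <- channels
  new("EEGRecording",
      subjectId = sprintf("sub-%s%03d", tolower(label), subjectIndex),
      label = label, channelNames = channels, samplingRate = fs,
      data = data)
}

#' Generate a full labelled cohort
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return list of \code{spec@nAD + spec@nHC} \linkS4class{EEGRecording}
#'   objects (AD subjects first) with unique subject ids.
#' @export
#' @examples
#' cohort <- generateCohort(cohortSpec(nAD = 2, nHC = 1, duration = 20,
#'                                     samplingRate = 128))
#' vapply(cohort, classLabel, character(1))
generateCohort <- function(spec) {
  validObject(spec)
  c(lapply(seq_len(spec@nAD), function(i) generateSubject(spec, "AD", i)),
    lapply(seq_len(spec@nHC), function(i) generateSubject(spec, "HC", i)))
}
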