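# Central S4 containers. Validity methods enforce the structural invariants
# the downstream stages rely on (channel/band bookkeeping, finiteness,
# subject-level integrity); numerical contracts are covered by the test suite.

#' Cohort specification for the synthetic EEG generator
#'
#' Describes a labelled synthetic cohort: group sizes, montage size, sampling
#' rate, duration, the per-class band-variance profile, and the per-class
#' shared-source connectivity strength. The generated cohort is a pure
#' function of this object (including its seed).
#'
#' @slot nAD,nHC number of AD / HC subjects (each at least 1).
#' @slot nChannels number of montage channels (19 for the full 10-20 set).
#' @slot samplingRate sampling rate in Hz.
#' @slot duration recording duration in seconds; \code{duration *
#'   samplingRate} must be an integer sample count.
#' @slot bandVarianceProfile 5 x 2 matrix of strictly positive variance
#'   multipliers, rows named by band (delta..gamma), columns \code{"AD"} and
#'   \code{"HC"}.
#' @slot connectivityStrength named numeric \code{c(AD=, HC=)} in [0,1]:
#'   weight of the per-band shared source when mixing channels.
#' @slot subjectLogSd standard deviation of the per-subject, per-band
#'   log-normal variance perturbation (between-subject variability).
#' @slot connectivitySd standard deviation of the per-subject logit-scale
#'   perturbation of the connectivity strength.
#' @slot effectChannels optional channel names; when non-empty the AD/HC
#'   band-variance contrast is planted only in those channels (all other
#'   channels, and the connectivity strength, follow the HC profile for both
#'   classes).
#' @slot seed integer root seed; per-subject streams are derived from
#'   (seed, label, subject index).
#' @seealso [cohortSpec()], [generateSubject()], [generateCohort()]
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nAD = "integer", nHC = "integer", nChannels = "integer",
    samplingRate = "numeric", duration = "numeric",
    bandVarianceProfile = "matrix", connectivityStrength = "numeric",
    subjectLogSd = "numeric", connectivitySd = "numeric",
    effectChannels = "character", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (object@nAD < 1L || object@nHC < 1L)
    msg <- c(msg, "nAD and nHC must each be >= 1")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  n <- object@duration * object@samplingRate
  if (abs(n - round(n)) > 1e-8)
    msg <- c(msg, "duration * samplingRate must be an integer sample count")
  prof <- object@bandVarianceProfile
  if (!all(dim(prof) == c(5L, 2L)) ||
      !identical(rownames(prof), bandNames()) ||
      !identical(colnames(prof), c("AD", "HC")))
    msg <- c(msg, "bandVarianceProfile must be 5x2 with band rows and AD/HC columns")
  else if (any(!is.finite(prof)) || any(prof <= 0))
    msg <- c(msg, "variance multipliers must be strictly positive")
  w <- object@connectivityStrength
  if (!identical(sort(names(w)), c("AD", "HC")) || any(w < 0) || any(w > 1))
    msg <- c(msg, "connectivityStrength must be named c(AD=, HC=) in [0, 1]")
  if (length(object@effectChannels) &&
      !all(object@effectChannels %in% montage1020()))
    msg <- c(msg, "effectChannels must be 10-20 montage labels")
  if (length(msg)) msg else TRUE
})

#' One subject's multi-channel EEG recording
#'
#' @slot subjectId subject identifier.
#' @slot label class label, \code{"AD"} or \code{"HC"} (may be \code{NA} for
#'   unlabelled ingested data).
#' @slot channelNames ordered 10-20 montage labels, one per data row.
#' @slot samplingRate sampling rate in Hz.
#' @slot data channels x samples numeric matrix, microvolt scale.
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    subjectId = "character", label = "character",
    channelNames = "character", samplingRate = "numeric", data = "matrix"))

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, "channel count must equal length(channelNames)")
  if (!all(object@channelNames %in% montage1020()))
    msg <- c(msg, paste("unknown channel name(s):",
      paste(setdiff(object@channelNames, montage1020()), collapse = ", ")))
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "duplicated channel names")
  if (!is.na(object@label) && !object@label %in% c("AD", "HC"))
    msg <- c(msg, "label must be 'AD', 'HC' or NA")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "data contains non-finite samples")
  if (length(msg)) msg else TRUE
})

#' Band-decomposed signals of one recording
#'
#' @slot subjectId,label,channelNames,samplingRate as in
#'   \linkS4class{EEGRecording}.
#' @slot signals named list (one element per band, canonical order) of
#'   channels x samples matrices, all the same shape.
#' @exportClass BandSignals
setClass("BandSignals",
  representation(
    subjectId = "character", label = "character",
    channelNames = "character", samplingRate = "numeric", signals = "list"))

setValidity("BandSignals", function(object) {
  msg <- character(0)
  if (!length(object@signals) || is.null(names(object@signals)))
    msg <- c(msg, "signals must be a named list of band matrices")
  dims <- lapply(object@signals, dim)
  if (length(unique(dims)) > 1L)
    msg <- c(msg, "all bands must have the same channels x samples shape")
  if (length(object@signals) &&
      nrow(object@signals[[1L]]) != length(object@channelNames))
    msg <- c(msg, "band matrices must have one row per channel")
  if (length(msg)) msg else TRUE
})

#' Sliding-window segments of one band-decomposed recording
#'
#' @slot subjectId,label,channelNames,samplingRate as in
#'   \linkS4class{BandSignals}.
#' @slot windowLength window length T in seconds.
#' @slot overlap overlap fraction in [0, 1).
#' @slot starts window start times in seconds, ordered.
#' @slot segments list of segments; each is a named list (per band) of
#'   channels x window-samples matrices.
#' @exportClass SegmentSet
setClass("SegmentSet",
  representation(
    subjectId = "character", label = "character",
    channelNames = "character", samplingRate = "numeric",
    windowLength = "numeric", overlap = "numeric",
    starts = "numeric", segments = "list"))

setValidity("SegmentSet", function(object) {
  msg <- character(0)
  if (length(object@starts) != length(object@segments))
    msg <- c(msg, "one start time per segment required")
  if (is.unsorted(object@starts))
    msg <- c(msg, "segments must be ordered by start time")
  if (object@overlap < 0 || object@overlap >= 1)
    msg <- c(msg, "overlap must be in [0, 1)")
  ws <- object@windowLength * object@samplingRate
  if (abs(ws - round(ws)) > 1e-8)
    msg <- c(msg, "windowLength * samplingRate must be an integer")
  if (length(msg)) msg else TRUE
})

#' Per-coordinate z-score statistics fitted on a training split
#'
#' @slot mean,sd channels x features x bands arrays; \code{sd} is floored at
#'   \code{floor} so constant coordinates map to 0 rather than NaN.
#' @slot floor the standard-deviation floor applied.
#' @exportClass NormalizationStats
setClass("NormalizationStats",
  representation(mean = "array", sd = "array", floor = "numeric"))

setValidity("NormalizationStats", function(object) {
  if (!identical(dim(object@mean), dim(object@sd)))
    return("mean and sd must have identical dimensions")
  if (any(object@sd <= 0)) return("sd must be strictly positive (floored)")
  TRUE
})

#' Graph-ready dataset: DE feature tensors plus adjacency tensors
#'
#' One sample per segment. Features are stored un-normalized (normalization
#' is fitted on the training split at training time); functional adjacency
#' is stored raw (absolute Pearson, diagonal 1) so channels can be dropped
#' before symmetric normalization; the structural adjacency is the raw
#' same-region binary matrix.
#'
#' @slot features channels x features x bands x samples array of DE values.
#' @slot adjacency channels x channels x bands x samples array of absolute
#'   Pearson correlations.
#' @slot structural channels x channels binary same-region matrix.
#' @slot meta data.frame with one row per sample: \code{subject_id},
#'   \code{label}, \code{start} (window start, seconds).
#' @slot channels channel names (dimension 1 of all tensors).
#' @slot bands band names (canonical order).
#' @slot featureGrid features x 2 matrix of sub-window (start, length) in
#'   seconds.
#' @exportClass GraphDataset
setClass("GraphDataset",
  representation(
    features = "array", adjacency = "array", structural = "matrix",
    meta = "data.frame", channels = "character", bands = "character",
    featureGrid = "matrix"))

setValidity("GraphDataset", function(object) {
  msg <- character(0)
  df <- dim(object@features); da <- dim(object@adjacency)
  if (length(df) != 4L || length(da) != 4L)
    return("features and adjacency must be 4-d arrays")
  n <- length(object@channels)
  if (df[1L] != n || da[1L] != n || da[2L] != n)
    msg <- c(msg, "tensor channel dimensions must match channels")
  if (df[3L] != length(object@bands) || da[3L] != length(object@bands))
    msg <- c(msg, "tensor band dimensions must match bands")
  if (df[4L] != nrow(object@meta) || da[4L] != nrow(object@meta))
    msg <- c(msg, "sample dimension must match meta rows")
  if (!all(dim(object@structural) == c(n, n)))
    msg <- c(msg, "structural must be channels x channels")
  if (!all(c("subject_id", "label", "start") %in% names(object@meta)))
    msg <- c(msg, "meta must have subject_id, label, start")
  if (any(!is.finite(object@features)))
    msg <- c(msg, "non-finite feature values")
  if (length(msg)) msg else TRUE
})

#' Architecture of the multi-graph convolutional classifier
#'
#' Defaults reproduce the reference configuration: N = 19 nodes, M = 32
#' input DE features, K = 16 GCN hidden units, L = 2 GCN output units,
#' J = 5 bands, fully connected widths S = 128 and F = 32, Z = 2 classes.
#'
#' @slot nodes,inputFeatures,gcnHidden,gcnOutput,bands,fcHidden1,fcHidden2,classes
#'   layer dimensions (all at least 1).
#' @slot weightSharing \code{"per_band"} (separate GCN weights per band, the
#'   default) or \code{"shared"}.
#' @slot gcnBias logical; GCN layers carry no bias by default.
#' @exportClass ArchitectureConfig
setClass("ArchitectureConfig",
  representation(
    nodes = "integer", inputFeatures = "integer", gcnHidden = "integer",
    gcnOutput = "integer", bands = "integer", fcHidden1 = "integer",
    fcHidden2 = "integer", classes = "integer", weightSharing = "character",
    gcnBias = "logical"))

setValidity("ArchitectureConfig", function(object) {
  dims <- c(object@nodes, object@inputFeatures, object@gcnHidden,
            object@gcnOutput, object@bands, object@fcHidden1,
            object@fcHidden2, object@classes)
  if (any(dims < 1L)) return("all dimensions must be >= 1")
  if (!object@weightSharing %in% c("per_band", "shared"))
    return("weightSharing must be 'per_band' or 'shared'")
  TRUE
})

#' Optimization settings for model training
#'
#' Defaults follow the reference configuration: Adam with learning rate
#' 0.001, batch size 10, 200 epochs, cross-entropy loss.
#'
#' @slot learningRate Adam step size.
#' @slot batchSize minibatch size.
#' @slot epochs number of passes over the training split.
#' @slot seed integer seed controlling weight initialization and shuffling.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@learningRate < 0) return("learningRate must be >= 0")
  if (object@batchSize < 1L || object@epochs < 1L)
    return("batchSize and epochs must be >= 1")
  TRUE
})

#' A trained multi-graph convolutional classifier
#'
#' @slot arch the \linkS4class{ArchitectureConfig} used.
#' @slot params named list of weight matrices (per-band GCN weights
#'   \code{W0}/\code{W1}, fully connected \code{Wf1..Wf3} with biases
#'   \code{bf1..bf3}).
#' @slot normStats the \linkS4class{NormalizationStats} fitted on the
#'   training split.
#' @slot lossCurves data.frame (epoch, train, test) of mean cross-entropy.
#' @slot bands,channels the band/channel names the model was trained on.
#' @slot trainConfig the \linkS4class{TrainConfig} used.
#' @exportClass MultiGCN
setClass("MultiGCN",
  representation(
    arch = "ArchitectureConfig", params = "list",
    normStats = "NormalizationStats", lossCurves = "data.frame",
    bands = "character", channels = "character",
    trainConfig = "TrainConfig"))

#' Classification metrics at a decision threshold, plus ROC-AUC
#'
#' Percent-scale accuracy, precision, recall, F1 and AUC with the underlying
#' confusion counts (AD is the positive class).
#'
#' @slot accuracy,precision,recall,f1,auc metrics in percent.
#' @slot tp,tn,fp,fn confusion counts at the threshold.
#' @slot threshold decision threshold on the AD-class probability.
#' @slot provenance free-text description of the split that produced the
#'   scores.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    accuracy = "numeric", precision = "numeric", recall = "numeric",
    f1 = "numeric", auc = "numeric",
    tp = "integer", tn = "integer", fp = "integer", fn = "integer",
    threshold = "numeric", provenance = "character"))

#' Subject-level train/test split (with optional CV folds)
#'
#' @slot assignment named character: subject id -> \code{"train"} or
#'   \code{"test"}.
#' @slot labels named character: subject id -> class label.
#' @slot folds named integer: training subject id -> fold number (empty
#'   until [kfoldPlan()] is applied).
#' @slot testFraction,seed the parameters that produced the plan.
#' @exportClass SplitPlan
setClass("SplitPlan",
  representation(assignment = "character", labels = "character",
                 folds = "integer",
                 testFraction = "numeric", seed = "integer"))

setValidity("SplitPlan", function(object) {
  msg <- character(0)
  if (!all(object@assignment %in% c("train", "test")))
    msg <- c(msg, "assignment values must be 'train' or 'test'")
  if (is.null(names(object@assignment)))
    msg <- c(msg, "assignment must be named by subject id")
  if (length(object@folds) &&
      !all(names(object@folds) %in%
           names(object@assignment)[object@assignment == "train"]))
    msg <- c(msg, "folds may only cover training subjects")
  if (length(msg)) msg else TRUE
})
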