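#' @name eegmgcn-accessors
#' @title Accessors for eegmgcn classes
#'
#' @description Small accessor generics: \code{channelNames()},
#' \code{samplingRate()}, \code{subjectId()}, \code{classLabel()},
#' \code{nSamples()} (number of dataset samples / segments) and
#' \code{lossCurves()} (per-epoch training and test cross-entropy of a
#' fitted model).
#'
#' @param object an eegmgcn object.
#' @return the corresponding slot value.
NULL

#' @rdname eegmgcn-accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname eegmgcn-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname eegmgcn-accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname eegmgcn-accessors
#' @export
setGeneric("classLabel", function(object) standardGeneric("classLabel"))
#' @rdname eegmgcn-accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @rdname eegmgcn-accessors
#' @export
setGeneric("lossCurves", function(object) standardGeneric("lossCurves"))

#' @rdname eegmgcn-accessors
setMethod("channelNames", "EEGRecording", function(object) object@channelNames)
#' @rdname eegmgcn-accessors
setMethod("channelNames", "BandSignals", function(object) object@channelNames)
#' @rdname eegmgcn-accessors
setMethod("channelNames", "SegmentSet", function(object) object@channelNames)
#' @rdname eegmgcn-accessors
setMethod("channelNames", "GraphDataset", function(object) object@channels)
#' @rdname eegmgcn-accessors
setMethod("channelNames", "MultiGCN", function(object) object@channels)

#' @rdname eegmgcn-accessors
setMethod("samplingRate", "EEGRecording", function(object) object@samplingRate)
#' @rdname eegmgcn-accessors
setMethod("samplingRate", "BandSignals", function(object) object@samplingRate)
#' @rdname eegmgcn-accessors
setMethod("samplingRate", "SegmentSet", function(object) object@samplingRate)

#' @rdname eegmgcn-accessors
setMethod("subjectId", "EEGRecording", function(object) object@subjectId)
#' @rdname eegmgcn-accessors
setMethod("classLabel", "EEGRecording", function(object) object@label)

#' @rdname eegmgcn-accessors
setMethod("nSamples", "GraphDataset", function(object) nrow(object@meta))
#' @rdname eegmgcn-accessors
setMethod("lossCurves", "MultiGCN", function(object) object@lossCurves)

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nAD, "AD +", object@nHC, "HC subjects,",
      object@nChannels, "channels @", object@samplingRate, "Hz,",
      object@duration, "s\n")
  cat("  connectivity strength: AD =", object@connectivityStrength[["AD"]],
      ", HC =", object@connectivityStrength[["HC"]], "\n")
  if (length(object@effectChannels))
    cat("  class contrast restricted to:",
        paste(object@effectChannels, collapse = ", "), "\n")
})

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording", object@subjectId, "(", object@label, "):",
      nrow(object@data), "channels x", ncol(object@data), "samples @",
      object@samplingRate, "Hz\n")
})

setMethod("show", "BandSignals", function(object) {
  cat("BandSignals", object@subjectId, ":",
      paste(names(object@signals), collapse = ", "), "|",
      length(object@channelNames), "channels x",
      ncol(object@signals[[1L]]), "samples\n")
})

setMethod("show", "SegmentSet", function(object) {
  cat("SegmentSet", object@subjectId, ":", length(object@segments),
      "windows of", object@windowLength, "s (overlap",
      object@overlap, ")\n")
})

setMethod("show", "GraphDataset", function(object) {
  d <- dim(object@features)
  cat("GraphDataset:", d[4L], "segments |", d[1L], "channels x", d[2L],
      "DE features x", d[3L], "bands\n")
  tab <- table(object@meta$label[!duplicated(object@meta$subject_id)])
  cat("  subjects:", paste(sprintf("%s=%d", names(tab), tab),
      collapse = ", "), "\n")
})

setMethod("show", "ArchitectureConfig", function(object) {
  cat(sprintf(
    "ArchitectureConfig: N=%d M=%d K=%d L=%d J=%d S=%d F=%d Z=%d (%s%s)\n",
    object@nodes, object@inputFeatures, object@gcnHidden, object@gcnOutput,
    object@bands, object@fcHidden1, object@fcHidden2, object@classes,
    object@weightSharing, if (object@gcnBias) ", gcn bias" else ""))
})

setMethod("show", "MultiGCN", function(object) {
  show(object@arch)
  cat("  trained", object@trainConfig@epochs, "epochs; final loss: train",
      sprintf("%.4f", tail(object@lossCurves$train, 1L)), "/ test",
      sprintf("%.4f", tail(object@lossCurves$test, 1L)), "\n")
  cat("  parameters:", countParameters(object), "\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport [%s]\n  Acc %.2f%%  Pre %.2f%%  Rec %.2f%%  F1 %.2f%%  AUC %.2f%%\n",
    object@provenance, object@accuracy, object@precision, object@recall,
    object@f1, object@auc))
  cat(sprintf("  TP=%d TN=%d FP=%d FN=%d @ threshold %.2f\n",
    object@tp, object@tn, object@fp, object@fn, object@threshold))
})

setMethod("show", "SplitPlan", function(object) {
  cat("SplitPlan:", sum(object@assignment == "train"), "train /",
      sum(object@assignment == "test"), "test subjects")
  if (length(object@folds))
    cat(";", max(object@folds), "CV folds over the training subjects")
  cat("\n")
})

#' @describeIn computeMetrics coerce a report to a one-row data.frame.
#' @param x a \linkS4class{MetricsReport}.
#' @param row.names,optional,... passed through (unused).
#' @export
as.data.frame.MetricsReport <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(accuracy = x@accuracy, precision = x@precision,
             recall = x@recall, f1 = x@f1, auc = x@auc,
             tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn,
             stringsAsFactors = FALSE)
}
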