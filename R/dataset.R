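# Assemble the graph-ready dataset: per segment, a DE feature tensor and a
# per-band functional adjacency, plus the shared structural adjacency.
# Subjects are processed one at a time so full-cohort raw signals are never
# held in memory together.

#' Build a graph-ready dataset from a cohort (or generate one on the fly)
#'
#' Runs the full front end per subject: fixed-duration selection, band
#' decomposition, sliding-window segmentation, DE feature extraction, and
#' per-segment functional adjacency. Features and adjacencies are stored
#' raw; normalization (z-scoring of features on the training split, degree
#' normalization of adjacencies) happens at training time.
#'
#' @param x a \linkS4class{CohortSpec} (subjects are generated lazily) or a
#'   list of \linkS4class{EEGRecording} objects.
#' @param bands band table from [bandDefinitions()].
#' @param duration fixed selection length in seconds; \code{NULL} (default)
#'   keeps each full recording.
#' @param T,overlap,mode window parameters, see [segmentWindows()].
#' @param M,subwindowLength feature-grid parameters, see [nodeFeatures()].
#' @param selectionOffset start offset of the fixed-duration selection.
#' @return a \linkS4class{GraphDataset}.
#' @export
buildGraphDataset <- function(x, bands = bandDefinitions(), duration = NULL,
                              T = 10, overlap = 0.9,
                              mode = c("tenfold", "dense"),
                              M = 32, subwindowLength = 1,
                              selectionOffset = 0) {
  mode <- match.arg(mode)
  recs <- if (is(x, "CohortSpec")) {
    c(lapply(seq_len(x@nAD), function(i) list(label = "AD", index = i)),
      lapply(seq_len(x@nHC), function(i) list(label = "HC", index = i)))
  } else {
    stopifnot(is.list(x), all(vapply(x, is, logical(1), "EEGRecording")))
    x
  }

  features <- list(); adjacency <- list(); meta <- list()
  channels <- NULL; grid <- NULL
  for (i in seq_along(recs)) {
    rec <- if (is(x, "CohortSpec"))
      generateSubject(x, recs[[i]]$label, recs[[i]]$index) else recs[[i]]
    if (is.null(channels)) channels <- rec@channelNames
    if (!identical(rec@channelNames, channels))
      stop("inconsistent channel order across subjects (subject ",
           rec@subjectId, ")")
    if (!is.null(duration))
      rec <- selectFixedDuration(rec, duration, selectionOffset)
    bs <- bandpassDecompose(rec, bands)
    segs <- segmentWindows(bs, T = T, overlap = overlap, mode = mode)
    nf <- nodeFeatures(segs, M = M, subwindowLength = subwindowLength)
    grid <- nf$grid
    for (s in seq_along(nf$values)) {
      features[[length(features) + 1L]] <- nf$values[[s]]
      adjacency[[length(adjacency) + 1L]] <-
        .adjacencyFromFeatures(nf$values[[s]])
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = segs@subjectId, label = segs@label,
        start = segs@starts[s], stringsAsFactors = FALSE)
    }
  }
  new("GraphDataset",
      features = simplify2array(features),
      adjacency = simplify2array(adjacency),
      structural = structuralAdjacency(channels),
      meta = do.call(rbind, meta),
      channels = channels, bands = bands$name, featureGrid = grid)
}

#' Persist a dataset's DE feature tensors as portable text
#'
#' Writes \code{features.csv} (one row per segment/channel/band, one column
#' per sub-window feature) and a JSON sidecar \code{features.json} with the
#' segment table (subject_id, label, start), channel and band names, and
#' the sub-window grid. Functional adjacencies are not stored: they are a
#' deterministic function of the features and are rebuilt on read.
#'
#' @param dataset a \linkS4class{GraphDataset}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeFeatureArchive <- function(dataset, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writeFeatureArchive needs the jsonlite package")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(dataset@features)
  rows <- expand.grid(channel = dataset@channels, band = dataset@bands,
                      sample = seq_len(d[4L]), stringsAsFactors = FALSE)
  vals <- matrix(aperm(dataset@features, c(1L, 3L, 4L, 2L)),
                 nrow = nrow(rows), ncol = d[2L])
  colnames(vals) <- sprintf("f%02d", seq_len(d[2L]))
  utils::write.csv(cbind(rows, vals), file.path(dir, "features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(meta = dataset@meta, channels = dataset@channels,
         bands = dataset@bands,
         grid = as.data.frame(dataset@featureGrid)),
    file.path(dir, "features.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a feature archive written by [writeFeatureArchive()]
#'
#' @param dir archive directory.
#' @return a \linkS4class{GraphDataset} with functional adjacencies
#'   recomputed from the stored features.
#' @export
readFeatureArchive <- function(dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("readFeatureArchive needs the jsonlite package")
  side <- jsonlite::read_json(file.path(dir, "features.json"),
                              simplifyVector = TRUE)
  tab <- utils::read.csv(file.path(dir, "features.csv"),
                         stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", names(tab))
  M <- length(fcols)
  nch <- length(side$channels); nb <- length(side$bands)
  ns <- nrow(side$meta)
  arr <- aperm(array(as.matrix(tab[, fcols]), c(nch, nb, ns, M)),
               c(1L, 4L, 2L, 3L))
  dimnames(arr) <- list(side$channels, NULL, side$bands, NULL)
  adjacency <- vapply(seq_len(ns), function(s)
    .adjacencyFromFeatures(arr[, , , s, drop = TRUE]),
    array(0, c(nch, nch, nb)))
  new("GraphDataset", features = arr, adjacency = adjacency,
      structural = structuralAdjacency(side$channels),
      meta = side$meta, channels = side$channels, bands = side$bands,
      featureGrid = as.matrix(side$grid))
}

#' Restrict a dataset to a subset of frequency bands
#'
#' @param dataset a \linkS4class{GraphDataset}.
#' @param bandSubset band names to keep (canonical order is preserved).
#' @return a \linkS4class{GraphDataset} with J = length(bandSubset).
#' @export
subsetBands <- function(dataset, bandSubset) {
  unknown <- setdiff(bandSubset, dataset@bands)
  if (length(unknown))
    stop("unknown band name(s): ", paste(unknown, collapse = ", "))
  keep <- dataset@bands[dataset@bands %in% bandSubset]
  idx <- match(keep, dataset@bands)
  new("GraphDataset",
      features = dataset@features[, , idx, , drop = FALSE],
      adjacency = dataset@adjacency[, , idx, , drop = FALSE],
      structural = dataset@structural, meta = dataset@meta,
      channels = dataset@channels, bands = keep,
      featureGrid = dataset@featureGrid)
}

#' Drop one channel from a dataset (leave-one-channel-out)
#'
#' Removes the channel's row from the feature tensor and its row and column
#' from both adjacencies; the structural matrix is rebuilt from the reduced
#' montage so later degree normalization sees the reduced graph.
#'
#' @param dataset a \linkS4class{GraphDataset}.
#' @param channel channel name to remove.
#' @return a \linkS4class{GraphDataset} with N - 1 channels.
#' @export
dropChannel <- function(dataset, channel) {
  if (!channel %in% dataset@channels)
    stop("channel '", channel, "' is not in the montage")
  keep <- which(dataset@channels != channel)
  new("GraphDataset",
      features = dataset@features[keep, , , , drop = FALSE],
      adjacency = dataset@adjacency[keep, keep, , , drop = FALSE],
      structural = structuralAdjacency(dataset@channels[keep]),
      meta = dataset@meta, channels = dataset@channels[keep],
      bands = dataset@bands, featureGrid = dataset@featureGrid)
}
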