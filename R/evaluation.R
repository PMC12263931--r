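# Subject-level splitting, k-fold cross-validation, the metric suite, and
# the band / electrode ablations. Augmented segments always inherit their
# subject's assignment, so no subject ever contributes to both sides of a
# split.

#' Subject-level train/test split
#'
#' Subjects (not segments) are sampled into train and test, stratified by
#' class so both classes appear on both sides; every segment of a subject
#' inherits the subject's side.
#'
#' @param dataset a \linkS4class{GraphDataset} (or a data.frame with
#'   \code{subject_id} and \code{label}).
#' @param testFraction fraction of subjects per class assigned to test,
#'   in (0, 1).
#' @param seed integer seed for the subject sampling.
#' @return a \linkS4class{SplitPlan}.
#' @export
subjectSplit <- function(dataset, testFraction = 0.2, seed = 1L) {
  meta <- if (is(dataset, "GraphDataset")) dataset@meta else dataset
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must be in (0, 1)")
  subj <- meta[!duplicated(meta$subject_id), c("subject_id", "label")]
  if (any(table(subj$label) < 2L))
    stop("need at least 2 subjects per class")
  set.seed(seed)
  assignment <- character(0)
  for (cls in unique(subj$label)) {
    ids <- subj$subject_id[subj$label == cls]
    nTest <- round(testFraction * length(ids))
    if (nTest < 1L || nTest >= length(ids))
      stop("testFraction leaves an empty train or test side for class ", cls)
    test <- sample(ids, nTest)
    a <- setNames(rep("train", length(ids)), ids)
    a[test] <- "test"
    assignment <- c(assignment, a)
  }
  new("SplitPlan", assignment = assignment,
      labels = setNames(subj$label, subj$subject_id),
      folds = integer(0),
      testFraction = testFraction, seed = as.integer(seed))
}

#' Assign cross-validation folds to the training subjects
#'
#' Training subjects are shuffled within class and dealt cyclically into k
#' folds, so fold sizes differ by at most one and each class spreads as
#' evenly as possible across folds; each subject lands in exactly one fold.
#'
#' @param plan a \linkS4class{SplitPlan} from [subjectSplit()].
#' @param k number of folds (default 5); \code{k} equal to the number of
#'   training subjects gives leave-one-subject-out.
#' @param seed integer seed for the fold shuffle.
#' @return the plan with its \code{folds} slot filled.
#' @export
kfoldPlan <- function(plan, k = 5, seed = 1L) {
  stopifnot(is(plan, "SplitPlan"))
  train <- names(plan@assignment)[plan@assignment == "train"]
  if (k > length(train))
    stop("k exceeds the number of training subjects")
  set.seed(seed)
  shuffled <- unlist(lapply(split(train, plan@labels[train]), sample),
                     use.names = FALSE)
  folds <- setNames(rep_len(seq_len(k), length(train)), shuffled)
  plan@folds <- folds
  validObject(plan)
  plan
}

#' Segment indices of one side of a split
#'
#' @param dataset a \linkS4class{GraphDataset}.
#' @param plan a \linkS4class{SplitPlan}.
#' @param side \code{"train"} or \code{"test"}.
#' @param excludeFold optionally drop one CV fold's subjects (train side),
#'   or with \code{onlyFold} select exactly that fold.
#' @param onlyFold select only this fold's subjects.
#' @return integer vector of segment indices.
#' @export
segmentIndices <- function(dataset, plan, side = c("train", "test"),
                           excludeFold = NULL, onlyFold = NULL) {
  side <- match.arg(side)
  subj <- names(plan@assignment)[plan@assignment == side]
  if (!is.null(excludeFold))
    subj <- setdiff(subj, names(plan@folds)[plan@folds == excludeFold])
  if (!is.null(onlyFold))
    subj <- intersect(subj, names(plan@folds)[plan@folds == onlyFold])
  which(dataset@meta$subject_id %in% subj)
}

#' Classification metrics from labels and AD-class probabilities
#'
#' Confusion counts at the threshold (AD is the positive class), accuracy,
#' precision, recall and F1 in percent, and ROC-AUC computed in the
#' Mann-Whitney rank form (midranks for ties; equivalent to the trapezoidal
#' area under the TPR/FPR curve).
#'
#' @param labels character/factor vector of \code{"AD"}/\code{"HC"}.
#' @param probs numeric vector of AD-class probabilities (or a matrix with
#'   an \code{"AD"} column as returned by [predictProbs()]).
#' @param threshold decision threshold (default 0.5).
#' @param provenance free-text description of the split.
#' @return a \linkS4class{MetricsReport}.
#' @export
#' @examples
#' computeMetrics(c("AD", "AD", "HC", "HC"), c(0.9, 0.6, 0.4, 0.1))
computeMetrics <- function(labels, probs, threshold = 0.5,
                           provenance = "") {
  if (is.matrix(probs)) probs <- probs[, "AD"]
  labels <- as.character(labels)
  if (length(labels) != length(probs))
    stop("labels and probs must have the same length")
  y <- .labelsAsInt(labels) == 1L
  if (!any(y) || all(y))
    stop("both classes must be present: AUC is undefined for single-class truth")
  pred <- probs >= threshold
  tp <- sum(pred & y); tn <- sum(!pred & !y)
  fp <- sum(pred & !y); fn <- sum(!pred & y)
  pre <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  rec <- tp / (tp + fn)
  f1 <- if (is.na(pre) || pre + rec == 0) NA_real_ else
    2 * pre * rec / (pre + rec)
  r <- rank(probs)
  auc <- (sum(r[y]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(!y))
  new("MetricsReport",
      accuracy = 100 * (tp + tn) / length(y),
      precision = 100 * pre, recall = 100 * rec, f1 = 100 * f1,
      auc = 100 * auc,
      tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn),
      threshold = threshold, provenance = provenance)
}

#' Train on a split's training segments and score its test segments
#'
#' @param dataset a \linkS4class{GraphDataset}.
#' @param plan a \linkS4class{SplitPlan}.
#' @param arch optional \linkS4class{ArchitectureConfig}.
#' @param tc a \linkS4class{TrainConfig}.
#' @return list with the fitted \code{model} (\linkS4class{MultiGCN}), the
#'   test-set \code{metrics} (\linkS4class{MetricsReport}), and the
#'   test-set \code{probs}.
#' @export
evaluateSplit <- function(dataset, plan, arch = NULL, tc = trainConfig()) {
  trainIdx <- segmentIndices(dataset, plan, "train")
  testIdx <- segmentIndices(dataset, plan, "test")
  model <- trainModel(dataset, trainIdx, testIdx, arch = arch, tc = tc)
  probs <- predictProbs(model, dataset, testIdx)
  metrics <- computeMetrics(dataset@meta$label[testIdx], probs,
                            provenance = sprintf(
                              "subject-level split (seed %d): %d train / %d test segments",
                              plan@seed, length(trainIdx), length(testIdx)))
  list(model = model, metrics = metrics, probs = probs)
}

#' Subject-level k-fold cross-validation on the training split
#'
#' For each fold, trains on the remaining folds' segments and scores the
#' held-out fold's segments; reports per-fold metrics and their mean and
#' standard deviation.
#'
#' @param dataset a \linkS4class{GraphDataset}.
#' @param plan a \linkS4class{SplitPlan} with folds (see [kfoldPlan()]).
#' @param arch optional \linkS4class{ArchitectureConfig}.
#' @param tc a \linkS4class{TrainConfig}.
#' @return list with \code{folds} (data.frame, one row per fold),
#'   \code{mean} and \code{sd} (named numeric over the metric columns).
#' @export
crossValidate <- function(dataset, plan, arch = NULL, tc = trainConfig()) {
  if (!length(plan@folds)) stop("plan has no folds; run kfoldPlan() first")
  k <- max(plan@folds)
  rows <- lapply(seq_len(k), function(f) {
    trainIdx <- segmentIndices(dataset, plan, "train", excludeFold = f)
    valIdx <- segmentIndices(dataset, plan, "train", onlyFold = f)
    model <- trainModel(dataset, trainIdx, arch = arch, tc = tc)
    probs <- predictProbs(model, dataset, valIdx)
    m <- computeMetrics(dataset@meta$label[valIdx], probs,
                        provenance = sprintf("CV fold %d", f))
    cbind(fold = f, as.data.frame(m))
  })
  folds <- do.call(rbind, rows)
  metricCols <- c("accuracy", "precision", "recall", "f1", "auc")
  list(folds = folds,
       mean = colMeans(folds[metricCols]),
       sd = vapply(folds[metricCols], sd, numeric(1)))
}

#' Classification performance per frequency-band subset
#'
#' Retrains the model restricted to each band subset (the flatten width
#' scales with the number of bands) and reports the full metric suite per
#' subset on the plan's test segments.
#'
#' @param dataset a \linkS4class{GraphDataset}.
#' @param plan a \linkS4class{SplitPlan}.
#' @param bandSets named list of band-name vectors; the default evaluates
#'   each single band plus the full set.
#' @param arch optional template \linkS4class{ArchitectureConfig}; its band
#'   count is adapted per subset.
#' @param tc a \linkS4class{TrainConfig}.
#' @return data.frame with one row per subset (name, bands, metrics).
#' @export
bandEvaluation <- function(dataset, plan,
                           bandSets = c(as.list(setNames(dataset@bands,
                                                         dataset@bands)),
                                        list(full = dataset@bands)),
                           arch = NULL, tc = trainConfig()) {
  if (!length(bandSets)) stop("bandSets must be non-empty")
  rows <- lapply(names(bandSets), function(nm) {
    sub <- subsetBands(dataset, bandSets[[nm]])
    subArch <- if (is.null(arch)) NULL else
      architectureConfig(nodes = arch@nodes,
                         inputFeatures = arch@inputFeatures,
                         gcnHidden = arch@gcnHidden,
                         gcnOutput = arch@gcnOutput,
                         bands = length(sub@bands),
                         fcHidden1 = arch@fcHidden1,
                         fcHidden2 = arch@fcHidden2,
                         classes = arch@classes,
                         weightSharing = arch@weightSharing,
                         gcnBias = arch@gcnBias)
    res <- evaluateSplit(sub, plan, arch = subArch, tc = tc)
    cbind(data.frame(subset = nm,
                     bands = paste(sub@bands, collapse = "+"),
                     stringsAsFactors = FALSE),
          as.data.frame(res$metrics))
  })
  do.call(rbind, rows)
}

#' Leave-one-channel-out electrode ablation
#'
#' For each montage channel, removes it from the feature tensor and both
#' adjacencies, retrains from scratch, scores the test segments, and ranks
#' channels by the AUC drop relative to the full model
#' (\code{delta_auc = full AUC - reduced AUC}).
#'
#' @param dataset a \linkS4class{GraphDataset}.
#' @param plan a \linkS4class{SplitPlan}.
#' @param arch optional template \linkS4class{ArchitectureConfig}; its node
#'   count is reduced by one for the ablated models.
#' @param tc a \linkS4class{TrainConfig}.
#' @param fullAUC full-model test AUC (percent); computed if missing.
#' @return data.frame with one row per channel (channel, region,
#'   auc_removed, delta_auc), sorted by decreasing delta_auc.
#' @export
electrodeAblation <- function(dataset, plan, arch = NULL,
                              tc = trainConfig(), fullAUC = NULL) {
  if (is.null(fullAUC))
    fullAUC <- evaluateSplit(dataset, plan, arch = arch, tc = tc)$metrics@auc
  reducedArch <- function() {
    if (is.null(arch)) return(NULL)
    architectureConfig(nodes = arch@nodes - 1L,
                       inputFeatures = arch@inputFeatures,
                       gcnHidden = arch@gcnHidden, gcnOutput = arch@gcnOutput,
                       bands = arch@bands, fcHidden1 = arch@fcHidden1,
                       fcHidden2 = arch@fcHidden2, classes = arch@classes,
                       weightSharing = arch@weightSharing,
                       gcnBias = arch@gcnBias)
  }
  rows <- lapply(dataset@channels, function(ch) {
    res <- evaluateSplit(dropChannel(dataset, ch), plan,
                         arch = reducedArch(), tc = tc)
    data.frame(channel = ch,
               region = unname(channelRegions(ch)),
               auc_removed = res$metrics@auc,
               delta_auc = fullAUC - res$metrics@auc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$delta_auc), ]
  rownames(out) <- NULL
  attr(out, "fullAUC") <- fullAUC
  out
}
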