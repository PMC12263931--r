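# Splitting, cross-validation, metrics and the statistical toolkit.

test_that("subject-level split keeps all of a subject's segments together", {
  ds <- .tinyDataset()
  plan <- subjectSplit(ds, 0.25, seed = 3)
  tr <- ds@meta$subject_id[segmentIndices(ds, plan, "train")]
  te <- ds@meta$subject_id[segmentIndices(ds, plan, "test")]
  expect_length(intersect(unique(tr), unique(te)), 0L)
  expect_setequal(c(unique(tr), unique(te)), unique(ds@meta$subject_id))
})

test_that("no subject crosses the partition over many random plans", {
  ds <- .tinyDataset()
  leaks <- vapply(1:100, function(s) {
    plan <- subjectSplit(ds, 0.25, seed = s)
    tr <- unique(ds@meta$subject_id[segmentIndices(ds, plan, "train")])
    te <- unique(ds@meta$subject_id[segmentIndices(ds, plan, "test")])
    length(intersect(tr, te))
  }, 1L)
  expect_identical(sum(leaks), 0L)
})

test_that("split fractions and error cases behave as specified", {
  meta <- data.frame(
    subject_id = sprintf("s%02d", 1:65),
    label = rep(c("AD", "HC"), c(36, 29)), start = 0)
  plan <- subjectSplit(meta, 0.2, seed = 1)
  expect_identical(sum(plan@assignment == "test"), 13L)   # 7 AD + 6 HC
  expect_identical(sum(plan@assignment == "train"), 52L)
  expect_error(subjectSplit(meta, 0), "testFraction")
  expect_error(subjectSplit(meta, 1.2), "testFraction")
  expect_error(subjectSplit(meta, 0.01), "empty")  # no test subject left
})

test_that("k-fold plans partition the training subjects evenly", {
  meta <- data.frame(
    subject_id = sprintf("s%02d", 1:65),
    label = rep(c("AD", "HC"), c(36, 29)), start = 0)
  plan <- kfoldPlan(subjectSplit(meta, 0.2, seed = 1), k = 5, seed = 2)
  sizes <- as.vector(table(plan@folds))
  expect_length(sizes, 5L)
  expect_true(all(sizes %in% c(10L, 11L)))
  expect_identical(sum(sizes), 52L)
  # each training subject in exactly one fold
  expect_setequal(names(plan@folds),
                  names(plan@assignment)[plan@assignment == "train"])

  loso <- kfoldPlan(subjectSplit(meta, 0.2, seed = 1), k = 52, seed = 2)
  expect_true(all(table(loso@folds) == 1L))
  expect_error(kfoldPlan(subjectSplit(meta, 0.2, seed = 1), k = 53),
               "exceeds")
})

test_that("metrics reproduce hand-computed confusion arithmetic", {
  # TP=3, FP=1, FN=1, TN=5
  labels <- c(rep("AD", 4), rep("HC", 6))
  probs <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.4, 0.3, 0.2, 0.1, 0.05)
  m <- computeMetrics(labels, probs)
  expect_equal(m@tp, 3L); expect_equal(m@fp, 1L)
  expect_equal(m@fn, 1L); expect_equal(m@tn, 5L)
  expect_equal(m@accuracy, 80)
  expect_equal(m@precision, 75)
  expect_equal(m@recall, 75)
  expect_equal(m@f1, 75)
})

test_that("perfect separation yields 100% on every metric", {
  m <- computeMetrics(rep(c("AD", "HC"), each = 5),
                      c(runif(5, 0.6, 1), runif(5, 0, 0.4)))
  expect_equal(c(m@accuracy, m@precision, m@recall, m@f1, m@auc),
               rep(100, 5))
})

test_that("rank-form AUC agrees with an independent ROC implementation", {
  set.seed(71)
  labels <- sample(c("AD", "HC"), 60, replace = TRUE, prob = c(0.5, 0.5))
  probs <- runif(60) + 0.3 * (labels == "AD")
  m <- computeMetrics(labels, probs)
  ref <- pROC::auc(pROC::roc(labels == "AD", probs, levels = c(FALSE, TRUE),
                             direction = "<", quiet = TRUE))
  expect_equal(m@auc, 100 * as.numeric(ref), tolerance = 1e-10)
})

test_that("random scores give chance-level AUC", {
  set.seed(72)
  labels <- rep(c("AD", "HC"), each = 1000)
  m <- computeMetrics(labels, runif(2000))
  expect_gt(m@auc, 45); expect_lt(m@auc, 55)
})

test_that("single-class truth is rejected for AUC", {
  expect_error(computeMetrics(rep("AD", 5), runif(5)), "single-class")
})

test_that("cross-validation returns one report per fold", {
  ds <- .tinyDataset()
  plan <- kfoldPlan(subjectSplit(ds, 0.25, seed = 5), k = 3, seed = 5)
  cv <- crossValidate(ds, plan, arch = tinyArch(ds),
                      tc = trainConfig(epochs = 10, seed = 1))
  expect_identical(nrow(cv$folds), 3L)
  expect_true(all(is.finite(cv$mean[c("accuracy", "auc")])))
  expect_length(cv$sd, 5L)
})

test_that("band subsetting and channel dropping reshape the dataset", {
  ds <- .tinyDataset()
  sub <- subsetBands(ds, c("alpha", "delta"))
  expect_identical(sub@bands, c("delta", "alpha"))  # canonical order kept
  expect_identical(dim(sub@features)[3], 2L)
  expect_error(subsetBands(ds, "mu"), "unknown band")

  red <- dropChannel(ds, "Pz")
  expect_identical(length(red@channels), 18L)
  expect_false("Pz" %in% red@channels)
  expect_identical(dim(red@adjacency)[1:2], c(18L, 18L))
  expect_identical(sum(red@structural),
                   sum(structuralAdjacency(setdiff(montage1020(), "Pz"))))
  expect_error(dropChannel(ds, "Qz"), "not in the montage")
})

test_that("band evaluation produces one report per subset", {
  ds <- .tinyDataset()
  plan <- subjectSplit(ds, 0.25, seed = 7)
  tab <- bandEvaluation(ds, plan,
                        bandSets = list(alpha = "alpha",
                                        full = bandNames()),
                        tc = trainConfig(epochs = 10, seed = 2))
  expect_identical(nrow(tab), 2L)
  expect_true(all(c("accuracy", "auc") %in% names(tab)))
  expect_identical(tab$bands[tab$subset == "full"],
                   "delta+theta+alpha+beta+gamma")
})

test_that("electrode ablation reports all channels ranked by AUC drop", {
  ds <- .tinyDataset()
  plan <- subjectSplit(ds, 0.25, seed = 8)
  # restrict to a 3-channel sub-analysis for speed: drop all but 3 channels
  small <- ds
  for (ch in setdiff(ds@channels, c("Fp1", "Cz", "Pz")))
    small <- dropChannel(small, ch)
  tab <- electrodeAblation(small, plan, tc = trainConfig(epochs = 10, seed = 3))
  expect_identical(nrow(tab), 3L)
  expect_setequal(tab$channel, c("Fp1", "Cz", "Pz"))
  expect_true(all(diff(tab$delta_auc) <= 0))
  expect_equal(tab$delta_auc, attr(tab, "fullAUC") - tab$auc_removed)
})
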