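# Statistical comparison toolkit: paired Wilcoxon signed-rank on per-fold
# F1 scores, DeLong's test for correlated ROC-AUCs (via pROC), Cohen's d,
# and Benjamini-Hochberg FDR adjustment over a comparison family.

#' Cohen's d effect size (pooled standard deviation)
#'
#' \code{d = (mean(a) - mean(b)) / s_pooled}, with the pooled standard
#' deviation over both vectors. Identical vectors give exactly 0.
#'
#' @param a,b numeric score vectors.
#' @return Cohen's d.
#' @export
cohensD <- function(a, b) {
  md <- mean(a) - mean(b)
  if (md == 0) return(0)
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (sp == 0) return(sign(md) * Inf)
  md / sp
}

#' DeLong's test for two correlated ROC-AUCs
#'
#' Compares the AUCs of two probability vectors scored on the same test
#' instances, using the asymptotic variance of the paired AUC difference.
#'
#' @param labels \code{"AD"}/\code{"HC"} truth for the shared test set.
#' @param probsA,probsB AD-class probabilities of the two models on those
#'   instances.
#' @return list with \code{p}, \code{aucA}, \code{aucB} and
#'   \code{aucDiff} (percentage points, A minus B).
#' @export
delongTest <- function(labels, probsA, probsB) {
  if (length(labels) != length(probsA) || length(labels) != length(probsB))
    stop("labels, probsA and probsB must have equal length")
  y <- .labelsAsInt(as.character(labels))
  rocA <- pROC::roc(y, probsA, levels = c(0, 1), direction = "<",
                    quiet = TRUE)
  rocB <- pROC::roc(y, probsB, levels = c(0, 1), direction = "<",
                    quiet = TRUE)
  tst <- pROC::roc.test(rocA, rocB, method = "delong", paired = TRUE)
  list(p = as.numeric(tst$p.value),
       aucA = 100 * as.numeric(pROC::auc(rocA)),
       aucB = 100 * as.numeric(pROC::auc(rocB)),
       aucDiff = 100 * (as.numeric(pROC::auc(rocA)) -
                        as.numeric(pROC::auc(rocB))))
}

#' Statistical comparison of two models
#'
#' Pairs per-fold F1 vectors with a Wilcoxon signed-rank test and Cohen's d,
#' and (when test-set probabilities are supplied) compares ROC-AUCs with
#' DeLong's test on the shared test instances.
#'
#' @param scoresA,scoresB paired per-fold score vectors (e.g. CV-fold F1)
#'   for the two models; the fold is the paired unit.
#' @param labels,probsA,probsB optional shared test labels plus each
#'   model's AD-class probabilities, for the DeLong comparison.
#' @param comparison label for the output row.
#' @return one-row data.frame: \code{f1_p} (Wilcoxon), \code{f1_d}
#'   (Cohen's d), and if probabilities were given \code{auc_p} (DeLong) and
#'   \code{auc_diff} (percentage points).
#' @export
statsSuite <- function(scoresA, scoresB, labels = NULL,
                       probsA = NULL, probsB = NULL,
                       comparison = "A vs B") {
  if (length(scoresA) != length(scoresB))
    stop("paired score vectors must have equal length")
  d <- scoresA - scoresB
  if (all(d == 0))
    stop("all paired differences are zero: Wilcoxon signed-rank undefined")
  w <- suppressWarnings(wilcox.test(scoresA, scoresB, paired = TRUE))
  out <- data.frame(comparison = comparison,
                    f1_p = as.numeric(w$p.value),
                    f1_d = cohensD(scoresA, scoresB),
                    stringsAsFactors = FALSE)
  if (!is.null(probsA)) {
    dl <- delongTest(labels, probsA, probsB)
    out$auc_p <- dl$p
    out$auc_diff <- dl$aucDiff
  }
  out
}

#' Benjamini-Hochberg adjustment over a family of comparisons
#'
#' Applies step-up FDR adjustment to the \code{f1_p} column and, when
#' present, the \code{auc_p} column of a stacked [statsSuite()] table
#' (each column is its own family, mirroring separate F1 and AUC testing).
#'
#' @param comparisons data.frame of stacked [statsSuite()] rows.
#' @return the table with \code{f1_p_adj} (and \code{auc_p_adj}) columns.
#' @export
#' @examples
#' p <- data.frame(comparison = letters[1:4],
#'                 f1_p = c(0.01, 0.02, 0.03, 0.04))
#' adjustComparisons(p)$f1_p_adj   # all 0.04 under the step-up rule
adjustComparisons <- function(comparisons) {
  comparisons$f1_p_adj <- p.adjust(comparisons$f1_p, method = "BH")
  if (!is.null(comparisons$auc_p))
    comparisons$auc_p_adj <- p.adjust(comparisons$auc_p, method = "BH")
  comparisons
}
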