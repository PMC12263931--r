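# Functional (Pearson) adjacency per segment and band, and the shared
# symmetric normalization used by both graph-convolution layers.

#' Functional adjacency from one band's node features
#'
#' Edge weight between channels m and n is the absolute Pearson correlation
#' of their M-feature vectors. Negative correlations are folded by the
#' absolute value (coupling magnitude) so the degree-based normalization is
#' well defined; the diagonal is exactly 1.
#'
#' @param X channels x M node-feature matrix for one band of one segment.
#' @return symmetric channels x channels matrix with entries in [0, 1] and
#'   unit diagonal.
#' @export
#' @examples
#' X <- matrix(rnorm(3 * 5), 3, dimnames = list(c("Fp1", "Fp2", "O1"), NULL))
#' functionalAdjacency(X)
functionalAdjacency <- function(X) {
  if (ncol(X) < 2L) stop("need at least 2 features per node")
  sds <- apply(X, 1L, sd)
  if (any(sds == 0)) {
    ch <- rownames(X)[which(sds == 0)[1L]]
    if (is.null(ch)) ch <- which(sds == 0)[1L]
    stop("constant feature vector for channel ", ch,
         ": Pearson correlation undefined")
  }
  A <- abs(cor(t(X)))
  diag(A) <- 1
  A
}

#' Symmetric degree normalization of an adjacency matrix
#'
#' Returns \eqn{\hat D^{-1/2} \hat A \hat D^{-1/2}} with
#' \eqn{\hat A = A + I} (self-loops, the standard renormalization trick,
#' which also floors isolated-node degrees at 1) and \eqn{\hat D} the
#' diagonal degree matrix of \eqn{\hat A}. The result is symmetric with
#' spectral radius at most 1.
#'
#' @param A symmetric non-negative square matrix (take the absolute value
#'   of signed correlations before calling).
#' @return normalized matrix of the same dimension.
#' @export
#' @examples
#' normalizeAdjacency(matrix(c(0, 1, 1, 0), 2))  # all entries 0.5
normalizeAdjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("A must be a square matrix")
  if (any(A < 0)) stop("A must be non-negative (pre-transform signed weights)")
  if (max(abs(A - t(A))) > 1e-10) stop("A must be symmetric")
  Ahat <- A + diag(nrow(A))
  dInv <- 1 / sqrt(rowSums(Ahat))
  out <- Ahat * tcrossprod(dInv)
  dimnames(out) <- dimnames(A)
  out
}

# Per-segment functional adjacency tensor (channels x channels x bands)
# from one segment's feature array (channels x M x bands).
.adjacencyFromFeatures <- function(featArr) {
  nb <- dim(featArr)[3L]
  nch <- dim(featArr)[1L]
  out <- array(NA_real_, c(nch, nch, nb),
               dimnames = list(dimnames(featArr)[[1L]],
                               dimnames(featArr)[[1L]],
                               dimnames(featArr)[[3L]]))
  for (b in seq_len(nb))
    out[, , b] <- functionalAdjacency(featArr[, , b, drop = TRUE])
  out
}

#' Export an adjacency matrix as a tab-separated table
#'
#' @param A adjacency matrix with channel-name dimnames.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAdjacencyTSV <- function(A, path) {
  write.table(A, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
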