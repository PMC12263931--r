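# Constructors, reference forward pass, parameter accounting, and the
# training front end around the compiled core.

#' Architecture configuration constructor
#'
#' Defaults reproduce the reference configuration (19 nodes, M = 32, K = 16,
#' L = 2, 5 bands, FC widths 128 and 32, 2 classes, per-band GCN weights,
#' no GCN bias).
#'
#' @param nodes,inputFeatures,gcnHidden,gcnOutput,bands,fcHidden1,fcHidden2,classes
#'   layer dimensions.
#' @param weightSharing \code{"per_band"} or \code{"shared"}.
#' @param gcnBias logical.
#' @return an \linkS4class{ArchitectureConfig}.
#' @export
architectureConfig <- function(nodes = 19, inputFeatures = 32,
                               gcnHidden = 16, gcnOutput = 2, bands = 5,
                               fcHidden1 = 128, fcHidden2 = 32, classes = 2,
                               weightSharing = c("per_band", "shared"),
                               gcnBias = FALSE) {
  new("ArchitectureConfig", nodes = as.integer(nodes),
      inputFeatures = as.integer(inputFeatures),
      gcnHidden = as.integer(gcnHidden), gcnOutput = as.integer(gcnOutput),
      bands = as.integer(bands), fcHidden1 = as.integer(fcHidden1),
      fcHidden2 = as.integer(fcHidden2), classes = as.integer(classes),
      weightSharing = match.arg(weightSharing), gcnBias = gcnBias)
}

#' Training configuration constructor
#'
#' @param learningRate Adam learning rate (default 0.001).
#' @param batchSize minibatch size (default 10).
#' @param epochs training epochs (default 200).
#' @param seed seed for weight initialization and shuffling.
#' @return a \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(learningRate = 0.001, batchSize = 10, epochs = 200,
                        seed = 1L) {
  new("TrainConfig", learningRate = learningRate,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed))
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize model parameters (Glorot uniform weights, zero biases)
#'
#' Uses the current R random stream; call \code{set.seed()} first for
#' reproducible initialization.
#'
#' @param arch an \linkS4class{ArchitectureConfig}.
#' @return named parameter list (\code{W0}, \code{W1} per band; \code{Wf1},
#'   \code{bf1}, ...; GCN biases \code{b0}/\code{b1} only if
#'   \code{arch@gcnBias}).
#' @export
initParameters <- function(arch) {
  nb <- if (arch@weightSharing == "shared") 1L else arch@bands
  flat <- arch@nodes * arch@gcnOutput * arch@bands
  p <- list(
    W0 = lapply(seq_len(nb), function(j)
      .glorot(arch@inputFeatures, arch@gcnHidden)),
    W1 = lapply(seq_len(nb), function(j)
      .glorot(arch@gcnHidden, arch@gcnOutput)),
    Wf1 = .glorot(flat, arch@fcHidden1),
    Wf2 = .glorot(arch@fcHidden1, arch@fcHidden2),
    Wf3 = .glorot(arch@fcHidden2, arch@classes),
    bf1 = matrix(0, 1, arch@fcHidden1),
    bf2 = matrix(0, 1, arch@fcHidden2),
    bf3 = matrix(0, 1, arch@classes))
  if (arch@gcnBias) {
    p$b0 <- lapply(seq_len(nb), function(j) matrix(0, 1, arch@gcnHidden))
    p$b1 <- lapply(seq_len(nb), function(j) matrix(0, 1, arch@gcnOutput))
  }
  p
}

#' One graph-convolution layer
#'
#' Computes \code{activation(Anorm \%*\% X \%*\% W (+ bias))}: each node
#' aggregates its neighbours' features through the normalized adjacency,
#' mixes them with the learnable weights, and applies the activation
#' (ReLU by default).
#'
#' @param X nodes x d_in input matrix.
#' @param Anorm normalized adjacency from [normalizeAdjacency()].
#' @param W d_in x d_out weight matrix.
#' @param bias optional 1 x d_out bias row added to every node.
#' @param activation activation function (default ReLU).
#' @return nodes x d_out output matrix.
#' @export
gcnLayer <- function(X, Anorm, W, bias = NULL,
                     activation = function(z) pmax(z, 0)) {
  if (ncol(Anorm) != nrow(X) || ncol(X) != nrow(W))
    stop("shape mismatch in gcnLayer")
  out <- Anorm %*% X %*% W
  if (!is.null(bias)) out <- sweep(out, 2L, as.numeric(bias), "+")
  activation(out)
}

#' Reference forward pass for one sample
#'
#' Pure-R forward pass: per band, two GCN layers (functional adjacency then
#' structural adjacency), column-major flatten to N*L, concatenation over
#' bands in band order, then the three fully connected layers and softmax.
#' Used as the readable reference; training and batched prediction run the
#' identical computation in compiled code.
#'
#' @param X normalized channels x M x bands feature array for one segment.
#' @param A1 normalized channels x channels x bands functional adjacency.
#' @param A2 normalized structural adjacency.
#' @param params parameter list (see [initParameters()]).
#' @param weightSharing \code{"per_band"} or \code{"shared"}.
#' @return list with \code{scores} (length-Z logits) and \code{probs}
#'   (softmax; class order HC, AD).
#' @export
forwardPass <- function(X, A1, A2, params, weightSharing = "per_band") {
  J <- dim(X)[3L]
  flat <- unlist(lapply(seq_len(J), function(j) {
    js <- if (weightSharing == "shared") 1L else j
    b0 <- if (is.null(params$b0)) NULL else params$b0[[js]]
    b1 <- if (is.null(params$b1)) NULL else params$b1[[js]]
    H1 <- gcnLayer(X[, , j, drop = TRUE], A1[, , j, drop = TRUE],
                   params$W0[[js]], b0)
    H2 <- gcnLayer(H1, A2, params$W1[[js]], b1)
    as.vector(H2)
  }))
  z1 <- pmax(as.vector(flat %*% params$Wf1) + as.numeric(params$bf1), 0)
  z2 <- pmax(as.vector(z1 %*% params$Wf2) + as.numeric(params$bf2), 0)
  scores <- as.vector(z2 %*% params$Wf3) + as.numeric(params$bf3)
  e <- exp(scores - max(scores))
  list(scores = scores, probs = e / sum(e))
}

#' Count scalar model parameters
#'
#' Total number of scalar learnable parameters. With the default
#' configuration (per-band GCN weights without bias, FC layers with biases)
#' the count is fully determined by the architecture; it is reported
#' alongside the configuration rather than asserted against any external
#' figure.
#'
#' @param object a parameter list, \linkS4class{ArchitectureConfig}, or
#'   \linkS4class{MultiGCN}.
#' @return integer scalar count.
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

#' @rdname countParameters
setMethod("countParameters", "list", function(object) {
  length(rapply(object, identity, how = "unlist"))
})

#' @rdname countParameters
setMethod("countParameters", "ArchitectureConfig", function(object) {
  nb <- if (object@weightSharing == "shared") 1L else object@bands
  flat <- object@nodes * object@gcnOutput * object@bands
  gcn <- nb * (object@inputFeatures * object@gcnHidden +
               object@gcnHidden * object@gcnOutput)
  if (object@gcnBias)
    gcn <- gcn + nb * (object@gcnHidden + object@gcnOutput)
  fc <- flat * object@fcHidden1 + object@fcHidden1 +
    object@fcHidden1 * object@fcHidden2 + object@fcHidden2 +
    object@fcHidden2 * object@classes + object@classes
  as.integer(gcn + fc)
})

#' @rdname countParameters
setMethod("countParameters", "MultiGCN", function(object) {
  countParameters(object@params)
})

# --- training front end -----------------------------------------------------

# Normalize every functional adjacency slice and the structural matrix, and
# precompute the fixed layer-1 propagation P = A1hat %*% Xnorm per sample
# and band (list of channels x M x samples arrays, one per band).
.prepareTensors <- function(dataset, normStats) {
  Xn <- applyNormalization(normStats, dataset@features)
  d <- dim(Xn)
  J <- d[3L]; S <- d[4L]
  P <- vector("list", J)
  for (j in seq_len(J)) {
    Pj <- array(0, c(d[1L], d[2L], S))
    for (s in seq_len(S)) {
      A1n <- normalizeAdjacency(dataset@adjacency[, , j, s])
      Pj[, , s] <- A1n %*% Xn[, , j, s]
    }
    P[[j]] <- Pj
  }
  list(P = P, A2 = normalizeAdjacency(dataset@structural))
}

.archForDataset <- function(dataset, arch) {
  d <- dim(dataset@features)
  if (arch@nodes != d[1L] || arch@inputFeatures != d[2L] ||
      arch@bands != d[3L])
    stop(sprintf(
      "architecture (N=%d, M=%d, J=%d) does not match the dataset (N=%d, M=%d, J=%d)",
      arch@nodes, arch@inputFeatures, arch@bands, d[1L], d[2L], d[3L]))
  arch
}

.labelsAsInt <- function(labels) {
  if (!all(labels %in% c("AD", "HC"))) stop("labels must be 'AD' or 'HC'")
  ifelse(labels == "AD", 1L, 0L)  # AD is the positive class
}

#' Train the multi-graph convolutional classifier
#'
#' Fits z-score normalization on the training segments only, normalizes all
#' adjacencies, and minimizes softmax cross-entropy with Adam over the
#' training segments. Deterministic given \code{tc@seed} (single-threaded
#' BLAS assumed).
#'
#' @param dataset a \linkS4class{GraphDataset}.
#' @param trainIdx integer segment indices of the training split (use
#'   [segmentIndices()] to derive them from a \linkS4class{SplitPlan}).
#' @param testIdx optional segment indices used only for the per-epoch test
#'   loss curve.
#' @param arch an \linkS4class{ArchitectureConfig}; defaults to the
#'   reference dimensions adapted to the dataset.
#' @param tc a \linkS4class{TrainConfig}.
#' @return a \linkS4class{MultiGCN}.
#' @export
trainModel <- function(dataset, trainIdx, testIdx = integer(0),
                       arch = NULL, tc = trainConfig()) {
  d <- dim(dataset@features)
  if (is.null(arch))
    arch <- architectureConfig(nodes = d[1L], inputFeatures = d[2L],
                               bands = d[3L])
  arch <- .archForDataset(dataset, arch)
  if (!length(trainIdx)) stop("empty training split")
  y <- .labelsAsInt(dataset@meta$label)
  if (length(unique(y[trainIdx])) < 2L)
    stop("training split contains a single class")

  normStats <- fitNormalization(
    dataset@features[, , , trainIdx, drop = FALSE])
  tensors <- .prepareTensors(dataset, normStats)

  set.seed(tc@seed)
  init <- initParameters(arch)
  fit <- cpp_train(tensors$P, tensors$A2, y, init,
                   as.integer(trainIdx), as.integer(testIdx),
                   tc@learningRate, tc@batchSize, tc@epochs,
                   arch@weightSharing == "shared", arch@gcnBias)
  new("MultiGCN", arch = arch, params = fit$params,
      normStats = normStats,
      lossCurves = data.frame(epoch = seq_len(tc@epochs),
                              train = fit$trainLoss, test = fit$testLoss),
      bands = dataset@bands, channels = dataset@channels,
      trainConfig = tc)
}

#' Predict class probabilities for dataset segments
#'
#' Applies the model's stored normalization and runs the forward pass.
#'
#' @param model a trained \linkS4class{MultiGCN}.
#' @param dataset a \linkS4class{GraphDataset} with the same channels and
#'   bands the model was trained on.
#' @param idx segment indices (default: all).
#' @return matrix with one row per segment and columns \code{HC},
#'   \code{AD} (softmax probabilities).
#' @export
predictProbs <- function(model, dataset, idx = seq_len(nSamples(dataset))) {
  stopifnot(is(model, "MultiGCN"))
  if (!identical(model@channels, dataset@channels) ||
      !identical(model@bands, dataset@bands))
    stop("dataset channels/bands do not match the model")
  tensors <- .prepareTensors(dataset, model@normStats)
  probs <- cpp_forward(tensors$P, tensors$A2, model@params,
                       as.integer(idx),
                       model@arch@weightSharing == "shared",
                       model@arch@gcnBias)
  colnames(probs) <- c("HC", "AD")
  rownames(probs) <- dataset@meta$subject_id[idx]
  probs
}
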