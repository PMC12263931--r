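# 10-20 montage bookkeeping: the 19-channel label set, its anatomical region
# assignment, and the structural (same-region) adjacency built from it.

.montage19 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "T3", "C3", "Cz", "C4", "T4",
                "T5", "P3", "Pz", "P4", "T6",
                "O1", "O2")

.region1020 <- c(
  Fp1 = "Frontal", Fp2 = "Frontal", F7 = "Frontal", F3 = "Frontal",
  Fz = "Frontal", F4 = "Frontal", F8 = "Frontal",
  C3 = "Central", Cz = "Central", C4 = "Central",
  P3 = "Parietal", Pz = "Parietal", P4 = "Parietal",
  T3 = "Temporal", T4 = "Temporal", T5 = "Temporal", T6 = "Temporal",
  O1 = "Occipital", O2 = "Occipital")

#' The 19-channel international 10-20 montage
#'
#' @return character vector of the 19 channel labels (Fp1 ... O2) in the
#'   canonical order used throughout the package.
#' @export
#' @examples
#' montage1020()
montage1020 <- function() .montage19

#' Anatomical region of each 10-20 channel
#'
#' Channels are grouped into five scalp regions: Frontal (Fp1, Fp2, F7, F3,
#' Fz, F4, F8), Central (C3, Cz, C4), Parietal (P3, Pz, P4), Temporal (T3,
#' T4, T5, T6) and Occipital (O1, O2).
#'
#' @param channels channel names; defaults to the full montage.
#' @return named character vector mapping channel to region.
#' @export
channelRegions <- function(channels = montage1020()) {
  unknown <- setdiff(channels, names(.region1020))
  if (length(unknown))
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  .region1020[channels]
}

#' Structural (same-region) adjacency of a 10-20 montage subset
#'
#' Binary N x N matrix with entry 1 where two channels lie in the same
#' anatomical region (the diagonal is therefore 1), 0 otherwise. This is the
#' shared adjacency of the second graph-convolution layer; it is a fixed
#' constant of the montage.
#'
#' @param channelNames channel labels; defaults to the full 19-channel
#'   montage.
#' @return binary symmetric matrix with channel-name dimnames.
#' @export
#' @examples
#' A <- structuralAdjacency()
#' sum(A)            # 87 unit entries for the full montage
#' A["Fp1", "F7"]    # both Frontal -> 1
structuralAdjacency <- function(channelNames = montage1020()) {
  reg <- channelRegions(channelNames)
  A <- outer(reg, reg, "==") * 1
  dimnames(A) <- list(channelNames, channelNames)
  A
}
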