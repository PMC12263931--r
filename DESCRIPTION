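Package: eegmgcn
Title: Multi-Graph Convolutional Networks for EEG-Based Alzheimer's
    Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies Alzheimer's disease patients against healthy
    controls from 19-channel resting-state EEG in the international 10-20
    layout. Differential-entropy features are extracted per channel over
    the five canonical frequency bands (delta, theta, alpha, beta, gamma)
    from overlapping sliding windows; each band is propagated through a
    two-layer graph convolutional network whose first layer uses a
    per-segment functional adjacency (absolute Pearson correlation of
    node features) and whose second layer uses a shared structural
    adjacency (same anatomical region under the 10-20 montage); band
    outputs are flattened, concatenated, and classified by three fully
    connected layers. Includes a synthetic cohort generator with
    class-dependent band power and inter-channel connectivity,
    subject-level splitting and cross-validation, band and
    leave-one-channel-out ablations, and statistical model comparison
    (Wilcoxon signed-rank, DeLong, Cohen's d, Benjamini-Hochberg FDR).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    pROC,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
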