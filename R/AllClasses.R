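#' @import methods
NULL

#' The five AASM sleep stages, in canonical order
#'
#' Wake, N1, N2, N3, REM. This ordering is used everywhere a stage index
#' appears (probability columns, confusion matrices, argmax tie-breaking).
#'
#' @export
STAGES <- c("Wake", "N1", "N2", "N3", "REM")

#' Stage tokens accepted from hypnogram parsing, before AASM remapping
#'
#' Includes the R&K stages S1-S4 and the MOVEMENT/UNKNOWN tokens that
#' [mapStages()] sends to `UNSCORED`.
#'
#' @export
STAGE_TOKENS <- c(STAGES, "S1", "S2", "S3", "S4", "MOVEMENT", "UNKNOWN",
                  "UNSCORED")

#' Raw single-channel polysomnography signal
#'
#' A full-night EEG trace as read from an EDF file, before epoching.
#'
#' @slot samples numeric vector, the signal in physical units (uV).
#' @slot fs sampling rate in Hz.
#' @slot channel channel label, e.g. `"Fpz-Cz"`.
#' @slot subjectId subject identifier.
#' @export
setClass("RawRecording",
  representation(samples = "numeric", fs = "numeric", channel = "character",
                 subjectId = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    if (length(object@samples) < 1L)
      msg <- c(msg, "samples must be non-empty")
    if (anyNA(object@samples))
      msg <- c(msg, "samples must not contain NA")
    if (length(msg)) msg else TRUE
  })

#' Epoched, labelled recording
#'
#' One subject's night reshaped into a P x M matrix of 30-second epochs with
#' one AASM stage label per epoch. Unscored epochs have already been dropped:
#' the labels carry only the five stages.
#'
#' @slot X numeric matrix, P epochs x M samples.
#' @slot labels factor of length P with levels [STAGES].
#' @slot fs sampling rate in Hz.
#' @slot epochLen epoch length in seconds (30).
#' @slot subjectId subject identifier.
#' @export
setClass("EpochedRecording",
  representation(X = "matrix", labels = "factor", fs = "numeric",
                 epochLen = "numeric", subjectId = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@X) != length(object@labels))
      msg <- c(msg, "nrow(X) must equal length(labels)")
    if (ncol(object@X) != object@fs * object@epochLen)
      msg <- c(msg, "ncol(X) must equal fs * epochLen")
    if (!identical(levels(object@labels), STAGES))
      msg <- c(msg, "labels must be a factor with levels Wake, N1, N2, N3, REM")
    if (anyNA(object@labels))
      msg <- c(msg, "labels must not contain NA (unscored epochs are dropped)")
    if (anyNA(object@X))
      msg <- c(msg, "X must not contain NA")
    if (length(msg)) msg else TRUE
  })

#' Principal-component model of subject spectral features
#'
#' Stores the column-wise z-scoring (centre/scale), the top-U loadings, and
#' the full eigenvalue spectrum of the feature covariance, from which the
#' retention of information (explained-variance fraction) is computed.
#'
#' @slot center,scale length-T numeric, column means and standard deviations.
#' @slot components T x U loading matrix (orthonormal columns).
#' @slot eigenvalues all T covariance eigenvalues, non-increasing.
#' @slot U number of retained components.
#' @slot roi fraction of eigenvalue mass retained by the first U components.
#' @slot featureNames feature labels.
#' @export
setClass("PCAModel",
  representation(center = "numeric", scale = "numeric", components = "matrix",
                 eigenvalues = "numeric", U = "integer", roi = "numeric",
                 featureNames = "character"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
      msg <- c(msg, "eigenvalues must be non-increasing")
    if (any(object@eigenvalues < -1e-8))
      msg <- c(msg, "eigenvalues must be non-negative")
    if (object@U < 1L || object@U > length(object@eigenvalues))
      msg <- c(msg, "U out of range")
    if (ncol(object@components) != object@U)
      msg <- c(msg, "components must have U columns")
    if (length(msg)) msg else TRUE
  })

#' Subject subgroup model (k-means in PCA space)
#'
#' Keeps the training points because subgroup distance at prediction time is
#' the mean Euclidean distance from the query to the subgroup's members
#' (member-mean, not centroid, by default).
#'
#' @slot centers k x U centroid matrix.
#' @slot assignment integer vector, subgroup index per training subject.
#' @slot k number of subgroups (>= 2).
#' @slot silhouette mean silhouette coefficient of the partition.
#' @slot points the S x U training coordinates.
#' @slot subjectIds training subject identifiers.
#' @export
setClass("ClusterModel",
  representation(centers = "matrix", assignment = "integer", k = "integer",
                 silhouette = "numeric", points = "matrix",
                 subjectIds = "character"),
  validity = function(object) {
    msg <- character()
    if (object@k < 2L) msg <- c(msg, "k must be >= 2")
    if (length(object@assignment) != nrow(object@points))
      msg <- c(msg, "one assignment per point required")
    if (any(tabulate(object@assignment, object@k) == 0L))
      msg <- c(msg, "every subgroup must be non-empty")
    if (object@silhouette < -1 || object@silhouette > 1)
      msg <- c(msg, "silhouette must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  })

#' Sequential CNN configuration
#'
#' Hyper-parameters of the dual-scale sequential convolutional network. The
#' small branch kernel spans fs/2 samples (high-frequency scale), the large
#' branch fs*4 samples (low-frequency scale); both convolve with height
#' `kernelH` over the epoch axis so that adjacent epochs are seen jointly.
#'
#' @slot fs sampling rate the model expects, Hz.
#' @slot nStages number of output classes (5).
#' @slot smallKernelW,largeKernelW kernel widths in samples.
#' @slot smallStride,largeStride convolution strides in samples.
#' @slot kernelH kernel height in epochs (2 = cross-epoch convolution).
#' @slot nFilters filters per branch in the first convolution; follow-up
#'   convolutions use twice this.
#' @slot seReduction squeeze-and-excitation bottleneck ratio.
#' @slot dropout dropout fraction on the concatenated features.
#' @slot lr,batchSize,maxEpochs,patience optimiser settings.
#' @slot validFraction fraction of training windows held out for early
#'   stopping when no validation set is supplied.
#' @slot classWeights use inverse-frequency class weights in the loss.
#' @slot restarts maximum seeded training restarts; the attempt with the
#'   best validation accuracy wins.
#' @slot restartFloor validation accuracy at which no further restart is
#'   attempted.
#' @slot seed RNG seed for initialisation and shuffling.
#' @export
setClass("SCNNConfig",
  representation(fs = "numeric", nStages = "integer", smallKernelW = "integer",
                 largeKernelW = "integer", smallStride = "integer",
                 largeStride = "integer", kernelH = "integer",
                 nFilters = "integer", seReduction = "integer",
                 dropout = "numeric", lr = "numeric", batchSize = "integer",
                 maxEpochs = "integer", patience = "integer",
                 validFraction = "numeric", classWeights = "logical",
                 restarts = "integer", restartFloor = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@kernelH < 1L) msg <- c(msg, "kernelH must be >= 1")
    if (object@seReduction < 1L) msg <- c(msg, "seReduction must be >= 1")
    if (object@nFilters %% object@seReduction != 0L)
      msg <- c(msg, "nFilters must be divisible by seReduction")
    if (object@dropout < 0 || object@dropout >= 1)
      msg <- c(msg, "dropout must be in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' A (possibly trained) sequential CNN
#'
#' @slot params named list of weight matrices and bias vectors (the
#'   best-validation training attempt).
#' @slot attempts parameter sets of all near-best training attempts;
#'   predictions average their probabilities (empty before training).
#' @slot config the [SCNNConfig-class] used to build the network.
#' @slot arch internal layer geometry (im2col operators, widths).
#' @slot history per-training-epoch loss/accuracy records of the winning
#'   attempt.
#' @slot trained whether [trainScnn()] has been run.
#' @export
setClass("SCNNModel",
  representation(params = "list", attempts = "list", config = "SCNNConfig",
                 arch = "list", history = "data.frame",
                 trained = "logical"))

#' Sliding-window sequence tensor
#'
#' The sequence-encoding of an epoched recording: window i stacks epochs
#' i .. i+L-1, so window i position j holds absolute epoch i+j-1.
#'
#' @slot data numeric array of shape (P-L+1, L, M).
#' @slot L window length in epochs.
#' @slot offset absolute epoch index of window 1 position 1 (1-based).
#' @export
setClass("SequenceTensor",
  representation(data = "array", L = "integer", offset = "integer"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3L) msg <- c(msg, "data must be a 3-d array")
    else if (d[2L] != object@L) msg <- c(msg, "dim(data)[2] must equal L")
    if (object@L < 1L) msg <- c(msg, "L must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Consolidated per-epoch stage scores
#'
#' Row m is the sum of the L1-normalised window/position probability rows
#' that cover epoch m; it therefore sums to `coverage[m]`, the number of
#' windows covering that epoch.
#'
#' @slot scores P x 5 numeric matrix.
#' @slot coverage integer vector, contributing windows per epoch.
#' @export
setClass("ConsolidatedProbs",
  representation(scores = "matrix", coverage = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@scores) != length(object@coverage))
      msg <- c(msg, "one coverage count per epoch required")
    if (any(object@scores < -1e-12))
      msg <- c(msg, "scores must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Ensemble fusion weights
#'
#' Normalised inverse-squared subgroup distances: subgroups spectrally closer
#' to the test subject get more say in the fused prediction.
#'
#' @slot weights length-k numeric, non-negative, summing to 1.
#' @slot distances the source subgroup distances.
#' @export
setClass("EnsembleWeights",
  representation(weights = "numeric", distances = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@weights) != length(object@distances))
      msg <- c(msg, "weights and distances must have equal length")
    if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
    if (abs(sum(object@weights) - 1) > 1e-9)
      msg <- c(msg, "weights must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' Staging performance report
#'
#' @slot acc overall accuracy.
#' @slot kappa Cohen's kappa from the confusion marginals.
#' @slot macroF1,macroSens,macroSpec unweighted means over defined classes.
#' @slot perClassF1,perClassSens,perClassSpec per-stage one-vs-rest values.
#' @slot aucPerClass one-vs-rest AUC per stage (NA if stage absent).
#' @slot confusion 5 x 5 count matrix, rows = truth, columns = prediction.
#' @export
setClass("MetricsReport",
  representation(acc = "numeric", kappa = "numeric", macroF1 = "numeric",
                 macroSens = "numeric", macroSpec = "numeric",
                 perClassF1 = "numeric", perClassSens = "numeric",
                 perClassSpec = "numeric", aucPerClass = "numeric",
                 confusion = "matrix"))
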