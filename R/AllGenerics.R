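#' Accessors for epoched recordings
#'
#' @param object an object.
#' @return `epochs()` the P x M signal matrix; `stageLabels()` the per-epoch
#'   stage factor; `samplingRate()` the sampling rate in Hz; `subjectId()` the
#'   subject identifier; `nEpochs()` the number of scored epochs.
#' @name recording-accessors
#' @aliases epochs stageLabels samplingRate subjectId nEpochs
NULL

#' @rdname recording-accessors
#' @export
setGeneric("epochs", function(object) standardGeneric("epochs"))

#' @rdname recording-accessors
#' @export
setGeneric("stageLabels", function(object) standardGeneric("stageLabels"))

#' @rdname recording-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname recording-accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname recording-accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' @rdname recording-accessors
#' @export
setMethod("epochs", "EpochedRecording", function(object) object@X)

#' @rdname recording-accessors
#' @export
setMethod("stageLabels", "EpochedRecording", function(object) object@labels)

#' @rdname recording-accessors
#' @export
setMethod("samplingRate", "EpochedRecording", function(object) object@fs)

#' @rdname recording-accessors
#' @export
setMethod("samplingRate", "RawRecording", function(object) object@fs)

#' @rdname recording-accessors
#' @export
setMethod("subjectId", "EpochedRecording", function(object) object@subjectId)

#' @rdname recording-accessors
#' @export
setMethod("subjectId", "RawRecording", function(object) object@subjectId)

#' @rdname recording-accessors
#' @export
setMethod("nEpochs", "EpochedRecording", function(object) nrow(object@X))

setMethod("show", "RawRecording", function(object) {
  cat(sprintf("RawRecording '%s' channel %s: %d samples at %g Hz (%.1f min)\n",
              object@subjectId, object@channel, length(object@samples),
              object@fs, length(object@samples) / object@fs / 60))
})

setMethod("show", "EpochedRecording", function(object) {
  tab <- table(object@labels)
  cat(sprintf("EpochedRecording '%s': %d epochs x %d samples at %g Hz\n",
              object@subjectId, nrow(object@X), ncol(object@X), object@fs))
  cat("  stages:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
})

setMethod("show", "PCAModel", function(object) {
  cat(sprintf("PCAModel: %d features -> %d components, retained information %.3f\n",
              length(object@center), object@U, object@roi))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k=%d subgroups over %d subjects, silhouette %.3f\n",
              object@k, nrow(object@points), object@silhouette))
  cat("  sizes:", paste(tabulate(object@assignment, object@k), collapse = ", "),
      "\n")
})

setMethod("show", "SCNNModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("SCNNModel (%s): %d parameters, %d filters/branch, kernel height %d\n",
              if (object@trained) "trained" else "untrained", np,
              object@config@nFilters, object@config@kernelH))
  if (nrow(object@history))
    cat(sprintf("  best validation accuracy %.3f after %d training epochs\n",
                max(object@history$validAcc), nrow(object@history)))
})

setMethod("show", "SequenceTensor", function(object) {
  d <- dim(object@data)
  cat(sprintf("SequenceTensor: %d windows x L=%d epochs x %d samples\n",
              d[1L], d[2L], d[3L]))
})

setMethod("show", "EnsembleWeights", function(object) {
  cat("EnsembleWeights:",
      paste(sprintf("%.3f", object@weights), collapse = ", "),
      "(distances:", paste(sprintf("%.3f", object@distances), collapse = ", "),
      ")\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: acc %.3f, kappa %.3f, macro F1 %.3f\n",
              object@acc, object@kappa, object@macroF1))
  cat("  per-class F1:",
      paste(sprintf("%s=%.3f", names(object@perClassF1), object@perClassF1),
            collapse = " "), "\n")
})
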