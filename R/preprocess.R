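# Signal conditioning and epoching.

#' Notch, band-pass and z-normalise a raw recording
#'
#' Applies, in order: an optional power-line notch (second-order IIR, quality
#' factor 30, zero-phase), a 4th-order Butterworth band-pass (zero-phase,
#' forward-backward), and whole-recording z-normalisation to zero mean and
#' unit standard deviation. Zero-phase filtering avoids phase distortion at
#' stage boundaries.
#'
#' @param rec a [RawRecording-class].
#' @param notch power-line frequency to notch, `50`, `60`, or `"none"`.
#' @param band length-2 numeric, band-pass corner frequencies in Hz
#'   (default `c(0.3, 35)`).
#' @param qualityFactor notch quality factor (default 30).
#' @param normalize apply the final z-normalisation (default TRUE); disable
#'   to inspect the filtered signal on its physical scale.
#' @return the filtered, normalised [RawRecording-class].
#' @export
preprocessRecording <- function(rec, notch = c("none", "50", "60"),
                                band = c(0.3, 35), qualityFactor = 30,
                                normalize = TRUE) {
  stopifnot(is(rec, "RawRecording"))
  notch <- as.character(notch)
  notch <- match.arg(notch)
  fs <- rec@fs
  nyq <- fs / 2
  if (length(band) != 2L || band[1L] <= 0 || band[1L] >= band[2L])
    stop("band must be increasing positive frequencies")
  if (band[2L] >= nyq)
    stop("band upper edge (", band[2L], " Hz) must be below Nyquist (", nyq,
         " Hz)")
  x <- rec@samples
  if (notch != "none") {
    f0 <- as.numeric(notch)
    if (f0 >= nyq)
      stop("notch frequency (", f0, " Hz) must be below Nyquist (", nyq, " Hz)")
    w0 <- 2 * pi * f0 / fs
    alpha <- sin(w0) / (2 * qualityFactor)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    x <- signal::filtfilt(signal::Arma(b = b / a[1L], a = a / a[1L]), x)
  }
  bp <- signal::butter(2, band / nyq, type = "pass")
  x <- signal::filtfilt(bp, x)
  if (normalize) x <- (x - mean(x)) / stats::sd(x)
  initialize(rec, samples = x)
}

#' Cut a recording into labelled 30-second epochs
#'
#' The signal is split into `P = min(floor(duration / epochLen), n labels)`
#' consecutive epochs of `epochLen * fs` samples; a trailing partial epoch is
#' discarded. Epochs labelled `UNSCORED` are dropped from both the signal and
#' the labels, so downstream epoch counts refer to scored epochs only.
#'
#' @param rec a [RawRecording-class] (typically preprocessed).
#' @param labels per-epoch stage factor from [mapStages()] with levels
#'   `c(STAGES, "UNSCORED")`.
#' @param epochLen epoch length in seconds (default 30).
#' @return an [EpochedRecording-class].
#' @export
epochAndAlign <- function(rec, labels, epochLen = 30) {
  stopifnot(is(rec, "RawRecording"))
  M <- as.integer(epochLen * rec@fs)
  P <- min(length(rec@samples) %/% M, length(labels))
  if (P < 1L)
    stop("recording shorter than one epoch (", length(rec@samples) / rec@fs,
         " s < ", epochLen, " s)")
  X <- matrix(rec@samples[seq_len(P * M)], nrow = P, ncol = M, byrow = TRUE)
  lab <- as.character(labels[seq_len(P)])
  keep <- lab != "UNSCORED" & !is.na(lab)
  if (!any(keep)) stop("no scored epochs remain after dropping UNSCORED")
  new("EpochedRecording", X = X[keep, , drop = FALSE],
      labels = stageFactor(lab[keep]), fs = rec@fs, epochLen = epochLen,
      subjectId = rec@subjectId)
}

#' Save / load an epoched recording
#'
#' Recordings are serialised with R's native RDS format (signal matrix as
#' float, labels, sampling rate, subject id).
#'
#' @param rec an [EpochedRecording-class].
#' @param path file path.
#' @return `saveRecording()` returns `path` invisibly; `readRecording()` the
#'   recording.
#' @export
saveRecording <- function(rec, path) {
  stopifnot(is(rec, "EpochedRecording"))
  saveRDS(rec, path)
  invisible(path)
}

#' @rdname saveRecording
#' @export
readRecording <- function(path) {
  rec <- readRDS(path)
  stopifnot(is(rec, "EpochedRecording"))
  rec
}
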