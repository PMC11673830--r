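# Subject-level spectral features: Welch PSD, band powers, fast/slow ratios.

#' Canonical EEG frequency bands (Hz)
#'
#' delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-35.
#'
#' @export
EEG_BANDS <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                  beta = c(13, 30), gamma = c(30, 35))

#' Welch power spectral density estimate
#'
#' Hann-windowed, 50%-overlapping segment averaging with density scaling:
#' the one-sided PSD integrates to the signal variance (each segment is
#' demeaned before windowing).
#'
#' @param x numeric signal, at least 256 samples.
#' @param fs sampling rate, Hz.
#' @param winSec segment length in seconds (default 4).
#' @param overlap fractional segment overlap (default 0.5).
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welchPsd <- function(x, fs, winSec = 4, overlap = 0.5) {
  n <- length(x)
  if (n < 256L) stop("signal too short for Welch PSD (need >= 256 samples)")
  nwin <- min(n, as.integer(round(winSec * fs)))
  step <- max(1L, as.integer(round(nwin * (1 - overlap))))
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / nwin)   # periodic Hann
  U <- sum(w^2)
  nfreq <- nwin %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * U * fs)
  # one-sided: double everything except DC and (for even nwin) Nyquist
  dbl <- rep(2, nfreq)
  dbl[1L] <- 1
  if (nwin %% 2L == 0L) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1L) * fs / nwin, psd = psd * dbl)
}

interpAt <- function(freq, psd, f0) {
  if (f0 %in% freq) return(psd[match(f0, freq)])
  stats::approx(freq, psd, xout = f0)$y
}

#' Thirteen spectral features from a PSD
#'
#' Absolute band power (trapezoidal integral of the density, with linear
#' interpolation at band edges) and mean spectral density (power divided by
#' bandwidth) in each of the five [EEG_BANDS], plus three fast/slow-wave
#' ratios: alpha/delta, beta/theta and (alpha+beta)/(delta+theta) power
#' ratios (denominator floored at 1e-12).
#'
#' @param freq,psd a PSD as returned by [welchPsd()]; must cover 0.5-35 Hz.
#' @return named numeric vector of 13 features, with attribute `bands` giving
#'   the band edges.
#' @export
bandFeatures <- function(freq, psd) {
  if (min(freq) > 0.5 || max(freq) < 35)
    stop("PSD must cover 0.5-35 Hz (got ", min(freq), "-", max(freq), " Hz)")
  eps <- 1e-12
  power <- density <- numeric(length(EEG_BANDS))
  for (i in seq_along(EEG_BANDS)) {
    b <- EEG_BANDS[[i]]
    inner <- freq > b[1L] & freq < b[2L]
    f <- c(b[1L], freq[inner], b[2L])
    p <- c(interpAt(freq, psd, b[1L]), psd[inner], interpAt(freq, psd, b[2L]))
    power[i] <- trapz(f, p)
    density[i] <- power[i] / (b[2L] - b[1L])
  }
  names(power) <- paste0(names(EEG_BANDS), "_power")
  names(density) <- paste0(names(EEG_BANDS), "_density")
  ratios <- c(
    alpha_delta_ratio = power[["alpha_power"]] / max(power[["delta_power"]], eps),
    beta_theta_ratio = power[["beta_power"]] / max(power[["theta_power"]], eps),
    fast_slow_ratio = (power[["alpha_power"]] + power[["beta_power"]]) /
      max(power[["delta_power"]] + power[["theta_power"]], eps))
  out <- c(power, density, ratios)
  attr(out, "bands") <- EEG_BANDS
  out
}

#' Subject-level spectral feature vector
#'
#' Per-epoch [bandFeatures()] averaged over all scored epochs of the subject.
#'
#' @param rec an [EpochedRecording-class].
#' @return named numeric vector of 13 features.
#' @export
subjectFeatures <- function(rec) {
  stopifnot(is(rec, "EpochedRecording"))
  X <- rec@X
  acc <- NULL
  for (p in seq_len(nrow(X))) {
    w <- welchPsd(X[p, ], rec@fs)
    f <- bandFeatures(w$freq, w$psd)
    acc <- if (is.null(acc)) f else acc + f
  }
  out <- acc / nrow(X)
  attr(out, "bands") <- EEG_BANDS
  out
}

#' Feature matrix for a cohort
#'
#' @param recordings list of [EpochedRecording-class] objects.
#' @return S x 13 matrix, one row per subject, rownames = subject ids.
#' @export
cohortFeatures <- function(recordings) {
  feats <- t(vapply(recordings, subjectFeatures,
                    numeric(length(EEG_BANDS) * 2L + 3L)))
  rownames(feats) <- vapply(recordings, subjectId, character(1))
  feats
}
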