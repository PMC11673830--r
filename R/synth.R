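# Seeded synthetic EEG cohorts: stage-specific band signatures, Markov
# hypnograms, and spectrally distinct subject subgroups, so the whole
# pipeline is testable without any recorded data.

#' Default stage band-power profiles
#'
#' Relative power weights per EEG band plus a broadband noise floor (weights
#' sum to 1), chosen to mimic textbook sleep EEG: Wake alpha/beta-dominant,
#' N1 theta-dominant, N2 theta-dominant with 13 Hz spindle bursts, N3
#' delta-dominant, REM mixed theta/beta.
#'
#' @return named list of per-stage profiles, each with elements
#'   `bandPowers` (named over delta..gamma), `noiseFloor` and `spindles`
#'   (bursts per epoch).
#' @export
defaultStageProfiles <- function() {
  mk <- function(d, t, a, b, g, floor = 0.15, spindles = 0L)
    list(bandPowers = c(delta = d, theta = t, alpha = a, beta = b, gamma = g),
         noiseFloor = floor, spindles = spindles)
  list(Wake = mk(0.05, 0.05, 0.40, 0.30, 0.05),
       N1   = mk(0.10, 0.55, 0.10, 0.05, 0.05),
       N2   = mk(0.20, 0.35, 0.22, 0.05, 0.03, spindles = 2L),
       N3   = mk(0.65, 0.10, 0.04, 0.03, 0.03),
       # REM theta outweighs beta by enough that theta stays the measured
       # dominant band: the broadband floor contributes power proportional
       # to bandwidth, which favours the wide beta band
       REM  = mk(0.05, 0.38, 0.10, 0.27, 0.05))
}

#' Default stage transition matrix
#'
#' A doubly stochastic chain: self-transition 0.75 for every stage, the
#' remaining mass spread uniformly over the other four stages. Two
#' properties matter to the pipeline. Stage persistence (bouts of about
#' four epochs) means most adjacent-epoch pairs share a stage, the regime
#' the cross-epoch convolutions are built for; and the exactly uniform
#' stationary distribution keeps every stage well represented in every
#' subject's night, so small training subgroups see enough of each stage
#' and subject-mean features are not dominated by night-composition
#' accidents. Real hypnograms are neither uniform nor geometric-bout; see
#' the methods vignette for what this simplification does and does not
#' test.
#'
#' @return 5 x 5 matrix with rows/columns named by [STAGES].
#' @export
defaultTransitionMatrix <- function() {
  m <- matrix(0.25 / 4, 5L, 5L) + diag(5L) * (0.75 - 0.25 / 4)
  rownames(m) <- colnames(m) <- STAGES
  m
}

#' Sample a hypnogram from a Markov chain
#'
#' The first epoch is Wake; every subsequent stage is drawn from the
#' transition row of the current stage. Deterministic given `seed`.
#'
#' @param transition 5 x 5 row-stochastic matrix over [STAGES].
#' @param n number of epochs.
#' @param seed RNG seed.
#' @return factor of length n with levels [STAGES].
#' @export
markovHypnogram <- function(transition, n, seed = 1L) {
  transition <- as.matrix(transition)
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition rows must be non-negative and sum to 1")
  cum <- t(apply(transition, 1L, cumsum))
  withSeed(seed, {
    u <- stats::runif(n)
    s <- integer(n)
    s[1L] <- 1L                         # Wake
    for (i in seq_len(n - 1L))
      s[i + 1L] <- findInterval(u[i + 1L], cum[s[i], ]) + 1L
    stageFactor(STAGES[pmin(s, 5L)])
  })
}

# Band-pass filter cache (filter design is fs-dependent but epoch-invariant).
.filterCache <- new.env(parent = emptyenv())

bandFilter <- function(lo, hi, fs) {
  key <- paste(lo, hi, fs)
  if (is.null(.filterCache[[key]]))
    .filterCache[[key]] <- signal::butter(2, c(lo, hi) / (fs / 2),
                                          type = "pass")
  .filterCache[[key]]
}

#' Synthesise one 30-second epoch with a given band signature
#'
#' Sums band-limited noise (white noise through a band-pass per EEG band)
#' scaled so each band's variance share matches the profile weight, plus a
#' broadband white-noise floor; N2-style profiles add 1-second 13 Hz
#' Hann-enveloped spindle bursts, with amplitude modest enough that the
#' profile's declared dominant band stays dominant per epoch. The epoch is
#' normalised to zero mean and unit variance.
#'
#' @param profile a stage profile as in [defaultStageProfiles()].
#' @param fs sampling rate, Hz (must exceed 70 so the gamma band fits).
#' @param epochLen epoch length in seconds (default 30).
#' @param seed RNG seed.
#' @return numeric vector of `epochLen * fs` samples.
#' @export
synthEpoch <- function(profile, fs, epochLen = 30, seed = 1L) {
  w <- profile$bandPowers
  stopifnot(all(w >= 0), profile$noiseFloor >= 0,
            abs(sum(w) + profile$noiseFloor - 1) < 1e-9)
  if (fs / 2 <= max(EEG_BANDS$gamma))
    stop("sampling rate too low for the 30-35 Hz gamma band")
  M <- as.integer(epochLen * fs)
  withSeed(seed, {
    x <- numeric(M)
    for (i in seq_along(EEG_BANDS)) {
      if (w[i] <= 0) next
      b <- EEG_BANDS[[i]]
      comp <- signal::filtfilt(bandFilter(b[1L], b[2L], fs),
                               stats::rnorm(M))
      x <- x + comp / stats::sd(comp) * sqrt(w[i])
    }
    if (profile$noiseFloor > 0)
      x <- x + stats::rnorm(M, 0, sqrt(profile$noiseFloor))
    nSpin <- profile$spindles %||% 0L
    if (nSpin > 0L) {
      burstLen <- as.integer(fs)                 # 1 s bursts
      env <- 0.5 - 0.5 * cos(2 * pi * seq_len(burstLen) / (burstLen + 1L))
      for (s in seq_len(nSpin)) {
        at <- sample.int(M - burstLen, 1L)
        tt <- seq_len(burstLen) / fs
        x[at:(at + burstLen - 1L)] <- x[at:(at + burstLen - 1L)] +
          1.2 * env * sin(2 * pi * 13 * tt)
      }
    }
    (x - mean(x)) / stats::sd(x)
  })
}

#' Specify a synthetic cohort
#'
#' The defaults are the reference study conditions of the package's
#' synthetic experiments: two spectral subgroups of three subjects, 200
#' scored epochs each at 100 Hz, with the second subgroup's alpha and beta
#' weights multiplied by `groupShift` (then renormalised), so the subgroups
#' differ along the fast/slow-wave axis the clustering module uses.
#'
#' @param nSubjectsPerGroup subjects per subgroup (default 3).
#' @param nGroups number of spectral subgroups (default 2).
#' @param groupShift multiplicative alpha/beta shift between consecutive
#'   groups (default 3).
#' @param epochsPerSubject scored epochs per subject (default 200).
#' @param fs sampling rate, Hz (default 100).
#' @param transition stage transition matrix
#'   (default [defaultTransitionMatrix()]).
#' @param profiles stage profiles (default [defaultStageProfiles()]).
#' @param seed master seed; all subject/epoch seeds derive from it.
#' @return a `cohortSpec` list.
#' @export
cohortSpec <- function(nSubjectsPerGroup = 3L, nGroups = 2L, groupShift = 3,
                       epochsPerSubject = 200L, fs = 100,
                       transition = defaultTransitionMatrix(),
                       profiles = defaultStageProfiles(), seed = 1L) {
  stopifnot(nSubjectsPerGroup >= 1L, nGroups >= 1L, epochsPerSubject >= 1L,
            all(abs(rowSums(transition) - 1) < 1e-9))
  structure(list(nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
                 nGroups = as.integer(nGroups), groupShift = groupShift,
                 epochsPerSubject = as.integer(epochsPerSubject), fs = fs,
                 transition = transition, profiles = profiles,
                 seed = as.integer(seed)),
            class = "cohortSpec")
}

shiftProfiles <- function(profiles, factor) {
  lapply(profiles, function(p) {
    w <- p$bandPowers
    w[c("alpha", "beta")] <- w[c("alpha", "beta")] * factor
    tot <- sum(w) + p$noiseFloor
    p$bandPowers <- w / tot
    p$noiseFloor <- p$noiseFloor / tot
    p
  })
}

#' Generate a synthetic multi-subject cohort
#'
#' Each subject gets a Markov hypnogram and per-epoch band-limited signals
#' from its stage's profile; subjects in group g use profiles whose alpha
#' and beta weights are scaled by `groupShift^(g-1)` (renormalised). Fully
#' deterministic given `spec$seed`.
#'
#' @param spec a [cohortSpec()].
#' @return list with `recordings` (list of [EpochedRecording-class]),
#'   `groups` (integer ground-truth group per subject) and `spec`.
#' @export
synthCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "cohortSpec"))
  M <- as.integer(30 * spec$fs)
  recordings <- list()
  groups <- integer(0)
  idx <- 0L
  for (g in seq_len(spec$nGroups)) {
    prof <- shiftProfiles(spec$profiles, spec$groupShift^(g - 1L))
    for (s in seq_len(spec$nSubjectsPerGroup)) {
      idx <- idx + 1L
      subjSeed <- childSeed(spec$seed, idx)
      hyp <- markovHypnogram(spec$transition, spec$epochsPerSubject,
                             seed = subjSeed)
      X <- matrix(0, spec$epochsPerSubject, M)
      for (e in seq_len(spec$epochsPerSubject))
        X[e, ] <- synthEpoch(prof[[as.character(hyp[e])]], spec$fs,
                             seed = childSeed(subjSeed, e))
      recordings[[idx]] <- new("EpochedRecording", X = X, labels = hyp,
                               fs = spec$fs, epochLen = 30,
                               subjectId = sprintf("S%02d", idx))
      groups[idx] <- g
    }
  }
  list(recordings = recordings, groups = groups, spec = spec)
}

#' Write a synthetic recording as EDF+ and CSV hypnogram fixtures
#'
#' Emits a single-channel EDF+ file whose annotation track carries the stage
#' labels as `Sleep stage X` events, and optionally a `epoch,stage` CSV
#' hypnogram, to exercise the EDF round trip.
#'
#' @param rec an [EpochedRecording-class].
#' @param edfPath output EDF path.
#' @param csvPath optional CSV hypnogram path.
#' @param channel channel label (default `"Fpz-Cz"`).
#' @return `edfPath`, invisibly.
#' @export
writeEdfFixture <- function(rec, edfPath, csvPath = NULL,
                            channel = "Fpz-Cz") {
  stopifnot(is(rec, "EpochedRecording"))
  stageText <- c(Wake = "Sleep stage W", N1 = "Sleep stage N1",
                 N2 = "Sleep stage N2", N3 = "Sleep stage N3",
                 REM = "Sleep stage R")
  P <- nrow(rec@X)
  ann <- data.frame(onset = (seq_len(P) - 1L) * rec@epochLen,
                    duration = rec@epochLen,
                    text = unname(stageText[as.character(rec@labels)]))
  writeEdf(edfPath,
           signals = list(list(label = channel, fs = rec@fs,
                               samples = as.vector(t(rec@X)))),
           annotations = ann, patient = rec@subjectId)
  if (!is.null(csvPath)) {
    csvToken <- c(Wake = "W", N1 = "N1", N2 = "N2", N3 = "N3", REM = "R")
    utils::write.csv(data.frame(epoch = seq_len(P),
                                stage = unname(csvToken[as.character(rec@labels)])),
                     csvPath, row.names = FALSE, quote = FALSE)
  }
  invisible(edfPath)
}
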