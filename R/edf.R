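# EDF/EDF+ reading and writing.
#
# EDF stores a 256-byte fixed header, 256 bytes of header per signal, then
# data records of little-endian int16 samples scaled linearly between the
# digital and physical ranges declared per signal. EDF+ adds an
# "EDF Annotations" signal holding time-stamped annotation lists (TALs):
#   +onset[\x15duration]\x14text\x14 ... \x00 padding
# Only the subset needed for PSG + hypnogram work is implemented.

padStr <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

# Render a number into <= `width` ASCII chars, reducing precision as needed.
fmtNum <- function(x, width = 8L) {
  for (digits in seq(10L, 1L)) {
    s <- trimws(formatC(x, digits = digits, format = "g"))
    if (nchar(s) <= width) return(s)
  }
  stop("cannot format ", x, " in ", width, " characters")
}

encodeTals <- function(events, recordStarts) {
  # Distribute annotation events over data records by onset; every record
  # leads with its timekeeping TAL.
  nRec <- length(recordStarts)
  recDur <- if (nRec > 1L) recordStarts[2L] - recordStarts[1L] else Inf
  out <- character(nRec)
  for (r in seq_len(nRec)) {
    tal <- sprintf("+%s\x14\x14", fmtNum(recordStarts[r], 12L))
    if (!is.null(events) && nrow(events)) {
      inRec <- which(events$onset >= recordStarts[r] &
                     events$onset < recordStarts[r] + recDur)
      for (i in inRec)
        tal <- paste0(tal, sprintf("+%s\x15%s\x14%s\x14",
                                   fmtNum(events$onset[i], 12L),
                                   fmtNum(events$duration[i], 12L),
                                   events$text[i]))
    }
    out[r] <- tal
  }
  out
}

#' Write signals (and optional annotations) to an EDF/EDF+ file
#'
#' A minimal EDF writer used by the synthetic fixture pipeline and tests.
#' Samples are quantised to 16-bit integers over each signal's observed
#' physical range, the quantisation the format imposes.
#'
#' @param path output file path.
#' @param signals list of signals, each a list with elements `label`,
#'   `fs` (Hz) and `samples` (numeric, physical units); optional `physicalDim`
#'   (default `"uV"`).
#' @param annotations optional data.frame with columns `onset`, `duration`
#'   (seconds) and `text`; written as an EDF+ annotation signal.
#' @param recordDuration data record length in seconds (default 1).
#' @param patient,recording free-text header fields.
#' @return `path`, invisibly.
#' @export
writeEdf <- function(path, signals, annotations = NULL, recordDuration = 1,
                     patient = "X X X X", recording = "Startdate 01-JAN-2000") {
  stopifnot(length(signals) >= 1L)
  spr <- vapply(signals, function(s) s$fs * recordDuration, numeric(1))
  if (any(spr != round(spr)))
    stop("fs * recordDuration must be an integer for every signal")
  nRec <- max(ceiling(vapply(signals, function(s) length(s$samples),
                             numeric(1)) / spr))
  recordStarts <- (seq_len(nRec) - 1L) * recordDuration

  annChars <- NULL
  if (!is.null(annotations)) {
    annChars <- encodeTals(annotations, recordStarts)
    annSpr <- max(64L, ceiling((max(nchar(annChars, type = "bytes")) + 2L) / 2L))
  }

  ns <- length(signals) + as.integer(!is.null(annotations))
  headerBytes <- 256L * (ns + 1L)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(padStr(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8L); wr(patient, 80L); wr(recording, 80L)
  wr("01.01.00", 8L); wr("00.00.00", 8L)
  wr(headerBytes, 8L)
  wr(if (is.null(annotations)) "" else "EDF+C", 44L)
  wr(nRec, 8L); wr(fmtNum(recordDuration), 8L); wr(ns, 4L)

  physMin <- physMax <- numeric(length(signals))
  for (i in seq_along(signals)) {
    x <- signals[[i]]$samples
    physMin[i] <- min(x); physMax[i] <- max(x)
    if (physMax[i] <= physMin[i]) physMax[i] <- physMin[i] + 1
  }
  labels <- c(vapply(signals, function(s) s$label, character(1)),
              if (!is.null(annotations)) "EDF Annotations")
  field <- function(values, width) for (v in values) wr(v, width)
  field(labels, 16L)
  field(rep("", ns), 80L)                                 # transducer
  field(c(vapply(signals, function(s) s$physicalDim %||% "uV", character(1)),
          if (!is.null(annotations)) ""), 8L)
  field(c(vapply(physMin, fmtNum, character(1)),
          if (!is.null(annotations)) "-1"), 8L)
  field(c(vapply(physMax, fmtNum, character(1)),
          if (!is.null(annotations)) "1"), 8L)
  field(c(rep("-32768", length(signals)),
          if (!is.null(annotations)) "-32768"), 8L)
  field(c(rep("32767", length(signals)),
          if (!is.null(annotations)) "32767"), 8L)
  field(rep("", ns), 80L)                                 # prefiltering
  field(c(spr, if (!is.null(annotations)) annSpr), 8L)
  field(rep("", ns), 32L)

  for (r in seq_len(nRec)) {
    for (i in seq_along(signals)) {
      x <- signals[[i]]$samples
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      seg <- numeric(spr[i])
      ok <- idx <= length(x)
      seg[ok] <- x[idx[ok]]
      dig <- round((seg - physMin[i]) / (physMax[i] - physMin[i]) * 65535 -
                     32768)
      writeBin(as.integer(pmin(32767, pmax(-32768, dig))), con, size = 2L,
               endian = "little")
    }
    if (!is.null(annotations)) {
      bytes <- c(charToRaw(annChars[r]),
                 rep(as.raw(0L), 2L * annSpr - nchar(annChars[r],
                                                     type = "bytes")))
      writeBin(bytes, con)
    }
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an EDF/EDF+ file
#'
#' Low-level reader returning every ordinary signal (label, sampling rate,
#' physical-unit samples) plus any EDF+ annotations as parsed TAL events.
#'
#' @param path an EDF/EDF+ file.
#' @return list with elements `signals` (list of `label`, `fs`, `samples`),
#'   `annotations` (data.frame `onset`, `duration`, `text`, possibly empty)
#'   and `patient`.
#' @export
readEdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8L)                               # version
  patient <- rd(80L); rd(80L); rd(8L); rd(8L)
  rd(8L); rd(44L)
  nRec <- as.integer(rd(8L))
  recDur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  labels <- vapply(seq_len(ns), function(i) rd(16L), character(1))
  for (i in seq_len(ns)) rd(80L)       # transducer
  for (i in seq_len(ns)) rd(8L)        # physical dim
  physMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  physMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  digMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  digMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8L)), numeric(1))
  for (i in seq_len(ns)) rd(80L)       # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8L)), integer(1))
  for (i in seq_len(ns)) rd(32L)

  isAnn <- labels == "EDF Annotations"
  raw <- vector("list", ns)
  for (i in seq_len(ns)) raw[[i]] <- vector("list", nRec)
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      if (isAnn[i]) raw[[i]][[r]] <- readBin(con, "raw", 2L * spr[i])
      else raw[[i]][[r]] <- readBin(con, "integer", spr[i], size = 2L,
                                    signed = TRUE, endian = "little")
    }
  }

  signals <- list()
  for (i in which(!isAnn)) {
    dig <- unlist(raw[[i]])
    gain <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    signals[[length(signals) + 1L]] <-
      list(label = labels[i], fs = spr[i] / recDur,
           samples = (dig - digMin[i]) * gain + physMin[i])
  }

  events <- data.frame(onset = numeric(0), duration = numeric(0),
                       text = character(0))
  for (i in which(isAnn)) {
    txt <- rawToChar(unlist(raw[[i]])[unlist(raw[[i]]) != as.raw(0L)])
    tals <- strsplit(txt, "\x14\x14", fixed = TRUE)[[1L]]
    for (tal in tals) {
      # Each remaining chunk may contain "+onset\x15dur\x14text" items.
      items <- regmatches(tal, gregexpr("[+-][0-9.]+(\x15[0-9.]+)?\x14[^\x14]+",
                                        tal))[[1L]]
      for (it in items) {
        head <- sub("\x14.*$", "", it)
        text <- sub("^[^\x14]*\x14", "", it)
        parts <- strsplit(head, "\x15", fixed = TRUE)[[1L]]
        events <- rbind(events, data.frame(
          onset = as.numeric(parts[1L]),
          duration = if (length(parts) > 1L) as.numeric(parts[2L]) else NA_real_,
          text = text))
      }
    }
  }
  list(signals = signals, annotations = events, patient = patient)
}

#' Read one EEG channel from a polysomnography EDF file
#'
#' @param path EDF/EDF+ file.
#' @param channel channel label to extract, e.g. `"Fpz-Cz"`.
#' @param subjectId identifier attached to the recording; defaults to the
#'   file name without extension.
#' @return a [RawRecording-class].
#' @export
readPsg <- function(path, channel, subjectId = NULL) {
  edf <- readEdf(path)
  labels <- vapply(edf$signals, function(s) s$label, character(1))
  hit <- which(labels == channel)
  if (!length(hit))
    stop("channel '", channel, "' not found; available: ",
         paste(labels, collapse = ", "))
  sig <- edf$signals[[hit[1L]]]
  new("RawRecording", samples = sig$samples, fs = sig$fs, channel = channel,
      subjectId = subjectId %||% sub("\\.[^.]*$", "", basename(path)))
}

csvStageMap <- c("W" = "Wake", "1" = "S1", "2" = "S2", "3" = "S3", "4" = "S4",
                 "R" = "REM", "N1" = "N1", "N2" = "N2", "N3" = "N3",
                 "M" = "MOVEMENT", "?" = "UNKNOWN")

annStageMap <- c("Sleep stage W" = "Wake", "Sleep stage 1" = "S1",
                 "Sleep stage 2" = "S2", "Sleep stage 3" = "S3",
                 "Sleep stage 4" = "S4", "Sleep stage R" = "REM",
                 "Sleep stage N1" = "N1", "Sleep stage N2" = "N2",
                 "Sleep stage N3" = "N3", "Sleep stage ?" = "UNKNOWN",
                 "Movement time" = "MOVEMENT")

#' Read a hypnogram into per-epoch stage tokens
#'
#' Stage tokens are preserved verbatim (R&K `S1`-`S4` stay distinct) so that
#' [mapStages()] controls the AASM remapping downstream.
#'
#' @param path hypnogram file.
#' @param dialect `"csv"` for a two-column `epoch,stage` table with stages in
#'   `W,1,2,3,4,R,N1,N2,N3,M,?`; `"edfplus"` for an EDF+ file whose
#'   annotation track holds `Sleep stage X` events with durations that are
#'   multiples of the epoch length.
#' @param epochLen epoch length in seconds (default 30).
#' @return factor of per-epoch tokens with levels [STAGE_TOKENS] and
#'   attribute `epochLen`.
#' @export
readHypnogram <- function(path, dialect = c("csv", "edfplus"), epochLen = 30) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    tab <- utils::read.csv(path, colClasses = "character")
    if (!all(c("epoch", "stage") %in% names(tab)))
      stop("CSV hypnogram must have columns 'epoch' and 'stage'")
    unknown <- setdiff(unique(tab$stage), names(csvStageMap))
    if (length(unknown))
      stop("unknown stage token(s): ", paste(unknown, collapse = ", "))
    tokens <- unname(csvStageMap[tab$stage])
  } else {
    edf <- readEdf(path)
    ev <- edf$annotations
    ev <- ev[ev$text %in% names(annStageMap), , drop = FALSE]
    if (!nrow(ev)) stop("no sleep stage annotations found in ", path)
    if (anyNA(ev$duration))
      stop("stage annotations must carry a duration")
    if (any(ev$duration %% epochLen != 0))
      stop("stage annotation durations must be multiples of ", epochLen, " s")
    if (any(ev$onset %% epochLen != 0))
      stop("stage annotation onsets must be multiples of ", epochLen, " s")
    ev <- ev[order(ev$onset), , drop = FALSE]
    nEp <- max((ev$onset + ev$duration) / epochLen)
    tokens <- rep("UNKNOWN", nEp)
    filled <- rep(FALSE, nEp)
    for (i in seq_len(nrow(ev))) {
      idx <- ev$onset[i] / epochLen + seq_len(ev$duration[i] / epochLen)
      if (any(filled[idx]))
        stop("overlapping stage annotations at ", ev$onset[i], " s")
      tokens[idx] <- annStageMap[[ev$text[i]]]
      filled[idx] <- TRUE
    }
  }
  out <- factor(tokens, levels = STAGE_TOKENS)
  attr(out, "epochLen") <- epochLen
  out
}

#' Remap R&K stage tokens to the AASM five-stage scheme
#'
#' Under `rk_to_aasm`, S1 becomes N1, S2 becomes N2, S3 and S4 merge into N3,
#' and MOVEMENT/UNKNOWN become UNSCORED (to be dropped at epoching).
#'
#' @param labels factor of stage tokens from [readHypnogram()].
#' @param scheme `"rk_to_aasm"` or `"identity"`.
#' @return factor with levels [STAGE_TOKENS] (identity) or
#'   `c(STAGES, "UNSCORED")` (rk_to_aasm).
#' @export
mapStages <- function(labels, scheme = c("rk_to_aasm", "identity")) {
  scheme <- match.arg(scheme)
  if (scheme == "identity") return(labels)
  map <- c(Wake = "Wake", N1 = "N1", N2 = "N2", N3 = "N3", REM = "REM",
           S1 = "N1", S2 = "N2", S3 = "N3", S4 = "N3",
           MOVEMENT = "UNSCORED", UNKNOWN = "UNSCORED", UNSCORED = "UNSCORED")
  out <- factor(unname(map[as.character(labels)]),
                levels = c(STAGES, "UNSCORED"))
  attr(out, "epochLen") <- attr(labels, "epochLen") %||% 30
  out
}
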