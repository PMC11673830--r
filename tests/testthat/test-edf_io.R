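test_that("EDF write/read round-trips signals within 16-bit quantization", {
  set.seed(31)
  x1 <- sin(2 * pi * 3 * seq_len(6000) / 100)
  x2 <- rnorm(6000)
  path <- withr::local_tempfile(fileext = ".edf")
  writeEdf(path, list(list(label = "Fpz-Cz", fs = 100, samples = x1),
                      list(label = "Pz-Oz", fs = 100, samples = x2)))
  r1 <- readPsg(path, "Fpz-Cz")
  r2 <- readPsg(path, "Pz-Oz")
  expect_equal(samplingRate(r1), 100)
  quant <- function(x) (max(x) - min(x)) / 65535
  expect_lt(max(abs(r1@samples - x1)), quant(x1))
  expect_lt(max(abs(r2@samples - x2)), quant(x2))
  # second channel is really the second channel
  expect_gt(max(abs(r2@samples - x1)), 0.5)
})

test_that("requesting a missing channel names the available ones", {
  path <- withr::local_tempfile(fileext = ".edf")
  writeEdf(path, list(list(label = "Fpz-Cz", fs = 50, samples = rnorm(500))))
  expect_error(readPsg(path, "EMG"), "Fpz-Cz")
  expect_error(readPsg("/nonexistent/file.edf", "Fpz-Cz"), "not found")
})

test_that("CSV hypnograms parse verbatim R&K tokens", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("epoch,stage", "1,W", "2,1", "3,2", "4,3", "5,4", "6,R"), path)
  h <- readHypnogram(path, "csv")
  expect_equal(as.character(h), c("Wake", "S1", "S2", "S3", "S4", "REM"))
  writeLines(c("epoch,stage", "1,Q"), path)
  expect_error(readHypnogram(path, "csv"), "unknown stage token")
})

test_that("EDF+ annotations expand by duration and reject bad durations", {
  path <- withr::local_tempfile(fileext = ".edf")
  ann <- data.frame(onset = 0, duration = 90, text = "Sleep stage W")
  writeEdf(path, list(list(label = "C4-A1", fs = 100, samples = rnorm(9000))),
           annotations = ann)
  h <- readHypnogram(path, "edfplus")
  expect_equal(as.character(h), rep("Wake", 3))

  ann$duration <- 45
  writeEdf(path, list(list(label = "C4-A1", fs = 100, samples = rnorm(9000))),
           annotations = ann)
  expect_error(readHypnogram(path, "edfplus"), "multiples of 30")
})

test_that("stage remapping merges S3/S4 into N3 and drops movement", {
  x <- factor(c("Wake", "S1", "S2", "S3", "S4", "REM", "MOVEMENT"),
              levels = STAGE_TOKENS)
  m <- mapStages(x, "rk_to_aasm")
  expect_equal(as.character(m),
               c("Wake", "N1", "N2", "N3", "N3", "REM", "UNSCORED"))
  expect_identical(mapStages(x, "identity"), x)
})

test_that("the notch removes a power-line sine by at least 20 dB", {
  fs <- 200
  x <- sin(2 * pi * 50 * seq_len(8000) / fs)
  rec <- new("RawRecording", samples = x, fs = fs, channel = "c",
             subjectId = "s")
  # measured pre-normalization so the attenuation is not rescaled away;
  # wide band-pass keeps 50 Hz inside the passband
  out <- preprocessRecording(rec, notch = "50", band = c(0.3, 60),
                             normalize = FALSE)
  db <- 20 * log10(sqrt(mean(out@samples^2)) / sqrt(mean(x^2)))
  expect_lt(db, -20)
})

test_that("z-normalization yields zero mean, unit sd, and is idempotent", {
  set.seed(7)
  rec <- new("RawRecording", samples = rnorm(5000, 3, 10), fs = 100,
             channel = "c", subjectId = "s")
  out <- preprocessRecording(rec, band = c(0.3, 35))
  expect_lt(abs(mean(out@samples)), 1e-6)
  expect_lt(abs(sd(out@samples) - 1), 1e-6)
  z <- out@samples
  z2 <- (z - mean(z)) / sd(z)
  expect_lt(max(abs(z2 - z)), 1e-12)
})

test_that("the passband preserves in-band signals", {
  fs <- 100
  x <- sin(2 * pi * 10 * seq_len(3000) / fs)
  rec <- new("RawRecording", samples = x, fs = fs, channel = "c",
             subjectId = "s")
  out <- preprocessRecording(rec, band = c(0.3, 35))
  expect_gt(cor(out@samples, x), 0.99)
  expect_error(preprocessRecording(rec, band = c(0.3, 50)), "Nyquist")
})

test_that("epoching truncates partial epochs and drops unscored labels", {
  rec <- new("RawRecording", samples = rnorm(9500), fs = 100, channel = "c",
             subjectId = "s")
  lab <- factor(c("Wake", "N2", "N3"), levels = c(STAGES, "UNSCORED"))
  er <- epochAndAlign(rec, lab)
  expect_equal(dim(epochs(er)), c(3L, 3000L))

  lab2 <- factor(c("Wake", "UNSCORED", "N2"), levels = c(STAGES, "UNSCORED"))
  er2 <- epochAndAlign(rec, lab2)
  expect_equal(nEpochs(er2), 2L)
  expect_equal(as.character(stageLabels(er2)), c("Wake", "N2"))
  expect_equal(epochs(er2)[2, ], epochs(er)[3, ])

  short <- new("RawRecording", samples = rnorm(1000), fs = 100,
               channel = "c", subjectId = "s")
  expect_error(epochAndAlign(short, lab), "shorter than one epoch")
  allUnscored <- factor(rep("UNSCORED", 3), levels = c(STAGES, "UNSCORED"))
  expect_error(epochAndAlign(rec, allUnscored), "no scored epochs")
})

test_that("fixture EDF+ files round-trip through the full input pipeline", {
  coh <- tinyCohort()
  rec <- coh$recordings[[1]]
  edf <- withr::local_tempfile(fileext = ".edf")
  csv <- withr::local_tempfile(fileext = ".csv")
  writeEdfFixture(rec, edf, csv)
  raw <- readPsg(edf, "Fpz-Cz")
  h <- mapStages(readHypnogram(edf, "edfplus"))
  er <- epochAndAlign(raw, h)
  expect_equal(nEpochs(er), nEpochs(rec))
  expect_equal(as.character(stageLabels(er)), as.character(stageLabels(rec)))
  expect_lt(max(abs(epochs(er) - epochs(rec))),
            (max(epochs(rec)) - min(epochs(rec))) / 65535)
  hcsv <- mapStages(readHypnogram(csv, "csv"))
  expect_equal(as.character(hcsv), as.character(stageLabels(rec)))
})

test_that("saved recordings reload identically", {
  rec <- tinyCohort()$recordings[[1]]
  path <- withr::local_tempfile(fileext = ".rds")
  saveRecording(rec, path)
  expect_equal(readRecording(path), rec)
})
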