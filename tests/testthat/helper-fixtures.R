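# Shared fixtures, built once per test session.

# A small two-group cohort at 80 Hz (gamma band still below Nyquist) used by
# several unit tests; the reference 100 Hz conditions live in the acceptance
# tests.
tinyCohortCache <- new.env()
tinyCohort <- function() {
  if (is.null(tinyCohortCache$coh))
    tinyCohortCache$coh <- synthCohort(cohortSpec(
      nSubjectsPerGroup = 2L, epochsPerSubject = 30L, fs = 80, seed = 42L))
  tinyCohortCache$coh
}

# A tiny network configuration that keeps unit tests fast.
tinyConfig <- function(fs = 80, maxEpochs = 2L, ...) {
  scnnConfig(fs = fs, nFilters = 4L, seReduction = 2L, batchSize = 16L,
             maxEpochs = maxEpochs, patience = 2L, seed = 9L, ...)
}

randomRecording <- function(P = 12L, fs = 80, seed = 1L, id = "R1") {
  set.seed(seed)
  new("EpochedRecording",
      X = matrix(rnorm(P * 30 * fs), P, 30 * fs),
      labels = factor(STAGES[sample.int(5L, P, replace = TRUE)],
                      levels = STAGES),
      fs = fs, epochLen = 30, subjectId = id)
}

# Adjusted Rand index between two labelings (independent of any package).
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp0 <- si * sj / n
  (sij - exp0) / ((si + sj) / 2 - exp0)
}

# Brute-force silhouette: literal per-point double loop.
bruteSilhouette <- function(points, assignment) {
  S <- nrow(points)
  s <- numeric(S)
  for (i in seq_len(S)) {
    di <- function(j) sqrt(sum((points[i, ] - points[j, ])^2))
    same <- setdiff(which(assignment == assignment[i]), i)
    if (!length(same)) { s[i] <- 0; next }
    a <- mean(vapply(same, di, numeric(1)))
    b <- Inf
    for (cc in setdiff(unique(assignment), assignment[i])) {
      members <- which(assignment == cc)
      b <- min(b, mean(vapply(members, di, numeric(1))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
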