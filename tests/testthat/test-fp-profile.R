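# peak quantification, normalization, averaging, overlap index

test_that("peakAmplitude measures within the half-open 4-ms window", {
  t <- seq(0, 20, by = 0.1)
  flat <- numeric(length(t))
  expect_equal(as.numeric(peakAmplitude(flat, t, 10)), 0)

  # -0.8 at 2 ms post-stimulus counts; +1.2 at 6 ms lies outside the window
  tr <- numeric(length(t))
  tr[which.min(abs(t - 12))] <- -0.8
  tr[which.min(abs(t - 16))] <- 1.2
  amp <- peakAmplitude(tr, t, stim_time_ms = 10)
  expect_equal(as.numeric(amp), 0.8)
  expect_equal(attr(amp, "sign"), -1)

  # the sample at the stimulus time itself is excluded (artifact exclusion)
  tr2 <- numeric(length(t))
  tr2[which.min(abs(t - 10))] <- 5
  expect_equal(as.numeric(peakAmplitude(tr2, t, 10)), 0)

  expect_error(peakAmplitude(tr, t, stim_time_ms = 18), "beyond")
  expect_error(peakAmplitude(tr, t, stim_time_ms = -1), "pre-stimulus")
})

test_that("peakAmplitude equals a brute-force scan and ignores DC offsets", {
  t <- seq(0, 20, by = 0.1)
  set.seed(301)
  for (i in 1:20) {
    tr <- stats::rnorm(length(t), sd = 0.3)
    amp <- as.numeric(peakAmplitude(tr, t, 10))
    # independent oracle: exhaustive scan over the window's samples
    base <- mean(tr[t < 10])
    win <- which(t > 10 + 1e-9 & t <= 14 + 1e-9)
    expect_equal(amp, max(abs(tr[win] - base)))
    # adding a constant offset to the whole trace changes nothing
    expect_equal(as.numeric(peakAmplitude(tr + 3.7, t, 10)), amp)
  }
})

test_that("buildSpatialProfile normalizes to unit maximum", {
  rec <- makeRecording(c(-0.2, -0.8, -0.4))
  prof <- buildSpatialProfile(rec)
  expect_equal(amplitudes(prof), c(0.25, 1, 0.5))
  expect_true(isNormalized(prof))
  raw <- buildSpatialProfile(rec, normalize = FALSE)
  expect_equal(amplitudes(raw), c(0.2, 0.8, 0.4))

  same <- buildSpatialProfile(makeRecording(c(-0.3, -0.3, -0.3)))
  expect_true(all(amplitudes(same) == 1))

  expect_error(buildSpatialProfile(makeRecording(c(0, 0, 0))), "zero")
})

test_that("every normalized profile has maximum exactly 1.0", {
  for (s in 1:10) {
    rec <- simulateRecording(syntheticConfig(noise_sd = 0.1, seed = s))
    expect_identical(max(amplitudes(buildSpatialProfile(rec))), 1)
  }
})

test_that("peakLocation breaks ties toward the distal edge", {
  expect_equal(peakLocation(makeProfile(c(0.25, 1, 0.5))), 10)
  expect_equal(peakLocation(makeProfile(c(1, 1, 0.2))), 0)
  rec <- simulateRecording(syntheticConfig(noise_sd = 0, seed = 1L))
  expect_equal(peakLocation(buildSpatialProfile(rec)), 50)
})

test_that("averageProfiles aligns at the distal edge and truncates", {
  a <- makeProfile(c(1, 0))
  b <- makeProfile(c(0, 1))
  expect_equal(amplitudes(averageProfiles(list(a, b))), c(0.5, 0.5))
  expect_false(isNormalized(averageProfiles(list(a, b))))

  same <- averageProfiles(list(a, a))
  expect_equal(amplitudes(same), amplitudes(a))

  long <- makeProfile(c(0.5, 1, 0.25, 0.1))
  avg <- averageProfiles(list(a, long))
  expect_equal(length(amplitudes(avg)), 2)
  expect_equal(avg@n_contributing, 2L)

  raw <- makeProfile(c(2, 4), normalized = FALSE)
  expect_error(averageProfiles(list(a, raw)), "mix|normalized")
})

test_that("ten synthetic HB profiles average to a peak near the mean centre", {
  coh <- simulateCohort("control", 10, modalities = "HB", jitter_sd_um = 15,
                        noise_sd = 0.05, seed = 21L)
  avg <- averageProfiles(lapply(coh, buildSpatialProfile))
  expect_lt(abs(positions(avg)[which.max(amplitudes(avg))] - 100), 20)
})

test_that("overlapIndex: worked examples, symmetry, and bounds", {
  self <- makeProfile(c(0.5, 1, 0.5))
  expect_equal(overlapIndex(self, self), 2)
  expect_equal(overlapIndex(makeProfile(c(1, 0, 0)), makeProfile(c(0, 0, 1))), 0)
  a <- makeProfile(c(1, 0.4, 0))
  b <- makeProfile(c(0, 0.6, 1), modality = "HB")
  expect_equal(overlapIndex(a, b), 0.4)
  expect_equal(overlapIndex(a, b, weighted = TRUE), 4)

  set.seed(77)
  for (i in 1:25) {
    x <- stats::runif(15); x <- x / max(x)
    y <- stats::runif(15); y <- y / max(y)
    pa <- makeProfile(x); pb <- makeProfile(y)
    o <- overlapIndex(pa, pb)
    expect_identical(o, overlapIndex(pb, pa))
    expect_gte(o, 0)
    expect_lte(o, min(sum(x), sum(y)))
  }

  raw <- makeProfile(c(2, 4), normalized = FALSE)
  expect_error(overlapIndex(a, raw), "normalized")
})

test_that("overlap never decreases as two unimodal profiles move closer", {
  bump <- function(center) {
    x <- seq(0, 150, by = 10)
    v <- exp(-(x - center)^2 / (2 * 15^2))
    makeProfile(v / max(v))
  }
  seps <- seq(100, 0, by = -10)
  ov <- vapply(seps, function(s) overlapIndex(bump(25), bump(25 + s)),
               numeric(1))
  expect_true(all(diff(ov) >= 0))
})
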