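# forward model: determinism, ground-truth round trips, source-sink balance

test_that("identical config and seed give bit-identical recordings", {
  cfg <- syntheticConfig(noise_sd = 0.1, seed = 42L)
  r1 <- simulateRecording(cfg)
  r2 <- simulateRecording(cfg)
  expect_identical(potentials(r1), potentials(r2))
  r3 <- simulateRecording(syntheticConfig(noise_sd = 0.1, seed = 43L))
  expect_false(identical(potentials(r1), potentials(r3)))
})

test_that("noise-free sink round-trips through the stencil to its centre", {
  for (center in c(40, 50, 100, 110)) {
    cfg <- syntheticConfig(sink_center_um = center, noise_sd = 0, seed = 1L)
    rec <- simulateRecording(cfg)
    sink <- locateMajorSink(computeCSD(rec))
    expect_equal(sink@location_um, center)
    expect_equal(groundTruth(rec)$true_sink_center_um, center)
  }
  # off-grid centre localizes to an adjacent grid point
  rec85 <- simulateRecording(syntheticConfig(sink_center_um = 85,
                                             noise_sd = 0, seed = 1L))
  expect_lte(abs(locateMajorSink(computeCSD(rec85))@location_um - 85), 5)
})

test_that("balanced configs have interior second-difference sum ~ 0", {
  for (cfg in list(syntheticConfig(noise_sd = 0, seed = 1L),
                   syntheticConfig(modality = "HB", noise_sd = 0, seed = 1L),
                   conditionPreset("dcr", "HB", noise_sd = 0, seed = 1L),
                   conditionPreset("mk801_late", "HB", noise_sd = 0, seed = 1L))) {
    rec <- simulateRecording(cfg)
    for (n in 1:2) {
      csd <- computeCSD(rec, n = n)
      expect_lt(max(abs(rowSums(csdValues(csd)))),
                1e-9 * max(abs(csdValues(csd))))
    }
  }
})

test_that("recurrent sink co-localizes with the primary sink", {
  rec <- simulateRecording(syntheticConfig(sink_center_um = 85, noise_sd = 0,
                                           seed = 1L))
  csd <- computeCSD(rec)
  primary <- locateMajorSink(csd, "monosynaptic")
  secondary <- locateMajorSink(csd, "recurrent")
  expect_equal(secondary@location_um, primary@location_um)
  expect_identical(secondary@kind, "secondary")
  expect_gt(secondary@time_ms, primary@time_ms)
})

test_that("invalid configs are rejected with descriptive errors", {
  expect_error(syntheticConfig(sink_width_um = -1), "width")
  expect_error(syntheticConfig(trace_duration_ms = 0), "duration")
  expect_error(syntheticConfig(stim_time_ms = 60), "stim")
  expect_error(syntheticConfig(axis_length_um = 155), "multiple")
  expect_error(syntheticConfig(sink_center_um = 10, source_balance = TRUE),
               "compact-support margin")
})

test_that("cohort: zero jitter pins all centres to the mean; seeds differ", {
  coh <- simulateCohort("control", 10, modalities = "HB", jitter_sd_um = 0,
                        seed = 5L)
  centers <- vapply(coh, function(r) groundTruth(r)$true_sink_center_um,
                    numeric(1))
  expect_true(all(centers == 100))
  coh2 <- simulateCohort("control", 2, modalities = "RGC", seed = 5L)
  expect_false(identical(potentials(coh2[[1]]), potentials(coh2[[2]])))
  expect_error(simulateCohort("control", 3, modalities = character(0)),
               "non-empty")
})

test_that("cohort-level mean peak locations recover the generator means", {
  coh <- simulateCohort("control", 20, modalities = c("RGC", "HB"),
                        jitter_sd_um = 15, noise_sd = 0.05, seed = 11L)
  peaks <- vapply(coh, function(r) peakLocation(buildSpatialProfile(r)),
                  numeric(1))
  mods <- vapply(coh, modality, character(1))
  expect_lt(abs(mean(peaks[mods == "RGC"]) - 50), 10)
  expect_lt(abs(mean(peaks[mods == "HB"]) - 100), 10)
})

test_that("localization error degrades monotonically with noise", {
  err_at <- function(noise_sd) {
    errs <- vapply(1:30, function(s) {
      rec <- simulateRecording(syntheticConfig(noise_sd = noise_sd,
                                               seed = s))
      abs(locateMajorSink(computeCSD(rec))@location_um - 50)
    }, numeric(1))
    mean(errs)
  }
  errs <- vapply(c(0, 0.1, 0.5, 1.5), err_at, numeric(1))
  expect_true(all(diff(errs) >= 0))
})

test_that("fluorescence pairs: determinism, grids, flat and peaked cases", {
  p1 <- simulateFluorescencePair(c(50, 100), seed = 9L)
  p2 <- simulateFluorescencePair(c(50, 100), seed = 9L)
  expect_identical(grayValues(p1$RGC), grayValues(p2$RGC))
  expect_identical(positions(p1$RGC), positions(p1$HB))

  # noise-free channel peaks at the grid point nearest its centre
  p <- simulateFluorescencePair(c(88.6, 100), noise_sd = 0, seed = 1L)
  expect_equal(peakLocation(p$RGC), 90)

  # zero-amplitude channels are flat baseline
  p0 <- simulateFluorescencePair(c(50, 100), amplitudes = c(0, 0),
                                 noise_sd = 0, seed = 1L)
  expect_true(all(grayValues(p0$RGC) == 20))
  expect_error(simulateFluorescencePair(c(50, 100), amplitudes = c(250, 250)),
               "255")
})
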