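# discrete second-difference stencil and sink localization

test_that("stencil is zero on spatially linear potentials", {
  t <- seq(0, 5, by = 0.1)
  x <- seq(0, 150, by = 10)
  v <- outer(1 + 0.2 * t, 3 * x - 7)  # linear in x at every t
  rec <- new("FPRecording", potentials = v, time_ms = t, positions_um = x,
             stim_time_ms = 1, modality = "RGC", tectum_id = "lin",
             condition = "control", seed = NULL, truth = list())
  for (n in 1:3)
    expect_equal(max(abs(csdValues(computeCSD(rec, n = n)))), 0)
})

test_that("stencil is exact on quadratics for every admissible n", {
  t <- seq(0, 2, by = 0.1)
  x <- seq(0, 150, by = 10)
  v <- matrix(rep(x^2, each = length(t)), nrow = length(t))
  rec <- new("FPRecording", potentials = v, time_ms = t, positions_um = x,
             stim_time_ms = 1, modality = "RGC", tectum_id = "quad",
             condition = "control", seed = NULL, truth = list())
  for (n in 1:5) {
    csd <- computeCSD(rec, n = n)
    expect_equal(unname(csdValues(csd)),
                 matrix(2, nrow(csdValues(csd)), ncol(csdValues(csd))))
    expect_equal(diffGrid(csd), n * 10)
  }
})

test_that("stencil matches a brute-force per-point oracle on random data", {
  set.seed(402)
  for (i in 1:10) {
    v <- matrix(stats::rnorm(35), nrow = 5, ncol = 7)
    rec <- new("FPRecording", potentials = v, time_ms = 1:5,
               positions_um = seq(0, 60, by = 10), stim_time_ms = 2,
               modality = "HB", tectum_id = "rand", condition = "control",
               seed = NULL, truth = list())
    for (n in 1:2)
      expect_equal(unname(csdValues(computeCSD(rec, n = n))),
                   bruteForceCSD(v, 10, n))
  }
})

test_that("computeCSD is linear in its input", {
  set.seed(403)
  t <- 1:4
  x <- seq(0, 70, by = 10)
  mk <- function(v) new("FPRecording", potentials = v, time_ms = t,
                        positions_um = x, stim_time_ms = 2, modality = "RGC",
                        tectum_id = "l", condition = "control", seed = NULL,
                        truth = list())
  v1 <- matrix(stats::rnorm(32), 4); v2 <- matrix(stats::rnorm(32), 4)
  lhs <- csdValues(computeCSD(mk(2 * v1 - 5 * v2)))
  rhs <- 2 * csdValues(computeCSD(mk(v1))) - 5 * csdValues(computeCSD(mk(v2)))
  expect_equal(lhs, rhs)
})

test_that("too few positions are rejected naming the minimum", {
  rec <- makeRecording(c(-1, -2, -3))
  expect_error(computeCSD(rec, n = 2), "at least 5 positions")
  expect_silent(computeCSD(rec, n = 1))
})

test_that("interior positions exclude the first and last n grid points", {
  rec <- simulateRecording(syntheticConfig(noise_sd = 0, seed = 1L))
  csd <- computeCSD(rec, n = 2)
  expect_equal(positions(csd), seq(20, 130, by = 10))
})

test_that("locateMajorSink finds the noise-free ground truth exactly", {
  for (center in c(50, 85, 100)) {
    rec <- simulateRecording(syntheticConfig(sink_center_um = center,
                                             noise_sd = 0, seed = 1L))
    sink <- locateMajorSink(computeCSD(rec))
    # exact for grid-aligned centres, nearest grid point otherwise
    expect_lte(abs(sink@location_um - center), 5)
    expect_identical(sink@kind, "primary")
    expect_identical(sink@polarity, "sink")
    # peak CSD occurs within the monosynaptic window
    expect_lte(sink@time_ms, stimTime(rec) + 4)
  }
})

test_that("sink-polarity flag flips which sign is detected", {
  rec <- simulateRecording(syntheticConfig(noise_sd = 0, seed = 1L))
  pos <- locateMajorSink(computeCSD(rec, sink_polarity = "positive"))
  neg <- locateMajorSink(computeCSD(rec, sink_polarity = "negative"))
  expect_equal(pos@location_um, 50)   # the sink has positive curvature
  expect_false(neg@location_um == 50) # flipped polarity finds the sources
})

test_that("tie-breaking is distal-most, then earliest", {
  t <- 1:5
  x <- seq(0, 60, by = 10)
  v <- matrix(0, 5, 7)
  # two equal-magnitude sinks (positive second difference at 20 and 40 um)
  v[3, 3] <- -1; v[5, 5] <- -1
  rec <- new("FPRecording", potentials = v, time_ms = t, positions_um = x,
             stim_time_ms = 2, modality = "RGC", tectum_id = "tie",
             condition = "control", seed = NULL, truth = list())
  sink <- locateMajorSink(computeCSD(rec, n = 1), "full")
  expect_equal(sink@location_um, 20)
  expect_equal(sink@time_ms, 3)
})

test_that("image plots are written for normal, all-zero, and flipped maps", {
  rec <- simulateRecording(syntheticConfig(noise_sd = 0, seed = 1L))
  csd <- computeCSD(rec)
  f <- withr::local_tempfile(fileext = ".pdf")
  plotCSDMap(csd, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)

  zero <- csd
  zero@values[] <- 0
  f2 <- withr::local_tempfile(fileext = ".pdf")
  plotCSDMap(zero, file = f2)
  expect_true(file.exists(f2))

  flipped <- computeCSD(rec, sink_polarity = "negative")
  f3 <- withr::local_tempfile(fileext = ".pdf")
  plotCSDMap(flipped, file = f3)
  expect_true(file.exists(f3))

  expect_error(plotCSDMap(csd, file = file.path(tempdir(), "x.bmp")),
               "unsupported")
})
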