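# axon-label line profile quantification

test_that("normalizeFluorescence: worked example and idempotence", {
  p <- makeFluor(c(10, 110, 60))
  n1 <- normalizeFluorescence(p, "min_subtract")
  expect_equal(grayValues(n1), c(0, 1, 0.5))
  expect_true(isNormalized(n1))
  # re-normalizing changes nothing
  expect_equal(grayValues(normalizeFluorescence(n1, "min_subtract")),
               grayValues(n1))
  # raw-scaled variant keeps the baseline
  n2 <- normalizeFluorescence(p, "none")
  expect_equal(grayValues(n2), c(10, 110, 60) / 110)

  expect_error(normalizeFluorescence(makeFluor(c(7, 7, 7))), "constant")
})

test_that("normalization preserves the argmax of synthetic Gaussians", {
  for (s in 1:5) {
    pair <- simulateFluorescencePair(c(60, 110), noise_sd = 4, seed = s)
    for (ch in pair)
      expect_equal(peakLocation(normalizeFluorescence(ch)), peakLocation(ch))
  }
})

test_that("peakLocation: nearest grid point, ties distal, spikes", {
  expect_equal(peakLocation(makeFluor(c(0, 1, 0.5))), 10)
  p <- simulateFluorescencePair(c(65.8, 120), noise_sd = 0, seed = 1L)
  expect_equal(peakLocation(p$RGC), 70)
  spike <- makeFluor(c(5, 5, 200, 5, 5))
  expect_equal(peakLocation(spike), 20)
  expect_equal(peakLocation(makeFluor(c(9, 9, 9, 3))), 0)  # tie -> distal
})

test_that("peakSeparation: worked examples and grid checks", {
  pair <- simulateFluorescencePair(c(40, 90), noise_sd = 0, seed = 1L)
  expect_equal(peakSeparation(pair$RGC, pair$HB), 50)
  expect_equal(peakSeparation(pair$RGC, pair$RGC), 0)
  other <- makeFluor(c(1, 2, 3), dx = 5)
  expect_error(peakSeparation(pair$RGC, other), "grids")
})

test_that("peak separation is recovered under realistic noise", {
  seps <- vapply(1:100, function(s) {
    pair <- simulateFluorescencePair(c(50, 100), noise_sd = 5, seed = s)
    peakSeparation(pair$RGC, pair$HB)
  }, numeric(1))
  expect_lt(abs(mean(seps) - 50), 10)
})

test_that("axonOverlapArea: oracle examples, symmetry, bounds", {
  # widened triangles meeting at 20 um: min-sum is 0.5, times dx = 5.0
  a <- makeFluor(c(0, 1, 0.5, 0, 0), normalized = TRUE)
  b <- makeFluor(c(0, 0, 0.5, 1, 0), normalized = TRUE)
  expect_equal(axonOverlapArea(a, b), 5)

  disj <- makeFluor(c(1, 0, 0, 0, 0), normalized = TRUE)
  disj2 <- makeFluor(c(0, 0, 0, 0, 1), normalized = TRUE)
  expect_equal(axonOverlapArea(disj, disj2), 0)

  expect_equal(axonOverlapArea(a, a), sum(grayValues(a)) * 10)

  set.seed(55)
  for (i in 1:20) {
    x <- stats::runif(16); x <- x / max(x)
    y <- stats::runif(16); y <- y / max(y)
    pa <- makeFluor(x, normalized = TRUE); pb <- makeFluor(y, normalized = TRUE)
    o <- axonOverlapArea(pa, pb)
    expect_identical(o, axonOverlapArea(pb, pa))
    expect_gte(o, 0)
    expect_lte(o, min(sum(x), sum(y)) * 10)
  }

  raw <- makeFluor(c(10, 200, 10))
  expect_error(axonOverlapArea(raw, raw), "normalized")
})

test_that("overlap area never increases as channel centres move apart", {
  areas <- vapply(seq(0, 100, by = 10), function(gap) {
    pair <- simulateFluorescencePair(c(40, 40 + gap), noise_sd = 0, seed = 1L)
    axonOverlapArea(normalizeFluorescence(pair$RGC),
                    normalizeFluorescence(pair$HB))
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("8-bit quantization moves the peak by at most one grid step", {
  # SNR >= 10: amplitude 180 gray values, noise SD <= 18
  for (s in 1:25) {
    pair <- simulateFluorescencePair(c(60, 100), amplitudes = c(180, 180),
                                     noise_sd = 15, seed = s)
    expect_lte(abs(peakLocation(pair$RGC) - 60), 10)
    expect_lte(abs(peakLocation(pair$HB) - 100), 10)
  }
})
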