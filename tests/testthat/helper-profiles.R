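# shared fixture builders (all in code; no stored data)

makeProfile <- function(amplitudes, dx = 10, normalized = max(amplitudes) == 1,
                        modality = "RGC", condition = "control", id = "t1") {
  new("SpatialProfile",
      positions_um = seq(0, by = dx, length.out = length(amplitudes)),
      amplitudes = amplitudes, normalized = normalized, n_contributing = 1L,
      modality = modality, condition = condition, tectum_id = id)
}

makeFluor <- function(intensity, dx = 10, channel = "RGC",
                      normalized = all(intensity <= 1), id = "s1") {
  new("FluorescenceProfile",
      positions_um = seq(0, by = dx, length.out = length(intensity)),
      intensity = intensity, channel = channel, normalized = normalized,
      specimen_id = id)
}

# a minimal recording whose per-position monosynaptic deflections are given:
# flat baseline 0, one rectangular deflection at 2 ms post-stimulus
makeRecording <- function(deflections, stim = 10, duration = 20, dx = 10,
                          modality = "RGC") {
  t <- seq(0, duration - 0.1, by = 0.1)
  v <- vapply(deflections, function(d)
    ifelse(t > stim + 1.5 & t < stim + 2.5, d, 0), numeric(length(t)))
  new("FPRecording", potentials = v, time_ms = t,
      positions_um = seq(0, by = dx, length.out = length(deflections)),
      stim_time_ms = stim, modality = modality, tectum_id = "fix",
      condition = "control", seed = NULL, truth = list())
}

# independent brute-force stencil oracle: per-point loop, no vectorization
bruteForceCSD <- function(v, dx, n) {
  P <- ncol(v)
  out <- matrix(NA_real_, nrow(v), P - 2 * n)
  for (ti in seq_len(nrow(v)))
    for (j in (n + 1):(P - n))
      out[ti, j - n] <- (v[ti, j + n] + v[ti, j - n] - 2 * v[ti, j]) / (n * dx)^2
  out
}
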