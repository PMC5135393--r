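# Peak field-potential quantification and spatial profiles.

#' Peak field-potential amplitude within the monosynaptic window
#'
#' The peak deflection is the largest absolute deviation of the trace from
#' its pre-stimulus baseline within the monosynaptic window, the half-open
#' interval (stim, stim + `window_ms`] (the sample at the stimulus time is
#' excluded so stimulus artifacts do not contaminate the measurement). The
#' baseline is the mean of all pre-stimulus samples. The sign of the
#' extremal deflection is attached as attribute `"sign"`.
#'
#' @param trace numeric vector, one voltage trace.
#' @param time_ms numeric vector of sample times (ms), same length.
#' @param stim_time_ms stimulus time (ms).
#' @param window_ms monosynaptic window length (ms); default 4, within which
#'   the direct (monosynaptic) response is known to occur.
#' @return Non-negative amplitude in recording units, with attribute
#'   `"sign"` (+1 or -1) giving the direction of the extremal deflection.
#' @examples
#' t <- seq(0, 20, by = 0.1)
#' tr <- ifelse(t > 11 & t < 13, -0.8, 0)
#' peakAmplitude(tr, t, stim_time_ms = 10)
#' @export
peakAmplitude <- function(trace, time_ms, stim_time_ms, window_ms = 4) {
  stopifnot(length(trace) == length(time_ms))
  pre <- time_ms < stim_time_ms
  if (!any(pre)) stop("no pre-stimulus samples available for the baseline")
  tol <- 1e-9
  if (stim_time_ms + window_ms > max(time_ms) + tol)
    stop("monosynaptic window extends beyond the end of the trace")
  baseline <- mean(trace[pre])
  win <- time_ms > stim_time_ms + tol & time_ms <= stim_time_ms + window_ms + tol
  dev <- trace[win] - baseline
  i <- which.max(abs(dev))
  amp <- abs(dev[i])
  attr(amp, "sign") <- if (amp == 0) 1 else sign(dev[i])
  amp
}

#' Build the spatial profile of peak amplitudes along the laminar axis
#'
#' Computes one [peakAmplitude()] per recording position and, by default,
#' normalizes the profile so that the largest amplitude of the tectum is
#' exactly 1.0 (the per-tectum normalization that makes profiles averageable
#' across tecta).
#'
#' @param recording an [FPRecording-class].
#' @param normalize logical; default TRUE.
#' @param window_ms monosynaptic window (ms); default 4.
#' @return A [SpatialProfile-class].
#' @examples
#' rec <- simulateRecording(syntheticConfig(noise_sd = 0, seed = 1L))
#' prof <- buildSpatialProfile(rec)
#' max(amplitudes(prof))  # 1.0 by construction
#' @export
buildSpatialProfile <- function(recording, normalize = TRUE, window_ms = 4) {
  stopifnot(is(recording, "FPRecording"))
  amps <- apply(recording@potentials, 2, peakAmplitude,
                time_ms = recording@time_ms,
                stim_time_ms = recording@stim_time_ms,
                window_ms = window_ms)
  amps <- as.numeric(amps)
  if (normalize) {
    m <- max(amps)
    if (m == 0)
      stop("all peak amplitudes are zero; normalization is undefined")
    amps <- amps / m
  }
  new("SpatialProfile", positions_um = recording@positions_um,
      amplitudes = amps, normalized = isTRUE(normalize),
      n_contributing = 1L, modality = recording@modality,
      condition = recording@condition, tectum_id = recording@tectum_id)
}

#' @rdname peakLocation
#' @export
setGeneric("peakLocation", function(x) standardGeneric("peakLocation"))

#' Position of the peak response
#'
#' Returns the distance from the distal edge (um) at which the maximum
#' amplitude (for a [SpatialProfile-class]) or the peak pixel intensity
#' (for a [FluorescenceProfile-class]) occurs. Ties are broken toward the
#' distal edge (the smallest position), keeping the measurement
#' deterministic in the distal-edge reference frame.
#'
#' @param x a [SpatialProfile-class] or [FluorescenceProfile-class].
#' @return Position in um from the distal edge.
#' @examples
#' p <- new("SpatialProfile", positions_um = c(0, 10, 20),
#'          amplitudes = c(0.25, 1, 0.5), normalized = TRUE,
#'          n_contributing = 1L, modality = "RGC", condition = "control",
#'          tectum_id = "t1")
#' peakLocation(p)  # 10
#' @name peakLocation
NULL

#' @rdname peakLocation
#' @export
setMethod("peakLocation", "SpatialProfile", function(x) {
  x@positions_um[which.max(x@amplitudes)]
})

#' @rdname peakLocation
#' @export
setMethod("peakLocation", "FluorescenceProfile", function(x) {
  x@positions_um[which.max(x@intensity)]
})

#' Average normalized spatial profiles across tecta
#'
#' Pointwise mean of normalized spatial profiles, aligned at the distal edge
#' (position 0) and truncated to the extent common to all profiles. The
#' result is flagged as not re-normalized (its maximum is typically < 1)
#' and carries `n_contributing`.
#'
#' @param profiles list of normalized [SpatialProfile-class] objects sharing
#'   the grid spacing and origin.
#' @return A [SpatialProfile-class] with `normalized = FALSE`.
#' @examples
#' a <- new("SpatialProfile", positions_um = c(0, 10), amplitudes = c(1, 0),
#'          normalized = TRUE, n_contributing = 1L, modality = "RGC",
#'          condition = "control", tectum_id = "a")
#' b <- new("SpatialProfile", positions_um = c(0, 10), amplitudes = c(0, 1),
#'          normalized = TRUE, n_contributing = 1L, modality = "RGC",
#'          condition = "control", tectum_id = "b")
#' amplitudes(averageProfiles(list(a, b)))  # 0.5 0.5
#' @export
averageProfiles <- function(profiles) {
  if (length(profiles) == 0) stop("no profiles to average")
  stopifnot(all(vapply(profiles, is, logical(1), "SpatialProfile")))
  norm <- vapply(profiles, function(p) isTRUE(p@normalized), logical(1))
  if (!all(norm)) {
    if (any(norm)) stop("cannot average a mix of normalized and raw profiles")
    stop("profiles must be normalized before averaging")
  }
  dx <- vapply(profiles, gridSpacing, numeric(1))
  if (max(abs(dx - dx[1])) > 1e-9)
    stop("profiles must share the same grid spacing")
  if (any(vapply(profiles, function(p) p@positions_um[1], numeric(1)) != 0))
    stop("profiles must be aligned at the distal edge (position 0)")
  len <- min(vapply(profiles, function(p) length(p@positions_um), integer(1)))
  amp <- rowMeans(vapply(profiles, function(p) p@amplitudes[seq_len(len)],
                         numeric(len)))
  p1 <- profiles[[1]]
  new("SpatialProfile", positions_um = p1@positions_um[seq_len(len)],
      amplitudes = amp, normalized = FALSE,
      n_contributing = length(profiles),
      modality = p1@modality, condition = p1@condition, tectum_id = "average")
}

#' Overlap index between two normalized spatial profiles
#'
#' Quantifies the spatial overlap between two afferent inputs by summing,
#' over the laminar positions common to both profiles, the portion of the
#' normalized field-potential amplitude shared by both: \eqn{\sum_x
#' \min(a(x), b(x))}. The index is symmetric, zero for disjoint supports,
#' and bounded above by the smaller profile sum. With `weighted = TRUE` the
#' sum is multiplied by the grid spacing dx (um), giving an area in
#' normalized-amplitude x um instead of a unitless sum.
#'
#' @param profile_a,profile_b normalized [SpatialProfile-class] objects on
#'   the same grid (aligned at the distal edge; truncated to the common
#'   extent).
#' @param weighted logical; default FALSE (plain sum over grid points,
#'   which reproduces the magnitude range of indices on ~15-point profiles).
#' @return Dimensionless overlap index (or amplitude-um when weighted).
#' @examples
#' a <- new("SpatialProfile", positions_um = c(0, 10, 20),
#'          amplitudes = c(1, 0.4, 0), normalized = TRUE,
#'          n_contributing = 1L, modality = "RGC", condition = "control",
#'          tectum_id = "a")
#' b <- new("SpatialProfile", positions_um = c(0, 10, 20),
#'          amplitudes = c(0, 0.6, 1), normalized = TRUE,
#'          n_contributing = 1L, modality = "HB", condition = "control",
#'          tectum_id = "b")
#' overlapIndex(a, b)  # 0.4
#' @export
overlapIndex <- function(profile_a, profile_b, weighted = FALSE) {
  stopifnot(is(profile_a, "SpatialProfile"), is(profile_b, "SpatialProfile"))
  if (!isTRUE(profile_a@normalized) || !isTRUE(profile_b@normalized))
    stop("both profiles must be normalized")
  dxa <- gridSpacing(profile_a)
  if (abs(dxa - gridSpacing(profile_b)) > 1e-9)
    stop("profiles have mismatched grid spacing")
  if (profile_a@positions_um[1] != 0 || profile_b@positions_um[1] != 0)
    stop("profiles must be aligned at the distal edge (position 0)")
  len <- min(length(profile_a@amplitudes), length(profile_b@amplitudes))
  s <- sum(pmin(profile_a@amplitudes[seq_len(len)],
                profile_b@amplitudes[seq_len(len)]))
  if (weighted) s * dxa else s
}
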