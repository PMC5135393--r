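# Accessor generics and methods, plus show() methods.

#' @rdname accessors
#' @export
setGeneric("potentials", function(x) standardGeneric("potentials"))
#' @rdname accessors
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("stimTime", function(x) standardGeneric("stimTime"))
#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))
#' @rdname accessors
#' @export
setGeneric("tectumId", function(x) standardGeneric("tectumId"))
#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("csdValues", function(x) standardGeneric("csdValues"))
#' @rdname accessors
#' @export
setGeneric("diffGrid", function(x) standardGeneric("diffGrid"))
#' @rdname accessors
#' @export
setGeneric("grayValues", function(x) standardGeneric("grayValues"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Accessors for tectalamina objects
#'
#' Small accessor functions for the S4 containers: `potentials()` returns the
#' time x position matrix of an [FPRecording-class]; `timeAxis()`,
#' `positions()`, `stimTime()`, `modality()`, `conditionLabel()`,
#' `tectumId()` return the corresponding metadata; `gridSpacing()` the
#' spatial grid step dx (um); `amplitudes()` and `isNormalized()` apply to
#' [SpatialProfile-class]; `csdValues()` and `diffGrid()` (the n*dx
#' differentiation grid, um) to [CSDMap-class]; `grayValues()` to
#' [FluorescenceProfile-class]; `groundTruth()` returns the simulation
#' ground-truth list of an [FPRecording-class] (empty for imported data).
#'
#' @param x one of the package's S4 objects.
#' @return The slot value; see details above.
#' @name accessors
#' @aliases potentials timeAxis positions stimTime modality conditionLabel
#'   tectumId gridSpacing amplitudes isNormalized csdValues diffGrid
#'   grayValues groundTruth
#' @examples
#' rec <- simulateRecording(syntheticConfig(seed = 1L))
#' dim(potentials(rec))
#' gridSpacing(rec)
#' groundTruth(rec)$true_sink_center_um
NULL

#' @rdname accessors
#' @export
setMethod("potentials", "FPRecording", function(x) x@potentials)
#' @rdname accessors
#' @export
setMethod("timeAxis", "FPRecording", function(x) x@time_ms)
#' @rdname accessors
#' @export
setMethod("timeAxis", "CSDMap", function(x) x@time_ms)
#' @rdname accessors
#' @export
setMethod("positions", "FPRecording", function(x) x@positions_um)
#' @rdname accessors
#' @export
setMethod("positions", "SpatialProfile", function(x) x@positions_um)
#' @rdname accessors
#' @export
setMethod("positions", "CSDMap", function(x) x@positions_um)
#' @rdname accessors
#' @export
setMethod("positions", "FluorescenceProfile", function(x) x@positions_um)
#' @rdname accessors
#' @export
setMethod("stimTime", "FPRecording", function(x) x@stim_time_ms)
#' @rdname accessors
#' @export
setMethod("stimTime", "CSDMap", function(x) x@stim_time_ms)
#' @rdname accessors
#' @export
setMethod("modality", "FPRecording", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("modality", "SpatialProfile", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("modality", "CSDMap", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("conditionLabel", "FPRecording", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("conditionLabel", "SpatialProfile", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("conditionLabel", "CSDMap", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("tectumId", "FPRecording", function(x) x@tectum_id)
#' @rdname accessors
#' @export
setMethod("gridSpacing", "FPRecording", function(x) {
  if (length(x@positions_um) < 2) stop("recording has fewer than 2 positions")
  x@positions_um[2] - x@positions_um[1]
})
#' @rdname accessors
#' @export
setMethod("gridSpacing", "SpatialProfile", function(x) {
  if (length(x@positions_um) < 2) stop("profile has fewer than 2 positions")
  x@positions_um[2] - x@positions_um[1]
})
#' @rdname accessors
#' @export
setMethod("gridSpacing", "CSDMap", function(x) x@dx_um)
#' @rdname accessors
#' @export
setMethod("gridSpacing", "FluorescenceProfile", function(x) {
  if (length(x@positions_um) < 2) stop("profile has fewer than 2 positions")
  x@positions_um[2] - x@positions_um[1]
})
#' @rdname accessors
#' @export
setMethod("amplitudes", "SpatialProfile", function(x) x@amplitudes)
#' @rdname accessors
#' @export
setMethod("isNormalized", "SpatialProfile", function(x) x@normalized)
#' @rdname accessors
#' @export
setMethod("isNormalized", "FluorescenceProfile", function(x) x@normalized)
#' @rdname accessors
#' @export
setMethod("csdValues", "CSDMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("diffGrid", "CSDMap", function(x) x@n * x@dx_um)
#' @rdname accessors
#' @export
setMethod("grayValues", "FluorescenceProfile", function(x) x@intensity)
#' @rdname accessors
#' @export
setMethod("groundTruth", "FPRecording", function(x) x@truth)

setMethod("show", "FPRecording", function(object) {
  cat(sprintf(
    "FPRecording: %s-evoked, tectum '%s' (%s)\n  %d samples x %d positions (0-%g um, dx = %g um), stim at %g ms\n",
    object@modality, object@tectum_id, object@condition,
    nrow(object@potentials), ncol(object@potentials),
    max(object@positions_um), gridSpacing(object), object@stim_time_ms))
  if (length(object@truth))
    cat(sprintf("  ground-truth sink at %g um\n",
                object@truth$true_sink_center_um))
})

setMethod("show", "SpatialProfile", function(object) {
  cat(sprintf(
    "SpatialProfile: %s (%s), %d positions (0-%g um)%s, n = %d tecta\n",
    object@modality, object@condition, length(object@positions_um),
    max(object@positions_um),
    if (object@normalized) ", normalized (max = 1.0)" else ", raw units",
    object@n_contributing))
})

setMethod("show", "CSDMap", function(object) {
  cat(sprintf(
    "CSDMap: %s (%s), %d samples x %d interior positions (%g-%g um)\n  differentiation grid %g um (n = %d, dx = %g um), sink polarity: %s\n",
    object@modality, object@condition, nrow(object@values),
    ncol(object@values), min(object@positions_um), max(object@positions_um),
    diffGrid(object), object@n, object@dx_um, object@sink_polarity))
})

setMethod("show", "SinkSource", function(object) {
  cat(sprintf("%s %s at %g um from the distal edge, t = %g ms (|CSD| = %.3g)\n",
              object@kind, object@polarity, object@location_um,
              object@time_ms, object@magnitude))
})

setMethod("show", "FluorescenceProfile", function(object) {
  cat(sprintf(
    "FluorescenceProfile: %s channel, specimen '%s', %d positions (0-%g um)%s\n",
    object@channel, object@specimen_id, length(object@positions_um),
    max(object@positions_um),
    if (object@normalized) ", normalized" else ", 8-bit gray values"))
})

setMethod("show", "GroupSummary", function(object) {
  cat(sprintf(
    "%s: mean %.4g +/- %.3g (SEM), n = %d; %g%% CI [%.4g, %.4g] (%s)\n",
    if (nzchar(object@label)) object@label else "group",
    object@mean, object@sem, object@n, 100 * object@level,
    object@ci_low, object@ci_high, object@ci_method))
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf(
    "%s: statistic = %.4g, p = %.4g (n = %d vs %d; Shapiro p = %.3g / %.3g)\n",
    object@test_used, object@statistic, object@p_value,
    object@n_a, object@n_b, object@normality_p_a, object@normality_p_b))
})
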