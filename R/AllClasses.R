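#' @import methods
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' FPRecording: evoked field potentials along the laminar axis
#'
#' A time x laminar-position matrix of evoked extracellular field potentials
#' for one tectum and one stimulated afferent modality. Positions are
#' distances in micrometres from the distal edge of the neuropil (the origin
#' of all spatial measurements), on a uniform grid; time is in milliseconds.
#'
#' @slot potentials numeric matrix, rows = time samples, columns = positions.
#' @slot time_ms numeric vector of sample times (ms), strictly increasing.
#' @slot positions_um numeric vector of recording positions (um from the
#'   distal edge), starting at 0, uniformly spaced.
#' @slot stim_time_ms stimulus time (ms), inside the time axis.
#' @slot modality `"RGC"` (retinal) or `"HB"` (hindbrain/mechanosensory).
#' @slot tectum_id character label for the tectum.
#' @slot condition character label (e.g. `"control"`, `"dcr"`).
#' @slot seed integer seed used to simulate the recording, or NULL for
#'   imported data.
#' @slot truth list of simulation ground truth (empty for imported data):
#'   `true_sink_center_um`, `true_sink_onset_ms`, `true_secondary_center_um`,
#'   `condition`.
#'
#' @seealso [simulateRecording()], [buildSpatialProfile()], [computeCSD()]
#' @export
setClass("FPRecording",
  representation(
    potentials = "matrix",
    time_ms = "numeric",
    positions_um = "numeric",
    stim_time_ms = "numeric",
    modality = "character",
    tectum_id = "character",
    condition = "character",
    seed = "integerOrNULL",
    truth = "list"
  )
)

setValidity("FPRecording", function(object) {
  msg <- character()
  p <- object@potentials
  if (!is.numeric(p)) msg <- c(msg, "'potentials' must be a numeric matrix")
  if (nrow(p) != length(object@time_ms))
    msg <- c(msg, "nrow(potentials) must equal length(time_ms)")
  if (ncol(p) != length(object@positions_um))
    msg <- c(msg, "ncol(potentials) must equal length(positions_um)")
  if (length(object@positions_um) >= 1 && object@positions_um[1] != 0)
    msg <- c(msg, "positions_um must start at 0 (the distal edge)")
  if (length(object@positions_um) >= 2) {
    d <- diff(object@positions_um)
    if (any(d <= 0)) msg <- c(msg, "positions_um must be strictly increasing")
    if (max(abs(d - d[1])) > 1e-8 * max(d))
      msg <- c(msg, "positions_um must be uniformly spaced")
  }
  if (length(object@time_ms) >= 2 && any(diff(object@time_ms) <= 0))
    msg <- c(msg, "time_ms must be strictly increasing")
  if (length(object@stim_time_ms) != 1 ||
      object@stim_time_ms < min(object@time_ms) ||
      object@stim_time_ms > max(object@time_ms))
    msg <- c(msg, "stim_time_ms must lie within the time axis")
  if (!object@modality %in% c("RGC", "HB"))
    msg <- c(msg, "modality must be 'RGC' or 'HB'")
  if (length(msg)) msg else TRUE
})

#' SpatialProfile: peak response amplitude along the laminar axis
#'
#' Per-position peak field-potential amplitudes, either raw (recording
#' units) or normalized so the largest amplitude of the tectum equals 1.0.
#'
#' @slot positions_um positions (um from the distal edge), uniform grid.
#' @slot amplitudes non-negative amplitudes, one per position.
#' @slot normalized logical; if TRUE the maximum is exactly 1.
#' @slot n_contributing number of tecta contributing (1 for a single tectum,
#'   >1 for a cross-tectum average).
#' @slot modality,condition,tectum_id character labels.
#' @seealso [buildSpatialProfile()], [averageProfiles()], [overlapIndex()]
#' @export
setClass("SpatialProfile",
  representation(
    positions_um = "numeric",
    amplitudes = "numeric",
    normalized = "logical",
    n_contributing = "integer",
    modality = "character",
    condition = "character",
    tectum_id = "character"
  )
)

setValidity("SpatialProfile", function(object) {
  msg <- character()
  if (length(object@positions_um) != length(object@amplitudes))
    msg <- c(msg, "positions_um and amplitudes must have equal length")
  if (length(object@amplitudes) == 0) msg <- c(msg, "profile must be non-empty")
  if (length(object@positions_um) >= 2) {
    d <- diff(object@positions_um)
    if (any(d <= 0)) msg <- c(msg, "positions_um must be strictly increasing")
    if (max(abs(d - d[1])) > 1e-8 * max(d))
      msg <- c(msg, "positions_um must be uniformly spaced")
  }
  if (any(object@amplitudes < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (isTRUE(object@normalized)) {
    if (max(object@amplitudes) != 1)
      msg <- c(msg, "normalized profile must have maximum exactly 1.0")
    if (any(object@amplitudes > 1))
      msg <- c(msg, "normalized amplitudes must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' CSDMap: discrete second spatial derivative of a field-potential recording
#'
#' Current-source-density estimates at interior laminar positions, obtained
#' from the three-point second-difference stencil with differentiation grid
#' `n * dx_um` micrometres. Units are potential per um^2 in arbitrary units
#' (no conductivity scaling). The `sink_polarity` flag records which sign is
#' interpreted as a current sink.
#'
#' @slot values numeric matrix, rows = time samples, columns = interior
#'   positions.
#' @slot time_ms numeric vector of sample times (ms).
#' @slot positions_um interior positions (um): the recording grid minus the
#'   first and last `n` points.
#' @slot n integer stencil step count; the differentiation grid is `n * dx_um`.
#' @slot dx_um recording grid spacing (um).
#' @slot stim_time_ms stimulus time (ms).
#' @slot sink_polarity `"positive"` (default: sinks are positive second
#'   derivatives) or `"negative"`.
#' @slot modality,condition,tectum_id character labels carried over from the
#'   recording.
#' @seealso [computeCSD()], [locateMajorSink()], [plotCSDMap()]
#' @export
setClass("CSDMap",
  representation(
    values = "matrix",
    time_ms = "numeric",
    positions_um = "numeric",
    n = "integer",
    dx_um = "numeric",
    stim_time_ms = "numeric",
    sink_polarity = "character",
    modality = "character",
    condition = "character",
    tectum_id = "character"
  )
)

setValidity("CSDMap", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@time_ms))
    msg <- c(msg, "nrow(values) must equal length(time_ms)")
  if (ncol(object@values) != length(object@positions_um))
    msg <- c(msg, "ncol(values) must equal length(positions_um)")
  if (object@n < 1) msg <- c(msg, "n must be a positive integer")
  if (object@dx_um <= 0) msg <- c(msg, "dx_um must be positive")
  if (!object@sink_polarity %in% c("positive", "negative"))
    msg <- c(msg, "sink_polarity must be 'positive' or 'negative'")
  if (length(msg)) msg else TRUE
})

#' SinkSource: a localized CSD extremum
#'
#' Location, time, and magnitude of a current sink (or source) identified in
#' a [CSDMap-class].
#'
#' @slot location_um position (um from the distal edge).
#' @slot time_ms time of the extremum (ms).
#' @slot magnitude absolute CSD magnitude at the extremum.
#' @slot kind `"primary"` (monosynaptic / full window) or `"secondary"`
#'   (recurrent window).
#' @slot polarity `"sink"` or `"source"`.
#' @export
setClass("SinkSource",
  representation(
    location_um = "numeric",
    time_ms = "numeric",
    magnitude = "numeric",
    kind = "character",
    polarity = "character"
  )
)

#' FluorescenceProfile: axon-label intensity along the laminar axis
#'
#' A line profile of fluorescence intensity (8-bit gray values 0-255, or
#' normalized intensity in [0, 1]) for one labeled afferent channel,
#' sampled along the distal-proximal laminar axis.
#'
#' @slot positions_um positions (um from the distal edge), uniform spacing.
#' @slot intensity gray values; integers in [0, 255] when raw, numeric in
#'   [0, 1] when normalized.
#' @slot channel `"RGC"` or `"HB"`.
#' @slot normalized logical.
#' @slot specimen_id character label.
#' @seealso [normalizeFluorescence()], [axonOverlapArea()]
#' @export
setClass("FluorescenceProfile",
  representation(
    positions_um = "numeric",
    intensity = "numeric",
    channel = "character",
    normalized = "logical",
    specimen_id = "character"
  )
)

setValidity("FluorescenceProfile", function(object) {
  msg <- character()
  if (length(object@positions_um) != length(object@intensity))
    msg <- c(msg, "positions_um and intensity must have equal length")
  if (length(object@positions_um) >= 2) {
    d <- diff(object@positions_um)
    if (any(d <= 0)) msg <- c(msg, "positions_um must be strictly increasing")
    if (max(abs(d - d[1])) > 1e-8 * max(d))
      msg <- c(msg, "positions_um must be uniformly spaced")
  }
  if (!object@channel %in% c("RGC", "HB"))
    msg <- c(msg, "channel must be 'RGC' or 'HB'")
  if (isTRUE(object@normalized)) {
    if (any(object@intensity < 0) || any(object@intensity > 1))
      msg <- c(msg, "normalized intensity must lie in [0, 1]")
  } else {
    v <- object@intensity
    if (any(v < 0) || any(v > 255) || any(v != round(v)))
      msg <- c(msg, "raw gray values must be integers in [0, 255]")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticConfig: forward-model parameters for one simulated recording
#'
#' Describes a single simulated evoked field-potential recording: the
#' laminar grid, the sampling clock, the spatiotemporal sink (a localized
#' negative-going potential well with an alpha-function time course peaking
#' within the 4-ms monosynaptic window), an optional co-localized recurrent
#' (secondary) sink, optional balancing sources via compact spatial support,
#' an optional diffuse secondary spatial component, and additive Gaussian
#' noise. Build with [syntheticConfig()] or [conditionPreset()].
#'
#' @slot axis_length_um laminar axis length (um), a positive multiple of
#'   `dx_um`; default 150.
#' @slot dx_um recording grid spacing (um); default 10.
#' @slot sample_rate_hz sampling rate (Hz); default 10000.
#' @slot trace_duration_ms trace duration (ms); default 50.
#' @slot stim_time_ms stimulus time (ms); default 10.
#' @slot condition one of `"control"`, `"dcr"`, `"mk801_early"`,
#'   `"mk801_late"`.
#' @slot modality `"RGC"` or `"HB"`.
#' @slot sink_center_um sink centre (um from the distal edge).
#' @slot sink_width_um spatial SD of the sink (um); default 12.
#' @slot sink_amplitude peak potential deflection (arbitrary units);
#'   default 1.
#' @slot source_balance logical; if TRUE the potential well has compact
#'   spatial support (zero on the outer 30 um at each end), which makes the
#'   interior second-difference sum exactly zero (balancing sources).
#' @slot recurrent_delay_ms onset delay of the recurrent sink relative to the
#'   primary onset (ms); default 8.
#' @slot recurrent_amplitude_fraction recurrent amplitude as a fraction of
#'   the primary amplitude; default 0.5 (0 disables it).
#' @slot diffuse_center_um,diffuse_width_um,diffuse_amplitude_fraction an
#'   optional broad, low-amplitude spatial component (used by the late
#'   MK-801 preset); fraction 0 disables it.
#' @slot noise_sd SD of additive i.i.d. Gaussian noise per sample (same
#'   units as the potential).
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticConfig",
  representation(
    axis_length_um = "numeric",
    dx_um = "numeric",
    sample_rate_hz = "numeric",
    trace_duration_ms = "numeric",
    stim_time_ms = "numeric",
    condition = "character",
    modality = "character",
    sink_center_um = "numeric",
    sink_width_um = "numeric",
    sink_amplitude = "numeric",
    source_balance = "logical",
    recurrent_delay_ms = "numeric",
    recurrent_amplitude_fraction = "numeric",
    diffuse_center_um = "numeric",
    diffuse_width_um = "numeric",
    diffuse_amplitude_fraction = "numeric",
    noise_sd = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@dx_um <= 0) msg <- c(msg, "dx_um must be positive")
  if (object@axis_length_um <= 0 ||
      abs(object@axis_length_um / object@dx_um -
          round(object@axis_length_um / object@dx_um)) > 1e-8)
    msg <- c(msg, "axis_length_um must be a positive multiple of dx_um")
  if (object@sink_center_um < 0 || object@sink_center_um > object@axis_length_um)
    msg <- c(msg, "sink_center_um must lie within [0, axis_length_um]")
  if (object@sink_width_um <= 0) msg <- c(msg, "sink_width_um must be positive")
  if (object@trace_duration_ms <= 0)
    msg <- c(msg, "trace_duration_ms must be positive")
  if (object@stim_time_ms < 0 ||
      object@stim_time_ms >= object@trace_duration_ms)
    msg <- c(msg, "stim_time_ms must lie inside the trace")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  if (object@sample_rate_hz <= 0) msg <- c(msg, "sample_rate_hz must be positive")
  if (!object@condition %in% c("control", "dcr", "mk801_early", "mk801_late"))
    msg <- c(msg, "unknown condition")
  if (!object@modality %in% c("RGC", "HB"))
    msg <- c(msg, "modality must be 'RGC' or 'HB'")
  if (isTRUE(object@source_balance)) {
    m <- balanceMarginUm(object@dx_um)
    lo <- m + object@dx_um / 2
    hi <- object@axis_length_um - m - object@dx_um / 2
    if (object@sink_center_um < lo || object@sink_center_um > hi)
      msg <- c(msg, sprintf(
        "with source_balance, sink_center_um must lie in [%g, %g] um (compact-support margin)",
        lo, hi))
  }
  if (length(msg)) msg else TRUE
})

#' GroupSummary: mean, SEM, and confidence interval of one group
#'
#' @slot mean,sem group mean and standard error of the mean.
#' @slot n number of observations.
#' @slot ci_low,ci_high bounds of the confidence interval.
#' @slot ci_method `"normal_z"` or `"student_t"`.
#' @slot level confidence level (default 0.95).
#' @slot label group label.
#' @seealso [summarizeGroup()], [confidenceInterval()]
#' @export
setClass("GroupSummary",
  representation(
    mean = "numeric", sem = "numeric", n = "integer",
    ci_low = "numeric", ci_high = "numeric",
    ci_method = "character", level = "numeric", label = "character"
  )
)

setValidity("GroupSummary", function(object) {
  msg <- character()
  if (object@sem < 0) msg <- c(msg, "sem must be >= 0")
  if (object@n < 1) msg <- c(msg, "n must be >= 1")
  if (object@ci_low > object@mean || object@ci_high < object@mean)
    msg <- c(msg, "ci_low <= mean <= ci_high must hold")
  if (length(msg)) msg else TRUE
})

#' TestResult: outcome of a normality-routed two-group comparison
#'
#' @slot statistic test statistic (t or Mann-Whitney U/W).
#' @slot p_value two-sided p-value.
#' @slot test_used `"unpaired_t"` or `"mann_whitney"`.
#' @slot normality_p_a,normality_p_b Shapiro-Wilk p-values per group.
#' @slot n_a,n_b group sizes.
#' @slot exact logical; TRUE when the exact Mann-Whitney distribution was
#'   used (NA for the t-test).
#' @seealso [compareGroups()]
#' @export
setClass("TestResult",
  representation(
    statistic = "numeric", p_value = "numeric", test_used = "character",
    normality_p_a = "numeric", normality_p_b = "numeric",
    n_a = "integer", n_b = "integer", exact = "logical"
  )
)

setValidity("TestResult", function(object) {
  if (object@p_value < 0 || object@p_value > 1) "p_value must lie in [0, 1]"
  else TRUE
})
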