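# Forward model: simulated evoked field potentials with known ground truth.
#
# The potential is a spatially localized negative-going well (the sink) with
# an alpha-function time course; its discrete second spatial difference is
# the implied ground-truth CSD: a central sink flanked by balancing sources.
# With source_balance the well has compact spatial support (exact zeros on
# the outer margin of the axis), so the interior second-difference sum
# telescopes to exactly zero for stencil steps n <= 2.

# Margin (um) that must be exactly zero at each axis end for the interior
# n = 2 second-difference sum to vanish identically: (2*2 - 1) * dx.
balanceMarginUm <- function(dx_um) 3 * dx_um

# Unit-peak laminar bump centred at `center`. Gaussian with SD `width`;
# when `margin_um` is non-NULL the bump is truncated (shifted-and-scaled) to
# exact zero at grid points within `margin_um` of either axis end, with a
# per-side support radius of at most 3*width.
.laminarBump <- function(positions_um, center_um, width_um, margin_um = NULL) {
  d <- positions_um - center_um
  if (is.null(margin_um)) return(exp(-d^2 / (2 * width_um^2)))
  L <- max(positions_um)
  r_left <- min(3 * width_um, center_um - margin_um)
  r_right <- min(3 * width_um, (L - margin_um) - center_um)
  out <- numeric(length(d))
  for (side in c(-1, 1)) {
    r <- if (side < 0) r_left else r_right
    sel <- if (side < 0) d <= 0 else d > 0
    if (r <= 0) next
    tail_val <- exp(-r^2 / (2 * width_um^2))
    v <- (exp(-d[sel]^2 / (2 * width_um^2)) - tail_val) / (1 - tail_val)
    v[abs(d[sel]) >= r] <- 0
    out[sel] <- pmax(v, 0)
  }
  out
}

# Alpha-function kernel, unit peak at t0 + tau; zero for t <= t0.
.alphaKernel <- function(t_ms, t0_ms, tau_ms) {
  s <- (t_ms - t0_ms) / tau_ms
  ifelse(s > 0, s * exp(1 - s), 0)
}

#' Construct a forward-model configuration
#'
#' Builds a [SyntheticConfig-class] describing one simulated evoked
#' field-potential recording. Defaults describe a control recording: a
#' 150-um laminar axis sampled every 10 um, traces digitized at 10 kHz for
#' 50 ms with the stimulus at 10 ms, a monosynaptic sink whose field
#' potential peaks ~2.5 ms after the stimulus (inside the 4-ms monosynaptic
#' window), and a co-localized recurrent sink at half amplitude starting
#' 8 ms later.
#'
#' @param axis_length_um,dx_um,sample_rate_hz,trace_duration_ms,stim_time_ms
#'   grid and clock parameters; see [SyntheticConfig-class].
#' @param condition,modality labels; see [SyntheticConfig-class].
#' @param sink_center_um sink centre (um from the distal edge). Default: the
#'   [conditionPreset()] centre for `condition`/`modality`.
#' @param sink_width_um,sink_amplitude,source_balance,recurrent_delay_ms,recurrent_amplitude_fraction
#'   sink shape parameters; see [SyntheticConfig-class].
#' @param diffuse_center_um,diffuse_width_um,diffuse_amplitude_fraction
#'   optional broad low-amplitude component (fraction 0 disables).
#' @param noise_sd additive Gaussian noise SD (potential units); default
#'   0.05 (5% of the unit sink amplitude).
#' @param seed integer RNG seed.
#' @return A validated [SyntheticConfig-class] object.
#' @examples
#' cfg <- syntheticConfig(modality = "HB", noise_sd = 0, seed = 7L)
#' cfg@sink_center_um
#' @export
syntheticConfig <- function(axis_length_um = 150, dx_um = 10,
                            sample_rate_hz = 10000, trace_duration_ms = 50,
                            stim_time_ms = 10, condition = "control",
                            modality = "RGC", sink_center_um = NULL,
                            sink_width_um = NULL, sink_amplitude = 1,
                            source_balance = TRUE, recurrent_delay_ms = 8,
                            recurrent_amplitude_fraction = 0.5,
                            diffuse_center_um = NA_real_,
                            diffuse_width_um = NA_real_,
                            diffuse_amplitude_fraction = 0,
                            noise_sd = 0.05, seed = 1L) {
  preset <- .conditionPresetTable(condition, modality)
  if (is.null(sink_center_um)) sink_center_um <- preset$center_um
  if (is.null(sink_width_um)) sink_width_um <- preset$width_um
  new("SyntheticConfig",
      axis_length_um = axis_length_um, dx_um = dx_um,
      sample_rate_hz = sample_rate_hz, trace_duration_ms = trace_duration_ms,
      stim_time_ms = stim_time_ms, condition = condition, modality = modality,
      sink_center_um = sink_center_um, sink_width_um = sink_width_um,
      sink_amplitude = sink_amplitude, source_balance = source_balance,
      recurrent_delay_ms = recurrent_delay_ms,
      recurrent_amplitude_fraction = recurrent_amplitude_fraction,
      diffuse_center_um = diffuse_center_um,
      diffuse_width_um = diffuse_width_um,
      diffuse_amplitude_fraction = diffuse_amplitude_fraction,
      noise_sd = noise_sd, seed = as.integer(seed))
}

# Condition/modality presets: sink centres (um from the distal edge) read
# from the study's group means; widths widened where the innervation pattern
# disperses. The late-MK-801 HB preset adds a low-amplitude diffuse
# component trespassing distally.
.conditionPresetTable <- function(condition, modality) {
  key <- paste(condition, modality, sep = ".")
  tab <- list(
    control.RGC = list(center_um = 50, width_um = 12),
    control.HB = list(center_um = 100, width_um = 12),
    dcr.RGC = list(center_um = 50, width_um = 12),
    dcr.HB = list(center_um = 69, width_um = 18),
    mk801_early.RGC = list(center_um = 72, width_um = 18),
    mk801_early.HB = list(center_um = 70, width_um = 18),
    mk801_late.RGC = list(center_um = 50, width_um = 12),
    mk801_late.HB = list(center_um = 100, width_um = 12,
                         diffuse_center_um = 70, diffuse_width_um = 30,
                         diffuse_amplitude_fraction = 0.25)
  )
  if (!key %in% names(tab))
    stop("no preset for condition '", condition, "' and modality '",
         modality, "'")
  tab[[key]]
}

#' Condition presets for the forward model
#'
#' Returns a ready-made [SyntheticConfig-class] whose sink centre and width
#' encode the experimental condition: `control` (RGC sink distal at 50 um,
#' HB sink proximal at 100 um), `dcr` (tectum devoid of contralateral RGC
#' input: HB sink shifted distally to 69 um and widened), `mk801_early`
#' (chronic NMDAR blockade from stage 39: desegregated, RGC 72 um / HB 70 um,
#' widened), and `mk801_late` (blockade from stage 45: control-like centres,
#' with an added low-amplitude diffuse HB component in distal territory).
#'
#' @param condition one of `"control"`, `"dcr"`, `"mk801_early"`,
#'   `"mk801_late"`.
#' @param modality `"RGC"` or `"HB"`.
#' @param ... further arguments passed to [syntheticConfig()] (e.g.
#'   `noise_sd`, `seed`).
#' @return A [SyntheticConfig-class].
#' @examples
#' conditionPreset("dcr", "HB", seed = 3L)@sink_center_um
#' @export
conditionPreset <- function(condition, modality, ...) {
  preset <- .conditionPresetTable(condition, modality)
  args <- list(condition = condition, modality = modality, ...)
  for (f in c("diffuse_center_um", "diffuse_width_um",
              "diffuse_amplitude_fraction"))
    if (is.null(args[[f]]) && !is.null(preset[[f]])) args[[f]] <- preset[[f]]
  if (is.null(args$sink_center_um)) args$sink_center_um <- preset$center_um
  if (is.null(args$sink_width_um)) args$sink_width_um <- preset$width_um
  do.call(syntheticConfig, args)
}

#' Simulate one evoked field-potential recording
#'
#' Generates an [FPRecording-class] from a [SyntheticConfig-class]. The
#' noise-free potential is \eqn{V(x,t) = -A\, b(x)\, [h_1(t) + f\, h_2(t)]}:
#' a unit-peak laminar bump \eqn{b(x)} centred on the sink (Gaussian of SD
#' `sink_width_um`; compactly supported when `source_balance` is set), an
#' alpha-function monosynaptic time course \eqn{h_1} with 1-ms synaptic
#' latency and 1.5-ms rise (field-potential peak ~2.5 ms post-stimulus,
#' inside the 4-ms monosynaptic window), and a co-localized recurrent
#' component \eqn{h_2} of amplitude fraction \eqn{f} delayed by
#' `recurrent_delay_ms`. Independent Gaussian noise of SD `noise_sd` is
#' added to every sample; pre-stimulus samples are baseline (0) plus noise.
#'
#' The discrete second spatial difference of the noise-free potential is the
#' implied ground-truth CSD: a positive (sink) extremum at the sink centre
#' flanked by negative (source) lobes. With `source_balance`, the compact
#' support makes the interior second-difference sum exactly zero for
#' stencil steps n <= 2 (source-sink balance).
#'
#' @param config a [SyntheticConfig-class].
#' @return An [FPRecording-class]; its ground truth is available via
#'   [groundTruth()] (`true_sink_center_um`, `true_sink_onset_ms`,
#'   `true_secondary_center_um`, `condition`).
#' @examples
#' rec <- simulateRecording(syntheticConfig(noise_sd = 0, seed = 1L))
#' peakLocation(buildSpatialProfile(rec))  # recovers the 50-um sink
#' @export
simulateRecording <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  dt_ms <- 1000 / config@sample_rate_hz
  time_ms <- seq(0, config@trace_duration_ms - dt_ms, by = dt_ms)
  positions_um <- seq(0, config@axis_length_um, by = config@dx_um)

  margin <- if (isTRUE(config@source_balance))
    balanceMarginUm(config@dx_um) else NULL
  bump <- .laminarBump(positions_um, config@sink_center_um,
                       config@sink_width_um, margin)
  latency_ms <- 1
  tau_ms <- 1.5
  onset_ms <- config@stim_time_ms + latency_ms
  h <- .alphaKernel(time_ms, onset_ms, tau_ms)
  if (config@recurrent_amplitude_fraction > 0) {
    h <- h + config@recurrent_amplitude_fraction *
      .alphaKernel(time_ms, onset_ms + config@recurrent_delay_ms, 3)
  }
  v <- -config@sink_amplitude * outer(h, bump)
  if (config@diffuse_amplitude_fraction > 0) {
    dbump <- .laminarBump(positions_um, config@diffuse_center_um,
                          config@diffuse_width_um, margin)
    v <- v - config@sink_amplitude * config@diffuse_amplitude_fraction *
      outer(h, dbump)
  }
  if (config@noise_sd > 0) {
    set.seed(config@seed)
    v <- v + matrix(stats::rnorm(length(v), sd = config@noise_sd),
                    nrow = nrow(v))
  }
  truth <- list(
    true_sink_center_um = config@sink_center_um,
    true_sink_onset_ms = onset_ms,
    true_secondary_center_um = config@sink_center_um,
    condition = config@condition
  )
  new("FPRecording", potentials = v, time_ms = time_ms,
      positions_um = positions_um, stim_time_ms = config@stim_time_ms,
      modality = config@modality, tectum_id = sprintf("sim%d", config@seed),
      condition = config@condition, seed = config@seed, truth = truth)
}

#' Simulate a cohort of tecta
#'
#' Generates `n_tecta` recordings per modality for one condition, with
#' per-tectum sink centres jittered around the condition means
#' (Gaussian jitter of SD `jitter_sd_um`, the across-animal variability of
#' laminar sink position) and per-recording seeds derived deterministically
#' from the master seed. Because jittered centres routinely fall outside the
#' compact-support window that exact source-sink balance requires, cohort
#' recordings are generated with `source_balance = FALSE` by default (plain
#' Gaussian laminar bumps, clamped to the axis); set `source_balance = TRUE`
#' to keep balanced recordings at the cost of clamping centres into the
#' feasible window.
#'
#' @param condition condition label, see [conditionPreset()].
#' @param n_tecta number of tecta (>= 1).
#' @param modalities character vector, subset of `c("RGC", "HB")`.
#' @param centers_um optional named numeric vector of mean sink centres per
#'   modality (um), overriding the condition presets, e.g.
#'   `c(RGC = 50, HB = 104)`.
#' @param jitter_sd_um SD of the per-tectum centre jitter (um); default 15.
#' @param noise_sd additive noise SD; default 0.05 (5% of unit amplitude).
#' @param seed master integer seed.
#' @param source_balance see above; default FALSE.
#' @param ... further [syntheticConfig()] arguments applied to every tectum.
#' @return A list with one element per tectum x modality, each a
#'   [FPRecording-class] (ground truth via [groundTruth()]).
#' @examples
#' coh <- simulateCohort("control", n_tecta = 3, modalities = "HB", seed = 1L)
#' vapply(coh, function(r) groundTruth(r)$true_sink_center_um, numeric(1))
#' @export
simulateCohort <- function(condition, n_tecta, modalities = c("RGC", "HB"),
                           centers_um = NULL, jitter_sd_um = 15,
                           noise_sd = 0.05, seed = 1L,
                           source_balance = FALSE, ...) {
  if (n_tecta < 1) stop("n_tecta must be >= 1")
  if (length(modalities) == 0) stop("modalities must be non-empty")
  if (!all(modalities %in% c("RGC", "HB")))
    stop("modalities must be a subset of c('RGC', 'HB')")
  set.seed(as.integer(seed))
  out <- list()
  for (m in modalities) {
    preset <- .conditionPresetTable(condition, m)
    mean_center <- if (!is.null(centers_um) && m %in% names(centers_um))
      centers_um[[m]] else preset$center_um
    jitter <- stats::rnorm(n_tecta, 0, jitter_sd_um)
    child_seeds <- sample.int(.Machine$integer.max - 1L, n_tecta)
    for (i in seq_len(n_tecta)) {
      center <- mean_center + jitter[i]
      # keep the centre inside the axis (and inside the compact-support
      # window when balanced recordings are requested)
      dx <- list(...)$dx_um
      if (is.null(dx)) dx <- 10
      L <- list(...)$axis_length_um
      if (is.null(L)) L <- 150
      if (isTRUE(source_balance)) {
        lo <- balanceMarginUm(dx) + dx / 2
        center <- min(max(center, lo), L - lo)
      } else {
        center <- min(max(center, 0), L)
      }
      cfg <- conditionPreset(condition, m, sink_center_um = center,
                             noise_sd = noise_sd,
                             source_balance = isTRUE(source_balance),
                             seed = child_seeds[i], ...)
      rec <- simulateRecording(cfg)
      rec@tectum_id <- sprintf("%s_t%02d", condition, i)
      out[[sprintf("%s_t%02d_%s", condition, i, m)]] <- rec
    }
  }
  out
}

#' Simulate a two-channel fluorescence line-profile pair
#'
#' Generates two [FluorescenceProfile-class] objects (RGC and HB channels)
#' on a shared position grid: per-channel Gaussian bump plus baseline plus
#' Gaussian noise, quantized to integer 8-bit gray values (clipped to
#' [0, 255]).
#'
#' @param centers_um numeric length 2: bump centres (um), RGC then HB.
#' @param widths_um numeric length 2: bump SDs (um); default c(15, 15).
#' @param amplitudes numeric length 2: bump amplitudes in gray values;
#'   default c(180, 180). `amplitudes + baseline` must not exceed 255.
#' @param baseline gray-value baseline; default 20.
#' @param noise_sd noise SD in gray values; default 5.
#' @param axis_length_um,dx_um position grid; default 150 um every 10 um.
#' @param seed integer RNG seed.
#' @param specimen_id character label.
#' @return A list with elements `RGC` and `HB`, each a
#'   [FluorescenceProfile-class].
#' @examples
#' fp <- simulateFluorescencePair(c(50, 100), noise_sd = 0, seed = 1L)
#' peakLocation(fp$HB)
#' @export
simulateFluorescencePair <- function(centers_um, widths_um = c(15, 15),
                                     amplitudes = c(180, 180), baseline = 20,
                                     noise_sd = 5, axis_length_um = 150,
                                     dx_um = 10, seed = 1L,
                                     specimen_id = "sim") {
  stopifnot(length(centers_um) == 2, length(widths_um) == 2,
            length(amplitudes) == 2)
  if (any(amplitudes < 0) || baseline < 0 || any(amplitudes + baseline > 255))
    stop("amplitudes + baseline must lie in [0, 255]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  positions_um <- seq(0, axis_length_um, by = dx_um)
  set.seed(as.integer(seed))
  channels <- c("RGC", "HB")
  out <- list()
  for (k in 1:2) {
    v <- baseline + amplitudes[k] *
      exp(-(positions_um - centers_um[k])^2 / (2 * widths_um[k]^2))
    if (noise_sd > 0)
      v <- v + stats::rnorm(length(v), sd = noise_sd)
    gray <- pmin(pmax(round(v), 0), 255)
    out[[channels[k]]] <- new("FluorescenceProfile",
      positions_um = positions_um, intensity = gray,
      channel = channels[k], normalized = FALSE, specimen_id = specimen_id)
  }
  out
}
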