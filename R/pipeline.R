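# End-to-end study orchestration: simulate (or load) -> profiles -> CSD ->
# fluorescence -> group statistics -> report files.

#' Build a study configuration
#'
#' Collects every knob of the end-to-end analysis in one validated list.
#' Analysis defaults mirror the recording conventions: a 4-ms monosynaptic
#' window, a 10-um recording grid, and a 20-um spatial differentiation grid
#' (stencil step n = 2).
#'
#' @param conditions character vector of condition labels; the first is the
#'   reference group for comparisons. Default `c("control", "dcr")`.
#' @param modalities character vector, subset of `c("RGC", "HB")`.
#' @param n_tecta tecta per condition; default 10.
#' @param centers_um optional named list of per-condition mean sink centres,
#'   e.g. `list(control = c(HB = 104), dcr = c(HB = 84))`; defaults to the
#'   condition presets.
#' @param jitter_sd_um per-tectum centre jitter SD (um); default 15.
#' @param noise_sd recording noise SD (fraction of unit amplitude);
#'   default 0.05.
#' @param mono_window_ms monosynaptic window (ms); default 4.
#' @param csd_n CSD stencil step count; default 2 (20-um grid on dx = 10).
#' @param sink_polarity `"positive"` or `"negative"`; default `"positive"`.
#' @param overlap_weighted logical; dx-weighted overlap index? Default FALSE.
#' @param ci_method `"normal_z"` or `"student_t"`; default `"normal_z"`.
#' @param normality_alpha Shapiro-Wilk gate level; default 0.05.
#' @param fluorescence logical; also simulate and quantify two-channel axon
#'   fluorescence per condition? Default FALSE.
#' @param input_dirs optional named list (by condition) of directories with
#'   recording CSVs + JSON sidecars to analyse instead of simulating.
#' @param seed master integer seed; default 1.
#' @param out_dir optional output directory for tables, figures, and the
#'   JSON report.
#' @param figure_format `"pdf"`, `"png"`, or `"svg"`; default `"pdf"`.
#' @return A list of class `"StudyConfig"`.
#' @seealso [runStudy()], [readStudyConfig()]
#' @export
studyConfig <- function(conditions = c("control", "dcr"),
                        modalities = c("RGC", "HB"), n_tecta = 10,
                        centers_um = NULL, jitter_sd_um = 15,
                        noise_sd = 0.05, mono_window_ms = 4, csd_n = 2,
                        sink_polarity = "positive", overlap_weighted = FALSE,
                        ci_method = "normal_z", normality_alpha = 0.05,
                        fluorescence = FALSE, input_dirs = NULL, seed = 1,
                        out_dir = NULL, figure_format = "pdf") {
  if (length(conditions) < 1) stop("at least one condition is required")
  if (!all(modalities %in% c("RGC", "HB")))
    stop("modalities must be a subset of c('RGC', 'HB')")
  if (n_tecta < 1) stop("n_tecta must be >= 1")
  if (mono_window_ms <= 0) stop("mono_window_ms must be positive")
  if (csd_n < 1) stop("csd_n must be >= 1")
  if (!sink_polarity %in% c("positive", "negative"))
    stop("sink_polarity must be 'positive' or 'negative'")
  if (!ci_method %in% c("normal_z", "student_t"))
    stop("ci_method must be 'normal_z' or 'student_t'")
  if (normality_alpha <= 0 || normality_alpha >= 1)
    stop("normality_alpha must lie in (0, 1)")
  if (jitter_sd_um < 0 || noise_sd < 0)
    stop("jitter_sd_um and noise_sd must be >= 0")
  if (!figure_format %in% c("pdf", "png", "svg"))
    stop("figure_format must be 'pdf', 'png', or 'svg'")
  if (!is.null(input_dirs)) {
    missing_d <- unlist(input_dirs)[!dir.exists(unlist(input_dirs))]
    if (length(missing_d))
      stop("input directory does not exist: ", paste(missing_d, collapse = ", "))
  }
  structure(list(
    conditions = conditions, modalities = modalities, n_tecta = n_tecta,
    centers_um = centers_um, jitter_sd_um = jitter_sd_um,
    noise_sd = noise_sd, mono_window_ms = mono_window_ms, csd_n = csd_n,
    sink_polarity = sink_polarity, overlap_weighted = overlap_weighted,
    ci_method = ci_method, normality_alpha = normality_alpha,
    fluorescence = fluorescence, input_dirs = input_dirs,
    seed = as.integer(seed), out_dir = out_dir,
    figure_format = figure_format), class = "StudyConfig")
}

#' Read a study configuration from JSON
#'
#' The configuration file is a single human-editable JSON object whose keys
#' match the arguments of [studyConfig()].
#'
#' @param path JSON file path.
#' @return A validated `"StudyConfig"`.
#' @export
readStudyConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: '", path, "'")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(studyConfig))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(studyConfig, raw)
}

.summaryRow <- function(gs, group, metric) {
  data.frame(group = group, metric = metric, mean = gs@mean, sem = gs@sem,
             n = gs@n, ci_low = gs@ci_low, ci_high = gs@ci_high,
             ci_method = gs@ci_method)
}

.comparisonRow <- function(tr, label, metric, mean_a, mean_b) {
  data.frame(comparison = label, metric = metric, mean_a = mean_a,
             mean_b = mean_b, statistic = tr@statistic, p_value = tr@p_value,
             test = tr@test_used, n_a = tr@n_a, n_b = tr@n_b,
             shapiro_p_a = tr@normality_p_a, shapiro_p_b = tr@normality_p_b)
}

.gatherRecordings <- function(config) {
  recs <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    if (!is.null(config$input_dirs) && !is.null(config$input_dirs[[cond]])) {
      dirp <- config$input_dirs[[cond]]
      files <- sort(list.files(dirp, pattern = "\\.csv$", full.names = TRUE))
      if (length(files) == 0)
        stop("input directory '", dirp, "' contains no recording CSVs")
      for (f in files) recs[[length(recs) + 1L]] <- readFPRecording(f)
    } else {
      centers <- if (!is.null(config$centers_um)) config$centers_um[[cond]]
      cohort <- simulateCohort(cond, config$n_tecta,
                               modalities = config$modalities,
                               centers_um = centers,
                               jitter_sd_um = config$jitter_sd_um,
                               noise_sd = config$noise_sd,
                               seed = config$seed + 7919L * ci)
      recs <- c(recs, cohort)
    }
  }
  recs
}

#' Run the end-to-end study
#'
#' Executes the complete analysis described by a `"StudyConfig"`: gather
#' recordings (simulated cohorts by default, or CSV directories), build
#' per-tectum normalized spatial profiles and peak locations, compute CSD
#' maps and locate the major monosynaptic sinks, compute RGC/HB overlap
#' indices per tectum where both modalities exist, optionally quantify
#' simulated two-channel axon fluorescence, then produce group summaries and
#' normality-routed comparisons (reference condition = the first listed).
#' When `out_dir` is set, writes `measurements.csv`, `summaries.csv`,
#' `comparisons.csv`, figures (average spatial profiles per condition and
#' one CSD image per condition x modality), and `report.json` containing
#' every number that appears in the tables and figures. The run is
#' deterministic given the config and seed.
#'
#' @param config a `"StudyConfig"` from [studyConfig()] /
#'   [readStudyConfig()].
#' @param out_dir output directory (overrides `config$out_dir`); NULL for no
#'   file output.
#' @param overwrite logical; refuse to overwrite an existing completed
#'   report unless TRUE.
#' @param verbose print per-stage progress; default FALSE.
#' @return Invisibly, a list of class `"ReportBundle"`: `measurements`,
#'   `summaries`, `comparisons`, `profiles` (average profiles), `csd_maps`
#'   (one per condition x modality), `fluorescence`, `figures` (paths),
#'   `report_path`.
#' @examples
#' cfg <- studyConfig(n_tecta = 3, seed = 1, fluorescence = FALSE)
#' bundle <- runStudy(cfg)
#' bundle$comparisons[, c("comparison", "metric", "p_value")]
#' @export
runStudy <- function(config, out_dir = config$out_dir, overwrite = FALSE,
                     verbose = FALSE) {
  stopifnot(inherits(config, "StudyConfig"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(out_dir)) {
    report_path <- file.path(out_dir, "report.json")
    if (file.exists(report_path) && !overwrite)
      stop("a completed report already exists at '", report_path,
           "'; pass overwrite = TRUE to replace it")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  say("gathering recordings (seed %d)", config$seed)
  recs <- .gatherRecordings(config)

  say("profiling %d recordings", length(recs))
  meas <- list(); profs <- list()
  for (r in recs) {
    prof <- buildSpatialProfile(r, window_ms = config$mono_window_ms)
    csd <- computeCSD(r, n = config$csd_n,
                      sink_polarity = config$sink_polarity)
    sink <- locateMajorSink(csd, "monosynaptic",
                            mono_window_ms = config$mono_window_ms)
    key <- paste(r@condition, r@modality, sep = ".")
    profs[[key]] <- c(profs[[key]], list(prof))
    meas[[length(meas) + 1L]] <- data.frame(
      tectum_id = r@tectum_id, condition = r@condition, modality = r@modality,
      fp_peak_um = peakLocation(prof), csd_sink_um = sink@location_um,
      true_center_um = if (length(r@truth))
        r@truth$true_sink_center_um else NA_real_)
  }
  measurements <- do.call(rbind, meas)

  # per-tectum RGC/HB overlap indices
  overlaps <- NULL
  if (all(c("RGC", "HB") %in% config$modalities)) {
    ov <- list()
    for (cond in config$conditions) {
      prgc <- profs[[paste(cond, "RGC", sep = ".")]]
      phb <- profs[[paste(cond, "HB", sep = ".")]]
      if (is.null(prgc) || is.null(phb)) next
      ids_r <- vapply(prgc, function(p) p@tectum_id, character(1))
      ids_h <- vapply(phb, function(p) p@tectum_id, character(1))
      for (id in intersect(ids_r, ids_h)) {
        ov[[length(ov) + 1L]] <- data.frame(
          tectum_id = id, condition = cond,
          overlap_index = overlapIndex(prgc[[match(id, ids_r)]],
                                       phb[[match(id, ids_h)]],
                                       weighted = config$overlap_weighted))
      }
    }
    if (length(ov)) overlaps <- do.call(rbind, ov)
  }

  say("group statistics")
  summaries <- list(); comparisons <- list()
  for (cond in config$conditions) for (m in config$modalities) {
    sub <- measurements[measurements$condition == cond &
                          measurements$modality == m, ]
    if (!nrow(sub)) next
    g <- paste(cond, m, sep = ".")
    summaries[[length(summaries) + 1L]] <-
      .summaryRow(summarizeGroup(sub$fp_peak_um, method = config$ci_method,
                                 label = g), g, "fp_peak_um")
    summaries[[length(summaries) + 1L]] <-
      .summaryRow(summarizeGroup(sub$csd_sink_um, method = config$ci_method,
                                 label = g), g, "csd_sink_um")
  }
  if (!is.null(overlaps)) {
    for (cond in unique(overlaps$condition)) {
      sub <- overlaps[overlaps$condition == cond, ]
      summaries[[length(summaries) + 1L]] <-
        .summaryRow(summarizeGroup(sub$overlap_index,
                                   method = config$ci_method, label = cond),
                    cond, "overlap_index")
    }
  }

  ref <- config$conditions[1]
  for (cond in setdiff(config$conditions, ref)) {
    for (m in config$modalities) for (metric in c("fp_peak_um", "csd_sink_um")) {
      a <- measurements[measurements$condition == ref &
                          measurements$modality == m, metric]
      b <- measurements[measurements$condition == cond &
                          measurements$modality == m, metric]
      if (length(a) >= 3 && length(b) >= 3)
        comparisons[[length(comparisons) + 1L]] <- .comparisonRow(
          compareGroups(a, b, alpha_normality = config$normality_alpha),
          sprintf("%s_vs_%s.%s", ref, cond, m), metric, mean(a), mean(b))
    }
    if (!is.null(overlaps)) {
      a <- overlaps[overlaps$condition == ref, "overlap_index"]
      b <- overlaps[overlaps$condition == cond, "overlap_index"]
      if (length(a) >= 3 && length(b) >= 3)
        comparisons[[length(comparisons) + 1L]] <- .comparisonRow(
          compareGroups(a, b, alpha_normality = config$normality_alpha),
          sprintf("%s_vs_%s", ref, cond), "overlap_index", mean(a), mean(b))
    }
  }
  # within-condition RGC vs HB segregation (peak separation significance)
  if (all(c("RGC", "HB") %in% config$modalities)) {
    for (cond in config$conditions) {
      for (metric in c("fp_peak_um", "csd_sink_um")) {
        a <- measurements[measurements$condition == cond &
                            measurements$modality == "RGC", metric]
        b <- measurements[measurements$condition == cond &
                            measurements$modality == "HB", metric]
        if (length(a) >= 3 && length(b) >= 3)
          comparisons[[length(comparisons) + 1L]] <- .comparisonRow(
            compareGroups(a, b, alpha_normality = config$normality_alpha),
            sprintf("%s.RGC_vs_HB", cond), metric, mean(a), mean(b))
      }
    }
  }

  # fluorescence (simulated specimens per condition)
  fluor <- NULL
  if (isTRUE(config$fluorescence)) {
    say("fluorescence quantification")
    fl <- list()
    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[ci]
      set.seed(config$seed + 104729L * ci)
      spec_seeds <- sample.int(.Machine$integer.max - 1L, config$n_tecta)
      c_rgc <- .conditionPresetTable(cond, "RGC")$center_um
      c_hb <- .conditionPresetTable(cond, "HB")$center_um
      jit <- matrix(stats::rnorm(2 * config$n_tecta, 0, config$jitter_sd_um / 2),
                    ncol = 2)
      for (i in seq_len(config$n_tecta)) {
        pair <- simulateFluorescencePair(
          centers_um = c(c_rgc + jit[i, 1], c_hb + jit[i, 2]),
          seed = spec_seeds[i],
          specimen_id = sprintf("%s_s%02d", cond, i))
        nr <- normalizeFluorescence(pair$RGC)
        nh <- normalizeFluorescence(pair$HB)
        fl[[length(fl) + 1L]] <- data.frame(
          specimen_id = pair$RGC@specimen_id, condition = cond,
          peak_rgc_um = peakLocation(nr), peak_hb_um = peakLocation(nh),
          separation_um = peakSeparation(nr, nh),
          overlap_area = axonOverlapArea(nr, nh))
      }
    }
    fluor <- do.call(rbind, fl)
    for (cond in config$conditions) {
      sub <- fluor[fluor$condition == cond, ]
      summaries[[length(summaries) + 1L]] <-
        .summaryRow(summarizeGroup(sub$separation_um,
                                   method = config$ci_method, label = cond),
                    cond, "fluor_separation_um")
      summaries[[length(summaries) + 1L]] <-
        .summaryRow(summarizeGroup(sub$overlap_area,
                                   method = config$ci_method, label = cond),
                    cond, "fluor_overlap_area")
    }
    for (cond in setdiff(config$conditions, ref)) {
      for (metric in c("separation_um", "overlap_area")) {
        a <- fluor[fluor$condition == ref, metric]
        b <- fluor[fluor$condition == cond, metric]
        if (length(a) >= 3 && length(b) >= 3)
          comparisons[[length(comparisons) + 1L]] <- .comparisonRow(
            compareGroups(a, b, alpha_normality = config$normality_alpha),
            sprintf("%s_vs_%s", ref, cond), paste0("fluor_", metric),
            mean(a), mean(b))
      }
    }
  }

  summaries <- do.call(rbind, summaries)
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else
    data.frame()

  # average profiles and one representative CSD map per condition x modality
  avg_profiles <- list(); csd_maps <- list()
  for (key in names(profs)) {
    avg_profiles[[key]] <- averageProfiles(profs[[key]])
  }
  for (r in recs) {
    key <- paste(r@condition, r@modality, sep = ".")
    if (is.null(csd_maps[[key]]))
      csd_maps[[key]] <- computeCSD(r, n = config$csd_n,
                                    sink_polarity = config$sink_polarity)
  }

  figures <- character()
  if (!is.null(out_dir)) {
    say("writing outputs to %s", out_dir)
    writeMeasurementsCSV(measurements, file.path(out_dir, "measurements.csv"))
    writeMeasurementsCSV(summaries, file.path(out_dir, "summaries.csv"))
    writeMeasurementsCSV(comparisons, file.path(out_dir, "comparisons.csv"))
    if (!is.null(overlaps))
      writeMeasurementsCSV(overlaps, file.path(out_dir, "overlap_indices.csv"))
    if (!is.null(fluor))
      writeMeasurementsCSV(fluor, file.path(out_dir, "fluorescence.csv"))
    fmt <- config$figure_format
    for (cond in config$conditions) {
      f <- file.path(out_dir, sprintf("profiles_%s.%s", cond, fmt))
      .plotAverageProfiles(avg_profiles, cond, f)
      figures <- c(figures, f)
    }
    for (key in names(csd_maps)) {
      f <- file.path(out_dir, sprintf("csd_%s.%s", gsub("\\.", "_", key), fmt))
      plotCSDMap(csd_maps[[key]], file = f)
      figures <- c(figures, f)
    }
    report <- list(
      config = unclass(config)[setdiff(names(config), "out_dir")],
      measurements = measurements, summaries = summaries,
      comparisons = comparisons, overlap_indices = overlaps,
      fluorescence = fluor,
      average_profiles = lapply(avg_profiles, function(p)
        list(positions_um = p@positions_um, amplitudes = p@amplitudes,
             n_contributing = p@n_contributing)),
      csd_maps = lapply(csd_maps, function(cm)
        list(positions_um = cm@positions_um, time_ms = cm@time_ms,
             values = cm@values)))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns")
    say("done in %.1f s", proc.time()[["elapsed"]] - t0)
  }

  invisible(structure(list(
    measurements = measurements, summaries = summaries,
    comparisons = comparisons, overlap_indices = overlaps,
    fluorescence = fluor, profiles = avg_profiles, csd_maps = csd_maps,
    figures = figures,
    report_path = if (!is.null(out_dir)) file.path(out_dir, "report.json")
      else NULL), class = "ReportBundle"))
}

# average spatial profiles of both modalities for one condition, one panel
.plotAverageProfiles <- function(avg_profiles, cond, file) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    png = grDevices::png(file, width = 700, height = 500),
    pdf = grDevices::pdf(file, width = 7, height = 5),
    svg = grDevices::svg(file, width = 7, height = 5),
    stop("unsupported figure format '.", ext, "'"))
  on.exit(grDevices::dev.off(), add = TRUE)
  keys <- grep(paste0("^", cond, "\\."), names(avg_profiles), value = TRUE)
  cols <- c(RGC = "darkgreen", HB = "firebrick")
  graphics::plot(NULL, xlim = c(0, max(vapply(avg_profiles[keys], function(p)
      max(p@positions_um), numeric(1)))), ylim = c(0, 1),
    xlab = "distance from distal edge (um)",
    ylab = "normalized peak FP amplitude",
    main = sprintf("average spatial FP profiles (%s)", cond))
  for (key in keys) {
    p <- avg_profiles[[key]]
    graphics::lines(p@positions_um, p@amplitudes, type = "b", pch = 16,
                    col = cols[[p@modality]])
  }
  graphics::legend("topright", legend = sub(paste0("^", cond, "\\."), "", keys),
                   col = cols[sub(paste0("^", cond, "\\."), "", keys)],
                   lty = 1, pch = 16, bty = "n")
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat("ReportBundle\n")
  cat(sprintf("  measurements: %d rows (%s)\n", nrow(x$measurements),
              paste(unique(x$measurements$condition), collapse = ", ")))
  cat(sprintf("  summaries: %d groups; comparisons: %d\n",
              nrow(x$summaries), nrow(x$comparisons)))
  if (!is.null(x$report_path)) cat("  report:", x$report_path, "\n")
  invisible(x)
}
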