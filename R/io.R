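# File formats: wide-CSV trace matrices with JSON sidecars, fluorescence
# CSVs, measurement tables. The same dialect serves simulated and real data.

.sidecarPath <- function(path) sub("\\.csv$", ".json", path, ignore.case = TRUE)

#' Write / read an FPRecording as wide CSV plus JSON sidecar
#'
#' The CSV has a `time_ms` first column and one column per laminar position,
#' headers being the distances in um from the distal edge (`"0"`, `"10"`,
#' ...). A JSON sidecar with the same basename carries the metadata
#' (modality, condition, tectum id, stimulus time, dx, seed) and any
#' simulation ground truth. The round trip is lossless to full stored
#' precision (values are written with 15 significant digits).
#'
#' @param recording an [FPRecording-class].
#' @param path CSV output path; the sidecar goes to the same path with a
#'   `.json` extension.
#' @return `writeFPRecording` invisibly returns `path`; `readFPRecording`
#'   returns an [FPRecording-class].
#' @examples
#' rec <- simulateRecording(syntheticConfig(seed = 1L))
#' f <- file.path(tempdir(), "rec.csv")
#' writeFPRecording(rec, f)
#' rec2 <- readFPRecording(f)
#' identical(potentials(rec), potentials(rec2))
#' @export
writeFPRecording <- function(recording, path) {
  stopifnot(is(recording, "FPRecording"))
  df <- data.frame(time_ms = recording@time_ms,
                   recording@potentials, check.names = FALSE)
  names(df) <- c("time_ms", format(recording@positions_um, trim = TRUE,
                                   scientific = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con)
  mat <- vapply(df, function(col) formatC(col, digits = 15, format = "g"),
                character(nrow(df)))
  writeLines(apply(mat, 1, paste, collapse = ","), con)
  meta <- list(modality = recording@modality,
               condition = recording@condition,
               tectum_id = recording@tectum_id,
               stim_time_ms = recording@stim_time_ms,
               dx_um = gridSpacing(recording),
               seed = recording@seed,
               ground_truth = recording@truth)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeFPRecording
#' @param sidecar path to the JSON sidecar; default: `path` with the
#'   extension replaced by `.json`.
#' @export
readFPRecording <- function(path, sidecar = .sidecarPath(path)) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar '", sidecar, "' for recording '", path, "'")
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_ms")
    stop("malformed header: first column must be 'time_ms', found '",
         names(df)[1], "'")
  pos_names <- names(df)[-1]
  pos <- suppressWarnings(as.numeric(pos_names))
  if (anyNA(pos)) {
    bad <- pos_names[which(is.na(pos))[1]]
    stop("malformed header: position column '", bad, "' is not numeric")
  }
  if (length(pos) >= 2) {
    d <- diff(pos)
    if (any(d <= 0))
      stop("position columns must be strictly increasing; offending column '",
           pos_names[which(d <= 0)[1] + 1], "'")
    if (max(abs(d - d[1])) > 1e-8 * max(d))
      stop("non-uniform position spacing; offending column '",
           pos_names[which(abs(d - d[1]) > 1e-8 * max(d))[1] + 1], "'")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("modality", "condition", "tectum_id", "stim_time_ms", "dx_um")
  missing_f <- setdiff(need, names(meta))
  if (length(missing_f))
    stop("sidecar '", sidecar, "' is missing required field(s): ",
         paste(missing_f, collapse = ", "))
  if (abs(meta$dx_um - (if (length(pos) >= 2) pos[2] - pos[1] else meta$dx_um)) > 1e-8)
    stop("sidecar dx_um disagrees with the CSV position headers")
  truth <- meta$ground_truth
  if (is.null(truth) || length(truth) == 0) truth <- list()
  new("FPRecording",
      potentials = unname(as.matrix(df[, -1, drop = FALSE])),
      time_ms = df$time_ms, positions_um = pos,
      stim_time_ms = meta$stim_time_ms, modality = meta$modality,
      tectum_id = meta$tectum_id, condition = meta$condition,
      seed = if (is.null(meta$seed)) NULL else as.integer(meta$seed),
      truth = as.list(truth))
}

#' Write / read fluorescence line profiles as long CSV
#'
#' Long format with columns `position_um`, `channel`, `gray_value`; the two
#' channels of a specimen share one file and one position grid.
#'
#' @param profiles list of [FluorescenceProfile-class] objects.
#' @param path CSV path.
#' @return `writeFluorescenceCSV` invisibly returns `path`;
#'   `readFluorescenceCSV` returns a named list of
#'   [FluorescenceProfile-class] objects (one per channel present).
#' @examples
#' fp <- simulateFluorescencePair(c(50, 100), seed = 1L)
#' f <- file.path(tempdir(), "fluor.csv")
#' writeFluorescenceCSV(fp, f)
#' names(readFluorescenceCSV(f))
#' @export
writeFluorescenceCSV <- function(profiles, path) {
  if (is(profiles, "FluorescenceProfile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(position_um = p@positions_um, channel = p@channel,
               gray_value = p@intensity)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFluorescenceCSV
#' @param specimen_id label attached to the profiles read; default the file
#'   basename.
#' @export
readFluorescenceCSV <- function(path,
                                specimen_id = tools::file_path_sans_ext(basename(path))) {
  df <- utils::read.csv(path)
  need <- c("position_um", "channel", "gray_value")
  missing_f <- setdiff(need, names(df))
  if (length(missing_f))
    stop("fluorescence CSV '", path, "' is missing column(s): ",
         paste(missing_f, collapse = ", "))
  grids <- split(df$position_um, df$channel)
  if (length(grids) > 1) {
    ref <- grids[[1]]
    for (g in grids[-1])
      if (length(g) != length(ref) || max(abs(g - ref)) > 1e-9)
        stop("channels in '", path, "' are on mismatched position grids")
  }
  lapply(split(df, df$channel), function(d) {
    raw <- all(d$gray_value == round(d$gray_value)) && max(d$gray_value) > 1
    new("FluorescenceProfile", positions_um = as.numeric(d$position_um),
        intensity = as.numeric(d$gray_value),
        channel = as.character(d$channel[1]),
        normalized = !raw, specimen_id = specimen_id)
  })
}

#' Write a measurement table as CSV
#'
#' Thin wrapper that writes per-tectum measurement tables (and any other
#' data frame the pipeline emits) without row names or quoting surprises.
#'
#' @param table a data.frame.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
writeMeasurementsCSV <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
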