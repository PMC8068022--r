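#' Pressure recording for one subject performing one task
#'
#' A `pressure_recording` is a T x 361 matrix of sensel pressures (kPa) sampled
#' at 50 Hz, plus metadata. Pressures must be finite and non-negative and at
#' least 3 frames are required (median filtering and derivatives need them).
#'
#' @param pressures Numeric matrix, frames x sensels, in kPa.
#' @param subject_id Subject identifier (coerced to character).
#' @param task_id Integer task id (1-21 in the reference protocol).
#' @param sample_rate_hz Sampling rate, default 50.
#' @param timestamps_s Optional length-T vector of seconds; defaults to a
#'   uniform grid at `sample_rate_hz`.
#' @param sex Optional "F"/"M", used by the sex ANOVA.
#' @return An object of class `pressure_recording`.
#' @export
pressure_recording <- function(pressures, subject_id, task_id,
                               sample_rate_hz = 50, timestamps_s = NULL,
                               sex = NULL) {
  pressures <- as.matrix(pressures)
  storage.mode(pressures) <- "double"
  if (nrow(pressures) < 3)
    stop("recording must have at least 3 frames, got ", nrow(pressures))
  if (any(!is.finite(pressures)))
    stop("pressures must all be finite")
  if (any(pressures < 0))
    stop("pressures must be non-negative; min = ", min(pressures))
  if (is.null(timestamps_s))
    timestamps_s <- (seq_len(nrow(pressures)) - 1) / sample_rate_hz
  if (length(timestamps_s) != nrow(pressures))
    stop("timestamps length must match number of frames")
  dt <- diff(timestamps_s)
  if (any(dt < 0)) stop("timestamps must be nondecreasing")
  if (any(abs(dt - 1 / sample_rate_hz) > 1e-6))
    stop("timestamps inconsistent with sample rate ", sample_rate_hz, " Hz")
  structure(list(
    subject_id = as.character(subject_id),
    task_id = as.integer(task_id),
    sample_rate_hz = sample_rate_hz,
    pressures = pressures,
    timestamps_s = as.numeric(timestamps_s),
    sex = if (is.null(sex)) NA_character_ else as.character(sex)
  ), class = "pressure_recording")
}

#' @export
print.pressure_recording <- function(x, ...) {
  cat(sprintf(
    "<pressure_recording> subject %s task %d: %d frames x %d sensels @ %g Hz\n",
    x$subject_id, x$task_id, nrow(x$pressures), ncol(x$pressures),
    x$sample_rate_hz))
  invisible(x)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read a recording from its CSV + JSON sidecar pair
#'
#' The on-disk dialect is a wide CSV with header `time_s,s001,...,s361` (one
#' row per frame, kPa, '.' decimal separator) and a JSON sidecar
#' (`<name>.json`) holding subject_id, task_id, sample_rate_hz and optional
#' sex/notes.
#'
#' @param path Path to the CSV file.
#' @param layout A `sensor_layout`; the column count must match.
#' @return A validated `pressure_recording`.
#' @export
read_recording <- function(path, layout) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  side <- sidecar_path(path)
  if (!file.exists(side)) stop("missing sidecar JSON: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("subject_id", "task_id", "sample_rate_hz"))
    if (is.null(meta[[f]])) stop("sidecar missing field '", f, "'")
  dt <- data.table::fread(path, sep = ",", header = TRUE)
  expect_cols <- c("time_s", sprintf("s%03d", seq_len(layout$n_sensels)))
  if (!identical(names(dt), expect_cols))
    stop("recording format error: expected ", length(expect_cols),
         " columns time_s,s001..s", layout$n_sensels, "; got ",
         ncol(dt), " columns")
  pressures <- as.matrix(dt[, -1])
  dimnames(pressures) <- NULL
  pressure_recording(
    pressures, subject_id = meta$subject_id, task_id = meta$task_id,
    sample_rate_hz = meta$sample_rate_hz, timestamps_s = dt$time_s,
    sex = meta$sex)
}

#' Write a recording as a CSV + JSON sidecar pair
#'
#' Values are serialized losslessly (shortest round-trip decimal), so
#' `read_recording(write_recording(x))` reproduces the pressures bit for bit.
#'
#' @param rec A `pressure_recording`.
#' @param path Destination CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pressure_recording"))
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, mode = 2) != 0)
    stop("cannot write to ", dir)
  # %.17g guarantees a bit-exact double round-trip (fwrite caps at 15 digits)
  num <- cbind(rec$timestamps_s, rec$pressures)
  cells <- matrix(sprintf("%.17g", num), nrow = nrow(num))
  header <- paste(c("time_s", sprintf("s%03d", seq_len(ncol(rec$pressures)))),
                  collapse = ",")
  rows <- do.call(paste, c(split(cells, col(cells)), sep = ","))
  writeLines(c(header, rows), path)
  meta <- list(subject_id = rec$subject_id, task_id = rec$task_id,
               sample_rate_hz = rec$sample_rate_hz)
  if (!is.na(rec$sex)) meta$sex <- rec$sex
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
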