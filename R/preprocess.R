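#' Median-filter every sensel series
#'
#' Each sensel's pressure trace is replaced by its running median (window 3 by
#' default) to remove single-frame noise artifacts; edges use replicate
#' padding, so for window 3 the endpoints are unchanged.
#'
#' @param rec A `pressure_recording`.
#' @param window Odd window length >= 3.
#' @return A filtered `pressure_recording` of the same shape.
#' @export
median_filter_sensels <- function(rec, window = 3) {
  stopifnot(inherits(rec, "pressure_recording"))
  if (window %% 2 == 0 || window < 3)
    stop("window must be an odd integer >= 3, got ", window)
  t_n <- nrow(rec$pressures)
  if (t_n < window)
    stop("recording has ", t_n, " frames; need at least ", window)
  half <- (window - 1) / 2
  pad_idx <- c(rep(1L, half), seq_len(t_n), rep(t_n, half))
  keep <- (half + 1):(half + t_n)
  filtered <- apply(rec$pressures, 2, function(col) {
    stats::runmed(col[pad_idx], window, endrule = "keep")[keep]
  })
  rec$pressures <- filtered
  rec
}

#' Discard saturated sensels
#'
#' A sensel that reaches the sensor's full scale (517 kPa) at any frame is
#' considered untrustworthy for the whole recording: its series is zeroed and
#' its id reported. The fractions of affected frames and of affected
#' sensel-recordings are attached for logging.
#'
#' @param rec A `pressure_recording`.
#' @param threshold_kpa Saturation threshold, default 517.
#' @param per_frame If `TRUE`, zero only the saturated frames instead of the
#'   whole sensel series.
#' @return List with elements `recording` (masked) and `discarded` (integer
#'   sensel ids), plus attributes `frac_frames` and `frac_sensels`.
#' @export
mask_saturated_sensels <- function(rec, threshold_kpa = 517,
                                   per_frame = FALSE) {
  stopifnot(inherits(rec, "pressure_recording"), threshold_kpa > 0)
  sat <- rec$pressures >= threshold_kpa
  hit <- which(colSums(sat) > 0)
  if (per_frame) {
    rec$pressures[sat] <- 0
  } else if (length(hit)) {
    rec$pressures[, hit] <- 0
  }
  if (length(hit) == ncol(sat))
    warning("all ", ncol(sat), " sensels saturated; grip force will be zero")
  out <- list(recording = rec, discarded = hit)
  attr(out, "frac_frames") <- mean(sat)
  attr(out, "frac_sensels") <- length(hit) / ncol(sat)
  out
}

#' Convert a recording's pressures into force series
#'
#' Force per sensel is pressure x sensel area (16 mm^2): `F[N] = p[kPa] * 1000
#' * 16e-6`. Region forces sum the region's sensels; the grip force GF sums
#' all sensels, so GF(t) equals the sum of region forces at every frame.
#'
#' @param rec A preprocessed `pressure_recording`.
#' @param layout A `sensor_layout`.
#' @param discarded_sensels Optional integer ids carried through from masking.
#' @return A `force_series`: list with `gf_n` (length-T), `region_force_n`
#'   (T x 18), `timestamps_s`, `subject_id`, `task_id`, `sex`,
#'   `discarded_sensels`.
#' @export
compute_forces <- function(rec, layout, discarded_sensels = integer(0)) {
  stopifnot(inherits(rec, "pressure_recording"),
            inherits(layout, "sensor_layout"))
  if (ncol(rec$pressures) != layout$n_sensels)
    stop("recording has ", ncol(rec$pressures), " sensels; layout expects ",
         layout$n_sensels)
  n_per_kpa <- 1000 * layout$sensel_area_mm2 * 1e-6  # 0.016 N per kPa
  force <- rec$pressures * n_per_kpa
  region_force <- vapply(layout$sensel_ids, function(ids)
    rowSums(force[, ids, drop = FALSE]), numeric(nrow(force)))
  structure(list(
    gf_n = rowSums(force),
    region_force_n = region_force,
    timestamps_s = rec$timestamps_s,
    sample_rate_hz = rec$sample_rate_hz,
    subject_id = rec$subject_id,
    task_id = rec$task_id,
    sex = rec$sex,
    discarded_sensels = discarded_sensels
  ), class = "force_series")
}

#' Full sensel-level preprocessing of one recording
#'
#' Median filter, saturation masking and force conversion in the standard
#' order.
#'
#' @inheritParams median_filter_sensels
#' @inheritParams mask_saturated_sensels
#' @param layout A `sensor_layout`.
#' @return A `force_series` (see [compute_forces()]); the filtered, masked
#'   recording is attached as attribute `recording`.
#' @export
preprocess_recording <- function(rec, layout, window = 3,
                                 threshold_kpa = 517) {
  filtered <- median_filter_sensels(rec, window)
  masked <- mask_saturated_sensels(filtered, threshold_kpa)
  fs <- compute_forces(masked$recording, layout,
                       discarded_sensels = masked$discarded)
  attr(fs, "recording") <- masked$recording
  fs
}

#' Normalize a time series onto the standard 101-point grid
#'
#' Task time is rescaled to [0, 1] and the values linearly interpolated at
#' relative-time increments of 0.01, so curves from executions of different
#' durations become comparable.
#'
#' @param values Numeric vector.
#' @param timestamps_s Strictly increasing timestamps of the same length.
#' @return A `normalized_curve`: list with `tau` (0, 0.01, ..., 1) and
#'   `values` (length 101).
#' @export
normalize_time <- function(values, timestamps_s) {
  if (length(values) < 2) stop("need at least 2 samples to normalize time")
  if (length(values) != length(timestamps_s))
    stop("values and timestamps lengths differ")
  if (any(diff(timestamps_s) <= 0))
    stop("timestamps must be strictly increasing")
  tau_in <- (timestamps_s - timestamps_s[1]) /
    (timestamps_s[length(timestamps_s)] - timestamps_s[1])
  grid <- normalized_grid()
  out <- stats::approx(tau_in, values, xout = grid, rule = 2)$y
  # endpoints preserved exactly (approx can round tau_in endpoints)
  out[1] <- values[1]
  out[length(out)] <- values[length(values)]
  normalized_curve(out)
}

#' @rdname normalize_time
#' @param values101 Length-101 numeric vector already on the grid.
#' @export
normalized_curve <- function(values101) {
  if (length(values101) != 101) stop("normalized curve must have 101 values")
  if (any(!is.finite(values101))) stop("normalized curve values must be finite")
  structure(list(tau = normalized_grid(), values = as.numeric(values101)),
            class = "normalized_curve")
}

normalized_grid <- function() seq(0, 1, by = 0.01)

#' First derivative of a normalized curve
#'
#' Central differences on the uniform grid, forward/backward at the endpoints.
#' Used as the synchronization cost signal: derivatives emphasize peaks and
#' valleys and ignore constant offsets.
#'
#' @param values Length-101 numeric vector (or a `normalized_curve`).
#' @return Length-101 derivative vector (per unit normalized time).
#' @export
curve_derivative <- function(values) {
  if (inherits(values, "normalized_curve")) values <- values$values
  n <- length(values)
  h <- 1 / (n - 1)
  d <- numeric(n)
  d[1] <- (values[2] - values[1]) / h
  d[n] <- (values[n] - values[n - 1]) / h
  d[2:(n - 1)] <- (values[3:n] - values[1:(n - 2)]) / (2 * h)
  d
}
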