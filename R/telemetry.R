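# Telemetry CSV layout: one row per ~260 ms sample from the chamber-inlet
# VOC sensors plus the five valve-state flags and the active stimulus label.
TELEMETRY_COLUMNS <- c("time_ms", "tvoc_primary_ppb", "tvoc_secondary_ppb",
                       "valve_clean", "valve_1", "valve_2", "valve_3",
                       "valve_4", "stimulus")

TVOC_SENSOR_MAX_PPB <- 32768L

#' Read and write VOC telemetry CSV files
#'
#' Telemetry rows carry the total-VOC (tVOC) readings from the primary
#' (odor-delivery) and secondary (positive-pressure) chamber inlets, the
#' five valve-state flags, and the active stimulus label, sampled at roughly
#' 260 ms intervals. Readings are validated against the sensor's raw range
#' of 0--32,768 ppb; timestamps must be strictly increasing.
#'
#' @param path CSV path with header
#'   `time_ms,tvoc_primary_ppb,tvoc_secondary_ppb,valve_clean,valve_1,valve_2,valve_3,valve_4,stimulus`.
#' @return `read_telemetry()` returns a data.frame of telemetry records;
#'   `write_telemetry()` returns `path` invisibly. Reading a file written by
#'   `write_telemetry()` reproduces the records exactly.
#' @export
read_telemetry <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TELEMETRY_COLUMNS, names(rec))
  if (length(missing))
    stop("telemetry file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rec <- rec[, TELEMETRY_COLUMNS]
  rec$stimulus <- as.character(rec$stimulus)
  if (nrow(rec) == 0L) return(rec)
  dt <- diff(rec$time_ms)
  if (any(dt <= 0)) {
    row <- which(dt <= 0)[1] + 1L
    stop(sprintf("telemetry time_ms not strictly increasing at row %d", row),
         call. = FALSE)
  }
  for (col in c("tvoc_primary_ppb", "tvoc_secondary_ppb")) {
    bad <- which(rec[[col]] < 0 | rec[[col]] > TVOC_SENSOR_MAX_PPB)
    if (length(bad))
      stop(sprintf("%s out of sensor range [0, %d] at row %d",
                   col, TVOC_SENSOR_MAX_PPB, bad[1]), call. = FALSE)
  }
  rec$stimulus[is.na(rec$stimulus)] <- ""
  rec
}

#' @rdname read_telemetry
#' @param records Telemetry data.frame with the columns listed above.
#' @export
write_telemetry <- function(records, path) {
  missing <- setdiff(TELEMETRY_COLUMNS, names(records))
  if (length(missing))
    stop("telemetry records missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  utils::write.csv(records[, TELEMETRY_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Primary-end reference geometry
#'
#' Defines where the primary (odor-delivery) end of the testing tube sits in
#' pixel space: the tube axis (`"x"` or `"y"`), the pixel coordinate of the
#' inner face of the primary end cap, and the axis direction in which
#' distance from that face increases (+1 or -1).
#'
#' @param axis Tube axis in the video frame, `"x"` or `"y"`.
#' @param origin_px Pixel coordinate of the primary-end inner face.
#' @param direction +1 if distance from the primary end grows with the
#'   coordinate, -1 otherwise.
#' @return A list of class `ohd_primary_ref`.
#' @export
primary_reference <- function(axis = c("x", "y"), origin_px = 0, direction = 1) {
  axis <- match.arg(axis)
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1", call. = FALSE)
  structure(list(axis = axis, origin_px = origin_px, direction = direction),
            class = "ohd_primary_ref")
}

#' Construct a tracking trace
#'
#' A tracking trace bundles per-frame centroid pixel coordinates from an
#' upstream video tracker with the pixel calibration and the primary-end
#' reference geometry needed to convert positions into distances from the
#' odor source.
#'
#' @param frames Data.frame with columns `frame` (0-based, strictly
#'   increasing), `time_s`, `x_px`, `y_px`.
#' @param avg_fps Average frames per second of the recording.
#' @param mm_per_pixel Video calibration, millimetres per pixel.
#' @param primary_ref A [primary_reference()].
#' @return An object of class `ohd_trace`.
#' @export
tracking_trace <- function(frames, avg_fps, mm_per_pixel,
                           primary_ref = primary_reference()) {
  stopifnot(is.data.frame(frames),
            all(c("frame", "time_s", "x_px", "y_px") %in% names(frames)))
  if (anyDuplicated(frames$frame))
    stop("duplicate frame indices in tracking trace", call. = FALSE)
  if (is.unsorted(frames$frame, strictly = TRUE))
    stop("frame indices must be strictly increasing", call. = FALSE)
  if (avg_fps <= 0) stop("avg_fps must be > 0", call. = FALSE)
  if (mm_per_pixel <= 0) stop("mm_per_pixel must be > 0", call. = FALSE)
  structure(list(frames = frames[, c("frame", "time_s", "x_px", "y_px")],
                 avg_fps = avg_fps, mm_per_pixel = mm_per_pixel,
                 primary_ref = primary_ref),
            class = "ohd_trace")
}

#' @export
print.ohd_trace <- function(x, ...) {
  cat(sprintf("Tracking trace: %d frames @ %.3g fps, %.3f mm/px\n",
              nrow(x$frames), x$avg_fps, x$mm_per_pixel))
  invisible(x)
}

#' Read and write tracking-trace CSV files
#'
#' The CSV layout is `frame,time_s,x_px,y_px`; the `time_s` column is
#' optional and, when absent, is derived as `frame / avg_fps` (frames
#' 0-based). Dropped frames are preserved as gaps in the frame index; no
#' interpolation is performed.
#'
#' @param path CSV path.
#' @param mm_per_pixel Video calibration (mm per pixel).
#' @param avg_fps Frames per second; required when the file has no `time_s`
#'   column, otherwise derived from the timestamps when omitted.
#' @param primary_ref A [primary_reference()].
#' @return `read_tracking()` returns an `ohd_trace`; `write_tracking()`
#'   returns `path` invisibly.
#' @export
read_tracking <- function(path, mm_per_pixel, avg_fps = NULL,
                          primary_ref = primary_reference()) {
  fr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "x_px", "y_px")
  missing <- setdiff(need, names(fr))
  if (length(missing))
    stop("tracking file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(fr$frame))
    stop("duplicate frame indices in tracking file", call. = FALSE)
  if (!"time_s" %in% names(fr)) {
    if (is.null(avg_fps))
      stop("avg_fps is required when the file has no time_s column",
           call. = FALSE)
    fr$time_s <- fr$frame / avg_fps
  } else if (is.null(avg_fps)) {
    n <- nrow(fr)
    if (n >= 2L) avg_fps <- (fr$frame[n] - fr$frame[1]) /
        (fr$time_s[n] - fr$time_s[1])
    else avg_fps <- 30
  }
  tracking_trace(fr[, c("frame", "time_s", "x_px", "y_px")],
                 avg_fps = avg_fps, mm_per_pixel = mm_per_pixel,
                 primary_ref = primary_ref)
}

#' @rdname read_tracking
#' @param trace An `ohd_trace`.
#' @export
write_tracking <- function(trace, path) {
  stopifnot(inherits(trace, "ohd_trace"))
  utils::write.csv(trace$frames, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-second VOC summary
#'
#' Averages tVOC readings into left-closed one-second buckets `[k, k+1)`.
#' Buckets with no readings are reported as `NA` (no interpolation).
#'
#' @param records Telemetry data.frame from [read_telemetry()].
#' @param sensor `"primary"` or `"secondary"`.
#' @return Data.frame with columns `second` (bucket start, integer) and
#'   `mean_ppb`, one row per second from 0 to the last observed second.
#' @export
per_second_voc <- function(records, sensor = c("primary", "secondary")) {
  sensor <- match.arg(sensor)
  if (nrow(records) == 0L) stop("telemetry is empty", call. = FALSE)
  col <- if (sensor == "primary") "tvoc_primary_ppb" else "tvoc_secondary_ppb"
  sec <- floor(records$time_ms / 1000)
  means <- tapply(records[[col]], sec, mean)
  all_sec <- 0:max(sec)
  out <- data.frame(second = all_sec, mean_ppb = NA_real_)
  out$mean_ppb[match(as.integer(names(means)), all_sec)] <- as.numeric(means)
  out
}

#' Per-trial VOC summary
#'
#' For each trial window, the mean of the per-second tVOC values whose
#' bucket starts inside the window, and the peak raw reading in the window.
#' Windows entirely outside the telemetry span yield `NA` with a warning.
#'
#' @param records Telemetry data.frame.
#' @param windows Trial windows from [trial_windows()].
#' @param sensor `"primary"` or `"secondary"`.
#' @return Data.frame with `trial`, `stimulus`, `presentation`, `mean_ppb`,
#'   `peak_ppb`.
#' @export
per_trial_voc <- function(records, windows, sensor = c("primary", "secondary")) {
  sensor <- match.arg(sensor)
  col <- if (sensor == "primary") "tvoc_primary_ppb" else "tvoc_secondary_ppb"
  ps <- per_second_voc(records, sensor)
  t_s <- records$time_ms / 1000
  out <- windows[, intersect(c("trial", "stimulus", "presentation"),
                             names(windows)), drop = FALSE]
  out$mean_ppb <- NA_real_
  out$peak_ppb <- NA_real_
  for (i in seq_len(nrow(windows))) {
    lo <- windows$t_start_s[i]; hi <- windows$t_end_s[i]
    in_win <- ps$second >= lo & ps$second < hi & !is.na(ps$mean_ppb)
    raw_in <- t_s >= lo & t_s < hi
    if (!any(raw_in)) {
      warning(sprintf("trial window %d lies outside the telemetry span", i),
              call. = FALSE)
      next
    }
    out$mean_ppb[i] <- mean(ps$mean_ppb[in_win])
    out$peak_ppb[i] <- max(records[[col]][raw_in])
  }
  out
}

#' Screen an odorant bottle for background VOCs
#'
#' Clean, empty bottles are usable only when their tVOC reading relative to
#' baseline air is low; a bottle passes when the summary statistic of its
#' readings (median by default) falls inside the acceptance band, bounds
#' inclusive. The default band of 30--70 ppb reflects typical background
#' levels of acceptable bottles.
#'
#' @param readings_ppb Numeric vector of bottle tVOC readings (ppb, relative
#'   to baseline air).
#' @param low,high Acceptance band (inclusive).
#' @param stat Summary statistic, default [stats::median].
#' @return A list with `pass` (logical), `statistic`, `n`, `low`, `high`.
#' @export
#' @examples
#' screen_bottle(c(45, 50, 55))$pass   # TRUE
#' screen_bottle(c(190, 200, 210))$pass # FALSE
screen_bottle <- function(readings_ppb, low = 30, high = 70,
                          stat = stats::median) {
  if (length(readings_ppb) == 0L)
    stop("no bottle readings supplied", call. = FALSE)
  s <- stat(readings_ppb)
  list(pass = s >= low && s <= high, statistic = s,
       n = length(readings_ppb), low = low, high = high)
}
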