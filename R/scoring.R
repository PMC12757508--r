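#' Zone-and-direction scoring rule
#'
#' Parameters of the automatic investigation-scoring rule: a frame counts as
#' investigating when the centroid lies between `inner_cm` and `outer_cm`
#' from the primary (odor) end of the tube during or after motion toward
#' that end. Centroids closer than `inner_cm` are treated as the animal
#' turning away from the stimulus and never count. Motion direction is
#' estimated from the displacement over a centred window of
#' `motion_window_frames` frames against a dead band of
#' `motion_epsilon_mm`.
#'
#' @param inner_cm Inner zone boundary (cm from the primary end), default 2.
#' @param outer_cm Outer zone boundary (cm), default 6.
#' @param motion_window_frames Frames in the centred displacement window;
#'   `NULL` (default) derives about 0.25 s worth of frames from the trace.
#' @param motion_epsilon_mm Displacement dead band per window (mm), default 2.
#' @param min_bout_s Minimum bout duration kept (seconds), default 0.
#' @return A list of class `ohd_zone_rule`.
#' @export
zone_rule <- function(inner_cm = 2, outer_cm = 6, motion_window_frames = NULL,
                      motion_epsilon_mm = 2, min_bout_s = 0) {
  if (!(inner_cm > 0 && inner_cm < outer_cm))
    stop("need 0 < inner_cm < outer_cm", call. = FALSE)
  if (!is.null(motion_window_frames) && motion_window_frames < 1)
    stop("motion_window_frames must be >= 1", call. = FALSE)
  structure(list(inner_cm = inner_cm, outer_cm = outer_cm,
                 motion_window_frames = motion_window_frames,
                 motion_epsilon_mm = motion_epsilon_mm,
                 min_bout_s = min_bout_s),
            class = "ohd_zone_rule")
}

default_motion_window <- function(rule, avg_fps) {
  if (!is.null(rule$motion_window_frames))
    return(as.integer(rule$motion_window_frames))
  max(2L, as.integer(round(0.25 * avg_fps)))
}

#' Convert a real-world distance to a pixel threshold
#'
#' Returns the smallest integer pixel count `p` such that
#' `p * mm_per_pixel >= 10 * distance_cm` (ceiling rule). At the usual
#' 0.458 mm/pixel calibration this maps the 2 cm and 6 cm zone boundaries to
#' 44 and 132 pixels.
#'
#' @param distance_cm Distance in centimetres (>= 0).
#' @param mm_per_pixel Calibration (> 0).
#' @return Integer pixel count.
#' @export
#' @examples
#' cm_to_px(2, 0.458)  # 44
#' cm_to_px(6, 0.458)  # 132
cm_to_px <- function(distance_cm, mm_per_pixel) {
  if (mm_per_pixel <= 0) stop("mm_per_pixel must be > 0", call. = FALSE)
  if (any(distance_cm < 0)) stop("distance_cm must be >= 0", call. = FALSE)
  as.integer(ceiling(round(10 * distance_cm / mm_per_pixel, 9)))
}

#' Per-frame distance from the primary end
#'
#' Projects each centroid onto the tube axis defined by the trace's
#' primary-end reference and converts the signed distance to millimetres via
#' the calibration; positions behind the reference face are clipped to 0.
#'
#' @param trace An `ohd_trace` with `primary_ref` set.
#' @return Numeric vector of distances (mm), one per frame.
#' @export
distance_from_primary <- function(trace) {
  stopifnot(inherits(trace, "ohd_trace"))
  ref <- trace$primary_ref
  if (is.null(ref)) stop("trace has no primary_ref", call. = FALSE)
  coord <- if (ref$axis == "x") trace$frames$x_px else trace$frames$y_px
  d_px <- ref$direction * (coord - ref$origin_px)
  pmax(0, d_px * trace$mm_per_pixel)
}

#' Label per-frame motion direction
#'
#' Displacement over a centred window of `window_frames` frames (clamped at
#' the trace edges): `toward` when the distance to the primary end shrinks
#' by more than `epsilon_mm` across the window, `away` when it grows by more
#' than `epsilon_mm`, `stationary` otherwise.
#'
#' @param distance_mm Per-frame distance series (mm).
#' @param window_frames Window length in frames (>= 1).
#' @param epsilon_mm Dead-band displacement (mm).
#' @return Character vector of labels in `{"toward","away","stationary"}`.
#' @export
motion_labels <- function(distance_mm, window_frames, epsilon_mm = 2) {
  n <- length(distance_mm)
  if (n < window_frames)
    stop("trace shorter than the motion window", call. = FALSE)
  lo <- pmax(1L, seq_len(n) - floor((window_frames - 1) / 2))
  hi <- pmin(n, seq_len(n) + ceiling((window_frames - 1) / 2))
  delta <- distance_mm[hi] - distance_mm[lo]
  ifelse(delta < -epsilon_mm, "toward",
         ifelse(delta > epsilon_mm, "away", "stationary"))
}

# carry the most recent non-stationary label forward; leading stationary
# frames have no direction yet and stay NA
carry_motion_labels <- function(labels) {
  ns <- labels != "stationary"
  idx <- which(ns)
  if (length(idx) == 0L) return(rep(NA_character_, length(labels)))
  pos <- findInterval(seq_along(labels), idx)
  out <- rep(NA_character_, length(labels))
  out[pos > 0L] <- labels[idx[pos[pos > 0L]]]
  out
}

#' Detect investigation bouts in a tracking trace
#'
#' Applies the zone-and-direction rule frame by frame: a frame is
#' investigating iff its distance from the primary end lies in
#' `[inner_cm, outer_cm]` and the most recent non-stationary motion label is
#' `toward` (stationary frames inherit the preceding direction; an initial
#' stationary run never counts). Frames closer than `inner_cm` are treated
#' as turning away and never count. Maximal runs of investigating frames
#' become bouts; bouts shorter than `min_bout_s` are dropped.
#'
#' @param trace An `ohd_trace`.
#' @param rule A [zone_rule()].
#' @return Data.frame of bouts with `start_s`, `end_s`, `n_frames`,
#'   `source = "auto"`; `end_s` is the start time of the frame after the
#'   last investigating frame, so `end_s - start_s = n_frames / avg_fps` on
#'   a gap-free trace.
#' @export
detect_bouts <- function(trace, rule = zone_rule()) {
  stopifnot(inherits(trace, "ohd_trace"), inherits(rule, "ohd_zone_rule"))
  d <- distance_from_primary(trace)
  w <- default_motion_window(rule, trace$avg_fps)
  labels <- motion_labels(d, w, rule$motion_epsilon_mm)
  investigating <- investigating_frames(d, labels,
                                        inner_mm = 10 * rule$inner_cm,
                                        outer_mm = 10 * rule$outer_cm)
  bouts_from_flags(investigating, trace$frames$time_s, trace$avg_fps,
                   min_bout_s = rule$min_bout_s)
}

investigating_frames <- function(distance_mm, labels, inner_mm, outer_mm) {
  eff <- carry_motion_labels(labels)
  in_zone <- distance_mm >= inner_mm & distance_mm <= outer_mm
  in_zone & !is.na(eff) & eff == "toward"
}

bouts_from_flags <- function(flags, time_s, avg_fps, min_bout_s = 0) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_frames = integer(0), source = character(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(start_s = time_s[starts],
                    end_s = time_s[ends] + 1 / avg_fps,
                    n_frames = ends - starts + 1L,
                    source = "auto", stringsAsFactors = FALSE)
  out[out$end_s - out$start_s >= min_bout_s - 1e-9, , drop = FALSE]
}

#' Convert a frame count to seconds
#'
#' @param n_frames Number of frames.
#' @param avg_fps Average frames per second (> 0).
#' @return `n_frames / avg_fps`, in seconds.
#' @export
frames_to_seconds <- function(n_frames, avg_fps) {
  if (avg_fps <= 0) stop("avg_fps must be > 0", call. = FALSE)
  n_frames / avg_fps
}

#' Tally investigation per trial
#'
#' Intersects time-ordered, non-overlapping investigation bouts with the
#' trial windows and sums the overlap per trial; bouts straddling a window
#' boundary are split between the neighbouring trials.
#'
#' @param bouts Bout data.frame (`start_s`, `end_s`, optional `source`).
#' @param windows Trial windows from [trial_windows()].
#' @param subject,session Identifiers copied into the output.
#' @param method `"auto"` or `"manual"`.
#' @return Data.frame of trial scores: `subject`, `session`, `stimulus`,
#'   `presentation`, `method`, `duration_s` (bounded by the window length).
#' @export
score_trials <- function(bouts, windows, subject = "S1", session = 1L,
                         method = c("auto", "manual")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(windows))
  if (nrow(bouts)) {
    o <- order(bouts$start_s)
    bouts <- bouts[o, , drop = FALSE]
    if (any(bouts$end_s <= bouts$start_s))
      stop("bout with end_s <= start_s", call. = FALSE)
    if (nrow(bouts) > 1L &&
        any(bouts$start_s[-1] < bouts$end_s[-nrow(bouts)] - 1e-9))
      stop("overlapping bouts", call. = FALSE)
  }
  dur <- vapply(seq_len(nrow(windows)), function(i) {
    lo <- windows$t_start_s[i]; hi <- windows$t_end_s[i]
    if (nrow(bouts) == 0L) return(0)
    ov <- pmin(bouts$end_s, hi) - pmax(bouts$start_s, lo)
    min(sum(pmax(0, ov)), hi - lo)
  }, numeric(1))
  data.frame(subject = subject, session = session,
             stimulus = if ("stimulus" %in% names(windows))
               windows$stimulus else NA_character_,
             presentation = if ("presentation" %in% names(windows))
               windows$presentation else NA_integer_,
             method = method, duration_s = dur,
             stringsAsFactors = FALSE)
}

#' Import manually scored investigation periods
#'
#' Normalizes hand-annotated investigation intervals so they can flow
#' through [score_trials()] like automatic bouts: rows are ordered by start
#' time and overlapping rows are merged into their union.
#'
#' @param annotation_rows Data.frame with columns `start_s`, `end_s`.
#' @return Bout data.frame with `start_s`, `end_s`, `source = "manual"`.
#' @export
import_manual_bouts <- function(annotation_rows) {
  stopifnot(is.data.frame(annotation_rows))
  if (nrow(annotation_rows) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      source = character(0), stringsAsFactors = FALSE))
  bad <- which(annotation_rows$end_s <= annotation_rows$start_s)
  if (length(bad))
    stop(sprintf("annotation row %d has end_s <= start_s", bad[1]),
         call. = FALSE)
  o <- order(annotation_rows$start_s, annotation_rows$end_s)
  s <- annotation_rows$start_s[o]; e <- annotation_rows$end_s[o]
  ms <- s[1]; me <- e[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= me) me <- max(me, e[i])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  data.frame(start_s = out_s, end_s = out_e, source = "manual",
             stringsAsFactors = FALSE)
}
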