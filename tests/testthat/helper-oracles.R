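# Independent brute-force oracles used across the suite. These are written
# as explicit per-element loops so they share no code path with the
# vectorized implementations they check.

# Open valve at each queried time, by replaying the event log from scratch.
# The clean valve (0) is normally open before any event.
oracle_open_valve <- function(events, times) {
  vapply(times, function(t) {
    open <- c(`0` = TRUE, `1` = FALSE, `2` = FALSE, `3` = FALSE, `4` = FALSE)
    rows <- events[events$time_s <= t, , drop = FALSE]
    if (nrow(rows)) {
      for (j in seq_len(nrow(rows)))
        open[as.character(rows$valve_id[j])] <- rows$state[j] == "open"
    }
    ids <- as.integer(names(open)[open])
    if (length(ids) == 1L) ids else NA_integer_
  }, integer(1))
}

# Frame-by-frame application of the zone-and-direction investigation rule.
oracle_investigating <- function(d_mm, window_frames, epsilon_mm,
                                 inner_mm, outer_mm) {
  n <- length(d_mm)
  lab <- character(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - floor((window_frames - 1) / 2))
    hi <- min(n, i + ceiling((window_frames - 1) / 2))
    delta <- d_mm[hi] - d_mm[lo]
    lab[i] <- if (delta < -epsilon_mm) "toward"
      else if (delta > epsilon_mm) "away" else "stationary"
  }
  inv <- logical(n)
  last <- NA_character_
  for (i in seq_len(n)) {
    if (lab[i] != "stationary") last <- lab[i]
    inv[i] <- !is.na(last) && last == "toward" &&
      d_mm[i] >= inner_mm && d_mm[i] <= outer_mm
  }
  inv
}

# Per-frame flags implied by a bout table on a regular frame grid.
flags_from_bouts <- function(bouts, time_s) {
  flags <- rep(FALSE, length(time_s))
  if (nrow(bouts) == 0L) return(flags)
  for (b in seq_len(nrow(bouts)))
    flags <- flags | (time_s >= bouts$start_s[b] - 1e-9 &
                        time_s < bouts$end_s[b] - 1e-9)
  flags
}

# Sum of bout/window overlaps computed interval by interval.
oracle_trial_duration <- function(bouts, lo, hi) {
  total <- 0
  if (nrow(bouts)) {
    for (b in seq_len(nrow(bouts))) {
      s <- max(bouts$start_s[b], lo)
      e <- min(bouts$end_s[b], hi)
      if (e > s) total <- total + (e - s)
    }
  }
  total
}

# Build an ohd_trace directly from a distance-from-primary series (mm).
trace_from_distance <- function(d_mm, fps = 30, mm_per_pixel = 0.458) {
  n <- length(d_mm)
  tracking_trace(
    data.frame(frame = seq_len(n) - 1L, time_s = (seq_len(n) - 1L) / fps,
               x_px = d_mm / mm_per_pixel, y_px = 0),
    avg_fps = fps, mm_per_pixel = mm_per_pixel,
    primary_ref = primary_reference("x", 0, 1)
  )
}

# Random bounded-walk distance series spanning the zone and its surrounds.
random_distance_series <- function(n, start = 80, step_sd = 6, L = 152.4) {
  d <- numeric(n)
  x <- start
  for (i in seq_len(n)) {
    x <- x + stats::rnorm(1, 0, step_sd)
    if (x < 0) x <- -x
    if (x > L) x <- 2 * L - x
    d[i] <- x
  }
  d
}

small_schedule <- function(n_stim = 1L, presentations = 1L, on_s = 10,
                           off_s = 10) {
  stimuli <- utils::head(ohd_default_stimuli()[c(2, 3, 4, 1), ], n_stim)
  build_ohd_schedule(paradigm_config(
    stimuli = stimuli, presentations_per_stimulus = presentations,
    on_s = on_s, off_s = off_s))
}
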