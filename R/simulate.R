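#' VOC simulation parameters
#'
#' First-order rise/decay kinetics for the chamber-inlet tVOC signal.
#' During a valve-ON period the primary-sensor concentration relaxes toward
#' the stimulus plateau with time constant `tau_rise_s`; during OFF it
#' relaxes back toward baseline with `tau_decay_s`. Readings are integer
#' ppb, capped at `cap_ppb` (sensor saturation, ~29,000 ppb) within the raw
#' 0--32,768 ppb range, sampled every `sample_interval_ms`. Odorant plateaus
#' default to 11,500 ppb, the middle of the 10,000--13,000 ppb dilution
#' target band; the clean stimulus stays at baseline.
#'
#' @param baseline_ppb Baseline air reading (ppb).
#' @param plateau_ppb Stimulus plateau (ppb): a scalar applied to every
#'   non-clean stimulus, or a named vector keyed by stimulus label.
#' @param tau_rise_s,tau_decay_s Rise/decay time constants (s).
#' @param noise_sd_ppb Gaussian read-noise SD (ppb); 0 for noiseless.
#' @param cap_ppb Saturation cap (ppb).
#' @param sensor_max_ppb Raw sensor maximum (ppb).
#' @param sample_interval_ms Sampling interval (ms).
#' @return A list of class `ohd_voc_params`.
#' @export
voc_params <- function(baseline_ppb = 50, plateau_ppb = 11500,
                       tau_rise_s = 10, tau_decay_s = 20, noise_sd_ppb = 5,
                       cap_ppb = 29000, sensor_max_ppb = 32768,
                       sample_interval_ms = 260) {
  if (any(plateau_ppb <= baseline_ppb))
    stop("plateau_ppb must exceed baseline_ppb", call. = FALSE)
  if (any(plateau_ppb > sensor_max_ppb) || cap_ppb > sensor_max_ppb)
    stop("plateau/cap cannot exceed the sensor maximum", call. = FALSE)
  if (tau_rise_s <= 0 || tau_decay_s <= 0)
    stop("time constants must be > 0", call. = FALSE)
  structure(list(baseline_ppb = baseline_ppb, plateau_ppb = plateau_ppb,
                 tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
                 noise_sd_ppb = noise_sd_ppb, cap_ppb = cap_ppb,
                 sensor_max_ppb = sensor_max_ppb,
                 sample_interval_ms = sample_interval_ms),
            class = "ohd_voc_params")
}

plateau_for <- function(params, label, category) {
  if (category == "clean") return(params$baseline_ppb)
  p <- params$plateau_ppb
  if (!is.null(names(p)) && label %in% names(p)) return(unname(p[label]))
  unname(p[1])
}

#' Behavioural agent parameters
#'
#' A mean-reverting (Ornstein--Uhlenbeck-type) random walk along the axis of
#' the 6-inch testing tube stands in for the mouse centroid. Once per second
#' the walk's target is drawn: the attraction point near the odor source
#' with probability `min(1, attract_scale * salience_s * r^(p-1))` during a
#' trial of stimulus `s` at presentation `p`, otherwise the rest point at
#' the far half of the tube. The per-presentation multiplier
#' `habituation_ratio` (r) produces habituation; the salience ordering
#' (clean lowest, social highest) produces dishabituation into more salient
#' stimuli.
#'
#' @param tube_length_mm Tube length (mm); default 152.4 (6 inches).
#' @param salience Named non-negative weights per stimulus label.
#' @param habituation_ratio Per-presentation salience multiplier r in (0,1].
#' @param attract_scale Scale mapping salience weights to attraction
#'   probabilities (kept small enough that defaults stay below 1, so the
#'   probability remains proportional to salience).
#' @param ou_theta Mean-reversion rate (1/s).
#' @param ou_sigma Diffusion scale (mm per sqrt(s)).
#' @param attract_point_mm Attraction target (mm from the primary end);
#'   default 30, inside the 20--60 mm investigation zone.
#' @param rest_point_mm Rest target (mm); default 90, outside the zone.
#' @param fps Frames per second of the emitted trace.
#' @return A list of class `ohd_agent_params`.
#' @export
agent_params <- function(tube_length_mm = 152.4,
                         salience = c(CLN = 0.05, NSA = 1, NSB = 1, SOC = 2.5),
                         habituation_ratio = 0.6, attract_scale = 0.3,
                         ou_theta = 2, ou_sigma = 25,
                         attract_point_mm = 30, rest_point_mm = 90,
                         fps = 30) {
  if (!(habituation_ratio > 0 && habituation_ratio <= 1))
    stop("habituation_ratio must be in (0, 1]", call. = FALSE)
  if (!(attract_point_mm > 0 && attract_point_mm < tube_length_mm))
    stop("attract_point_mm must lie inside the tube", call. = FALSE)
  if (any(salience < 0)) stop("salience weights must be >= 0", call. = FALSE)
  structure(list(tube_length_mm = tube_length_mm, salience = salience,
                 habituation_ratio = habituation_ratio,
                 attract_scale = attract_scale,
                 ou_theta = ou_theta, ou_sigma = ou_sigma,
                 attract_point_mm = attract_point_mm,
                 rest_point_mm = rest_point_mm, fps = fps),
            class = "ohd_agent_params")
}

#' Simulate VOC telemetry for a session
#'
#' Generates primary/secondary tVOC readings at the configured sampling
#' interval. The noiseless primary concentration follows
#' `C(t) = target + (C(t0) - target) * exp(-(t - t0)/tau)` within each valve
#' segment (target = stimulus plateau with `tau_rise_s` during ON, baseline
#' with `tau_decay_s` during OFF), which reduces to the familiar
#' `B + (P - B)(1 - exp(-(t - t0)/tau))` rise when the segment starts from
#' baseline. Readings are rounded, floored at 0 and capped at the
#' saturation level; the secondary sensor stays at baseline plus noise.
#'
#' @param schedule An `ohd_schedule`.
#' @param params A [voc_params()].
#' @param seed Integer seed.
#' @return Telemetry data.frame in the [read_telemetry()] layout.
#' @export
simulate_voc_telemetry <- function(schedule, params = voc_params(), seed = 1L) {
  stopifnot(inherits(schedule, "ohd_schedule"),
            inherits(params, "ohd_voc_params"))
  set.seed(seed)
  t_ms <- seq(0, schedule$total_duration_s * 1000 - 1,
              by = params$sample_interval_ms)
  t_s <- t_ms / 1000
  n <- length(t_s)
  conc <- numeric(n)
  valve <- integer(n)  # open valve id at each sample
  stim <- character(n)
  tr <- schedule$trials
  C0 <- params$baseline_ppb
  for (i in seq_len(nrow(tr))) {
    plateau <- plateau_for(params, tr$stimulus[i], tr$category[i])
    on_idx <- which(t_s >= tr$t_start_s[i] & t_s < tr$t_on_end_s[i])
    conc[on_idx] <- plateau + (C0 - plateau) *
      exp(-(t_s[on_idx] - tr$t_start_s[i]) / params$tau_rise_s)
    C_close <- plateau + (C0 - plateau) *
      exp(-(tr$t_on_end_s[i] - tr$t_start_s[i]) / params$tau_rise_s)
    off_idx <- which(t_s >= tr$t_on_end_s[i] & t_s < tr$t_end_s[i])
    conc[off_idx] <- params$baseline_ppb + (C_close - params$baseline_ppb) *
      exp(-(t_s[off_idx] - tr$t_on_end_s[i]) / params$tau_decay_s)
    C0 <- params$baseline_ppb + (C_close - params$baseline_ppb) *
      exp(-(tr$t_end_s[i] - tr$t_on_end_s[i]) / params$tau_decay_s)
    in_trial <- t_s >= tr$t_start_s[i] & t_s < tr$t_end_s[i]
    stim[in_trial] <- tr$stimulus[i]
    valve[t_s >= tr$t_start_s[i] & t_s < tr$t_on_end_s[i]] <- tr$valve_id[i]
  }
  clip <- function(x) pmin(params$cap_ppb, pmax(0, round(x)))
  primary <- clip(conc + stats::rnorm(n, 0, params$noise_sd_ppb))
  secondary <- clip(params$baseline_ppb + stats::rnorm(n, 0, params$noise_sd_ppb))
  data.frame(time_ms = as.integer(t_ms),
             tvoc_primary_ppb = as.integer(primary),
             tvoc_secondary_ppb = as.integer(secondary),
             valve_clean = as.integer(valve == 0L),
             valve_1 = as.integer(valve == 1L),
             valve_2 = as.integer(valve == 2L),
             valve_3 = as.integer(valve == 3L),
             valve_4 = as.integer(valve == 4L),
             stimulus = stim, stringsAsFactors = FALSE)
}

#' Simulate a mouse centroid trace with ground-truth bouts
#'
#' Evolves the axial position as a discrete-time mean-reverting walk
#' `x[k+1] = x[k] + theta * (mu[k] - x[k]) * dt + sigma * sqrt(dt) * xi[k]`,
#' reflected into the tube, with the per-second target `mu` drawn as
#' described in [agent_params()]. Ground-truth investigation bouts are
#' obtained by applying the zone-and-direction rule to the exact simulated
#' positions before pixel export; the exported trace carries pixel
#' coordinates (3-decimal sub-pixel precision, as commercial trackers emit)
#' with small lateral jitter, so re-scoring the exported trace exercises the
#' full read/convert/score path.
#'
#' @param schedule An `ohd_schedule`.
#' @param params An [agent_params()].
#' @param zone A [zone_rule()] (used for the ground truth).
#' @param seed Integer seed.
#' @param mm_per_pixel Calibration used for the pixel export.
#' @return A list with `trace` (an `ohd_trace`), `truth_bouts` (data.frame
#'   like [detect_bouts()] output with `source = "truth"`), and `x_mm`
#'   (exact axial positions).
#' @export
simulate_agent_trace <- function(schedule, params = agent_params(),
                                 zone = zone_rule(), seed = 1L,
                                 mm_per_pixel = 0.458) {
  stopifnot(inherits(schedule, "ohd_schedule"),
            inherits(params, "ohd_agent_params"))
  set.seed(seed)
  fps <- params$fps
  total_s <- schedule$total_duration_s
  n <- as.integer(round(total_s * fps))
  tr <- schedule$trials
  # per-second attraction targets
  secs <- 0:(ceiling(total_s) - 1L)
  trial_of_sec <- findInterval(secs, tr$t_start_s)
  w <- numeric(length(secs))
  in_trial <- trial_of_sec >= 1L & secs < total_s
  idx <- trial_of_sec[in_trial]
  sal <- params$salience[tr$stimulus[idx]]
  sal[is.na(sal)] <- 0
  w[in_trial] <- unname(sal) *
    params$habituation_ratio^(tr$presentation[idx] - 1L) * params$attract_scale
  attracted <- stats::runif(length(secs)) < pmin(1, w)
  mu_sec <- ifelse(attracted, params$attract_point_mm, params$rest_point_mm)
  # frame-level walk
  dt <- 1 / fps
  xi <- stats::rnorm(n)
  sd_step <- params$ou_sigma * sqrt(dt)
  theta_dt <- params$ou_theta * dt
  L <- params$tube_length_mm
  x <- numeric(n)
  xk <- params$rest_point_mm
  for (k in seq_len(n)) {
    mu <- mu_sec[floor((k - 1L) * dt) + 1L]
    xk <- xk + theta_dt * (mu - xk) + sd_step * xi[k]
    if (xk < 0) xk <- -xk
    if (xk > L) xk <- 2 * L - xk
    if (xk < 0) xk <- 0
    x[k] <- xk
  }
  time_s <- (seq_len(n) - 1L) / fps
  # ground truth from the exact positions (distance from primary end = x)
  wlen <- default_motion_window(zone, fps)
  labels <- motion_labels(x, wlen, zone$motion_epsilon_mm)
  flags <- investigating_frames(x, labels, 10 * zone$inner_cm,
                                10 * zone$outer_cm)
  truth <- bouts_from_flags(flags, time_s, fps, min_bout_s = zone$min_bout_s)
  if (nrow(truth)) truth$source <- "truth"
  y_jitter <- stats::rnorm(n, 0, 2)
  frames <- data.frame(frame = seq_len(n) - 1L, time_s = time_s,
                       x_px = round(x / mm_per_pixel, 3),
                       y_px = round(35 + y_jitter, 3))
  trace <- tracking_trace(frames, avg_fps = fps, mm_per_pixel = mm_per_pixel,
                          primary_ref = primary_reference("x", 0, 1))
  list(trace = trace, truth_bouts = truth, x_mm = x)
}

#' Expected salience per (stimulus, presentation)
#'
#' The generator's ground-truth effect structure: each presentation of
#' stimulus `s` carries expected salience `salience_s * r^(p-1)`.
#' Habituation differences are negative whenever `r < 1`; dishabituation
#' into the next stimulus is positive whenever its salience exceeds the
#' previous stimulus' salience times `r^2`.
#'
#' @param params An [agent_params()].
#' @param config A [paradigm_config()].
#' @return Data.frame with `stimulus`, `presentation`, `expected_salience`.
#' @export
true_effect_table <- function(params = agent_params(),
                              config = paradigm_config()) {
  stim <- config$stimuli$label
  npres <- config$presentations_per_stimulus
  out <- expand.grid(presentation = seq_len(npres), stimulus = stim,
                     stringsAsFactors = FALSE)[, c("stimulus", "presentation")]
  sal <- params$salience[out$stimulus]
  sal[is.na(sal)] <- 0
  out$expected_salience <- unname(sal) *
    params$habituation_ratio^(out$presentation - 1L)
  out
}

#' Generate a complete synthetic session on disk
#'
#' Builds the schedule, valve event log, VOC telemetry, tracking trace and
#' ground-truth bouts for one subject, writes them as plain-text fixtures
#' (`events.csv`, `telemetry.csv`, `trace.csv`, `truth_bouts.csv`,
#' `truth_params.json`), and returns all components. Component seeds are
#' derived from the master seed by fixed offsets (+1 telemetry, +2 agent).
#'
#' @param config A [paradigm_config()].
#' @param voc A [voc_params()].
#' @param agent An [agent_params()].
#' @param zone A [zone_rule()].
#' @param seed Master integer seed.
#' @param outdir Output directory (created if needed).
#' @param mm_per_pixel Calibration for the trace export.
#' @return Invisibly, a list with `schedule`, `events`, `telemetry`,
#'   `trace`, `truth_bouts`, `truth`, `windows`, `paths`, `seeds`.
#' @export
generate_session <- function(config = paradigm_config(), voc = voc_params(),
                             agent = agent_params(), zone = zone_rule(),
                             seed = 1L, outdir = tempfile("ohd_session_"),
                             mm_per_pixel = 0.458) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list(master = seed, telemetry = seed + 1L, agent = seed + 2L)
  schedule <- build_ohd_schedule(config)
  events <- schedule_to_valve_events(schedule)
  windows <- trial_windows(events, config$on_s, config$off_s,
                           schedule = schedule)
  telemetry <- simulate_voc_telemetry(schedule, voc, seed = seeds$telemetry)
  sim <- simulate_agent_trace(schedule, agent, zone, seed = seeds$agent,
                              mm_per_pixel = mm_per_pixel)
  paths <- list(
    events = file.path(outdir, "events.csv"),
    telemetry = file.path(outdir, "telemetry.csv"),
    trace = file.path(outdir, "trace.csv"),
    truth_bouts = file.path(outdir, "truth_bouts.csv"),
    truth_params = file.path(outdir, "truth_params.json")
  )
  write_valve_events(events, paths$events)
  write_telemetry(telemetry, paths$telemetry)
  write_tracking(sim$trace, paths$trace)
  utils::write.csv(sim$truth_bouts, paths$truth_bouts, row.names = FALSE,
                   quote = FALSE)
  truth <- list(
    seeds = seeds,
    mm_per_pixel = mm_per_pixel,
    fps = agent$fps,
    voc = unclass(voc),
    agent = unclass(agent),
    zone = unclass(zone),
    expected_salience = true_effect_table(agent, config)
  )
  jsonlite::write_json(truth, paths$truth_params, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(schedule = schedule, events = events, telemetry = telemetry,
                 trace = sim$trace, truth_bouts = sim$truth_bouts,
                 truth = truth, windows = windows, paths = paths,
                 seeds = seeds))
}

#' Simulate and score a cohort of subjects
#'
#' Runs the trajectory generator and the automatic scorer for `n_subjects`
#' independent subjects under one paradigm and returns the stacked
#' trial-score table, ready for [habituation_diffs()] / [ohd_effects()].
#'
#' @param n_subjects Number of subjects.
#' @param config A [paradigm_config()].
#' @param agent An [agent_params()].
#' @param zone A [zone_rule()].
#' @param seed Master integer seed; subject i uses `seed + i`.
#' @param mm_per_pixel Calibration for the exported traces.
#' @return Trial-score data.frame across all subjects.
#' @export
simulate_cohort_scores <- function(n_subjects = 24L,
                                   config = paradigm_config(),
                                   agent = agent_params(),
                                   zone = zone_rule(), seed = 1L,
                                   mm_per_pixel = 0.458) {
  schedule <- build_ohd_schedule(config)
  windows <- trial_windows(NULL, config$on_s, config$off_s,
                           schedule = schedule)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sim <- simulate_agent_trace(schedule, agent, zone, seed = seed + i,
                                mm_per_pixel = mm_per_pixel)
    bouts <- detect_bouts(sim$trace, zone)
    out[[i]] <- score_trials(bouts, windows,
                             subject = sprintf("S%02d", i), session = 1L,
                             method = "auto")
  }
  do.call(rbind, out)
}
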