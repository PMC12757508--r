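#' Default OHD stimulus panel
#'
#' The four-stimulus panel used in the olfactory habituation/dishabituation
#' (OHD) paradigm: a clean-air control (CLN), two nonsocial odorants
#' (NSA, NSB) and a same-sex social (urine) odor (SOC). Valve 0 is the
#' normally-open clean-air valve; odorant valves are numbered 1--4, with the
#' social stimulus reserved for the final odorant valve to limit
#' cross-contamination of social odors.
#'
#' @return A data.frame with columns `label`, `valve_id` and `category`
#'   (one of `"clean"`, `"nonsocial"`, `"social"`).
#' @export
#' @examples
#' ohd_default_stimuli()
ohd_default_stimuli <- function() {
  data.frame(
    label    = c("CLN", "NSA", "NSB", "SOC"),
    valve_id = c(0L, 1L, 2L, 4L),
    category = c("clean", "nonsocial", "nonsocial", "social"),
    stringsAsFactors = FALSE
  )
}

validate_stimuli <- function(stimuli) {
  if (!is.data.frame(stimuli) || nrow(stimuli) == 0L)
    stop("`stimuli` must be a non-empty data.frame", call. = FALSE)
  required <- c("label", "valve_id", "category")
  missing <- setdiff(required, names(stimuli))
  if (length(missing))
    stop("`stimuli` is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(stimuli$valve_id))
    stop("valve_id must be unique within a paradigm", call. = FALSE)
  if (!all(stimuli$valve_id %in% 0:4))
    stop("valve_id must be an integer in 0..4", call. = FALSE)
  if (!all(stimuli$category %in% c("clean", "nonsocial", "social")))
    stop("category must be one of clean/nonsocial/social", call. = FALSE)
  bad <- stimuli$category == "clean" & stimuli$valve_id != 0L
  if (any(bad))
    stop("the clean stimulus must map to valve_id 0", call. = FALSE)
  invisible(stimuli)
}

#' Paradigm configuration
#'
#' Bundles the timing parameters of an OHD session: the ordered stimulus
#' panel, the number of sequential presentations per stimulus, and the valve
#' ON / OFF durations that make up each 2-minute trial. Defaults reproduce
#' the standard automated paradigm: 60 s ON, 60 s OFF, three presentations
#' of each of four stimuli (12 trials, 24 min), preceded by 5 min of chamber
#' habituation and six clean-valve noise-habituation trials.
#'
#' @param stimuli Ordered stimulus panel; see [ohd_default_stimuli()].
#' @param presentations_per_stimulus Sequential presentations per stimulus.
#' @param on_s Valve ON duration (seconds) per trial.
#' @param off_s Valve OFF (clean-air flush) duration per trial.
#' @param chamber_habituation_s Chamber habituation before testing (seconds).
#' @param noise_habituation_trials Clean-valve trials of noise habituation.
#' @return An object of class `ohd_paradigm`.
#' @export
paradigm_config <- function(stimuli = ohd_default_stimuli(),
                            presentations_per_stimulus = 3L,
                            on_s = 60,
                            off_s = 60,
                            chamber_habituation_s = 300,
                            noise_habituation_trials = 6L) {
  validate_stimuli(stimuli)
  if (presentations_per_stimulus < 1L)
    stop("presentations_per_stimulus must be >= 1", call. = FALSE)
  if (on_s <= 0) stop("on_s must be > 0", call. = FALSE)
  if (off_s < 0) stop("off_s must be >= 0", call. = FALSE)
  if (noise_habituation_trials < 0L)
    stop("noise_habituation_trials must be >= 0", call. = FALSE)
  structure(
    list(
      stimuli = stimuli,
      presentations_per_stimulus = as.integer(presentations_per_stimulus),
      on_s = as.numeric(on_s),
      off_s = as.numeric(off_s),
      chamber_habituation_s = as.numeric(chamber_habituation_s),
      noise_habituation_trials = as.integer(noise_habituation_trials)
    ),
    class = "ohd_paradigm"
  )
}

#' Build the trial schedule for an OHD session
#'
#' Lays out one trial per (stimulus, presentation) pair, stimuli in panel
#' order with consecutive presentations, starting at t = 0. Trials are
#' contiguous: each spans `on_s + off_s` seconds from its valve onset to the
#' next trial's onset.
#'
#' @param config A [paradigm_config()].
#' @return An object of class `ohd_schedule`: a list with `trials` (a
#'   data.frame with columns `trial`, `stimulus`, `valve_id`, `category`,
#'   `presentation`, `t_start_s`, `t_on_end_s`, `t_end_s`), `on_s`, `off_s`
#'   and `total_duration_s`.
#' @export
#' @examples
#' sched <- build_ohd_schedule(paradigm_config())
#' nrow(sched$trials)        # 12 trials
#' sched$total_duration_s    # 1440 s = 24 min
build_ohd_schedule <- function(config) {
  if (!inherits(config, "ohd_paradigm"))
    stop("`config` must be created with paradigm_config()", call. = FALSE)
  stim <- config$stimuli
  npres <- config$presentations_per_stimulus
  n_trials <- nrow(stim) * npres
  period <- config$on_s + config$off_s
  idx <- seq_len(n_trials)
  stim_idx <- rep(seq_len(nrow(stim)), each = npres)
  t_start <- (idx - 1) * period
  trials <- data.frame(
    trial = idx,
    stimulus = stim$label[stim_idx],
    valve_id = stim$valve_id[stim_idx],
    category = stim$category[stim_idx],
    presentation = rep(seq_len(npres), times = nrow(stim)),
    t_start_s = t_start,
    t_on_end_s = t_start + config$on_s,
    t_end_s = t_start + period,
    stringsAsFactors = FALSE
  )
  structure(
    list(trials = trials, on_s = config$on_s, off_s = config$off_s,
         total_duration_s = n_trials * period),
    class = "ohd_schedule"
  )
}

#' @export
print.ohd_schedule <- function(x, ...) {
  cat(sprintf("OHD schedule: %d trials, %.0f s total (%.1f min)\n",
              nrow(x$trials), x$total_duration_s, x$total_duration_s / 60))
  print(utils::head(x$trials, 12L))
  invisible(x)
}

#' Emit the valve event log implied by a schedule
#'
#' The apparatus feeds air through exactly one valve at a time: the trial's
#' odorant valve during its ON period and the clean-air valve (id 0)
#' otherwise. Clean-stimulus trials therefore produce no transitions (the
#' clean valve simply stays open). Events are `(time_s, valve_id, state)`
#' rows; paired close/open rows at the same instant represent the
#' simultaneous switch between valves.
#'
#' @param schedule An `ohd_schedule`.
#' @return A data.frame with columns `time_s`, `valve_id`, `state`
#'   (`"open"`/`"closed"`), time-ordered with the first event at time 0.
#' @export
schedule_to_valve_events <- function(schedule) {
  stopifnot(inherits(schedule, "ohd_schedule"))
  tr <- schedule$trials
  time_s <- numeric(0); valve <- integer(0); state <- character(0)
  add <- function(t, v, s) {
    time_s <<- c(time_s, t); valve <<- c(valve, v); state <<- c(state, s)
  }
  cur <- 0L  # clean valve normally open
  for (i in seq_len(nrow(tr))) {
    v <- tr$valve_id[i]
    if (v != cur) {
      add(tr$t_start_s[i], cur, "closed")
      add(tr$t_start_s[i], v, "open")
      cur <- v
    }
    if (cur != 0L) {
      add(tr$t_on_end_s[i], cur, "closed")
      add(tr$t_on_end_s[i], 0L, "open")
      cur <- 0L
    }
  }
  if (length(time_s) == 0L || time_s[1] > 0)
    { time_s <- c(0, time_s); valve <- c(0L, valve); state <- c("open", state) }
  data.frame(time_s = time_s, valve_id = valve, state = state,
             stringsAsFactors = FALSE)
}

#' Validate valve exclusivity in an event log
#'
#' Replays a time-ordered valve event log and reports every interval during
#' which zero valves or two or more valves are open. The clean-air valve
#' (id 0) is assumed open before the first event, matching its normally-open
#' hardware state.
#'
#' @param events Data.frame with `time_s`, `valve_id`, `state`, time-ordered.
#' @return A data.frame of violations with columns `time_s`, `type`
#'   (`"none_open"` or `"multiple_open"`) and `detail`; zero rows when the
#'   log is valid.
#' @export
validate_valve_events <- function(events) {
  stopifnot(is.data.frame(events),
            all(c("time_s", "valve_id", "state") %in% names(events)))
  if (is.unsorted(events$time_s))
    stop("valve events must be time-ordered", call. = FALSE)
  if (!all(events$state %in% c("open", "closed")))
    stop("state must be 'open' or 'closed'", call. = FALSE)
  open <- c(`0` = TRUE, `1` = FALSE, `2` = FALSE, `3` = FALSE, `4` = FALSE)
  viol_t <- numeric(0); viol_type <- character(0); viol_detail <- character(0)
  times <- unique(events$time_s)
  for (t in times) {
    rows <- events[events$time_s == t, , drop = FALSE]
    for (j in seq_len(nrow(rows)))
      open[as.character(rows$valve_id[j])] <- rows$state[j] == "open"
    n_open <- sum(open)
    if (n_open != 1L) {
      viol_t <- c(viol_t, t)
      viol_type <- c(viol_type, if (n_open == 0L) "none_open" else "multiple_open")
      viol_detail <- c(viol_detail,
                       if (n_open == 0L) "no valve open"
                       else paste0("valves open: ",
                                   paste(names(open)[open], collapse = ",")))
    }
  }
  data.frame(time_s = viol_t, type = viol_type, detail = viol_detail,
             stringsAsFactors = FALSE)
}

#' Derive per-trial scoring windows
#'
#' Each trial window runs from a stimulus valve onset to the next trial's
#' onset (ON + OFF, nominally 120 s). From the event log alone only
#' odorant-valve episodes are recoverable, because clean-stimulus trials
#' produce no transitions; pass `schedule` to obtain windows for every trial
#' (clean windows are then taken from the schedule).
#'
#' @param events Validated valve event log (may be `NULL` when `schedule`
#'   is supplied).
#' @param on_s,off_s Nominal ON and OFF durations (seconds), used to close
#'   the final window.
#' @param schedule Optional `ohd_schedule`; when given, windows (including
#'   clean-stimulus trials) are generated from it.
#' @return A data.frame with columns `trial`, `stimulus` (when known),
#'   `presentation` (when known), `valve_id`, `t_start_s`, `t_on_end_s`,
#'   `t_end_s`.
#' @export
trial_windows <- function(events, on_s = 60, off_s = 60, schedule = NULL) {
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "ohd_schedule"))
    tr <- schedule$trials
    return(tr[, c("trial", "stimulus", "presentation", "valve_id",
                  "t_start_s", "t_on_end_s", "t_end_s")])
  }
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0L)
    return(data.frame(trial = integer(0), stimulus = character(0),
                      presentation = integer(0), valve_id = integer(0),
                      t_start_s = numeric(0), t_on_end_s = numeric(0),
                      t_end_s = numeric(0), stringsAsFactors = FALSE))
  v <- validate_valve_events(events)  # also checks ordering
  on_rows <- events[events$state == "open" & events$valve_id != 0L, , drop = FALSE]
  if (nrow(on_rows) == 0L)
    return(data.frame(trial = integer(0), stimulus = character(0),
                      presentation = integer(0), valve_id = integer(0),
                      t_start_s = numeric(0), t_on_end_s = numeric(0),
                      t_end_s = numeric(0), stringsAsFactors = FALSE))
  onset <- on_rows$time_s
  valve <- on_rows$valve_id
  # actual close time of each episode: first 'closed' for that valve after onset
  on_end <- vapply(seq_along(onset), function(i) {
    closes <- events$time_s[events$valve_id == valve[i] &
                              events$state == "closed" &
                              events$time_s > onset[i]]
    if (length(closes)) min(closes) else onset[i] + on_s
  }, numeric(1))
  t_end <- c(onset[-1], onset[length(onset)] + on_s + off_s)
  if (any(on_end > t_end + 1e-9))
    stop("overlapping ON episodes in event log", call. = FALSE)
  data.frame(trial = seq_along(onset), stimulus = NA_character_,
             presentation = NA_integer_, valve_id = valve,
             t_start_s = onset, t_on_end_s = on_end, t_end_s = t_end,
             stringsAsFactors = FALSE)
}

#' Read/write a valve event log as CSV
#'
#' CSV layout is `time_s,valve_id,state`.
#'
#' @param events Event log data.frame.
#' @param path File path.
#' @return `read_valve_events()` returns the event data.frame;
#'   `write_valve_events()` returns `path` invisibly.
#' @export
write_valve_events <- function(events, path) {
  utils::write.csv(events[, c("time_s", "valve_id", "state")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_valve_events
#' @export
read_valve_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "valve_id", "state")
  if (!all(need %in% names(ev)))
    stop("valve event file must have columns time_s,valve_id,state",
         call. = FALSE)
  ev$valve_id <- as.integer(ev$valve_id)
  ev[, need]
}
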