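#' Run a single trial of the multiple-choice interface
#'
#' Executes the trial state machine for the chosen task. Reach tasks
#' (static/dynamic) draw a target size from the size grid (and a speed
#' from the speed grid for the dynamic task), spawn the target, and let the
#' agent respond: a touch on the disc is a *hit* (acoustic "ding", 0.37 mL
#' reward), a touch on the background a *failure* ("error", no reward), and
#' no touch within the 5 s timeout an *ignored* trial (no feedback). The
#' picture task presents one of 126 pictures for exactly 5 s, is recorded
#' as *viewed* and never rewarded. Every outcome is followed by an
#' inter-trial interval drawn uniformly from 1.5--2.5 s.
#'
#' @param task `"static"`, `"dynamic"` or `"picture"`.
#' @param agent An [agent_profile()].
#' @param config An [session_config()].
#' @param geometry An [screen_geometry()] object.
#' @param layout The button layout in force.
#' @param t_now Trial initiation time from session start, seconds.
#' @return List with `record` (one-row data frame in the trial-log schema,
#'   see [trial_log_columns()]), `duration_s` (trial duration from
#'   initiation to outcome), `busy_s` (duration plus the sampled ITI) and
#'   `event` (`"ding"`, `"error"` or `NA`).
#' @export
run_trial <- function(task, agent, config = session_config(),
                      geometry = screen_geometry(),
                      layout = make_layout(), t_now = 0) {
  stopifnot(task %in% mci_tasks)
  rec <- list(
    session_id = NA_character_, session_date = NA_character_,
    group_id = agent$group_id, animal_id = agent$animal_id,
    trial_index = NA_integer_, t_init_s = t_now,
    session_duration_s = config$session_duration_s,
    clock_hour = NA_real_,
    layout_left = unname(layout["left"]),
    layout_middle = unname(layout["middle"]),
    layout_right = unname(layout["right"]),
    chosen_position = task_position(layout, task), chosen_task = task,
    target_size_deg = NA_integer_, target_speed_deg_s = NA_integer_,
    outcome = NA_character_, touch_x_deg = NA_real_, touch_y_deg = NA_real_,
    response_time_s = NA_real_, reward_ml = 0, picture_index = NA_integer_
  )
  event <- NA_character_
  if (task == "picture") {
    rec$outcome <- "viewed"
    rec$picture_index <- sample.int(config$picture_pool_size, 1)
    duration <- config$picture_duration_s
  } else {
    d <- sample(config$size_values, 1)
    v <- if (task == "dynamic") sample(config$speed_values, 1) else 0L
    rec$target_size_deg <- d
    rec$target_speed_deg_s <- v
    target <- spawn_target(d, v, geometry)
    resp <- attempt_touch(agent, target, geometry, config$timeout_s)
    if (resp$ignored) {
      rec$outcome <- "ignored"
      duration <- config$timeout_s
    } else {
      at_touch <- if (v > 0) step_target(target, resp$response_time_s, geometry)
                  else target
      rec$outcome <- classify_touch(resp$point, at_touch, geometry)
      rec$touch_x_deg <- resp$point[1]
      rec$touch_y_deg <- resp$point[2]
      rec$response_time_s <- resp$response_time_s
      duration <- resp$response_time_s
      if (rec$outcome == "hit") {
        rec$reward_ml <- config$reward_ml
        event <- "ding"
      } else if (rec$outcome == "failure") {
        event <- "error"
      }
    }
  }
  iti <- stats::runif(1, config$iti_range_s[1], config$iti_range_s[2])
  list(record = as.data.frame(rec, stringsAsFactors = FALSE),
       duration_s = duration, busy_s = duration + iti, event = event)
}

#' Run one animal's session
#'
#' Generates the agent's trial-initiation times from its engagement
#' process, maintains the hourly layout schedule (a fresh layout at t = 0
#' and at every `shuffle_period_s` boundary, never repeating the previous
#' arrangement), and runs one trial per initiation. Initiations that fall
#' while the device is still busy (previous trial plus its inter-trial
#' interval) are skipped. Each record carries the layout in force at its
#' initiation time.
#'
#' @param agent An [agent_profile()].
#' @param config An [session_config()].
#' @param geometry An [screen_geometry()] object.
#' @param session_id Identifier stored in the log.
#' @param session_idx Session index (covariate for the agent's session
#'   slope), e.g. 1..6.
#' @param session_date Calendar date string stored in the log.
#' @param start_clock_hour Wall-clock hour of session start (e.g. 8.5).
#' @return Data frame of trial records (possibly zero rows) in the
#'   trial-log schema.
#' @export
run_session <- function(agent, config = session_config(),
                        geometry = screen_geometry(),
                        session_id = "S1", session_idx = 1,
                        session_date = "2023-01-01",
                        start_clock_hour = 8) {
  duration <- config$session_duration_s
  times <- sample_engagement_times(agent$lambda0, agent$k, duration)
  n_epochs <- ceiling(duration / config$shuffle_period_s)
  layouts <- vector("list", n_epochs)
  layouts[[1]] <- make_layout()
  if (n_epochs > 1) {
    for (e in 2:n_epochs) layouts[[e]] <- make_layout(previous = layouts[[e - 1]])
  }
  rows <- vector("list", length(times))
  n_kept <- 0L
  busy_until <- 0
  for (t in times) {
    if (t < busy_until) next
    epoch <- min(floor(t / config$shuffle_period_s) + 1, n_epochs)
    layout <- layouts[[epoch]]
    choice <- choose_task(agent, layout, t_norm = t / duration,
                          session_idx = session_idx)
    trial <- run_trial(choice$task, agent, config, geometry, layout, t)
    n_kept <- n_kept + 1L
    rec <- trial$record
    rec$session_id <- session_id
    rec$session_date <- session_date
    rec$trial_index <- n_kept
    rec$clock_hour <- start_clock_hour + t / 3600
    rows[[n_kept]] <- rec
    busy_until <- t + trial$busy_s
  }
  if (n_kept == 0L) return(empty_trial_log())
  do.call(rbind, rows[seq_len(n_kept)])
}
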