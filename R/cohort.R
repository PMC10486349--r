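#' Cohort specification
#'
#' A set of synthetic agents organized in social groups, plus the session
#' schedule. Group members share one device timeline per session: their
#' trials are interleaved by time into a single session log.
#'
#' @param agents List of [agent_profile()] objects.
#' @param n_sessions Number of (weekly) sessions.
#' @param session_dates Character vector of dates, one per session.
#' @param start_clock_hour Wall-clock hour at which sessions start.
#' @param unlabeled_fraction Share of trials emitted with a missing
#'   `animal_id`, to exercise the labels-merge path (default 0).
#' @param session_duration_range_s Range from which each session's actual
#'   duration is drawn (uniform, once per session, shared by all groups
#'   running in parallel); the default varies around the nominal 8 h so
#'   the duration covariate of the engagement-trend analysis is exercised.
#' @return An object of class `mci_cohort`.
#' @export
cohort_spec <- function(agents, n_sessions = 6,
                        session_dates = NULL,
                        start_clock_hour = 8,
                        unlabeled_fraction = 0,
                        session_duration_range_s = c(7.65, 8.35) * 3600) {
  stopifnot(length(agents) >= 1, n_sessions >= 1,
            unlabeled_fraction >= 0, unlabeled_fraction <= 1,
            length(session_duration_range_s) == 2,
            session_duration_range_s[1] <= session_duration_range_s[2])
  sizes <- table(vapply(agents, function(a) a$group_id, ""))
  if (is.null(session_dates))
    session_dates <- format(as.Date("2023-01-07") + 7 * (seq_len(n_sessions) - 1))
  stopifnot(length(session_dates) == n_sessions)
  structure(list(agents = agents, n_sessions = n_sessions,
                 session_dates = session_dates,
                 start_clock_hour = start_clock_hour,
                 unlabeled_fraction = unlabeled_fraction,
                 session_duration_range_s = session_duration_range_s,
                 group_sizes = sizes),
            class = "mci_cohort")
}

#' @method print mci_cohort
#' @export
print.mci_cohort <- function(x, ...) {
  cat(sprintf("MCI cohort: %d animals in %d groups, %d sessions\n",
              length(x$agents), length(x$group_sizes), x$n_sessions))
  invisible(x)
}

#' Default 16-animal cohort
#'
#' Mirrors the structure of the study population the simulator emulates:
#' 16 animals in 7 social groups of 2--3, six weekly ~8 h sessions. Ten
#' animals carry a static-task preference and two a dynamic-task
#' preference (logit utility gap `pref_gap`); four are indifferent. Every
#' agent expects ~418 trials per session (its base rate is rescaled so the
#' expected thinned count is `trials_per_session` at decay `k`), and the
#' default decay `k = 0.25` places the median normalized trial time near
#' 0.47. Small per-animal position biases and time/session slopes are
#' drawn from the supplied ranges.
#'
#' @param n_sessions Number of sessions.
#' @param trials_per_session Expected trials per animal-session.
#' @param k Engagement decay shared by all agents.
#' @param pref_gap Logit utility gap of preferring animals.
#' @param bias_sd Spread of the per-animal left/right position biases.
#' @param session_duration_s Session length used to scale the base rate.
#' @return An `mci_cohort`.
#' @export
default_cohort <- function(n_sessions = 6, trials_per_session = 418,
                           k = 0.25, pref_gap = 2, bias_sd = 0.3,
                           session_duration_s = 8 * 3600) {
  groups <- rep(paste0("G", 1:7), times = c(2, 2, 2, 2, 2, 3, 3))
  ids <- sprintf("m%02d", 1:16)
  pref <- c(rep("static", 10), rep("dynamic", 2), rep("none", 4))
  lambda0 <- engagement_rate_for(trials_per_session, k, session_duration_s)
  agents <- lapply(1:16, function(i) {
    u <- c(static = 0, dynamic = 0, picture = 0)
    if (pref[i] != "none") u[pref[i]] <- pref_gap
    b <- c(left = stats::rnorm(1, 0, bias_sd), middle = 0,
           right = stats::rnorm(1, 0, bias_sd))
    gamma <- c(static = stats::rnorm(1, 0, 0.1),
               dynamic = stats::rnorm(1, 0, 0.1), picture = 0)
    delta <- c(static = stats::rnorm(1, 0, 0.05),
               dynamic = stats::rnorm(1, 0, 0.05), picture = 0)
    agent_profile(ids[i], groups[i], u = u, b = b, gamma = gamma,
                  delta = delta, lambda0 = lambda0, k = k)
  })
  cohort_spec(agents, n_sessions = n_sessions)
}

#' Base rate giving a target expected trial count under decay
#'
#' For the thinned engagement process the expected count over a session is
#' `lambda0 * T * (1 - exp(-k)) / k` (and `lambda0 * T` at `k = 0`); this
#' inverts that relation.
#'
#' @param n_expected Target expected trials per session.
#' @param k Decay rate.
#' @param duration Session length in seconds.
#' @return Base rate `lambda0` in trials/second.
#' @export
engagement_rate_for <- function(n_expected, k, duration) {
  frac <- if (k == 0) 1 else (1 - exp(-k)) / k
  n_expected / (duration * frac)
}

#' Simulate a full cohort
#'
#' Runs [run_session()] for every animal-session, interleaves group
#' members' trials into shared per-group session logs (trials re-indexed
#' by time), optionally blanks a share of `animal_id` labels, and returns
#' the concatenated trial log together with the ground-truth parameter
#' table used by recovery tests.
#'
#' All randomness flows through R's RNG; `set.seed()` before calling for a
#' byte-identical log.
#'
#' @param spec An [cohort_spec()].
#' @param config An [session_config()].
#' @param geometry An [screen_geometry()] object.
#' @return List with `log` (trial-log data frame) and `truth` (one row of
#'   generative parameters per agent).
#' @export
simulate_cohort <- function(spec, config = session_config(),
                            geometry = screen_geometry()) {
  logs <- list()
  for (s in seq_len(spec$n_sessions)) {
    cfg_s <- config
    cfg_s$session_duration_s <- stats::runif(1,
                                             spec$session_duration_range_s[1],
                                             spec$session_duration_range_s[2])
    for (agent in spec$agents) {
      sid <- paste0(agent$group_id, "_S", s)
      logs[[paste(agent$animal_id, s)]] <-
        run_session(agent, cfg_s, geometry,
                    session_id = sid, session_idx = s,
                    session_date = spec$session_dates[s],
                    start_clock_hour = spec$start_clock_hour)
    }
  }
  log <- do.call(rbind, logs)
  rownames(log) <- NULL
  # group members share a device: merge by time within each session log
  ord <- order(log$session_id, log$t_init_s)
  log <- log[ord, , drop = FALSE]
  log$trial_index <- stats::ave(seq_len(nrow(log)), log$session_id,
                                FUN = seq_along)
  rownames(log) <- NULL
  if (spec$unlabeled_fraction > 0) {
    drop <- stats::runif(nrow(log)) < spec$unlabeled_fraction
    log$animal_id[drop] <- NA_character_
  }
  truth <- do.call(rbind, lapply(spec$agents, function(a) {
    data.frame(animal_id = a$animal_id, group_id = a$group_id,
               u_static = unname(a$u["static"]),
               u_dynamic = unname(a$u["dynamic"]),
               u_picture = unname(a$u["picture"]),
               b_left = unname(a$b["left"]), b_right = unname(a$b["right"]),
               gamma_static = unname(a$gamma["static"]),
               gamma_dynamic = unname(a$gamma["dynamic"]),
               delta_static = unname(a$delta["static"]),
               delta_dynamic = unname(a$delta["dynamic"]),
               lambda0 = a$lambda0, k = a$k,
               sigma0 = a$sigma0, sigma_v = a$sigma_v,
               p_ignore = a$p_ignore, motor_delay_s = a$motor_delay_s,
               stringsAsFactors = FALSE)
  }))
  list(log = log, truth = truth)
}
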