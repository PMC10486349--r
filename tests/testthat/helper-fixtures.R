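# Shared fixture builders. Everything is generated in code; seeds are fixed
# inside each test that needs reproducibility.

fixture_geometry <- function() screen_geometry()

# a small cohort: n_pref animals preferring `pref_task` by `gap` logits,
# the rest indifferent; two social groups
fixture_agents <- function(n = 6, n_pref = 3, pref_task = "static",
                           gap = 2, trials_per_session = 120,
                           duration_s = 4 * 3600, k = 0.25) {
  lapply(seq_len(n), function(i) {
    u <- c(static = 0, dynamic = 0, picture = 0)
    if (i <= n_pref) u[pref_task] <- gap
    agent_profile(sprintf("a%02d", i),
                  group_id = if (i <= ceiling(n / 2)) "G1" else "G2",
                  u = u,
                  lambda0 = engagement_rate_for(trials_per_session, k,
                                                duration_s),
                  k = k)
  })
}

fixture_log <- function(seed = 7, n_sessions = 3, duration_s = 4 * 3600,
                        ...) {
  set.seed(seed)
  simulate_cohort(cohort_spec(fixture_agents(duration_s = duration_s, ...),
                              n_sessions = n_sessions),
                  session_config(session_duration_s = duration_s))
}

# hand-rolled one-row trial record for io tests
fixture_record <- function(outcome = "hit", task = "static",
                           session_id = "G1_S1", trial_index = 1L,
                           animal_id = "a01") {
  data.frame(
    session_id = session_id, session_date = "2023-01-07", group_id = "G1",
    animal_id = animal_id, trial_index = trial_index, t_init_s = 12.5,
    session_duration_s = 28800, clock_hour = 8.3,
    layout_left = "static", layout_middle = "dynamic",
    layout_right = "picture",
    chosen_position = "left", chosen_task = task,
    target_size_deg = 7L, target_speed_deg_s = 0L, outcome = outcome,
    touch_x_deg = 30.1, touch_y_deg = 25.2, response_time_s = 1.1,
    reward_ml = if (outcome == "hit") 0.37 else 0,
    picture_index = NA_integer_, stringsAsFactors = FALSE)
}
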