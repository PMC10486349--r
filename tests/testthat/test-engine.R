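geo <- screen_geometry()
cfg <- session_config()

# agents engineered for deterministic trial outcomes
never_touches <- agent_profile("nt", p_ignore = 1)
sharp_shooter <- agent_profile("ss", sigma0 = 1e-6, sigma_v = 0,
                               p_ignore = 0)

test_that("picture trials last exactly 5 s, log a picture index, pay nothing", {
  set.seed(21)
  for (i in 1:5) {
    tr <- run_trial("picture", never_touches, cfg, geo, make_layout(), 100)
    expect_identical(tr$record$outcome, "viewed")
    expect_identical(tr$duration_s, cfg$picture_duration_s)
    expect_identical(tr$record$reward_ml, 0)
    expect_true(tr$record$picture_index %in% 1:126)
    expect_true(is.na(tr$event))
  }
})

test_that("an agent that never touches produces an ignored trial at timeout", {
  set.seed(22)
  tr <- run_trial("static", never_touches, cfg, geo, make_layout(), 0)
  expect_identical(tr$record$outcome, "ignored")
  expect_identical(tr$duration_s, cfg$timeout_s)
  expect_identical(tr$record$reward_ml, 0)
  expect_true(is.na(tr$record$response_time_s))
})

test_that("an accurate toucher hits and earns exactly one reward unit", {
  set.seed(23)
  tr <- run_trial("static", sharp_shooter, cfg, geo, make_layout(), 0)
  expect_identical(tr$record$outcome, "hit")
  expect_identical(tr$record$reward_ml, 0.37)
  expect_identical(tr$event, "ding")
  expect_lte(tr$record$response_time_s, cfg$timeout_s)
  # ITI appended after the outcome
  expect_gte(tr$busy_s - tr$duration_s, 1.5)
  expect_lte(tr$busy_s - tr$duration_s, 2.5)
})

test_that("dynamic trials record size and speed from the integer grids", {
  set.seed(24)
  recs <- do.call(rbind, lapply(1:40, function(i)
    run_trial("dynamic", sharp_shooter, cfg, geo, make_layout(), i)$record))
  expect_true(all(recs$target_size_deg %in% 5:10))
  expect_true(all(recs$target_speed_deg_s %in% 10:30))
  stat <- run_trial("static", sharp_shooter, cfg, geo, make_layout(), 0)
  expect_identical(stat$record$target_speed_deg_s, 0L)
})

test_that("a session has hourly layout epochs and schedule-consistent records", {
  set.seed(25)
  busy <- agent_profile("bz", lambda0 = 400 / (8 * 3600), p_ignore = 0.1)
  log <- run_session(busy, cfg, geo, session_id = "S1")
  expect_gt(nrow(log), 100)
  # exactly 8 epochs in an 8 h session: layout constant within each hour,
  # and consecutive hours differ
  hr <- floor(log$t_init_s / 3600)
  expect_setequal(unique(hr), 0:7)
  key <- paste(log$layout_left, log$layout_middle, log$layout_right)
  per_hour <- tapply(key, hr, function(x) unique(x))
  expect_true(all(lengths(per_hour) == 1))
  expect_true(all(unlist(per_hour[-1]) != unlist(per_hour[-8])))
  # records ordered, indexed, inside the session
  expect_identical(log$trial_index, seq_len(nrow(log)))
  expect_true(all(diff(log$t_init_s) > 0))
  expect_true(all(log$t_init_s >= 0 & log$t_init_s <= cfg$session_duration_s))
  # chosen position matches the layout in force
  pos_of_choice <- ifelse(log$layout_left == log$chosen_task, "left",
                   ifelse(log$layout_middle == log$chosen_task, "middle",
                          "right"))
  expect_identical(log$chosen_position, pos_of_choice)
  # reward accounting is exact
  expect_identical(sum(log$reward_ml), 0.37 * sum(log$outcome == "hit"))
})

test_that("an agent generating no initiations yields an empty session", {
  set.seed(26)
  lazy <- agent_profile("lz", lambda0 = 1e-9)
  log <- run_session(lazy, cfg, geo)
  expect_identical(nrow(log), 0L)
  expect_identical(names(log), trial_log_columns())
})

test_that("cohort simulation is deterministic and carries ground truth", {
  sim1 <- fixture_log(seed = 31, n_sessions = 2, trials_per_session = 40)
  sim2 <- fixture_log(seed = 31, n_sessions = 2, trials_per_session = 40)
  expect_identical(sim1$log, sim2$log)
  expect_identical(nrow(sim1$truth), 6L)
  # group members share a session timeline: indices follow merged time
  one <- sim1$log[sim1$log$session_id == sim1$log$session_id[1], ]
  expect_identical(one$trial_index, seq_len(nrow(one)))
  expect_true(all(diff(one$t_init_s) > 0))
  expect_gt(length(unique(one$animal_id)), 1)
  # outcome enums and reward bookkeeping hold cohort-wide
  expect_true(all(sim1$log$outcome %in% c("hit", "failure", "ignored",
                                          "viewed")))
  expect_identical((sim1$log$outcome == "viewed"),
                   (sim1$log$chosen_task == "picture"))
  expect_identical(sum(sim1$log$reward_ml),
                   0.37 * sum(sim1$log$outcome == "hit"))
})

test_that("unlabeled fraction blanks animal ids for the labels workflow", {
  set.seed(33)
  spec <- cohort_spec(fixture_agents(n = 4, trials_per_session = 30),
                      n_sessions = 1, unlabeled_fraction = 0.5)
  sim <- simulate_cohort(spec, session_config(session_duration_s = 3600))
  frac <- mean(is.na(sim$log$animal_id))
  expect_gt(frac, 0.3)
  expect_lt(frac, 0.7)
})
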