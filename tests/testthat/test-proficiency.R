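mk_dyn <- function(size, speed, outcome) {
  data.frame(target_size_deg = size, target_speed_deg_s = speed,
             outcome = outcome, stringsAsFactors = FALSE)
}

test_that("hit rate by size counts hits over scored trials only", {
  rec <- mk_dyn(c(5, 5, 5, 5, 6, 6, 7), 0,
                c("hit", "hit", "hit", "failure", "hit", "ignored",
                  "ignored"))
  hr <- hit_rate_by_size(rec, sizes = 5:8)
  expect_equal(unname(hr["5"]), 0.75)
  expect_equal(unname(hr["6"]), 1.0)       # ignored excluded
  expect_true(is.na(hr["7"]))              # only an ignored trial
  expect_true(is.na(hr["8"]))              # empty cell is missing, not 0
  hr_inc <- hit_rate_by_size(rec, sizes = 5:8, include_ignored = TRUE)
  expect_equal(unname(hr_inc["6"]), 0.5)
})

test_that("chance adjustment is the documented affine shift", {
  tab <- xbi_chance_table()
  expect_equal(adjusted_hit_rate(0.5, 10, table = tab), 0.5 - 0.3024)
  expect_equal(adjusted_hit_rate(1.0, 5, table = tab), 0.9267)
  expect_equal(adjusted_hit_rate(0.0733, 5, table = tab), 0,
               tolerance = 1e-12)
  # the shift preserves the ordering of speeds within a size
  rates <- c(0.9, 0.7, 0.55, 0.4)
  adj <- adjusted_hit_rate(rates, 7, table = tab)
  expect_identical(order(adj), order(rates))
  expect_error(adjusted_hit_rate(0.5, 11, table = tab), "chance-table")
})

test_that("speed correlation matches the Fisher-z closed form", {
  # 21-point fixture with a noisy negative trend
  set.seed(81)
  speeds <- 10:30
  adj <- 0.6 - 0.012 * (speeds - 10) + round(rnorm(21, 0, 0.03), 4)
  got <- speed_correlation(speeds, adj, alpha = 0.003)
  # formula-level recomputation
  r <- sum((speeds - mean(speeds)) * (adj - mean(adj))) /
    sqrt(sum((speeds - mean(speeds))^2) * sum((adj - mean(adj))^2))
  z <- atanh(r)
  ci <- tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(21 - 3))
  tstat <- r * sqrt((21 - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), 21 - 2)
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$ci, ci, tolerance = 1e-6)
  expect_equal(got$p, p, tolerance = 1e-12)
  expect_identical(got$n, 21L)
  expect_identical(got$significant, p < 0.003)
  # exact linear decrease: r = -1
  lin <- speed_correlation(10:14, seq(0.5, 0.1, length.out = 5))
  expect_equal(lin$r, -1, tolerance = 1e-12)
  # degenerate inputs flagged, not crashed
  flat <- speed_correlation(10:30, rep(0.4, 21))
  expect_true(flat$insufficient)
  short <- speed_correlation(10:30, c(0.4, 0.3, rep(NA, 19)))
  expect_true(short$insufficient)
})

test_that("the Bonferroni family alpha follows the cohort size", {
  expect_equal(bonferroni_alpha(16), 0.05 / 16)
  expect_equal(round(bonferroni_alpha(16), 3), 0.003)
  expect_equal(bonferroni_alpha(10, 0.01), 0.001)
})

test_that("heatmap cells mask under the trial minimum and average correctly", {
  tab <- xbi_chance_table()
  rec <- mk_dyn(rep(5, 6), rep(10, 6), rep("hit", 6))
  hm <- size_speed_heatmap(rec, sizes = 5:6, speeds = c(10, 11),
                           table = tab, min_trials = 5)
  expect_equal(hm$adj_rate["5", "10"], 1 - 0.0733)
  expect_identical(hm$n["5", "10"], 6L)
  expect_true(is.na(hm$adj_rate["5", "11"]))
  # single record is below the default minimum: masked, but counted
  one <- size_speed_heatmap(mk_dyn(5, 10, "hit"), sizes = 5:6,
                            speeds = c(10, 11), table = tab)
  expect_true(all(is.na(one$adj_rate)))
  expect_identical(one$n["5", "10"], 1L)
  # with the minimum lowered, the single hit scores 1 - chance
  one2 <- size_speed_heatmap(mk_dyn(5, 10, "hit"), sizes = 5:6,
                             speeds = c(10, 11), table = tab,
                             min_trials = 1)
  expect_equal(one2$adj_rate["5", "10"], 0.9267)
})

test_that("best combo takes the argmax with small-size, small-speed ties", {
  adj <- matrix(NA_real_, 2, 2, dimnames = list(c(5, 6), c(10, 11)))
  adj[1, 2] <- 0.4; adj[2, 1] <- 0.2
  bc <- best_combo(list(adj_rate = adj))
  expect_identical(c(bc$size, bc$speed), c(5L, 11L))
  # tie between (5,10) and (6,10): smaller size wins
  adj2 <- matrix(0.3, 2, 2, dimnames = list(c(5, 6), c(10, 11)))
  adj2[, 2] <- 0.1
  bc2 <- best_combo(list(adj_rate = adj2))
  expect_identical(c(bc2$size, bc2$speed), c(5L, 10L))
  expect_null(best_combo(list(adj_rate = adj * NA)))
})

test_that("per-animal analysis recovers speed sensitivity from simulation", {
  set.seed(82)
  sharp <- agent_profile("s1", sigma0 = 1.5, sigma_v = 0.1, p_ignore = 0)
  sim <- simulate_touches(sharp, sample(5:10, 3000, TRUE),
                          sample(10:30, 3000, TRUE))
  sim$animal_id <- "s1"
  sim$chosen_task <- "dynamic"
  prof <- analyze_proficiency(sim, table = xbi_chance_table())
  row <- prof$animals[1, ]
  expect_lt(row$speed_r, -0.5)
  expect_true(row$significant)       # alpha = 0.05 / 1 animal
  expect_lte(row$best_speed, 15L)    # optimum sits at the slow end
  # static hit rates increase with size for an accurate agent
  set.seed(83)
  stat <- simulate_touches(sharp, sample(5:10, 3000, TRUE), rep(0, 3000))
  stat$animal_id <- "s1"; stat$chosen_task <- "static"
  hr <- hit_rate_by_size(stat)
  expect_true(all(diff(hr) > 0))
})
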