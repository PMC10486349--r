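geo <- screen_geometry()

test_that("engagement process has the homogeneous-Poisson mean at k = 0", {
  set.seed(51)
  counts <- replicate(60, length(sample_engagement_times(400 / 3600, 0, 3600)))
  expect_lt(abs(mean(counts) - 400), 3 * sqrt(400 / 60))
  t <- sample_engagement_times(400 / 3600, 0, 3600)
  expect_true(!is.unsorted(t))
  expect_true(all(t >= 0 & t <= 3600))
})

test_that("k = 0 trial times are uniform; k = 2 concentrates the first half", {
  set.seed(52)
  m0 <- replicate(200, median(sample_engagement_times(0.1, 0, 3600)) / 3600)
  expect_lt(abs(mean(m0) - 0.5), 3 * (0.5 / sqrt(360)) * sqrt(pi / 2) /
              sqrt(200))
  m2 <- replicate(200, median(sample_engagement_times(0.1, 2, 3600)) / 3600)
  expect_gte(mean(m2 < 0.5), 0.95)
  # closed-form median of the exponentially tilted time density:
  # F(m) = (1 - exp(-k m)) / (1 - exp(-k)) = 1/2  =>  m = 0.2831 at k = 2
  m_theory <- -log(1 - 0.5 * (1 - exp(-2))) / 2
  expect_equal(mean(m2), m_theory, tolerance = 0.02)
})

test_that("engagement intensity histogram matches the exponential shape", {
  set.seed(53)
  t <- sample_engagement_times(1e5 / 3600, 1.5, 3600) / 3600
  breaks <- seq(0, 1, length.out = 21)
  obs <- table(cut(t, breaks))
  cdf <- function(x) (1 - exp(-1.5 * x)) / (1 - exp(-1.5))
  p <- diff(cdf(breaks))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("task choice follows the softmax of utilities and biases", {
  layout <- structure(c(left = "static", middle = "dynamic",
                        right = "picture"), class = "mci_layout")
  flat <- agent_profile("f")
  expect_equal(unname(task_choice_probs(flat, layout)), rep(1 / 3, 3))
  # utility gap 2: P(static) = e^2 / (e^2 + 2)
  pref <- agent_profile("p", u = c(static = 2, dynamic = 0, picture = 0))
  p_theory <- exp(2) / (exp(2) + 2)
  expect_equal(unname(task_choice_probs(pref, layout)["static"]), p_theory,
               tolerance = 1e-12)
  set.seed(54)
  draws <- replicate(10000, choose_task(pref, layout)$task)
  expect_lt(abs(mean(draws == "static") - p_theory),
            3 * sqrt(p_theory * (1 - p_theory) / 10000))
  # position bias shifts choice toward the favored side
  sided <- agent_profile("s", b = c(left = 1.5, middle = 0, right = 0))
  expect_gt(task_choice_probs(sided, layout)["static"], 1 / 3)
  # seeded draw sequence is reproducible
  set.seed(55); a <- replicate(20, choose_task(pref, layout)$task)
  set.seed(55); b <- replicate(20, choose_task(pref, layout)$task)
  expect_identical(a, b)
})

test_that("touch accuracy follows the Gaussian disc-coverage law", {
  # hit probability at v = 0 equals 1 - exp(-(d/2)^2 / (2 sigma^2)) for a
  # centered target (clipping negligible)
  ag <- agent_profile("t", sigma0 = 2, sigma_v = 0, p_ignore = 0)
  tg <- structure(list(center = c(geo$width_deg / 2,
                                  (geo$height_deg + 7) / 2),
                       diameter_deg = 6, velocity = c(0, 0)),
                  class = "mci_target")
  set.seed(56)
  hits <- replicate(4000, {
    resp <- attempt_touch(ag, tg, geo, 5)
    classify_touch(resp$point, tg, geo) == "hit"
  })
  p_theory <- 1 - exp(-(3^2) / (2 * 4))
  expect_lt(abs(mean(hits) - p_theory),
            3 * sqrt(p_theory * (1 - p_theory) / 4000))
  # noiseless limit: certain hit
  exact <- agent_profile("e", sigma0 = 1e-9, sigma_v = 0, p_ignore = 0)
  resp <- attempt_touch(exact, tg, geo, 5)
  expect_identical(classify_touch(resp$point, tg, geo), "hit")
  # ignoring happens with the configured probability
  lazy <- agent_profile("l", p_ignore = 1)
  expect_true(attempt_touch(lazy, tg, geo, 5)$ignored)
})

test_that("hit rate rises with size and falls with speed", {
  ag <- agent_profile("m", sigma0 = 2, sigma_v = 0.08, p_ignore = 0)
  set.seed(57)
  grid <- expand.grid(size = c(5, 7, 10), speed = c(10, 20, 30))
  rate <- mapply(function(d, v) {
    sim <- simulate_touches(ag, rep(d, 2000), rep(v, 2000), geo)
    mean(sim$outcome == "hit")
  }, grid$size, grid$speed)
  rate <- matrix(rate, 3, 3)   # rows sizes, cols speeds
  expect_true(all(apply(rate, 2, diff) > 0))   # larger is easier
  expect_true(all(apply(rate, 1, diff) < 0))   # faster is harder
})

test_that("batch touch simulation matches the single-trial touch model", {
  ag <- agent_profile("b", sigma0 = 2.5, sigma_v = 0, p_ignore = 0)
  set.seed(58)
  batch <- simulate_touches(ag, rep(6, 4000), rep(0, 4000), geo)
  p_batch <- mean(batch$outcome == "hit")
  single <- replicate(2000, {
    tg <- spawn_target(6, 0, geo)
    resp <- attempt_touch(ag, tg, geo, 5)
    classify_touch(resp$point, tg, geo) == "hit"
  })
  se <- sqrt(p_batch * (1 - p_batch) * (1 / 4000 + 1 / 2000))
  expect_lt(abs(p_batch - mean(single)), 4 * se)
})
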