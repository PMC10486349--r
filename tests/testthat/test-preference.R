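test_that("the Polya-Gamma sampler matches closed-form moments", {
  set.seed(91)
  # PG(1, 0): mean 1/4, variance 1/24
  x0 <- rpolyagamma(rep(0, 5e4))
  expect_lt(abs(mean(x0) - 0.25), 4 * sqrt(1 / 24 / 5e4))
  expect_lt(abs(var(x0) - 1 / 24), 0.002)
  # general tilting: mean tanh(z/2) / (2 z)
  for (z in c(0.5, 2, 6)) {
    x <- rpolyagamma(rep(z, 5e4))
    m <- tanh(z / 2) / (2 * z)
    expect_lt(abs(mean(x) - m), 4 * sd(x) / sqrt(5e4))
  }
  # distribution-level check against the truncated infinite-series
  # representation PG(1,z) = (1/2 pi^2) sum g_k / ((k-1/2)^2 + z^2/(4 pi^2))
  z <- 2; K <- 2000; n <- 1e4
  denom <- (seq_len(K) - 0.5)^2 + z^2 / (4 * pi^2)
  series <- colSums(matrix(rexp(K * n), K, n) / denom) / (2 * pi^2)
  ks <- suppressWarnings(ks.test(rpolyagamma(rep(z, n)), series))
  expect_gt(ks$p.value, 0.001)
})

test_that("the design encodes outcomes, button positions and z-covariates", {
  sim <- fixture_log(seed = 92, n_sessions = 3, trials_per_session = 60)
  d <- build_design(sim$log)
  expect_identical(length(d$y), nrow(sim$log))
  expect_setequal(unique(d$y), 1:3)
  expect_identical(d$y[sim$log$chosen_task == "picture"][1], 1L)
  # the static task's encoded position matches the layout columns
  i <- which(sim$log$layout_middle == "static")[1]
  expect_identical(d$pos_static[i], 2L)
  # z-scores are standardized over the modeled trials
  expect_lt(abs(mean(d$z_time)), 1e-10)
  expect_equal(sd(d$z_time), 1, tolerance = 1e-10)
  expect_equal(sd(d$z_session), 1, tolerance = 1e-10)
  # the two position codes are anti-correlated by construction (the
  # layout is a bijection; population correlation -1/2); the covariates
  # must pass the 0.5 collinearity screen
  pc <- d$predictor_correlations
  expect_lt(abs(pc["pos_static", "pos_dynamic"] + 0.5), 0.15)
  covs <- c("z_time", "z_session")
  off <- pc[covs, setdiff(colnames(pc), covs), drop = FALSE]
  expect_true(all(abs(off) < 0.5))
  # unlabeled trials are excluded with a message
  log2 <- sim$log
  log2$animal_id[1:5] <- NA
  expect_message(d2 <- build_design(log2), "5 unlabeled")
  expect_identical(length(d2$y), nrow(sim$log) - 5L)
  # single-session input drops the session covariate with a warning
  one <- sim$log[sim$log$session_date == sim$log$session_date[1], ]
  expect_warning(d3 <- build_design(one), "session covariate")
  expect_true(all(d3$z_session == 0))
})

test_that("prior-predictive task probabilities are near-uniform and symmetric", {
  set.seed(93)
  p <- prior_predictive_probs(40000)
  m <- colMeans(p)
  # exact prior symmetry between the two non-reference categories; the
  # reference category sits slightly below 1/3 (softmax Jensen effect)
  expect_lt(abs(m["static"] - m["dynamic"]), 0.012)
  expect_true(all(abs(m - 1 / 3) < 0.05))
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-12)
})

test_that("posterior matches a long-run JAGS fit on a fixed-effects model", {
  # one animal, one session: all grouping factors collapse, leaving the
  # fixed-effects multinomial logit, which rjags can serve as an
  # independent oracle for under identical priors
  set.seed(94)
  n <- 400
  posS <- sample(1:3, n, TRUE)
  posD <- vapply(posS, function(p) sample(setdiff(1:3, p), 1), 1L)
  zt <- rnorm(n)
  eta_s <- 0.8 + 0.5 * (posS == 1) + 0.4 * zt
  eta_d <- -0.3 - 0.3 * (posD == 3)
  pm <- cbind(1, exp(eta_s), exp(eta_d))
  y <- apply(pm / rowSums(pm), 1, function(p) sample(1:3, 1, prob = p))
  log <- data.frame(
    session_id = "S1", session_date = "2023-01-07", group_id = "G1",
    animal_id = "a01", trial_index = seq_len(n), t_init_s = seq_len(n),
    session_duration_s = n + 1, clock_hour = 8,
    layout_left = "x", layout_middle = "x", layout_right = "x",
    chosen_task = c("picture", "static", "dynamic")[y],
    chosen_position = "left", target_size_deg = NA, target_speed_deg_s = NA,
    outcome = "viewed", touch_x_deg = NA, touch_y_deg = NA,
    response_time_s = NA, reward_ml = 0, picture_index = NA,
    stringsAsFactors = FALSE)
  d <- suppressWarnings(build_design(log))
  d$pos_static <- posS; d$pos_dynamic <- posD
  d$z_time <- zt
  fit <- suppressMessages(
    fit_preference_model(d, chains = 2, iter = 2000, warmup = 500,
                         seed = 95))
  got <- colMeans(do.call(rbind, fit$draws))

  library(rjags)
  jm_str <- "model {
    for (i in 1:n) {
      e[i,1] <- 1
      e[i,2] <- exp(b0[1] + bl[1]*(posS[i]==1) + br[1]*(posS[i]==3)
                    + bt[1]*zt[i] + bs[1]*zs[i])
      e[i,3] <- exp(b0[2] + bl[2]*(posD[i]==1) + br[2]*(posD[i]==3)
                    + bt[2]*zt[i] + bs[2]*zs[i])
      y[i] ~ dcat(e[i,1:3])
    }
    for (j in 1:2) {
      b0[j] ~ dnorm(0, 1)
      bl[j] ~ dnorm(0, 4); br[j] ~ dnorm(0, 4)
      bt[j] ~ dnorm(0, 4); bs[j] ~ dnorm(0, 4)
    }
  }"
  jm <- jags.model(textConnection(jm_str),
                   data = list(n = n, y = y, posS = posS, posD = posD,
                               zt = zt, zs = d$z_session),
                   inits = list(.RNG.name = "base::Mersenne-Twister",
                                .RNG.seed = 96),
                   n.chains = 1, n.adapt = 1000, quiet = TRUE)
  jsamp <- coda.samples(jm, c("b0", "bl", "br", "bt", "bs"), n.iter = 8000)
  jmean <- colMeans(as.matrix(jsamp))
  map <- c("static:(Intercept)" = "b0[1]", "dynamic:(Intercept)" = "b0[2]",
           "static:pos_left" = "bl[1]", "dynamic:pos_left" = "bl[2]",
           "static:pos_right" = "br[1]", "dynamic:pos_right" = "br[2]",
           "static:z_time" = "bt[1]", "dynamic:z_time" = "bt[2]")
  for (nm in names(map)) {
    expect_lt(abs(got[nm] - jmean[map[nm]]), 0.05)
  }
})

test_that("posterior probabilities are normalized and recover preference", {
  sim <- fixture_log(seed = 97, n_sessions = 3, trials_per_session = 80)
  d <- build_design(sim$log)
  fit <- suppressWarnings(
    fit_preference_model(d, chains = 2, iter = 500, warmup = 250,
                         seed = 98))
  expect_identical(fit$divergences, 0L)
  tab <- posterior_task_probs(fit, "a01")
  draws <- attr(tab, "draws")
  expect_equal(rowSums(draws), rep(1, nrow(draws)), tolerance = 1e-12)
  expect_true(all(tab$lower <= tab$mean & tab$mean <= tab$upper))
  # the utility-gap-2 animal prefers static: P(static) well above 1/3
  expect_gt(tab$mean[tab$task == "static"], 0.55)
  v <- preference_verdict(fit, "a01")
  expect_identical(v$verdict, "static")
  expect_error(posterior_task_probs(fit, "nobody"), "unknown animal")
})

test_that("verdicts apply the interval-separation evidence rule", {
  # handcrafted fits whose intercept draws imply known interval layouts
  mk_fit <- function(b0s, b0d, noise) {
    nm <- c("static:(Intercept)", "dynamic:(Intercept)")
    m <- cbind(rnorm(400, b0s, noise), rnorm(400, b0d, noise))
    colnames(m) <- nm
    structure(list(draws = list(m), par_names = nm,
                   animal_levels = "a01",
                   animal_group = c(a01 = "G1")),
              class = "mci_preference_fit")
  }
  set.seed(99)
  # tight, well-separated intervals: clear static preference
  sep <- preference_verdict(mk_fit(3, 0, 0.05), "a01")
  expect_identical(sep$verdict, "static")
  expect_gt(min(sep$table$lower[sep$table$task == "static"]),
            max(sep$table$upper[sep$table$task != "static"]))
  # wide, overlapping intervals: no evidence
  overlap <- preference_verdict(mk_fit(0, 0, 2), "a01")
  expect_identical(overlap$verdict, "none")
})
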