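#' Synthetic behavioral agent
#'
#' A generative stand-in for one animal, with known ground-truth parameters
#' so that every analysis stage has a recoverable target. The choice model
#' mirrors the categorical mixed model used in the preference analysis: on
#' each trial the probability of selecting a task is a softmax over
#' `u_task + b_position(task's button) + gamma_task * t_norm +
#' delta_task * session_idx`. Engagement follows a nonhomogeneous Poisson
#' process with exponentially decaying intensity, and touch accuracy is an
#' isotropic 2-D Gaussian whose spread grows linearly with target speed.
#'
#' @param animal_id,group_id Identifiers.
#' @param u Named length-3 numeric, task utilities on the logit scale
#'   (`static`, `dynamic`, `picture`).
#' @param b Named length-3 numeric, position biases (`left`, `middle`,
#'   `right`); `middle` is the reference and is forced to 0.
#' @param gamma Named length-3 numeric, within-session (normalized time)
#'   slopes per task; the picture entry is the reference (0).
#' @param delta Named length-3 numeric, session-index slopes per task;
#'   picture is the reference (0).
#' @param lambda0 Engagement base rate, trials/second (> 0).
#' @param k Dimensionless engagement decay rate (>= 0); intensity is
#'   `lambda0 * exp(-k * t / T)`.
#' @param sigma0 Touch noise at speed 0, degrees (> 0).
#' @param sigma_v Additional touch noise per unit speed, deg per (deg/s).
#' @param p_ignore Probability of ignoring a reach trial.
#' @param motor_delay_s Base response latency, seconds.
#' @param rt_jitter_s Width of the uniform response-latency jitter, seconds.
#' @return An object of class `mci_agent`.
#' @export
agent_profile <- function(animal_id, group_id = "G1",
                          u = c(static = 0, dynamic = 0, picture = 0),
                          b = c(left = 0, middle = 0, right = 0),
                          gamma = c(static = 0, dynamic = 0, picture = 0),
                          delta = c(static = 0, dynamic = 0, picture = 0),
                          lambda0 = 418 / (8 * 3600), k = 0,
                          sigma0 = 2, sigma_v = 0.08,
                          p_ignore = 0.05,
                          motor_delay_s = 0.8, rt_jitter_s = 0.6) {
  stopifnot(lambda0 > 0, k >= 0, sigma0 > 0, sigma_v >= 0,
            p_ignore >= 0, p_ignore <= 1,
            motor_delay_s >= 0, rt_jitter_s >= 0)
  u <- u[mci_tasks]; gamma <- gamma[mci_tasks]; delta <- delta[mci_tasks]
  b <- b[mci_positions]
  if (anyNA(u) || anyNA(b) || anyNA(gamma) || anyNA(delta))
    stop("u/gamma/delta must name all tasks and b all positions")
  b["middle"] <- 0
  structure(list(animal_id = animal_id, group_id = group_id,
                 u = u, b = b, gamma = gamma, delta = delta,
                 lambda0 = lambda0, k = k, sigma0 = sigma0, sigma_v = sigma_v,
                 p_ignore = p_ignore, motor_delay_s = motor_delay_s,
                 rt_jitter_s = rt_jitter_s),
            class = "mci_agent")
}

#' @method print mci_agent
#' @export
print.mci_agent <- function(x, ...) {
  cat(sprintf("Synthetic agent %s (group %s)\n", x$animal_id, x$group_id))
  cat(sprintf("  utilities: static %.2f dynamic %.2f picture %.2f\n",
              x$u["static"], x$u["dynamic"], x$u["picture"]))
  cat(sprintf("  engagement: lambda0 %.4g /s, decay k %.2f; touch: sigma0 %.2f deg + %.3f deg/(deg/s)\n",
              x$lambda0, x$k, x$sigma0, x$sigma_v))
  invisible(x)
}

#' Trial initiation times from a decaying engagement process
#'
#' Draws event times from a nonhomogeneous Poisson process on `[0, T]` with
#' intensity `lambda(t) = lambda0 * exp(-k * t / T)` by thinning against
#' the homogeneous envelope at `lambda0`. Any `k > 0` concentrates trials
#' in the first half of the session.
#'
#' @param lambda0 Base rate, events/second.
#' @param k Decay rate (>= 0).
#' @param duration Session length `T` in seconds.
#' @return Sorted numeric vector of event times in `[0, T]`.
#' @export
sample_engagement_times <- function(lambda0, k, duration) {
  stopifnot(lambda0 > 0, k >= 0, duration > 0)
  n <- stats::rpois(1, lambda0 * duration)
  t <- sort(stats::runif(n, 0, duration))
  if (k > 0) t <- t[stats::runif(n) < exp(-k * t / duration)]
  t
}

#' Softmax task-choice probabilities of an agent
#'
#' @param profile An [agent_profile()].
#' @param layout Current button layout ([make_layout()]).
#' @param t_norm Normalized session time in `[0, 1]`.
#' @param session_idx Session index (e.g. 1..6).
#' @return Named length-3 probability vector over tasks.
#' @export
task_choice_probs <- function(profile, layout, t_norm = 0, session_idx = 0) {
  pos_of <- vapply(mci_tasks, function(tk) task_position(layout, tk), "")
  eta <- profile$u + profile$b[pos_of] +
    profile$gamma * t_norm + profile$delta * session_idx
  p <- exp(eta - max(eta))
  p <- p / sum(p)
  names(p) <- mci_tasks
  p
}

#' Draw one task choice
#'
#' @inheritParams task_choice_probs
#' @return List with `task` and its current `position`.
#' @export
choose_task <- function(profile, layout, t_norm = 0, session_idx = 0) {
  p <- task_choice_probs(profile, layout, t_norm, session_idx)
  task <- sample(mci_tasks, 1, prob = p)
  list(task = task, position = task_position(layout, task))
}

#' Simulate one touch attempt at a reach target
#'
#' With probability `p_ignore` the agent ignores the trial. Otherwise it
#' plans a touch at latency `motor_delay_s + U(0, rt_jitter_s)`,
#' extrapolates the target's motion to that moment (so the aim point is
#' the target's true position at touch time), and lands with isotropic
#' Gaussian error of sd `sigma0 + sigma_v * v`, clipped to the background
#' region.
#'
#' @param profile An [agent_profile()].
#' @param target An [spawn_target()] state at trial onset.
#' @param geometry An [screen_geometry()] object.
#' @param timeout Trial timeout in seconds; the response latency is capped
#'   just below it.
#' @return Either `list(ignored = TRUE)` or
#'   `list(ignored = FALSE, point = c(x, y), response_time_s = rt)`.
#' @export
attempt_touch <- function(profile, target, geometry = screen_geometry(),
                          timeout = 5) {
  if (stats::runif(1) < profile$p_ignore) return(list(ignored = TRUE))
  rt <- profile$motor_delay_s + stats::runif(1, 0, profile$rt_jitter_s)
  rt <- min(rt, timeout * 0.999)
  v <- sqrt(sum(target$velocity^2))
  at_touch <- if (v > 0) step_target(target, rt, geometry) else target
  sigma <- profile$sigma0 + profile$sigma_v * v
  point <- at_touch$center + stats::rnorm(2, 0, sigma)
  bg <- geometry$background
  point <- c(min(max(point[1], bg["xmin"]), bg["xmax"]),
             min(max(point[2], bg["ymin"]), bg["ymax"]))
  list(ignored = FALSE, point = unname(point), response_time_s = rt)
}

#' Vectorized reach-outcome simulation for one agent
#'
#' Batch version of the touch model of [attempt_touch()] for proficiency
#' studies: for trial `i` a target of diameter `sizes[i]` moving at
#' `speeds[i]` is spawned, and the hit/failure/ignored outcome recorded.
#' Because the agent extrapolates target motion exactly, the hit
#' probability per trial is the Gaussian disc-coverage
#' `1 - exp(-(d/2)^2 / (2 * sigma^2))` with `sigma = sigma0 + sigma_v * v`
#' (up to boundary clipping); this function simulates the touches rather
#' than evaluating that formula.
#'
#' @param profile An [agent_profile()].
#' @param sizes,speeds Equal-length vectors of target diameters (deg) and
#'   speeds (deg/s).
#' @param geometry An [screen_geometry()] object.
#' @return Data frame with columns `target_size_deg`, `target_speed_deg_s`,
#'   `outcome`.
#' @export
simulate_touches <- function(profile, sizes, speeds,
                             geometry = screen_geometry()) {
  stopifnot(length(sizes) == length(speeds))
  n <- length(sizes)
  bg <- geometry$background
  r <- sizes / 2
  # spawn centers (uniform over positions keeping the disc inside)
  cx <- stats::runif(n, bg["xmin"] + r, bg["xmax"] - r)
  cy <- stats::runif(n, bg["ymin"] + r, bg["ymax"] - r)
  ignored <- stats::runif(n) < profile$p_ignore
  sigma <- profile$sigma0 + profile$sigma_v * speeds
  # aim point equals the true target center at touch time; only the
  # Gaussian landing error decides the outcome
  px <- pmin(pmax(cx + stats::rnorm(n, 0, sigma), bg["xmin"]), bg["xmax"])
  py <- pmin(pmax(cy + stats::rnorm(n, 0, sigma), bg["ymin"]), bg["ymax"])
  hit <- sqrt((px - cx)^2 + (py - cy)^2) <= r
  outcome <- ifelse(ignored, "ignored", ifelse(hit, "hit", "failure"))
  data.frame(target_size_deg = sizes, target_speed_deg_s = speeds,
             outcome = outcome, stringsAsFactors = FALSE)
}
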