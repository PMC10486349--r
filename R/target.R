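#' Spawn a reach target
#'
#' Places a red disc of diameter `d` uniformly at random such that it lies
#' fully inside the background region (screen minus task bar), and, for a
#' moving target, draws a direction uniformly on `[0, 2*pi)` at speed `v`.
#'
#' @param d Target diameter, degrees of visual angle.
#' @param v Speed magnitude, degrees per second (0 for the static task).
#' @param geometry An [screen_geometry()] object.
#' @return An object of class `mci_target`: list with `center` (length-2,
#'   deg), `diameter_deg`, and `velocity` (length-2, deg/s).
#' @export
spawn_target <- function(d, v = 0, geometry = screen_geometry()) {
  stopifnot(d > 0, v >= 0)
  bg <- geometry$background
  r <- d / 2
  if (bg["xmax"] - bg["xmin"] < d || bg["ymax"] - bg["ymin"] < d)
    stop("target of diameter ", d, " deg does not fit in the background")
  center <- c(stats::runif(1, bg["xmin"] + r, bg["xmax"] - r),
              stats::runif(1, bg["ymin"] + r, bg["ymax"] - r))
  if (v > 0) {
    theta <- stats::runif(1, 0, 2 * pi)
    vel <- v * c(cos(theta), sin(theta))
  } else {
    vel <- c(0, 0)
  }
  structure(list(center = unname(center), diameter_deg = d,
                 velocity = unname(vel)),
            class = "mci_target")
}

# Fold an unbounded 1-D position into [lo, hi] by specular reflection.
# Returns position and the velocity sign multiplier. Exact for any dt.
fold_reflect <- function(p, v, lo, hi) {
  L <- hi - lo
  u <- (p - lo) %% (2 * L)
  if (u <= L) list(p = lo + u, s = 1) else list(p = lo + 2 * L - u, s = -1)
}

#' Advance a bouncing target
#'
#' Linear motion with specular (mirror) reflection of the disc at the
#' background-region boundary. The reflection is computed analytically by
#' unfolding the trajectory, so the step is exact for arbitrarily large
#' `dt`, the speed magnitude is conserved to machine precision, and the
#' disc can never exit the background region.
#'
#' @param state An `mci_target` from [spawn_target()].
#' @param dt Time step in seconds (> 0).
#' @param geometry An [screen_geometry()] object.
#' @return The advanced `mci_target`.
#' @export
step_target <- function(state, dt, geometry = screen_geometry()) {
  stopifnot(dt > 0)
  r <- state$diameter_deg / 2
  bg <- geometry$background
  cx <- fold_reflect(state$center[1] + state$velocity[1] * dt,
                     state$velocity[1], bg["xmin"] + r, bg["xmax"] - r)
  cy <- fold_reflect(state$center[2] + state$velocity[2] * dt,
                     state$velocity[2], bg["ymin"] + r, bg["ymax"] - r)
  state$center <- unname(c(cx$p, cy$p))
  state$velocity <- unname(c(state$velocity[1] * cx$s,
                             state$velocity[2] * cy$s))
  state
}

#' Classify a screen touch
#'
#' A touch is a *hit* when it lands on the target disc (Euclidean distance
#' from the center at most the radius, boundary inclusive), a *failure*
#' when it lands in the gray background outside the disc, and a *taskbar*
#' touch when it falls in the bottom task-bar strip -- task-bar touches
#' during a trial carry no outcome.
#'
#' @param point Length-2 numeric, touch location in degrees.
#' @param target Optional `mci_target`; with `NULL` no hit is possible.
#' @param geometry An [screen_geometry()] object.
#' @return One of `"hit"`, `"failure"`, `"taskbar"`.
#' @export
classify_touch <- function(point, target = NULL, geometry = screen_geometry()) {
  stopifnot(length(point) == 2)
  if (point[1] < 0 || point[1] > geometry$width_deg ||
      point[2] < 0 || point[2] > geometry$height_deg)
    stop("touch point lies outside the screen")
  if (point[2] < geometry$taskbar_height_deg) return("taskbar")
  if (!is.null(target)) {
    if (sqrt(sum((point - target$center)^2)) <= target$diameter_deg / 2)
      return("hit")
  }
  "failure"
}
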