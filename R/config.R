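#' Session configuration of the multiple-choice paradigm
#'
#' Temporal and stimulus parameters of a session: the 5 s response timeout,
#' the uniform 1.5--2.5 s inter-trial interval, the 0.37 mL fluid reward
#' per hit, the 5 s picture presentation from a 126-picture pool, the
#' hourly button-layout shuffle, an ~8 h session, and the integer grids of
#' target sizes (5..10 deg) and speeds (10..30 deg/s).
#'
#' @param timeout_s Response timeout for the reach tasks, seconds.
#' @param iti_range_s Length-2 range of the uniform inter-trial interval.
#' @param reward_ml Fluid reward per hit, milliliters.
#' @param picture_duration_s Picture presentation time, seconds.
#' @param picture_pool_size Number of pictures in the pool.
#' @param shuffle_period_s Seconds between button-layout shuffles.
#' @param session_duration_s Session length, seconds.
#' @param size_values Integer grid of target diameters, degrees.
#' @param speed_values Integer grid of target speeds, deg/s.
#' @return An object of class `mci_session_config`.
#' @export
session_config <- function(timeout_s = 5,
                           iti_range_s = c(1.5, 2.5),
                           reward_ml = 0.37,
                           picture_duration_s = 5,
                           picture_pool_size = 126,
                           shuffle_period_s = 3600,
                           session_duration_s = 8 * 3600,
                           size_values = 5:10,
                           speed_values = 10:30) {
  stopifnot(timeout_s > 0, length(iti_range_s) == 2,
            iti_range_s[1] <= iti_range_s[2], iti_range_s[1] >= 0,
            reward_ml >= 0, picture_duration_s > 0,
            picture_pool_size >= 1, shuffle_period_s > 0,
            session_duration_s > 0,
            length(size_values) >= 1, length(speed_values) >= 1,
            all(size_values > 0), all(speed_values > 0))
  cfg <- list(timeout_s = timeout_s, iti_range_s = iti_range_s,
              reward_ml = reward_ml, picture_duration_s = picture_duration_s,
              picture_pool_size = picture_pool_size,
              shuffle_period_s = shuffle_period_s,
              session_duration_s = session_duration_s,
              size_values = as.integer(size_values),
              speed_values = as.integer(speed_values))
  class(cfg) <- "mci_session_config"
  cfg
}

#' @method print mci_session_config
#' @export
print.mci_session_config <- function(x, ...) {
  cat("MCI session configuration\n")
  cat(sprintf("  duration %.1f h, layout shuffle every %.0f min\n",
              x$session_duration_s / 3600, x$shuffle_period_s / 60))
  cat(sprintf("  timeout %g s, ITI U(%g, %g) s, reward %g mL/hit\n",
              x$timeout_s, x$iti_range_s[1], x$iti_range_s[2], x$reward_ml))
  cat(sprintf("  picture: %g s from pool of %d\n",
              x$picture_duration_s, x$picture_pool_size))
  cat(sprintf("  sizes {%s} deg, speeds {%s} deg/s\n",
              paste(range(x$size_values), collapse = ".."),
              paste(range(x$speed_values), collapse = "..")))
  invisible(x)
}

#' Read or write a configuration file
#'
#' Geometry and session configuration travel as a single JSON (or YAML)
#' document with two top-level sections, `geometry` and `session`. Fields
#' not present fall back to the defaults of [screen_geometry()] and
#' [session_config()].
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_config()`: list with elements `geometry` and `session`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  geo <- do.call(screen_geometry, as.list(raw$geometry))
  ses <- do.call(session_config, as.list(raw$session))
  list(geometry = geo, session = ses)
}

#' @rdname read_config
#' @param geometry,session Objects to serialize.
#' @export
write_config <- function(path, geometry = screen_geometry(),
                         session = session_config()) {
  geo <- geometry[c("width_cm", "height_cm", "viewing_distance_cm",
                    "taskbar_height_deg")]
  ses <- unclass(session)
  payload <- list(geometry = geo, session = ses)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(payload, path)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
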