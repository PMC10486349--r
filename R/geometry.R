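#' Screen geometry of the touchscreen apparatus
#'
#' Describes the physical touchscreen (a 15-inch panel, 30.4 cm by 22.8 cm by
#' default) viewed from a fixed mouthpiece 24 cm away, together with the
#' height of the task bar, the bottom strip holding the three task buttons.
#' All in-package coordinates are expressed in degrees of visual angle with
#' the origin at the bottom-left screen corner, x to the right and y up; the
#' *background region* (where targets live and touches score) is the screen
#' minus the task-bar strip.
#'
#' Overall screen extents are mapped to degrees symmetrically about the
#' screen center (`2 * atan(extent / 2 / distance)`); individual stimulus
#' sizes use the linear tangent scale of [deg_to_cm()].
#'
#' @param width_cm,height_cm Physical screen size in cm.
#' @param viewing_distance_cm Eye(mouthpiece)-to-screen distance in cm.
#' @param taskbar_height_deg Height of the task-bar strip in degrees of
#'   visual angle. The buttons are 5 degrees in diameter; the default adds a
#'   2-degree margin.
#' @return An object of class `mci_geometry` with the inputs plus derived
#'   fields `width_deg`, `height_deg` and `background` (the rectangle
#'   `c(xmin, xmax, ymin, ymax)` in degrees).
#' @examples
#' geo <- screen_geometry()
#' geo$width_deg
#' @export
screen_geometry <- function(width_cm = 30.4, height_cm = 22.8,
                            viewing_distance_cm = 24,
                            taskbar_height_deg = 7) {
  stopifnot(width_cm > 0, height_cm > 0, viewing_distance_cm > 0,
            taskbar_height_deg > 0)
  width_deg <- 2 * atan(width_cm / 2 / viewing_distance_cm) * 180 / pi
  height_deg <- 2 * atan(height_cm / 2 / viewing_distance_cm) * 180 / pi
  if (taskbar_height_deg >= height_deg)
    stop("taskbar_height_deg must be smaller than the screen height (",
         round(height_deg, 2), " deg)")
  geo <- list(
    width_cm = width_cm, height_cm = height_cm,
    viewing_distance_cm = viewing_distance_cm,
    taskbar_height_deg = taskbar_height_deg,
    width_deg = width_deg, height_deg = height_deg,
    background = c(xmin = 0, xmax = width_deg,
                   ymin = taskbar_height_deg, ymax = height_deg)
  )
  class(geo) <- "mci_geometry"
  geo
}

#' @method print mci_geometry
#' @export
print.mci_geometry <- function(x, ...) {
  cat("Touchscreen geometry\n")
  cat(sprintf("  screen: %.1f x %.1f cm at %.1f cm (%.1f x %.1f deg)\n",
              x$width_cm, x$height_cm, x$viewing_distance_cm,
              x$width_deg, x$height_deg))
  cat(sprintf("  task bar: bottom %.1f deg; background %.1f x %.1f deg\n",
              x$taskbar_height_deg, x$width_deg,
              x$height_deg - x$taskbar_height_deg))
  invisible(x)
}

#' Convert between degrees of visual angle and on-screen centimeters
#'
#' Flat-screen tangent convention for small, centrally referenced stimuli:
#' `cm = distance * tan(deg)`. The two functions are exact inverses.
#'
#' @param angle_deg Visual angle in degrees (non-negative).
#' @param x_cm On-screen extent in cm (non-negative).
#' @param geometry An [screen_geometry()] object.
#' @return Numeric vector of the converted values.
#' @export
deg_to_cm <- function(angle_deg, geometry = screen_geometry()) {
  if (any(angle_deg < 0)) stop("angle_deg must be non-negative")
  geometry$viewing_distance_cm * tan(angle_deg * pi / 180)
}

#' @rdname deg_to_cm
#' @export
cm_to_deg <- function(x_cm, geometry = screen_geometry()) {
  if (any(x_cm < 0)) stop("x_cm must be non-negative")
  atan(x_cm / geometry$viewing_distance_cm) * 180 / pi
}

#' Probability of touching the target by chance
#'
#' The likelihood that an uninformed touch, uniform over the background
#' region, lands on the target disc: the stimulus-to-background surface
#' ratio. Used to correct hit rates for the size-dependence of chance
#' performance. It scales exactly as `d^2` for a fixed background.
#'
#' An explicit per-size `table` (named vector, names = diameters in degrees,
#' values = probabilities) may be supplied instead of the computed area
#' ratio, e.g. a device calibration table; see [xbi_chance_table()].
#'
#' @param d Target diameter(s) in degrees of visual angle.
#' @param geometry An [screen_geometry()] object.
#' @param table Optional named probability vector overriding the computed
#'   ratio.
#' @return Probability (vector) in `[0, 1]`.
#' @export
chance_level <- function(d, geometry = screen_geometry(), table = NULL) {
  if (!is.null(table)) {
    idx <- match(as.character(d), names(table))
    if (anyNA(idx))
      stop("no chance-table entry for size(s): ",
           paste(d[is.na(idx)], collapse = ", "))
    return(unname(table[idx]))
  }
  bg <- geometry$background
  bw <- bg["xmax"] - bg["xmin"]
  bh <- bg["ymax"] - bg["ymin"]
  if (any(d > min(bw, bh)))
    stop("target diameter exceeds the background region")
  unname(pi * (d / 2)^2 / (bw * bh))
}

#' Calibrated per-size chance levels of the reference apparatus
#'
#' The per-size chance probabilities used with the original cage-mounted
#' device (XBI) for the six target diameters 5 to 10 degrees. They deviate
#' from a pure disc-area/background-area ratio at the documented geometry
#' (pixel-level rounding and the rendered background differ from the
#' idealized rectangle), so they are carried as an explicit calibration
#' table rather than recomputed; pass the table to [chance_level()] or to
#' the proficiency functions to reproduce the device's adjustment
#' constants.
#'
#' @return Named numeric vector: names are diameters in degrees ("5".."10"),
#'   values are probabilities.
#' @export
xbi_chance_table <- function() {
  c("5" = 0.0733, "6" = 0.1053, "7" = 0.1441,
    "8" = 0.1881, "9" = 0.2399, "10" = 0.3024)
}
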