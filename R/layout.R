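#' Tasks and button positions of the multiple-choice interface
#'
#' The home screen offers three tasks on a three-button task bar. `mci_tasks`
#' and `mci_positions` are the canonical orderings used throughout the
#' package.
#'
#' @format Character vectors of length 3.
#' @export
mci_tasks <- c("static", "dynamic", "picture")

#' @rdname mci_tasks
#' @export
mci_positions <- c("left", "middle", "right")

#' Draw a button layout
#'
#' Assigns the three tasks to the left/middle/right button positions as a
#' uniformly drawn bijection. During a session the arrangement is
#' re-drawn ("pseudorandomized") every hour; by default a re-draw is
#' rejected until it differs from the previous arrangement, so consecutive
#' epochs never repeat.
#'
#' Consumes the R random number generator; seed it for reproducibility.
#'
#' @param previous Optional previous layout to differ from.
#' @param allow_repeat If `TRUE`, the previous layout may be drawn again.
#' @return Named character vector of class `mci_layout`: names are
#'   positions (`left`, `middle`, `right`), values are tasks.
#' @examples
#' set.seed(1)
#' make_layout()
#' @export
make_layout <- function(previous = NULL, allow_repeat = FALSE) {
  draw <- function() {
    x <- sample(mci_tasks)
    names(x) <- mci_positions
    class(x) <- "mci_layout"
    x
  }
  layout <- draw()
  if (!is.null(previous) && !allow_repeat) {
    while (identical(unclass(layout), unclass(previous))) layout <- draw()
  }
  layout
}

#' @method print mci_layout
#' @export
print.mci_layout <- function(x, ...) {
  cat("Button layout:", paste(names(x), unclass(x), sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}

#' Position of a task's button in a layout
#'
#' @param layout An [make_layout()] layout.
#' @param task One of `"static"`, `"dynamic"`, `"picture"`.
#' @return The position name (`left`, `middle` or `right`).
#' @export
task_position <- function(layout, task) {
  pos <- names(layout)[match(task, unclass(layout))]
  if (is.na(pos)) stop("unknown task: ", task)
  pos
}
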