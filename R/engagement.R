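#' Normalized trial-initiation times
#'
#' Each trial's initiation time divided by the session duration, so that 0
#' is the session start and 1 the session end; order is preserved.
#'
#' @param t_init_s Trial initiation times, seconds from session start.
#' @param duration_s Session duration, seconds (> 0).
#' @return Numeric vector in `[0, 1]`.
#' @export
normalized_trial_times <- function(t_init_s, duration_s) {
  stopifnot(duration_s > 0)
  t_init_s / duration_s
}

#' Median of a distribution of normalized trial times
#'
#' The session proportion by which the animal had performed half of its
#' trials. Standard sample median (mean of the middle two values for even
#' counts).
#'
#' @param values Non-empty numeric vector.
#' @return The median.
#' @export
session_median <- function(values) {
  if (length(values) == 0) stop("cannot take the median of an empty session")
  stats::median(values)
}

#' One-sample shift test of the median distribution against 0.5
#'
#' Two-sided one-sample t-test of the mean of the animal-session medians
#' against the uniform-engagement value 0.5. A mean below 0.5 indicates
#' that animals perform more trials in the first half of the session.
#'
#' @param medians Numeric vector of animal-session medians (N >= 2,
#'   non-degenerate).
#' @return List with `t`, `df` (= N - 1), `p`, `mean` and `n`.
#' @export
shift_test <- function(medians) {
  n <- length(medians)
  if (n < 2) stop("shift_test needs at least two medians")
  if (stats::sd(medians) == 0)
    stop("shift_test undefined for zero-variance medians")
  tt <- stats::t.test(medians, mu = 0.5, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = mean(medians), n = n)
}

#' First-order partial correlation
#'
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`, with
#' a two-sided p-value from `t = r * sqrt((n - 3) / (1 - r^2))` on `n - 3`
#' degrees of freedom.
#'
#' @param x,y,z Equal-length numeric vectors (n >= 3; the p-value needs
#'   n >= 4 and is `NA` otherwise).
#' @return List with `r`, `p`, `df`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n < 3) stop("partial correlation needs at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    stop("partial correlation undefined for constant inputs")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- max(min(r, 1), -1)
  df <- n - 3
  if (df < 1) {
    p <- NA_real_
  } else if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  list(r = r, p = p, df = df)
}

#' Across-session engagement trend of one animal
#'
#' Partial correlation between per-session trial counts and the session
#' index, controlling for session duration, asking whether engagement
#' decays across sessions once duration differences are accounted for.
#'
#' @param trials Per-session trial counts.
#' @param session_idx Session indices.
#' @param duration_s Per-session durations, seconds.
#' @return As [partial_correlation()].
#' @export
trials_trend <- function(trials, session_idx, duration_s) {
  if (length(trials) < 3) stop("trials_trend needs at least 3 sessions")
  partial_correlation(trials, session_idx, duration_s)
}

#' Engagement summary of a trial log
#'
#' Computes, per animal-session, the trial count and the median normalized
#' trial time; across all animal-sessions, the shift test of the medians
#' against 0.5; and per animal (with >= 4 sessions), the partial
#' correlation of trial counts with session index controlling for session
#' duration. Animal-sessions with zero trials simply do not appear in the
#' log and are therefore excluded from the median distribution.
#'
#' @param log Trial-log data frame (labeled).
#' @return Object of class `mci_engagement`: list with `sessions` (one row
#'   per animal-session), `shift` (the cohort test) and `trend` (one row
#'   per animal).
#' @export
analyze_engagement <- function(log) {
  log <- log[!is.na(log$animal_id), , drop = FALSE]
  if (nrow(log) == 0) stop("no labeled trials in the log")
  key <- interaction(log$animal_id, log$session_id, drop = TRUE)
  sessions <- do.call(rbind, lapply(split(log, key), function(d) {
    m <- session_median(normalized_trial_times(d$t_init_s,
                                               d$session_duration_s[1]))
    data.frame(animal_id = d$animal_id[1], session_id = d$session_id[1],
               session_date = d$session_date[1],
               n_trials = nrow(d), duration_s = d$session_duration_s[1],
               median_norm_time = m, stringsAsFactors = FALSE)
  }))
  rownames(sessions) <- NULL
  shift <- shift_test(sessions$median_norm_time)
  trend <- do.call(rbind, lapply(split(sessions, sessions$animal_id),
                                 function(d) {
    d <- d[order(d$session_date), , drop = FALSE]
    na_row <- data.frame(animal_id = d$animal_id[1], n_sessions = nrow(d),
                         r_partial = NA_real_, p = NA_real_,
                         stringsAsFactors = FALSE)
    if (nrow(d) < 3) return(na_row)
    tr <- tryCatch(trials_trend(d$n_trials, seq_len(nrow(d)), d$duration_s),
                   error = function(e) NULL)
    if (is.null(tr)) return(na_row)
    data.frame(animal_id = d$animal_id[1], n_sessions = nrow(d),
               r_partial = tr$r, p = tr$p, stringsAsFactors = FALSE)
  }))
  rownames(trend) <- NULL
  structure(list(sessions = sessions, shift = shift, trend = trend),
            class = "mci_engagement")
}

#' @method print mci_engagement
#' @export
print.mci_engagement <- function(x, ...) {
  cat("Engagement summary\n")
  cat(sprintf("  %d animal-sessions; mean trials/session %.1f\n",
              nrow(x$sessions), mean(x$sessions$n_trials)))
  cat(sprintf("  median-of-medians %.3f; shift test t = %.2f, df = %d, p = %.4g\n",
              stats::median(x$sessions$median_norm_time),
              x$shift$t, x$shift$df, x$shift$p))
  invisible(x)
}
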