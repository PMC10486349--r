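#' Trial-log schema
#'
#' Column names (exact and ordered) of the CSV trial log: one row per
#' trial, UTF-8, comma-separated, missing values as empty strings.
#'
#' @return Character vector of column names.
#' @export
trial_log_columns <- function() {
  c("session_id", "session_date", "group_id", "animal_id", "trial_index",
    "t_init_s", "session_duration_s", "clock_hour",
    "layout_left", "layout_middle", "layout_right",
    "chosen_position", "chosen_task", "target_size_deg",
    "target_speed_deg_s", "outcome", "touch_x_deg", "touch_y_deg",
    "response_time_s", "reward_ml", "picture_index")
}

# zero-row data frame in the schema
empty_trial_log <- function() {
  cols <- trial_log_columns()
  chr <- c("session_id", "session_date", "group_id", "animal_id",
           "layout_left", "layout_middle", "layout_right",
           "chosen_position", "chosen_task", "outcome")
  int <- c("trial_index", "target_size_deg", "target_speed_deg_s",
           "picture_index")
  out <- lapply(cols, function(cl) {
    if (cl %in% chr) character(0)
    else if (cl %in% int) integer(0)
    else numeric(0)
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

valid_outcomes <- c("hit", "failure", "ignored", "viewed")

#' Write or read a trial log
#'
#' Lossless CSV round-trip of the trial log in the fixed schema of
#' [trial_log_columns()]. `read_trial_log()` validates the header, the
#' outcome/task/position enumerations and basic numeric invariants, and
#' reports offending row numbers.
#'
#' @param records Trial-log data frame.
#' @param path File path.
#' @return `read_trial_log()` returns the validated data frame.
#' @export
write_trial_log <- function(records, path) {
  missing_cols <- setdiff(trial_log_columns(), names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  utils::write.csv(records[, trial_log_columns()], path, row.names = FALSE,
                   na = "", quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (!identical(names(df), trial_log_columns()))
    stop("trial log header mismatch; expected exactly: ",
         paste(trial_log_columns(), collapse = ", "))
  if (nrow(df) == 0) return(empty_trial_log())
  to_num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  to_int <- function(x) suppressWarnings(as.integer(ifelse(x == "", NA, x)))
  to_chr <- function(x) ifelse(x == "", NA_character_, x)
  num_cols <- c("t_init_s", "session_duration_s", "clock_hour",
                "touch_x_deg", "touch_y_deg", "response_time_s", "reward_ml")
  int_cols <- c("trial_index", "target_size_deg", "target_speed_deg_s",
                "picture_index")
  for (cl in num_cols) df[[cl]] <- to_num(df[[cl]])
  for (cl in int_cols) df[[cl]] <- to_int(df[[cl]])
  for (cl in setdiff(trial_log_columns(), c(num_cols, int_cols)))
    df[[cl]] <- to_chr(df[[cl]])
  fail <- function(rows, what) {
    if (length(rows))
      stop("invalid trial log: ", what, " at row(s) ",
           paste(utils::head(rows, 5), collapse = ", "),
           if (length(rows) > 5) " ..." else "")
  }
  fail(which(!df$outcome %in% valid_outcomes), "unknown outcome value")
  fail(which(!df$chosen_task %in% mci_tasks), "unknown chosen_task")
  fail(which(!df$chosen_position %in% mci_positions), "unknown chosen_position")
  fail(which(is.na(df$t_init_s) | df$t_init_s < 0), "missing/negative t_init_s")
  fail(which(is.na(df$session_duration_s) | df$session_duration_s <= 0),
       "non-positive session_duration_s")
  fail(which(df$t_init_s > df$session_duration_s),
       "t_init_s beyond session end")
  fail(which((df$outcome == "viewed") != (df$chosen_task == "picture")),
       "outcome 'viewed' inconsistent with chosen_task")
  fail(which(df$outcome == "hit" & df$reward_ml <= 0),
       "hit without reward")
  fail(which(df$outcome != "hit" & df$reward_ml != 0),
       "reward on a non-hit")
  df
}

#' Merge offline animal-identity labels into a trial log
#'
#' Emulates post-hoc manual identification: a labels table keyed by
#' `(session_id, trial_index)` fills empty `animal_id` fields. Labels that
#' conflict with an existing non-empty identity are reported and the
#' original is preserved; labels with no matching trial are reported as
#' unmatched.
#'
#' @param log Trial-log data frame.
#' @param labels Data frame with columns `session_id`, `trial_index`,
#'   `animal_id`; keys must be unique.
#' @return List with `log` (labeled), `conflicts` and `unmatched`
#'   (data frames).
#' @export
merge_labels <- function(log, labels) {
  stopifnot(all(c("session_id", "trial_index", "animal_id") %in% names(labels)))
  key <- function(d) paste(d$session_id, d$trial_index, sep = "\r")
  if (anyDuplicated(key(labels)))
    stop("duplicate (session_id, trial_index) keys in labels")
  idx <- match(key(log), key(labels))
  matched <- !is.na(idx)
  proposed <- labels$animal_id[idx]
  conflict <- matched & !is.na(log$animal_id) & log$animal_id != proposed
  fill <- matched & is.na(log$animal_id)
  log$animal_id[fill] <- proposed[fill]
  unmatched <- labels[!key(labels) %in% key(log), , drop = FALSE]
  list(log = log,
       conflicts = data.frame(
         session_id = log$session_id[conflict],
         trial_index = log$trial_index[conflict],
         existing = log$animal_id[conflict],
         label = proposed[conflict], stringsAsFactors = FALSE),
       unmatched = unmatched)
}
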