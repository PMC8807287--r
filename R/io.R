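# Fixed, versioned CSV formats for the four cohort tables. Missing values
# are encoded as empty fields.

trial_columns <- c("participant_id", "block_index", "trial_index",
                   "stimulus_digit", "is_target", "responded", "rt")
rating_columns <- c("participant_id", "block_index", "fatigue", "motivation")
memory_columns <- c("participant_id", "task", "phase", "item_index",
                    "outcome", "rt")
participant_columns <- c("participant_id", "group", "age", "gender",
                         "days_since_diagnosis", "maintenance_interval")

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s file %s is missing column(s): %s",
                 what, path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read and validate a vigilance trial table
#'
#' Reads the trial CSV (`participant_id, block_index, trial_index,
#' stimulus_digit, is_target, responded, rt`), coerces types, and
#' validates the trial-record invariants: unique (participant, block,
#' trial) keys, targets are exactly the digit-0 trials, and RTs only on
#' responded trials within the (0, 1 s] stimulus window.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_trials <- function(path) {
  df <- read_table_checked(path, trial_columns, "trial")
  df$is_target <- as.logical(df$is_target)
  df$responded <- as.logical(df$responded)
  df$rt <- as.numeric(df$rt)
  key <- paste(df$participant_id, df$block_index, df$trial_index)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (participant, block, trial) key at row %d",
                 anyDuplicated(key)), call. = FALSE)
  }
  bad_target <- which(df$is_target != (df$stimulus_digit == 0))
  if (length(bad_target)) {
    stop(sprintf("is_target inconsistent with stimulus_digit at row %d",
                 bad_target[1]), call. = FALSE)
  }
  has_rt <- !is.na(df$rt)
  bad_rt <- which(has_rt & (!df$responded | df$rt <= 0 | df$rt > 1))
  if (length(bad_rt)) {
    stop(sprintf(
      "rt must accompany a response and lie in (0, 1] seconds: row %d",
      bad_rt[1]), call. = FALSE)
  }
  df
}

#' Read and validate a per-block rating table
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_ratings <- function(path) {
  df <- read_table_checked(path, rating_columns, "rating")
  for (col in c("fatigue", "motivation")) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 100))
    if (length(bad)) {
      stop(sprintf("%s rating outside [0, 100] at row %d", col, bad[1]),
           call. = FALSE)
    }
  }
  df
}

#' Read and validate a memory-probe table
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_memory_probes <- function(path) {
  df <- read_table_checked(path, memory_columns, "memory probe")
  ok_phase <- df$phase %in% c("immediate", "delayed")
  if (!all(ok_phase)) {
    stop(sprintf("unknown phase at row %d", which(!ok_phase)[1]),
         call. = FALSE)
  }
  obj <- df$task == "object"
  ok_out <- !obj | df$outcome %in%
    c("correct", "same_object_wrong_orientation", "other_error")
  if (!all(ok_out)) {
    stop(sprintf("unknown object-task outcome at row %d",
                 which(!ok_out)[1]), call. = FALSE)
  }
  df
}

#' Read and validate a participant metadata table
#'
#' Enforces that `days_since_diagnosis` is present only for participants
#' whose group is the exposed (first) group when `exposed_group` is given.
#'
#' @param path CSV file path.
#' @param exposed_group optional label of the group for which
#'   days-since-diagnosis must be present (and absent elsewhere).
#' @return validated data.frame.
#' @export
read_participants <- function(path, exposed_group = NULL) {
  df <- read_table_checked(path, participant_columns, "participant")
  if (anyDuplicated(df$participant_id)) {
    stop("duplicate participant_id in participant table", call. = FALSE)
  }
  if (any(!is.na(df$maintenance_interval) & df$maintenance_interval <= 0)) {
    stop("maintenance_interval must be positive", call. = FALSE)
  }
  if (!is.null(exposed_group)) {
    has_days <- !is.na(df$days_since_diagnosis)
    if (any(has_days & df$group != exposed_group)) {
      stop(sprintf("days_since_diagnosis present outside group '%s'",
                   exposed_group), call. = FALSE)
    }
  }
  df
}

#' Write a cohort to four CSV files
#'
#' Writes `participants.csv`, `trials.csv`, `ratings.csv` and
#' `memory.csv` with the package's fixed headers; missing values as
#' empty fields.
#'
#' @param cohort a `vigimem_cohort` (or a list with the four tables).
#' @param dir output directory (created if needed).
#' @return invisibly, the four file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("participants.csv", "trials.csv",
                            "ratings.csv", "memory.csv"))
  tables <- cohort[c("participants", "trials", "ratings", "memory")]
  for (i in seq_along(paths)) {
    utils::write.csv(tables[[i]], paths[i], row.names = FALSE, na = "")
  }
  invisible(paths)
}

#' Read a cohort from a directory of CSV files
#'
#' Counterpart of [write_cohort()]; all four tables are validated.
#'
#' @param dir directory containing the four CSVs.
#' @return list of class `vigimem_cohort`.
#' @export
read_cohort <- function(dir) {
  cohort <- list(
    participants = read_participants(file.path(dir, "participants.csv")),
    trials = read_trials(file.path(dir, "trials.csv")),
    ratings = read_ratings(file.path(dir, "ratings.csv")),
    memory = read_memory_probes(file.path(dir, "memory.csv"))
  )
  class(cohort) <- "vigimem_cohort"
  cohort
}
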