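#' Score one memory phase for one participant
#'
#' Counts the outcome categories of an 8-alternative object-memory probe
#' phase: accuracy is the fraction of `correct` choices and the
#' orientation false-alarm rate the fraction of
#' `same_object_wrong_orientation` choices (the misbinding error - right
#' object, wrong orientation).
#'
#' @param records data.frame of probe records for a single participant and
#'   phase, with an `outcome` column and optionally `rt`.
#' @return list with `accuracy`, `orientation_fa` (unit fractions),
#'   `mean_rt` and `n_items`.
#' @examples
#' recs <- data.frame(outcome = c(rep("correct", 12),
#'                                rep("same_object_wrong_orientation", 6),
#'                                rep("other_error", 2)))
#' score_memory_phase(recs)   # accuracy 0.6, orientation_fa 0.3
#' @export
score_memory_phase <- function(records) {
  if (nrow(records) == 0L) {
    stop("no probe records supplied for this phase", call. = FALSE)
  }
  n <- nrow(records)
  list(
    accuracy = sum(records$outcome == "correct") / n,
    orientation_fa =
      sum(records$outcome == "same_object_wrong_orientation") / n,
    mean_rt = if ("rt" %in% names(records)) mean(records$rt, na.rm = TRUE)
              else NA_real_,
    n_items = n
  )
}

#' Memory decrement statistic
#'
#' The raw change is delayed minus immediate accuracy (percentage points
#' when inputs are percentages); the normalized decrement divides the raw
#' change by the immediate accuracy and is expressed in percent. The
#' normalized value is invariant to whether accuracies are supplied as
#' unit fractions or percentages.
#'
#' @param immediate,delayed accuracies on a common scale.
#' @return list with `raw_change` and `normalized` (NA with a zero
#'   immediate accuracy).
#' @examples
#' memory_decrement(50, 40)   # raw -10 points, normalized -20%
#' @export
memory_decrement <- function(immediate, delayed) {
  raw <- delayed - immediate
  list(raw_change = raw,
       normalized = ifelse(immediate > 0, 100 * raw / immediate, NA_real_))
}

#' Group difference in raw memory change
#'
#' `(delayed_b - immediate_b) - (delayed_a - immediate_a)`: how much larger
#' group b's raw accuracy change is than group a's, in percentage points.
#'
#' @param immediate_a,delayed_a,immediate_b,delayed_b group mean accuracies
#'   (percent).
#' @return difference in percentage points.
#' @examples
#' group_raw_change_difference(60.0, 52.5, 60.1, 61.8)   # 9.2
#' @export
group_raw_change_difference <- function(immediate_a, delayed_a,
                                        immediate_b, delayed_b) {
  (delayed_b - immediate_b) - (delayed_a - immediate_a)
}

#' Per-participant memory outcomes
#'
#' Scores both phases of the object-memory probe for every participant and
#' assembles the memory endpoints: immediate/delayed accuracy, raw and
#' normalized memory decrement, and the orientation false-alarm rate at
#' each phase, all as percentages. Participants missing either phase are
#' excluded (listwise) with a message.
#'
#' @param memory probe table (`participant_id`, `task`, `phase`,
#'   `item_index`, `outcome`, `rt`).
#' @param participants optional metadata table; when given, `group` and
#'   `maintenance_interval` are joined onto the result.
#' @param task which task to score (default `"object"`).
#' @return data.frame, one row per participant: `immediate_accuracy`,
#'   `delayed_accuracy`, `raw_change`, `memory_decrement`,
#'   `orientation_fa_immediate`, `orientation_fa_delayed`,
#'   `rt_immediate`, `rt_delayed` (plus joined metadata).
#' @export
score_memory <- function(memory, participants = NULL, task = "object") {
  memory <- memory[memory$task == task, , drop = FALSE]
  if (nrow(memory) == 0L) {
    stop(sprintf("no probe records for task '%s'", task), call. = FALSE)
  }
  one <- function(mm) {
    has <- c("immediate", "delayed") %in% mm$phase
    if (!all(has)) return(NULL)
    imm <- score_memory_phase(mm[mm$phase == "immediate", , drop = FALSE])
    del <- score_memory_phase(mm[mm$phase == "delayed", , drop = FALSE])
    dec <- memory_decrement(100 * imm$accuracy, 100 * del$accuracy)
    data.frame(
      participant_id = mm$participant_id[1],
      immediate_accuracy = 100 * imm$accuracy,
      delayed_accuracy = 100 * del$accuracy,
      raw_change = dec$raw_change,
      memory_decrement = dec$normalized,
      orientation_fa_immediate = 100 * imm$orientation_fa,
      orientation_fa_delayed = 100 * del$orientation_fa,
      rt_immediate = imm$mean_rt,
      rt_delayed = del$mean_rt,
      stringsAsFactors = FALSE
    )
  }
  parts <- split(memory, memory$participant_id)
  rows <- lapply(parts, one)
  dropped <- names(parts)[vapply(rows, is.null, logical(1))]
  if (length(dropped)) {
    message(sprintf("dropping %d participant(s) missing a memory phase: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(participants)) {
    idx <- match(out$participant_id, participants$participant_id)
    out$group <- participants$group[idx]
    if ("maintenance_interval" %in% names(participants)) {
      out$maintenance_interval <- participants$maintenance_interval[idx]
    }
  }
  out
}

#' Residualize memory decrements on maintenance interval
#'
#' Robustness adjustment for comparisons between groups whose delayed
#' probes were separated from the immediate probes by different intervals:
#' the decrement is replaced by the residual of a least-squares regression
#' on the maintenance interval (fitted across all supplied participants),
#' re-centred on the grand mean.
#'
#' @param outcomes output of [score_memory()] containing
#'   `memory_decrement` and `maintenance_interval`.
#' @return `outcomes` with an added `memory_decrement_adj` column.
#' @export
adjust_for_maintenance <- function(outcomes) {
  ok <- !is.na(outcomes$memory_decrement) &
    !is.na(outcomes$maintenance_interval)
  fit <- stats::lm(memory_decrement ~ maintenance_interval,
                   data = outcomes[ok, , drop = FALSE])
  outcomes$memory_decrement_adj <- NA_real_
  outcomes$memory_decrement_adj[ok] <-
    stats::residuals(fit) + mean(outcomes$memory_decrement[ok])
  outcomes
}
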