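#' Classify vigilance trials into signal-detection outcomes
#'
#' Labels every stimulus presentation as a true positive (response to a
#' target), false positive (response to a non-target), false negative
#' (missed target) or true negative (correctly withheld response). A
#' keypress is attributed to the stimulus on screen during its one-second
#' window, which the input format already encodes as `responded`.
#'
#' @param trials data.frame with columns `participant_id`, `block_index`,
#'   `trial_index`, `is_target`, `responded` (and optionally `rt`).
#' @return the input with an `outcome` column in `{"TP","FP","FN","TN"}`.
#' @examples
#' classify_trials(data.frame(participant_id = "p1", block_index = 1,
#'                            trial_index = 0:1, is_target = c(TRUE, FALSE),
#'                            responded = c(TRUE, TRUE)))
#' @export
classify_trials <- function(trials) {
  req <- c("participant_id", "block_index", "trial_index", "is_target",
           "responded")
  miss <- setdiff(req, names(trials))
  if (length(miss)) {
    stop(sprintf("trial table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  key <- paste(trials$participant_id, trials$block_index, trials$trial_index)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (participant, block, trial) keys in trial table (e.g. row %d)",
                 anyDuplicated(key)), call. = FALSE)
  }
  trials$outcome <- ifelse(trials$is_target,
                           ifelse(trials$responded, "TP", "FN"),
                           ifelse(trials$responded, "FP", "TN"))
  trials
}

#' F1 score from outcome counts
#'
#' The harmonic mean of precision and sensitivity,
#' `F1 = 2*TP / (2*TP + FP + FN)`. It emphasizes responses to the rare
#' target and disregards correct rejections, making it suitable for
#' rare-target detection accuracy. Undefined (NA) when the denominator is
#' zero (no targets and no false alarms).
#'
#' @param tp,fp,fn non-negative outcome counts (vectorized).
#' @return F1 in \[0, 1\], or NA where undefined.
#' @examples
#' block_f1(10, 5, 5)   # 2/3
#' @export
block_f1 <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0, na.rm = TRUE)) {
    stop("outcome counts must be non-negative", call. = FALSE)
  }
  denom <- 2 * tp + fp + fn
  ifelse(denom == 0, NA_real_, 2 * tp / denom)
}

#' Trimmed mean reaction time for one block
#'
#' Mean RT over correct (true-positive) responses after excluding RTs more
#' than two sample standard deviations from the block mean. The exclusion
#' is applied once, not iterated. With fewer than three RTs the standard
#' deviation is not a meaningful trimming criterion and exclusion is
#' skipped.
#'
#' @param rts numeric vector of true-positive reaction times (seconds).
#' @return list with `mean_rt` (NA if no RTs) and `n_excluded`.
#' @examples
#' block_rt(c(0.4, 0.5, 0.6))
#' @export
block_rt <- function(rts) {
  rts <- rts[!is.na(rts)]
  if (length(rts) == 0L) return(list(mean_rt = NA_real_, n_excluded = 0L))
  if (length(rts) < 3L) return(list(mean_rt = mean(rts), n_excluded = 0L))
  m <- mean(rts); s <- sd(rts)
  keep <- abs(rts - m) <= 2 * s
  list(mean_rt = mean(rts[keep]), n_excluded = sum(!keep))
}

#' Per-block signal-detection scores for every participant
#'
#' Aggregates classified trials into one row per participant and block:
#' outcome counts, the block F1 score, and the 2-SD-trimmed mean RT over
#' true-positive responses.
#'
#' @param trials trial table (see [classify_trials()]); an `rt` column is
#'   used for RT summaries when present.
#' @return data.frame with columns `participant_id`, `block_index`, `tp`,
#'   `fp`, `fn`, `tn`, `n_trials`, `f1`, `mean_rt`, `n_rt_excluded`.
#' @export
score_blocks <- function(trials) {
  trials <- classify_trials(trials)
  key <- paste(trials$participant_id, trials$block_index, sep = "\r")
  grp <- factor(key, levels = unique(key))
  first <- !duplicated(grp)
  # rowsum may reorder rows; realign by group label
  count_of <- function(lab) {
    cnt <- rowsum((trials$outcome == lab) + 0L, grp)
    as.integer(cnt[match(levels(grp), rownames(cnt)), 1])
  }
  out <- data.frame(
    participant_id = trials$participant_id[first],
    block_index = trials$block_index[first],
    tp = count_of("TP"), fp = count_of("FP"),
    fn = count_of("FN"), tn = count_of("TN"),
    stringsAsFactors = FALSE
  )
  out$n_trials <- out$tp + out$fp + out$fn + out$tn
  out$f1 <- block_f1(out$tp, out$fp, out$fn)

  out$mean_rt <- NA_real_
  out$n_rt_excluded <- 0L
  if ("rt" %in% names(trials)) {
    is_tp_rt <- trials$outcome == "TP" & !is.na(trials$rt)
    if (any(is_tp_rt)) {
      rt_by <- split(trials$rt[is_tp_rt], grp[is_tp_rt])
      trimmed <- lapply(rt_by, block_rt)
      idx <- match(names(rt_by), levels(grp))
      out$mean_rt[idx] <- vapply(trimmed, `[[`, numeric(1), "mean_rt")
      out$n_rt_excluded[idx] <- vapply(trimmed, `[[`, integer(1),
                                       "n_excluded")
    }
  }
  out[order(out$participant_id, out$block_index), , drop = FALSE]
}

#' Per-participant vigilance decrement summary
#'
#' Condenses block scores (and optional per-block ratings) into the
#' participant-level vigilance endpoints. Baseline accuracy is the mean F1
#' over the first three scored minutes (blocks 1-3), final accuracy the
#' mean over the last three (blocks 7-9 for a 9-block task); the practice
#' block (index 0) is never included. The vigilance decrement is the
#' absolute change (final minus baseline) normalized by the baseline and
#' expressed in percent. Rating baselines are means over ratings after
#' blocks 1-3 and rating changes are last-3 minus first-3 means.
#' Accuracies are carried as unit fractions internally and rendered as
#' percentages in the returned table.
#'
#' Participants with an undefined block F1 among the baseline or final
#' blocks, or with a zero baseline, get NA decrements (flagged via
#' `decrement_defined`) and are dropped from normalized-decrement
#' comparisons downstream.
#'
#' @param block_scores output of [score_blocks()].
#' @param ratings optional rating table (`participant_id`, `block_index`,
#'   `fatigue`, `motivation`).
#' @param n_blocks number of scored blocks (default: largest block index).
#' @return data.frame, one row per participant, with percentage-scale
#'   columns `baseline_accuracy`, `final_accuracy`, `absolute_change`,
#'   `vigilance_decrement`, `overall_accuracy`, second-scale `mean_rt`,
#'   `rt_change_normalized` (percent), rating summaries, and the flag
#'   `decrement_defined`.
#' @export
participant_vigilance <- function(block_scores, ratings = NULL,
                                  n_blocks = NULL) {
  n_blocks <- n_blocks %||% max(block_scores$block_index)
  if (n_blocks < 6) {
    stop("need at least 6 scored blocks to define baseline and final windows",
         call. = FALSE)
  }
  base_blocks <- 1:3
  final_blocks <- (n_blocks - 2):n_blocks

  win_mean <- function(x, blk, window, min_n = length(window)) {
    x <- x[blk %in% window]
    if (length(x) < min_n || anyNA(x)) NA_real_ else mean(x)
  }

  one <- function(bs) {
    base <- win_mean(bs$f1, bs$block_index, base_blocks)
    fin <- win_mean(bs$f1, bs$block_index, final_blocks)
    overall <- {
      x <- bs$f1[bs$block_index %in% 1:n_blocks]
      if (anyNA(x) || length(x) < n_blocks) NA_real_ else mean(x)
    }
    abs_change <- fin - base
    decr <- if (!is.na(base) && base > 0 && !is.na(fin)) {
      100 * abs_change / base
    } else NA_real_
    rt_base <- win_mean(bs$mean_rt, bs$block_index, base_blocks, min_n = 1)
    rt_fin <- win_mean(bs$mean_rt, bs$block_index, final_blocks, min_n = 1)
    rt_all <- {
      x <- bs$mean_rt[bs$block_index %in% 1:n_blocks]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }
    data.frame(
      participant_id = bs$participant_id[1],
      baseline_accuracy = 100 * base,
      final_accuracy = 100 * fin,
      absolute_change = 100 * abs_change,
      vigilance_decrement = decr,
      overall_accuracy = 100 * overall,
      mean_rt = rt_all,
      rt_change_normalized = if (!is.na(rt_base) && rt_base > 0 &&
                                 !is.na(rt_fin)) {
        100 * (rt_fin - rt_base) / rt_base
      } else NA_real_,
      decrement_defined = !is.na(decr),
      stringsAsFactors = FALSE
    )
  }

  out <- do.call(rbind, lapply(split(block_scores,
                                     block_scores$participant_id), one))
  rownames(out) <- NULL

  out$fatigue_baseline <- NA_real_
  out$fatigue_change <- NA_real_
  out$motivation_baseline <- NA_real_
  out$motivation_change <- NA_real_
  if (!is.null(ratings)) {
    rsum <- function(rr) {
      fb <- win_mean(rr$fatigue, rr$block_index, base_blocks)
      ff <- win_mean(rr$fatigue, rr$block_index, final_blocks)
      mb <- win_mean(rr$motivation, rr$block_index, base_blocks)
      mf <- win_mean(rr$motivation, rr$block_index, final_blocks)
      c(fb, ff - fb, mb, mf - mb)
    }
    rs <- lapply(split(ratings, ratings$participant_id), rsum)
    idx <- match(out$participant_id, names(rs))
    mat <- do.call(rbind, rs)[idx, , drop = FALSE]
    out$fatigue_baseline <- mat[, 1]
    out$fatigue_change <- mat[, 2]
    out$motivation_baseline <- mat[, 3]
    out$motivation_change <- mat[, 4]
  }
  out
}

#' Score a vigilance trial table end to end
#'
#' Convenience wrapper: [score_blocks()] then [participant_vigilance()].
#'
#' @param trials trial table.
#' @param ratings optional rating table.
#' @param n_blocks number of scored blocks (default inferred).
#' @return per-participant summary data.frame (see
#'   [participant_vigilance()]).
#' @export
score_vigilance <- function(trials, ratings = NULL, n_blocks = NULL) {
  participant_vigilance(score_blocks(trials), ratings, n_blocks)
}

#' Per-minute F1 matrix
#'
#' Arranges block F1 scores as a participants-by-timepoints matrix
#' (including the practice block at t = 0), the input expected by
#' [bootstrap_timeseries()].
#'
#' @param block_scores output of [score_blocks()].
#' @return numeric matrix, rownames participant ids, one column per block
#'   index present.
#' @export
f1_matrix <- function(block_scores) {
  blocks <- sort(unique(block_scores$block_index))
  ids <- unique(block_scores$participant_id)
  m <- matrix(NA_real_, length(ids), length(blocks),
              dimnames = list(ids, paste0("block", blocks)))
  m[cbind(match(block_scores$participant_id, ids),
          match(block_scores$block_index, blocks))] <- block_scores$f1
  m
}
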