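#' Simulate one memory-probe session
#'
#' Draws per-item outcomes for one participant and phase of the
#' 8-alternative object-memory probe. Each item is classified as `correct`,
#' `same_object_wrong_orientation` (the misbinding error: right object,
#' wrong orientation) or `other_error`. At the delayed phase,
#' `misbind_inflation` probability mass is transferred from `correct` to
#' `same_object_wrong_orientation`; the `other_error` mass is unchanged, so
#' the delayed deficit is localized to orientation misbinding.
#'
#' @param n_items number of probe items.
#' @param p_correct probability of a correct choice at the immediate phase.
#' @param p_misbind probability of a same-object/wrong-orientation error at
#'   the immediate phase.
#' @param phase `"immediate"` or `"delayed"`.
#' @param misbind_inflation mass transferred from correct to misbind at the
#'   delayed phase (ignored at the immediate phase). May be negative.
#' @param rt_log_mean,rt_log_sd log-normal response-time parameters.
#' @return data.frame with columns `item_index`, `outcome`, `rt`.
#' @examples
#' set.seed(1)
#' simulate_memory_session(20, p_correct = 0.6, p_misbind = 0.3)
#' @export
simulate_memory_session <- function(n_items, p_correct, p_misbind,
                                    phase = c("immediate", "delayed"),
                                    misbind_inflation = 0,
                                    rt_log_mean = log(3), rt_log_sd = 0.4) {
  phase <- match.arg(phase)
  check_count(n_items, "n_items", min = 1)
  check_prob(p_correct, "p_correct")
  check_prob(p_misbind, "p_misbind")
  if (p_correct + p_misbind > 1) {
    stop_config("p_misbind", "correct + misbind probabilities exceed 1")
  }
  if (phase == "delayed") {
    p_correct <- p_correct - misbind_inflation
    p_misbind <- p_misbind + misbind_inflation
    if (p_correct < 0 || p_correct > 1 || p_misbind < 0 || p_misbind > 1) {
      stop_config("misbind_inflation",
                  "category probabilities fall outside [0, 1] after inflation")
    }
  }
  p <- c(correct = p_correct,
         same_object_wrong_orientation = p_misbind,
         other_error = 1 - p_correct - p_misbind)
  outcome <- sample(names(p), n_items, replace = TRUE, prob = p)
  data.frame(
    item_index = seq_len(n_items) - 1L,
    outcome = outcome,
    rt = exp(rnorm(n_items, rt_log_mean, rt_log_sd)),
    stringsAsFactors = FALSE
  )
}

# Expected value of max(0, 1 - D/tau) for D ~ Uniform(a, b); used to
# renormalize the recovery factor so the configured group-mean drift is
# preserved in expectation.
recovery_normalizer <- function(range, tau) {
  if (is.infinite(tau)) return(1)
  a <- range[1]; b <- range[2]
  if (a >= tau) return(0)
  u <- min(b, tau)
  if (b == a) return(max(0, 1 - a / tau))
  ((u - a) - (u^2 - a^2) / (2 * tau)) / (b - a)
}

# Inverse-CDF draw from a log-normal truncated to (0, upper].
rlnorm_trunc <- function(n, meanlog, sdlog, upper = 1) {
  hi <- plnorm(upper, meanlog, sdlog)
  qlnorm(runif(n, 0, hi), meanlog, sdlog)
}

#' Simulate a two-group cohort of trial-level task data
#'
#' Generates the four tables the analysis pipeline consumes: participant
#' metadata, vigilance trials, per-block fatigue/motivation ratings and
#' memory-probe records. Each participant draws from an RNG stream derived
#' from `(seed, participant index)`, so the cohort is byte-identical for a
#' given configuration and can be extended without perturbing existing
#' participants.
#'
#' The vigilance model: participant i in group g responds to a target in
#' block b with probability `clip(p0_i + drift_i * (b - 2), 0.01, 0.99)`,
#' a linear per-block drift centred so blocks 1-3 average to the
#' participant's baseline hit rate; non-targets elicit false alarms at
#' `fa_rate`. For the group with days-since-diagnosis, the drift is scaled
#' by a recovery factor `max(0, 1 - days/tau)` normalized to mean 1.
#' Reaction times are log-normal truncated to (0, 1 s].
#'
#' @param config a [cohort_config()] object.
#' @param seed optional override of `config$seed`.
#' @return an object of class `vigimem_cohort`: a list with data.frames
#'   `participants`, `trials`, `ratings`, `memory` (see
#'   [write_cohort()] for the fixed column sets).
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_group_a = 4, n_group_b = 4))
#' head(cohort$trials)
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "vigimem_config"))
  validate_cohort_config(config)
  seed <- seed %||% config$seed
  cfg <- config

  n <- c(cfg$n_group_a, cfg$n_group_b)
  group_of <- rep(1:2, n)
  n_total <- sum(n)
  within_idx <- c(seq_len(n[1]), seq_len(n[2]))
  ids <- sprintf("%s_%03d", cfg$group_labels[group_of], within_idx)
  # the RNG stream index depends only on (group, within-group position),
  # so enlarging either group never perturbs existing participants
  stream_idx <- (group_of - 1L) * 1000000L + within_idx

  tpb <- cfg$trials_per_block
  blocks <- 0:cfg$n_blocks          # block 0 is practice
  n_trials <- length(blocks) * tpb
  rec_norm <- recovery_normalizer(cfg$days_since_diagnosis_range,
                                  cfg$recovery_tau_days)

  meta <- vector("list", n_total)
  trl <- vector("list", n_total)
  rat <- vector("list", n_total)
  mem <- vector("list", n_total)

  for (i in seq_len(n_total)) {
    g <- group_of[i]
    with_seed(participant_seed(seed, stream_idx[i]), {
      # --- metadata -------------------------------------------------
      age <- max(18, round(rnorm(1, cfg$age_mean[g], cfg$age_sd[g])))
      gender <- if (runif(1) < cfg$p_female[g]) "female" else "male"
      days <- if (g == 1L) {
        round(runif(1, cfg$days_since_diagnosis_range[1],
                    cfg$days_since_diagnosis_range[2]))
      } else NA_real_
      maintenance <- max(5, rnorm(1, cfg$maintenance_mean[g],
                                  cfg$maintenance_sd[g]))
      grit <- min(5, max(1, rnorm(1, cfg$grit_mean[g], cfg$grit_sd[g])))
      nfi_physical <- max(0, rnorm(1, c(8.4, 9.2)[g], c(4.4, 4.9)[g]))
      hads_anxiety <- max(0, rnorm(1, c(8.0, 8.3)[g], c(4.0, 3.7)[g]))

      # --- participant-level latent structure ------------------------
      r <- cfg$shared_latent_r
      u <- rnorm(1)                       # shared factor
      z_vig <- sqrt(r) * u + sqrt(1 - r) * rnorm(1)
      z_mem <- sqrt(r) * u + sqrt(1 - r) * rnorm(1)

      rec <- if (g == 1L && !is.infinite(cfg$recovery_tau_days)) {
        if (rec_norm > 0) max(0, 1 - days / cfg$recovery_tau_days) / rec_norm
        else 0
      } else 1
      drift <- cfg$hit_drift_per_block[g] * rec + cfg$hit_drift_sd * z_vig
      p0 <- min(0.99, max(0.01, rnorm(1, cfg$baseline_hit_rate_mean[g],
                                      cfg$baseline_hit_rate_sd[g])))

      # --- vigilance trials -----------------------------------------
      block_idx <- rep(blocks, each = tpb)
      p_hit <- pmin(0.99, pmax(0.01, p0 + drift * (block_idx - 2)))
      is_target <- runif(n_trials) < cfg$target_prob
      digit <- ifelse(is_target, 0L,
                      sample(1:9, n_trials, replace = TRUE))
      p_resp <- ifelse(is_target, p_hit, cfg$fa_rate)
      responded <- runif(n_trials) < p_resp
      rt <- rep(NA_real_, n_trials)
      nr <- sum(responded)
      if (nr > 0) {
        rt[responded] <- rlnorm_trunc(nr, cfg$rt_log_mean, cfg$rt_log_sd)
      }
      trl[[i]] <- list(participant_id = rep(ids[i], n_trials),
                       block_index = block_idx,
                       trial_index = rep(seq_len(tpb) - 1L, length(blocks)),
                       stimulus_digit = digit,
                       is_target = is_target,
                       responded = responded,
                       rt = rt)

      # --- ratings (one pair after every block, incl. practice) ------
      fat <- cfg$fatigue_start[g] + cfg$fatigue_slope[g] * blocks +
        rnorm(length(blocks), 0, cfg$rating_sd)
      mot <- cfg$motivation_start[g] + cfg$motivation_slope[g] * blocks +
        rnorm(length(blocks), 0, cfg$rating_sd)
      rat[[i]] <- list(participant_id = rep(ids[i], length(blocks)),
                       block_index = blocks,
                       fatigue = pmin(100, pmax(0, fat)),
                       motivation = pmin(100, pmax(0, mot)))

      # --- memory probes --------------------------------------------
      p_cor <- min(0.99, max(0.01, rnorm(1, cfg$memory_p_correct_immediate[g],
                                         cfg$memory_p_correct_sd)))
      p_mis <- cfg$memory_p_misbind_immediate[g] *
        (1 - p_cor) / (1 - cfg$memory_p_correct_immediate[g])
      p_mis <- min(1 - p_cor, max(0, p_mis))
      delta <- cfg$delay_misbind_inflation[g] + cfg$delay_misbind_sd * z_mem
      delta <- min(min(p_cor, 1 - p_mis), max(max(-p_mis, p_cor - 1), delta))
      imm <- simulate_memory_session(cfg$memory_n_items, p_cor, p_mis,
                                     phase = "immediate",
                                     rt_log_mean = log(3))
      del <- simulate_memory_session(cfg$memory_n_items, p_cor, p_mis,
                                     phase = "delayed",
                                     misbind_inflation = delta,
                                     rt_log_mean = log(2.2))
      k <- cfg$memory_n_items
      mem[[i]] <- list(
        participant_id = rep(ids[i], 2L * k),
        task = rep("object", 2L * k),
        phase = rep(c("immediate", "delayed"), each = k),
        item_index = c(imm$item_index, del$item_index),
        outcome = c(imm$outcome, del$outcome),
        rt = c(imm$rt, del$rt)
      )

      meta[[i]] <- list(participant_id = ids[i],
                        group = cfg$group_labels[g],
                        age = age, gender = gender,
                        days_since_diagnosis = days,
                        maintenance_interval = maintenance,
                        grit = grit, nfi_physical = nfi_physical,
                        hads_anxiety = hads_anxiety)
    })
  }

  bind_rows_list <- function(lst) {
    cols <- names(lst[[1]])
    out <- lapply(cols, function(cn) unlist(lapply(lst, `[[`, cn),
                                            use.names = FALSE))
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }

  cohort <- list(participants = bind_rows_list(meta),
                 trials = bind_rows_list(trl),
                 ratings = bind_rows_list(rat),
                 memory = bind_rows_list(mem))
  attr(cohort, "config") <- cfg
  attr(cohort, "seed") <- as.integer(seed)
  class(cohort) <- "vigimem_cohort"
  cohort
}

#' @export
print.vigimem_cohort <- function(x, ...) {
  cat("<vigimem cohort>\n")
  cat(sprintf("  participants: %d (%s)\n", nrow(x$participants),
              paste(sprintf("%s n=%d", names(table(x$participants$group)),
                            as.integer(table(x$participants$group))),
                    collapse = ", ")))
  cat(sprintf("  vigilance trials: %d; ratings: %d; memory probes: %d\n",
              nrow(x$trials), nrow(x$ratings), nrow(x$memory)))
  invisible(x)
}
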