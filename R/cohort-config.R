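#' Hit rate implied by a target F1 score
#'
#' Under the trial model of the vigilance task (targets at probability
#' `target_prob`, false-alarm probability `fa_rate` on non-targets), the
#' expected outcome counts per block are proportional to TP = q*h,
#' FP = (1-q)*f and FN = q*(1-h), with q the target probability, h the hit
#' probability and f the false-alarm probability. Solving
#' F1 = 2*TP / (2*TP + FP + FN) for h gives the hit rate that yields a
#' desired expected F1. Used to express generator defaults on the accuracy
#' scale the study reports.
#'
#' @param f1 desired F1 score(s), in (0, 1).
#' @param fa_rate false-alarm probability on non-target trials.
#' @param target_prob probability that a trial is a target.
#' @return hit probability (may exceed \[0,1\] for unattainable F1; the
#'   caller is expected to validate).
#' @export
hit_rate_for_f1 <- function(f1, fa_rate = 0.05, target_prob = 0.25) {
  q <- target_prob
  f1 * ((1 - q) * fa_rate + q) / (q * (2 - f1))
}

#' Configuration for a synthetic two-group cohort
#'
#' Builds a validated configuration object for [simulate_cohort()]. The
#' defaults emulate the structure of a two-group online study of COVID-19
#' survivors (group a, n = 53) versus controls (group b, n = 83): a 9-block
#' sustained-attention task of 60 one-second trials per block (plus one
#' practice block, index 0) with 25% target probability, baseline F1
#' accuracy near 75-79% declining over minutes (more steeply in group a), a
#' 20-item 8-alternative object-memory probe tested immediately and ~30
#' minutes later with inflated same-object/wrong-orientation errors at
#' delay in group a, and a recovery-with-time effect that attenuates the
#' vigilance decrement with days since diagnosis.
#'
#' Per-group parameters are length-2 vectors `(group a, group b)`; scalars
#' are recycled.
#'
#' @param n_group_a,n_group_b participants per group.
#' @param group_labels labels for the two groups.
#' @param n_blocks number of scored blocks (a practice block indexed 0 is
#'   always generated in addition).
#' @param trials_per_block trials per one-minute block.
#' @param target_prob probability a trial is a target (digit 0).
#' @param baseline_hit_rate_mean,baseline_hit_rate_sd per-group mean/SD of
#'   the participant-level hit probability at baseline (centre of blocks
#'   1-3). Defaults invert the study-like baseline F1 of 0.755 / 0.785 via
#'   [hit_rate_for_f1()].
#' @param hit_drift_per_block per-group linear change in hit probability
#'   per block. Defaults give expected normalized vigilance decrements of
#'   about -12.3% and -0.9%.
#' @param hit_drift_sd between-participant SD of the drift.
#' @param fa_rate false-alarm probability on non-target trials.
#' @param rt_log_mean,rt_log_sd log-normal reaction-time parameters
#'   (seconds, log scale); RTs are truncated to (0, 1\] to respect the 1-s
#'   stimulus cadence.
#' @param fatigue_start,fatigue_slope,motivation_start,motivation_slope
#'   per-group visual-analogue rating trajectories (0-100 scale; slope per
#'   block).
#' @param rating_sd rating noise SD.
#' @param memory_n_items number of object-memory items per phase.
#' @param memory_p_correct_immediate per-group mean probability of a
#'   correct choice at the immediate probe.
#' @param memory_p_correct_sd between-participant SD of that probability.
#' @param memory_p_misbind_immediate per-group mean probability of a
#'   same-object/wrong-orientation error at the immediate probe.
#' @param delay_misbind_inflation per-group probability mass transferred
#'   from "correct" to "same_object_wrong_orientation" at the delayed
#'   probe; other-error mass is unchanged across phases.
#' @param delay_misbind_sd between-participant SD of the transfer.
#' @param shared_latent_r correlation in \[0,1\] between the participant-
#'   level noise on the vigilance drift and on the misbinding transfer
#'   (the within-participant coupling of the two decrements is not a
#'   published quantity; 0 disables it).
#' @param age_mean,age_sd per-group age distribution (years).
#' @param p_female per-group probability of gender "female".
#' @param days_since_diagnosis_range uniform range (days) for group a's
#'   time since diagnosis; group b has none.
#' @param recovery_tau_days horizon (days) of the recovery model: group a's
#'   drift is scaled by max(0, 1 - days/tau), renormalized to mean 1 over
#'   the configured days distribution so the configured group mean
#'   decrement is preserved. `Inf` disables recovery.
#' @param maintenance_mean,maintenance_sd per-group memory maintenance
#'   interval (minutes) between immediate and delayed probes.
#' @param grit_mean,grit_sd per-group short grit scale scores.
#' @param seed integer seed; every participant draws from an RNG stream
#'   derived from `(seed, participant index)`.
#' @return an object of class `vigimem_config` (a validated list).
#' @examples
#' cfg <- cohort_config(n_group_a = 10, n_group_b = 10, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' @export
cohort_config <- function(n_group_a = 53,
                          n_group_b = 83,
                          group_labels = c("covid", "control"),
                          n_blocks = 9,
                          trials_per_block = 60,
                          target_prob = 0.25,
                          baseline_hit_rate_mean =
                            hit_rate_for_f1(c(0.755, 0.785), fa_rate, target_prob),
                          baseline_hit_rate_sd = c(0.12, 0.12),
                          hit_drift_per_block = (
                            hit_rate_for_f1(c(0.755 * (1 - 0.123),
                                              0.785 * (1 - 0.009)),
                                            fa_rate, target_prob) -
                              baseline_hit_rate_mean) / 6,
                          hit_drift_sd = 0.01,
                          fa_rate = 0.05,
                          rt_log_mean = log(0.45),
                          rt_log_sd = 0.25,
                          fatigue_start = c(62.5, 48.1),
                          fatigue_slope = c(1.32, 2.35),
                          motivation_start = c(58.1, 61.3),
                          motivation_slope = c(-2.6, -2.8),
                          rating_sd = 15,
                          memory_n_items = 20,
                          memory_p_correct_immediate = c(0.600, 0.601),
                          memory_p_correct_sd = 0.12,
                          memory_p_misbind_immediate = c(0.306, 0.286),
                          delay_misbind_inflation = c(0.075, -0.017),
                          delay_misbind_sd = 0.03,
                          shared_latent_r = 0,
                          age_mean = c(28.0, 29.0),
                          age_sd = c(8.6, 10.3),
                          p_female = c(0.434, 0.373),
                          days_since_diagnosis_range = c(5, 330),
                          recovery_tau_days = 270,
                          maintenance_mean = c(27.9, 29.6),
                          maintenance_sd = c(8.7, 9.9),
                          grit_mean = c(3.1, 3.3),
                          grit_sd = c(0.6, 0.8),
                          seed = 1L) {
  two <- function(x) if (length(x) == 1L) rep(x, 2L) else x

  cfg <- list(
    n_group_a = n_group_a, n_group_b = n_group_b,
    group_labels = as.character(group_labels),
    n_blocks = n_blocks, trials_per_block = trials_per_block,
    target_prob = target_prob,
    baseline_hit_rate_mean = two(baseline_hit_rate_mean),
    baseline_hit_rate_sd = two(baseline_hit_rate_sd),
    hit_drift_per_block = two(hit_drift_per_block),
    hit_drift_sd = hit_drift_sd,
    fa_rate = fa_rate,
    rt_log_mean = rt_log_mean, rt_log_sd = rt_log_sd,
    fatigue_start = two(fatigue_start), fatigue_slope = two(fatigue_slope),
    motivation_start = two(motivation_start),
    motivation_slope = two(motivation_slope),
    rating_sd = rating_sd,
    memory_n_items = memory_n_items,
    memory_p_correct_immediate = two(memory_p_correct_immediate),
    memory_p_correct_sd = memory_p_correct_sd,
    memory_p_misbind_immediate = two(memory_p_misbind_immediate),
    delay_misbind_inflation = two(delay_misbind_inflation),
    delay_misbind_sd = delay_misbind_sd,
    shared_latent_r = shared_latent_r,
    age_mean = two(age_mean), age_sd = two(age_sd),
    p_female = two(p_female),
    days_since_diagnosis_range = days_since_diagnosis_range,
    recovery_tau_days = recovery_tau_days,
    maintenance_mean = two(maintenance_mean),
    maintenance_sd = two(maintenance_sd),
    grit_mean = two(grit_mean), grit_sd = two(grit_sd),
    seed = seed
  )
  validate_cohort_config(cfg)
  class(cfg) <- "vigimem_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  check_count(cfg$n_group_a, "n_group_a", min = 1)
  check_count(cfg$n_group_b, "n_group_b", min = 1)
  if (length(cfg$group_labels) != 2L || anyDuplicated(cfg$group_labels)) {
    stop_config("group_labels", "must be two distinct labels")
  }
  check_count(cfg$n_blocks, "n_blocks", min = 1)
  check_count(cfg$trials_per_block, "trials_per_block", min = 1)
  check_prob(cfg$target_prob, "target_prob", allow_zero = FALSE,
             allow_one = FALSE)
  check_prob(cfg$baseline_hit_rate_mean, "baseline_hit_rate_mean")
  if (any(cfg$baseline_hit_rate_sd < 0)) {
    stop_config("baseline_hit_rate_sd", "must be non-negative")
  }
  if (!is.numeric(cfg$hit_drift_per_block) ||
      any(abs(cfg$hit_drift_per_block) > 1)) {
    stop_config("hit_drift_per_block",
                "must be a signed probability change per block in [-1, 1]")
  }
  if (cfg$hit_drift_sd < 0) stop_config("hit_drift_sd", "must be non-negative")
  check_prob(cfg$fa_rate, "fa_rate")
  if (cfg$rt_log_sd <= 0) stop_config("rt_log_sd", "must be positive")
  if (cfg$rating_sd < 0) stop_config("rating_sd", "must be non-negative")
  check_count(cfg$memory_n_items, "memory_n_items", min = 1)
  check_prob(cfg$memory_p_correct_immediate, "memory_p_correct_immediate")
  check_prob(cfg$memory_p_misbind_immediate, "memory_p_misbind_immediate")
  if (any(cfg$memory_p_correct_immediate +
            cfg$memory_p_misbind_immediate > 1)) {
    stop_config("memory_p_misbind_immediate",
                "correct + misbind probabilities must not exceed 1")
  }
  # outcome-category probabilities must remain valid after the delay
  # transfer in both directions
  p_cor_d <- cfg$memory_p_correct_immediate - cfg$delay_misbind_inflation
  p_mis_d <- cfg$memory_p_misbind_immediate + cfg$delay_misbind_inflation
  if (any(p_cor_d < 0 | p_cor_d > 1 | p_mis_d < 0 | p_mis_d > 1)) {
    stop_config("delay_misbind_inflation",
                "delayed-phase category probabilities fall outside [0, 1]")
  }
  if (cfg$shared_latent_r < 0 || cfg$shared_latent_r > 1) {
    stop_config("shared_latent_r", "must lie in [0, 1]")
  }
  if (any(cfg$age_sd < 0)) stop_config("age_sd", "must be non-negative")
  check_prob(cfg$p_female, "p_female")
  d <- cfg$days_since_diagnosis_range
  if (length(d) != 2L || any(d < 0) || d[2] < d[1]) {
    stop_config("days_since_diagnosis_range",
                "must be an increasing non-negative pair (days)")
  }
  if (!(is.infinite(cfg$recovery_tau_days) || cfg$recovery_tau_days > 0)) {
    stop_config("recovery_tau_days", "must be positive (days) or Inf")
  }
  if (any(cfg$maintenance_mean <= 0)) {
    stop_config("maintenance_mean", "must be positive (minutes)")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)) {
    stop_config("seed", "must be a single integer")
  }
  invisible(cfg)
}

#' @export
print.vigimem_config <- function(x, ...) {
  cat("<vigimem cohort configuration>\n")
  cat(sprintf("  groups: %s (n=%d) vs %s (n=%d)\n",
              x$group_labels[1], x$n_group_a,
              x$group_labels[2], x$n_group_b))
  cat(sprintf("  vigilance: %d blocks x %d trials (+practice), P(target)=%.2f\n",
              x$n_blocks, x$trials_per_block, x$target_prob))
  cat(sprintf("  baseline hit rate: %.3f / %.3f; drift per block: %+.4f / %+.4f\n",
              x$baseline_hit_rate_mean[1], x$baseline_hit_rate_mean[2],
              x$hit_drift_per_block[1], x$hit_drift_per_block[2]))
  cat(sprintf("  memory: %d items, P(correct) %.2f / %.2f, delay misbind %+.3f / %+.3f\n",
              x$memory_n_items,
              x$memory_p_correct_immediate[1], x$memory_p_correct_immediate[2],
              x$delay_misbind_inflation[1], x$delay_misbind_inflation[2]))
  cat(sprintf("  seed: %d\n", as.integer(x$seed)))
  invisible(x)
}
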