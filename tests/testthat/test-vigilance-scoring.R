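test_that("trial classification follows the signal-detection taxonomy", {
  tr <- data.frame(participant_id = "p1", block_index = 1,
                   trial_index = 0:3,
                   is_target = c(TRUE, FALSE, TRUE, FALSE),
                   responded = c(TRUE, TRUE, FALSE, FALSE))
  out <- classify_trials(tr)
  expect_equal(out$outcome, c("TP", "FP", "FN", "TN"))
  dup <- rbind(tr, tr[1, ])
  expect_error(classify_trials(dup), "duplicate")
})

test_that("block F1 matches hand examples and the harmonic-mean oracle", {
  expect_equal(block_f1(45, 0, 0), 1)
  expect_equal(block_f1(0, 0, 15), 0)
  expect_equal(block_f1(10, 5, 5), 2 / 3)
  expect_true(is.na(block_f1(0, 0, 0)))
  expect_error(block_f1(-1, 0, 0), "non-negative")
  set.seed(101)
  for (i in 1:1000) {
    tp <- rpois(1, 8); fp <- rpois(1, 3); fn <- rpois(1, 4)
    expect_equal(block_f1(tp, fp, fn), oracle_f1(tp, fp, fn))
  }
})

test_that("F1 is monotone in TP, FP and FN", {
  set.seed(7)
  for (i in 1:200) {
    tp <- sample(0:30, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    f <- block_f1(tp, fp, fn)
    if (is.na(f)) next
    expect_gte(block_f1(tp + 1, fp, fn), f)
    expect_lte(block_f1(tp, fp + 1, fn), f)
    expect_lte(block_f1(tp, fp, fn + 1), f)
  }
  # f1 = 1 iff no errors and at least one hit
  expect_equal(block_f1(1, 0, 0), 1)
  expect_lt(block_f1(10, 1, 0), 1)
  expect_lt(block_f1(10, 0, 1), 1)
})

test_that("RT trimming applies the 2-SD rule once and skips tiny blocks", {
  expect_equal(block_rt(c(0.4, 0.5, 0.6)),
               list(mean_rt = 0.5, n_excluded = 0L))
  expect_equal(block_rt(0.4), list(mean_rt = 0.4, n_excluded = 0L))
  expect_equal(block_rt(c(0.4, 0.9)),
               list(mean_rt = 0.65, n_excluded = 0L))
  expect_equal(block_rt(numeric()),
               list(mean_rt = NA_real_, n_excluded = 0L))
  # injected gross outlier is excluded and the trimmed mean matches a
  # brute-force recomputation
  set.seed(33)
  rts <- c(rlnorm(100, log(0.45), 0.2), 5)
  got <- block_rt(rts)
  want <- oracle_trimmed_rt(rts)
  expect_equal(got$mean_rt, want$mean_rt)
  expect_equal(got$n_excluded, want$n_excluded)
  expect_gte(got$n_excluded, 1L)
  # oracle equivalence over random small blocks
  for (i in 1:1000) {
    n <- sample(1:12, 1)
    rts <- rlnorm(n, log(0.5), 0.4)
    if (runif(1) < 0.3) rts <- c(rts, runif(1, 2, 6))
    got <- block_rt(rts)
    want <- oracle_trimmed_rt(rts)
    expect_equal(got$mean_rt, want$mean_rt)
    expect_equal(got$n_excluded, want$n_excluded)
  }
})

test_that("block scores conserve trial counts and align with hand-built data", {
  tr <- make_tiny_trials()
  bs <- score_blocks(tr)
  expect_equal(nrow(bs), 10)
  expect_true(all(bs$tp == 10 & bs$fn == 5 & bs$fp == 2 & bs$tn == 43))
  expect_true(all(bs$tp + bs$fp + bs$fn + bs$tn == 60))
  expect_equal(bs$f1, rep(oracle_f1(10, 2, 5), 10))
  expect_equal(bs$mean_rt, rep(0.5, 10))
})

test_that("scoring is invariant to trial row order", {
  cohort <- simulate_cohort(cohort_config(n_group_a = 3, n_group_b = 3,
                                          seed = 8))
  bs1 <- score_blocks(cohort$trials)
  set.seed(1)
  shuffled <- cohort$trials[sample(nrow(cohort$trials)), ]
  bs2 <- score_blocks(shuffled)
  o <- function(d) {
    d <- d[order(d$participant_id, d$block_index), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(o(bs1), o(bs2))
})

test_that("participant summary computes decrements as defined", {
  mk_scores <- function(f1s) {
    data.frame(participant_id = "p1", block_index = 0:9,
               f1 = f1s, mean_rt = 0.5, n_rt_excluded = 0L)
  }
  flat <- participant_vigilance(mk_scores(rep(0.7, 10)))
  expect_equal(flat$absolute_change, 0)
  expect_equal(flat$vigilance_decrement, 0)
  expect_equal(flat$baseline_accuracy, 70)
  declining <- participant_vigilance(
    mk_scores(c(0.85, 0.80, 0.80, 0.80, 0.75, 0.7, 0.65, 0.6, 0.6, 0.6)))
  expect_equal(declining$baseline_accuracy, 80)
  expect_equal(declining$final_accuracy, 60)
  expect_equal(declining$absolute_change, -20)
  expect_equal(declining$vigilance_decrement, -25)
  # group-level mean trajectory: baseline 75.5% falling to 67.8% gives an
  # absolute change of -7.7 points
  traj <- participant_vigilance(
    mk_scores(c(0.76, rep(0.755, 3), 0.73, 0.71, 0.70, rep(0.678, 3))))
  expect_equal(traj$absolute_change, 67.8 - 75.5, tolerance = 1e-9)
  # zero baseline: decrement undefined and flagged
  zero <- participant_vigilance(
    mk_scores(c(0.5, 0, 0, 0, 0.1, 0.1, 0.1, 0.2, 0.2, 0.2)))
  expect_true(is.na(zero$vigilance_decrement))
  expect_false(zero$decrement_defined)
})

test_that("practice block is scored but excluded from baseline and final", {
  bs <- data.frame(participant_id = "p1", block_index = 0:9,
                   f1 = c(0.1, rep(0.8, 9)), mean_rt = NA_real_,
                   n_rt_excluded = 0L)
  s <- participant_vigilance(bs)
  expect_equal(s$baseline_accuracy, 80)
  expect_equal(s$overall_accuracy, 80)
})

test_that("rating summaries use first-3 and last-3 block windows", {
  bs <- data.frame(participant_id = "p1", block_index = 0:9, f1 = 0.8,
                   mean_rt = NA_real_, n_rt_excluded = 0L)
  ratings <- data.frame(participant_id = "p1", block_index = 0:9,
                        fatigue = seq(10, 100, by = 10),
                        motivation = rep(50, 10))
  s <- participant_vigilance(bs, ratings)
  expect_equal(s$fatigue_baseline, mean(c(20, 30, 40)))
  expect_equal(s$fatigue_change, mean(c(80, 90, 100)) - mean(c(20, 30, 40)))
  expect_equal(s$motivation_change, 0)
})

test_that("zero-drift cohorts have decrements centred on zero", {
  cfg <- cohort_config(n_group_a = 150, n_group_b = 150,
                       hit_drift_per_block = 0,
                       recovery_tau_days = Inf, seed = 55)
  vig <- score_vigilance(simulate_cohort(cfg)$trials)
  dec <- vig$vigilance_decrement[!is.na(vig$vigilance_decrement)]
  se <- sd(dec) / sqrt(length(dec))
  expect_lt(abs(mean(dec)), 3 * se)
})

test_that("f1_matrix arranges scores participants x timepoints", {
  cohort <- simulate_cohort(cohort_config(n_group_a = 2, n_group_b = 2,
                                          seed = 9))
  bs <- score_blocks(cohort$trials)
  m <- f1_matrix(bs)
  expect_equal(dim(m), c(4, 10))
  expect_equal(m["covid_001", "block3"],
               bs$f1[bs$participant_id == "covid_001" &
                       bs$block_index == 3])
})
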