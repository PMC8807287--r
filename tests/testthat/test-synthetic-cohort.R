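small_cfg <- function(...) {
  cohort_config(n_group_a = 6, n_group_b = 6, seed = 11, ...)
}

test_that("cohorts are byte-identical given config and seed", {
  c1 <- simulate_cohort(small_cfg())
  c2 <- simulate_cohort(small_cfg())
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$trials, c2$trials)
  expect_identical(c1$ratings, c2$ratings)
  expect_identical(c1$memory, c2$memory)
  c3 <- simulate_cohort(small_cfg(), seed = 12)
  expect_false(identical(c1$trials, c3$trials))
})

test_that("extending a cohort leaves existing participants untouched", {
  c1 <- simulate_cohort(cohort_config(n_group_a = 5, n_group_b = 3,
                                      seed = 4))
  c2 <- simulate_cohort(cohort_config(n_group_a = 8, n_group_b = 3,
                                      seed = 4))
  shared <- c1$participants$participant_id
  t1 <- c1$trials[c1$trials$participant_id %in% shared, ]
  t2 <- c2$trials[c2$trials$participant_id %in% shared, ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_identical(t1, t2)
  m1 <- c1$memory[c1$memory$participant_id %in% shared, ]
  m2 <- c2$memory[c2$memory$participant_id %in% shared, ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_identical(m1, m2)
})

test_that("trial counts and target fraction follow the task structure", {
  cohort <- simulate_cohort(cohort_config(n_group_a = 10, n_group_b = 10,
                                          seed = 3))
  counts <- table(cohort$trials$participant_id)
  expect_true(all(counts == (9 + 1) * 60))
  # pooled target fraction within binomial 99% bounds of 0.25
  n <- nrow(cohort$trials)
  bounds <- binom_bounds99(0.25, n)
  frac <- mean(cohort$trials$is_target)
  expect_gt(frac, bounds[1])
  expect_lt(frac, bounds[2])
  # trial invariants
  expect_true(all(cohort$trials$is_target ==
                    (cohort$trials$stimulus_digit == 0)))
  has_rt <- !is.na(cohort$trials$rt)
  expect_true(all(cohort$trials$responded[has_rt]))
  expect_true(all(cohort$trials$rt[has_rt] > 0 &
                    cohort$trials$rt[has_rt] <= 1))
  # ratings: one pair per block incl. practice, within scale
  expect_true(all(table(cohort$ratings$participant_id) == 10))
  expect_true(all(cohort$ratings$fatigue >= 0 &
                    cohort$ratings$fatigue <= 100))
  expect_true(all(cohort$ratings$motivation >= 0 &
                    cohort$ratings$motivation <= 100))
  # memory: both phases, n_items records each, known categories
  tab <- table(cohort$memory$participant_id, cohort$memory$phase)
  expect_true(all(tab == 20))
  expect_true(all(cohort$memory$outcome %in%
                    c("correct", "same_object_wrong_orientation",
                      "other_error")))
  # metadata invariants
  pm <- cohort$participants
  expect_true(all(is.na(pm$days_since_diagnosis[pm$group == "control"])))
  expect_true(all(!is.na(pm$days_since_diagnosis[pm$group == "covid"])))
  expect_true(all(pm$maintenance_interval > 0))
})

test_that("memory session respects degenerate and chance-level regimes", {
  set.seed(1)
  all_correct <- simulate_memory_session(20, p_correct = 1, p_misbind = 0)
  expect_true(all(all_correct$outcome == "correct"))
  # uniform guessing over 8 options: long-run accuracy at chance (12.5%)
  guess <- simulate_memory_session(40000, p_correct = 1 / 8,
                                   p_misbind = 3 / 8)
  acc <- mean(guess$outcome == "correct")
  bounds <- binom_bounds99(1 / 8, 40000)
  expect_gt(acc, bounds[1])
  expect_lt(acc, bounds[2])
  # zero inflation: immediate and delayed distributions match in
  # expectation
  set.seed(2)
  imm <- simulate_memory_session(60000, 0.6, 0.3, phase = "immediate")
  del <- simulate_memory_session(60000, 0.6, 0.3, phase = "delayed",
                                 misbind_inflation = 0)
  expect_equal(mean(imm$outcome == "correct"),
               mean(del$outcome == "correct"), tolerance = 0.01)
  expect_equal(mean(imm$outcome == "same_object_wrong_orientation"),
               mean(del$outcome == "same_object_wrong_orientation"),
               tolerance = 0.01)
  # invalid probabilities after inflation are refused
  expect_error(simulate_memory_session(20, 0.1, 0.3, phase = "delayed",
                                       misbind_inflation = 0.5),
               "misbind_inflation")
})

test_that("delayed probes inflate misbinding by the configured mass", {
  set.seed(5)
  n <- 50000
  imm <- simulate_memory_session(n, 0.6, 0.3, phase = "immediate")
  del <- simulate_memory_session(n, 0.6, 0.3, phase = "delayed",
                                 misbind_inflation = 0.08)
  d_mis <- mean(del$outcome == "same_object_wrong_orientation") -
    mean(imm$outcome == "same_object_wrong_orientation")
  se <- sqrt(2 * 0.35 * 0.65 / n)
  expect_lt(abs(d_mis - 0.08), 3 * se)
  # other-error mass unchanged
  d_other <- mean(del$outcome == "other_error") -
    mean(imm$outcome == "other_error")
  expect_lt(abs(d_other), 3 * sqrt(2 * 0.1 * 0.9 / n))
})

test_that("configured group decrement difference is recovered at n=200", {
  cfg <- cohort_config(n_group_a = 200, n_group_b = 200, seed = 2024)
  cohort <- simulate_cohort(cfg)
  vig <- score_vigilance(cohort$trials)
  grp <- cohort$participants$group[match(vig$participant_id,
                                         cohort$participants$participant_id)]
  dec_a <- vig$vigilance_decrement[grp == "covid"]
  dec_b <- vig$vigilance_decrement[grp == "control"]
  delta_hat <- mean(dec_a, na.rm = TRUE) - mean(dec_b, na.rm = TRUE)
  se <- sqrt(var(dec_a, na.rm = TRUE) / sum(!is.na(dec_a)) +
               var(dec_b, na.rm = TRUE) / sum(!is.na(dec_b)))
  expect_lt(abs(delta_hat - (-12.3 - (-0.9))), 3 * se)
})
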