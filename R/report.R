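# End-to-end analysis: scoring -> decrements -> parametric + resampling
# endpoints -> time-binned and correlation analyses -> Bonferroni.

DAYS_PER_MONTH <- 30.44

group_summary <- function(values, groups, labels) {
  do.call(rbind, lapply(labels, function(g) {
    v <- values[groups == g & !is.na(values)]
    data.frame(group = g, mean = mean(v), sd = stats::sd(v),
               n = length(v), stringsAsFactors = FALSE)
  }))
}

endpoint_comparison <- function(values, groups, labels, n_iter, seed,
                                alpha = 0.05) {
  a <- values[groups == labels[1]]
  b <- values[groups == labels[2]]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) return(NULL)
  list(summary = group_summary(values, groups, labels),
       t_test = pooled_t(a, b),
       bootstrap = bootstrap_group_test(a, b, n_iter = n_iter,
                                        alpha = alpha, seed = seed))
}

#' Bin an endpoint by time since diagnosis and compare bins to controls
#'
#' Splits the exposed group's participants into time-since-diagnosis bins
#' (months, `days / 30.44`) at the supplied edges and compares each bin's
#' endpoint values against the control group with a bootstrap group test
#' and a pooled t-test. Empty bins are reported as empty rather than
#' raising an error.
#'
#' @param values named-by-nothing numeric endpoint values, one per
#'   participant (aligned with `participants` rows).
#' @param participants metadata table with `group` and
#'   `days_since_diagnosis`.
#' @param exposed_group,control_group group labels.
#' @param edges_months bin edges in months (default `c(2, 9)` giving bins
#'   0-2, 2-9, >9 months).
#' @param n_iter,seed,alpha bootstrap settings.
#' @return list with `bins` (data.frame: bin label, n, mean, se) and
#'   `tests` (one comparison per non-empty bin).
#' @export
bin_by_time_since_diagnosis <- function(values, participants,
                                        exposed_group, control_group,
                                        edges_months = c(2, 9),
                                        n_iter = 10000, seed = NULL,
                                        alpha = 0.05) {
  stopifnot(length(values) == nrow(participants))
  months <- participants$days_since_diagnosis / DAYS_PER_MONTH
  exp_idx <- participants$group == exposed_group & !is.na(values)
  if (!any(exp_idx & !is.na(months))) {
    stop("days_since_diagnosis absent for the exposed group",
         call. = FALSE)
  }
  ctrl <- values[participants$group == control_group & !is.na(values)]
  breaks <- c(0, edges_months, Inf)
  labels <- paste0(utils::head(breaks, -1), "-",
                   ifelse(is.finite(breaks[-1]), breaks[-1], "Inf"), "m")
  bin_of <- cut(months, breaks, labels = labels, include.lowest = TRUE)

  bins <- do.call(rbind, lapply(labels, function(lb) {
    v <- values[exp_idx & !is.na(bin_of) & bin_of == lb]
    data.frame(bin = lb, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                    else NA_real_,
               stringsAsFactors = FALSE)
  }))
  tests <- lapply(labels, function(lb) {
    v <- values[exp_idx & !is.na(bin_of) & bin_of == lb]
    if (length(v) < 2 || length(ctrl) < 2) return(NULL)
    list(t_test = pooled_t(v, ctrl),
         bootstrap = bootstrap_group_test(v, ctrl, n_iter = n_iter,
                                          alpha = alpha, seed = seed))
  })
  names(tests) <- labels
  list(bins = bins, tests = tests)
}

#' Run the full two-group analysis pipeline
#'
#' Takes the four cohort tables through every stage: vigilance block
#' scoring and participant decrement summaries, memory outcomes and the
#' misbinding decomposition, group summaries with pooled t-tests and JZS
#' Bayes factors, the bootstrap time-series divergence mask over
#' per-minute F1, bootstrap group tests for the decrement endpoints,
#' Spearman and partial correlations of the decrements with days since
#' diagnosis (controlling age and grit when available), time-binned
#' comparisons against controls, and Bonferroni adjustment of the battery
#' endpoint p-values.
#'
#' With a single-group cohort, group comparisons and time-series
#' endpoints are skipped (with a message) and within-group summaries are
#' still produced.
#'
#' @param cohort a `vigimem_cohort` or list with `participants`,
#'   `trials`, `ratings`, `memory` tables.
#' @param groups optional two group labels `(exposed, control)`; default
#'   the cohort's group levels in order of appearance.
#' @param n_iter bootstrap iterations for every resampling endpoint.
#' @param alpha significance level.
#' @param bonferroni_m family size for Bonferroni adjustment over the
#'   battery endpoints (default 29, the full test-battery ledger).
#' @param vigilance_bin_edges,memory_bin_edges time-since-diagnosis bin
#'   edges in months.
#' @param seed integer seed governing every resampling endpoint.
#' @return object of class `vigimem_report`: a nested list with elements
#'   `vigilance` (per-participant summary, endpoint comparisons,
#'   `timeseries` mask), `memory` (outcomes, comparisons, one-sample
#'   tests, misbinding), `correlations`, `time_bins`, `bonferroni`, and
#'   `provenance` (seed, n_iter, package version, group ns).
#' @export
run_full_analysis <- function(cohort, groups = NULL, n_iter = 10000,
                              alpha = 0.05, bonferroni_m = 29,
                              vigilance_bin_edges = c(2, 9),
                              memory_bin_edges = 6,
                              seed = 1L) {
  participants <- cohort$participants
  groups <- groups %||% unique(participants$group)
  two_groups <- length(groups) >= 2L
  if (!two_groups) {
    message("single-group cohort: group comparisons and time-series ",
            "endpoints skipped")
  }

  ## --- vigilance scoring -------------------------------------------
  blocks <- score_blocks(cohort$trials)
  vig <- score_vigilance(cohort$trials, cohort$ratings)
  vig$group <- participants$group[match(vig$participant_id,
                                        participants$participant_id)]

  vig_endpoints <- c("baseline_accuracy", "final_accuracy",
                     "overall_accuracy", "absolute_change",
                     "vigilance_decrement", "mean_rt",
                     "rt_change_normalized", "fatigue_baseline",
                     "fatigue_change", "motivation_baseline",
                     "motivation_change")
  vig_comparisons <- NULL
  timeseries <- NULL
  if (two_groups) {
    vig_comparisons <- lapply(stats::setNames(vig_endpoints,
                                              vig_endpoints),
                              function(ep) {
      endpoint_comparison(vig[[ep]], vig$group, groups, n_iter, seed,
                          alpha)
    })
    f1m <- f1_matrix(blocks)
    gid <- participants$group[match(rownames(f1m),
                                    participants$participant_id)]
    timeseries <- bootstrap_timeseries(
      f1m[gid == groups[1], , drop = FALSE],
      f1m[gid == groups[2], , drop = FALSE],
      n_iter = n_iter, alpha = alpha, seed = seed)
  } else {
    vig_comparisons <- lapply(stats::setNames(vig_endpoints,
                                              vig_endpoints),
                              function(ep) {
      list(summary = group_summary(vig[[ep]], vig$group, groups))
    })
  }

  ## --- memory scoring ----------------------------------------------
  memory <- NULL
  mem_comparisons <- NULL
  mem_one_sample <- NULL
  misbinding <- NULL
  if (!is.null(cohort$memory) && nrow(cohort$memory) > 0) {
    memory <- score_memory(cohort$memory, participants)
    mem_endpoints <- c("immediate_accuracy", "delayed_accuracy",
                       "raw_change", "memory_decrement",
                       "orientation_fa_immediate", "orientation_fa_delayed")
    if (two_groups) {
      mem_comparisons <- lapply(stats::setNames(mem_endpoints,
                                                mem_endpoints),
                                function(ep) {
        endpoint_comparison(memory[[ep]], memory$group, groups, n_iter,
                            seed, alpha)
      })
      sums <- mem_comparisons$immediate_accuracy$summary
      dsums <- mem_comparisons$delayed_accuracy$summary
      misbinding <- list(
        raw_change_difference = group_raw_change_difference(
          sums$mean[1], dsums$mean[1], sums$mean[2], dsums$mean[2]),
        fa_comparison_immediate =
          mem_comparisons$orientation_fa_immediate$t_test,
        fa_comparison_delayed =
          mem_comparisons$orientation_fa_delayed$t_test)
    } else {
      mem_comparisons <- lapply(stats::setNames(mem_endpoints,
                                                mem_endpoints),
                                function(ep) {
        list(summary = group_summary(memory[[ep]], memory$group, groups))
      })
    }
    mem_one_sample <- lapply(stats::setNames(groups, groups),
                             function(g) {
      v <- memory$memory_decrement[memory$group == g]
      v <- v[!is.na(v)]
      if (length(v) >= 2) one_sample_t(v) else NULL
    })
  }

  ## --- correlations -------------------------------------------------
  correlations <- NULL
  time_bins <- NULL
  exp_days <- participants$days_since_diagnosis[
    participants$group == groups[1]]
  if (any(!is.na(exp_days))) {
    pick <- function(df, col) {
      idx <- participants$group == groups[1]
      v <- df[[col]][match(participants$participant_id[idx],
                           df$participant_id)]
      list(v = v, days = participants$days_since_diagnosis[idx],
           age = participants$age[idx],
           grit = if ("grit" %in% names(participants)) {
             participants$grit[idx]
           } else NULL)
    }
    corr_block <- function(df, col) {
      z <- pick(df, col)
      ok <- stats::complete.cases(z$v, z$days)
      if (sum(ok) < 4) return(NULL)
      out <- list(spearman = spearman_cor(z$v, z$days))
      cov <- data.frame(age = z$age)
      if (!is.null(z$grit)) cov$grit <- z$grit
      out$partial <- tryCatch(partial_spearman(z$v, z$days, cov),
                              error = function(e) NULL)
      out
    }
    correlations <- list(
      vigilance_decrement_vs_days = corr_block(vig, "vigilance_decrement"),
      memory_decrement_vs_days = if (!is.null(memory)) {
        corr_block(memory, "memory_decrement")
      } else NULL)

    if (two_groups) {
      align <- function(df, col) {
        df[[col]][match(participants$participant_id, df$participant_id)]
      }
      time_bins <- list(
        vigilance_decrement = bin_by_time_since_diagnosis(
          align(vig, "vigilance_decrement"), participants,
          groups[1], groups[2], edges_months = vigilance_bin_edges,
          n_iter = n_iter, seed = seed, alpha = alpha),
        memory_decrement = if (!is.null(memory)) {
          bin_by_time_since_diagnosis(
            align(memory, "memory_decrement"), participants,
            groups[1], groups[2], edges_months = memory_bin_edges,
            n_iter = n_iter, seed = seed, alpha = alpha)
        } else NULL)
    }
  }

  ## --- multiple-testing adjustment ----------------------------------
  bonferroni <- NULL
  if (two_groups) {
    battery_p <- c(
      vigilance_decrement = vig_comparisons$vigilance_decrement$t_test$p,
      memory_decrement =
        if (!is.null(mem_comparisons)) {
          mem_comparisons$memory_decrement$t_test$p
        } else NULL)
    battery_p <- battery_p[!vapply(battery_p, is.null, logical(1))]
    bonferroni <- data.frame(
      endpoint = names(battery_p),
      p = as.numeric(battery_p),
      p_adjusted = bonferroni_adjust(as.numeric(battery_p), bonferroni_m),
      m = bonferroni_m, stringsAsFactors = FALSE)
  }

  structure(list(
    groups = groups,
    vigilance = list(participants = vig, block_scores = blocks,
                     comparisons = vig_comparisons,
                     timeseries = timeseries),
    memory = list(outcomes = memory, comparisons = mem_comparisons,
                  one_sample = mem_one_sample, misbinding = misbinding),
    correlations = correlations,
    time_bins = time_bins,
    bonferroni = bonferroni,
    provenance = list(seed = as.integer(seed), n_iter = n_iter,
                      alpha = alpha,
                      n_per_group = as.list(table(participants$group)),
                      package_version =
                        as.character(utils::packageVersion("vigimem")))
  ), class = "vigimem_report")
}

#' @export
print.vigimem_report <- function(x, ...) {
  cat("<vigimem analysis report>\n")
  ns <- x$provenance$n_per_group
  cat(sprintf("  cohort: %s\n",
              paste(sprintf("%s n=%s", names(ns), unlist(ns)),
                    collapse = ", ")))
  if (!is.null(x$vigilance$comparisons$vigilance_decrement$t_test)) {
    tt <- x$vigilance$comparisons$vigilance_decrement$t_test
    cat(sprintf("  vigilance decrement: t(%d) = %.2f, p = %.3g\n",
                tt$df, tt$t, tt$p))
  }
  if (!is.null(x$vigilance$timeseries)) {
    sig <- which(x$vigilance$timeseries$significant)
    cat(sprintf("  time-series divergence at minutes: %s\n",
                if (length(sig)) paste(sig - 1, collapse = ", ")
                else "none"))
  }
  if (!is.null(x$memory$comparisons$memory_decrement$t_test)) {
    tt <- x$memory$comparisons$memory_decrement$t_test
    cat(sprintf("  memory decrement: t(%d) = %.2f, p = %.3g\n",
                tt$df, tt$t, tt$p))
  }
  cat(sprintf("  seed %d, %d bootstrap iterations\n",
              x$provenance$seed, x$provenance$n_iter))
  invisible(x)
}

#' Render a report's group-comparison table
#'
#' Flattens the endpoint comparisons of a [run_full_analysis()] report
#' into one data.frame shaped like a published group-comparison table:
#' per endpoint, the per-group mean (SD) and the pooled t, df, p and
#' Bayes factors. Every number is taken from the report object; nothing
#' is recomputed at formatting time.
#'
#' @param report a `vigimem_report`.
#' @param which `"vigilance"` or `"memory"`.
#' @return data.frame.
#' @export
report_table <- function(report, which = c("vigilance", "memory")) {
  which <- match.arg(which)
  comps <- if (which == "vigilance") report$vigilance$comparisons
           else report$memory$comparisons
  rows <- lapply(names(comps), function(ep) {
    cc <- comps[[ep]]
    if (is.null(cc) || is.null(cc$summary)) return(NULL)
    s <- cc$summary
    row <- data.frame(endpoint = ep, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(s))) {
      row[[paste0(s$group[i], "_mean_sd")]] <-
        sprintf("%.1f (%.1f)", s$mean[i], s$sd[i])
      row[[paste0(s$group[i], "_n")]] <- s$n[i]
    }
    if (!is.null(cc$t_test)) {
      row$t <- round_half_away(cc$t_test$t, 1)
      row$df <- cc$t_test$df
      row$p <- signif(cc$t_test$p, 2)
      row$bf10 <- signif(cc$t_test$bf10, 2)
      row$bf01 <- signif(cc$t_test$bf01, 2)
      row$boot_p <- signif(cc$bootstrap$p_two_sided, 2)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
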