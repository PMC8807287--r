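# Bootstrap resampling inference for unbalanced two-group designs.
#
# Both procedures resample N participants (rows) with replacement from
# each group per iteration - N defaulting to the smaller group's size -
# and record the difference of group means. Rows are redrawn jointly
# across timepoints, since the participant is the resampling unit.
# Internally the resample is drawn as multinomial row weights, which is
# distributionally identical to sampling row indices with replacement and
# lets the iteration loop collapse into one matrix product.

boot_weights <- function(n_rows, n_resample, n_iter) {
  # n_rows x n_iter matrix of resample counts per row
  stats::rmultinom(n_iter, n_resample, rep(1 / n_rows, n_rows))
}

#' Bootstrap divergence detection for group time series
#'
#' Identifies timepoints at which two groups' mean time courses diverge.
#' Per iteration, `n_resample` participants are drawn with replacement
#' from each group and the timepoint-wise difference of group means
#' (a minus b) is recorded. A timepoint is flagged as significant when
#' more than `1 - alpha` of the iteration differences share a sign (the
#' 95% sign criterion at the default `alpha = 0.05`). Ties at exactly zero
#' count toward neither sign. A conventional two-sided bootstrap p-value,
#' `2 * min(P(diff <= 0), P(diff >= 0))`, is reported per timepoint
#' alongside the sign proportions; note the literal sign criterion
#' corresponds to a two-sided size of about `2 * alpha`.
#'
#' @param series_a,series_b numeric matrices, participants x timepoints,
#'   sharing the timepoint axis. NA cells are ignored within each
#'   column mean.
#' @param n_iter bootstrap iterations.
#' @param alpha significance level of the sign criterion.
#' @param n_resample resample size per group; default the smaller group.
#' @param seed integer seed (results are deterministic given it).
#' @return object of class `vigimem_boot_ts`: list with `diff_mean`,
#'   `prop_positive`, `prop_negative`, `significant` (the mask),
#'   `p_two_sided`, `n_iter`, `n_resample`, `alpha`, `seed`.
#' @examples
#' a <- matrix(rnorm(50 * 9, 1), 50)
#' b <- matrix(rnorm(60 * 9, 0), 60)
#' bootstrap_timeseries(a, b, n_iter = 500, seed = 1)$significant
#' @export
bootstrap_timeseries <- function(series_a, series_b, n_iter = 10000,
                                 alpha = 0.05, n_resample = NULL,
                                 seed = NULL) {
  series_a <- as.matrix(series_a)
  series_b <- as.matrix(series_b)
  if (ncol(series_a) != ncol(series_b)) {
    stop("the two series must share the timepoint axis", call. = FALSE)
  }
  if (nrow(series_a) < 2L || nrow(series_b) < 2L) {
    stop("each group needs at least 2 participants", call. = FALSE)
  }
  n_resample <- n_resample %||% min(nrow(series_a), nrow(series_b))

  with_seed(seed, {
    # NA-tolerant resampled column means: weight only non-missing cells
    # and renormalize per column.
    col_means <- function(x, w) {
      obs <- !is.na(x)
      x0 <- ifelse(obs, x, 0)
      sums <- crossprod(w, x0)            # n_iter x T
      cnts <- crossprod(w, obs + 0)
      sums / cnts
    }
    wa <- boot_weights(nrow(series_a), n_resample, n_iter)
    wb <- boot_weights(nrow(series_b), n_resample, n_iter)
    d <- col_means(series_a, wa) - col_means(series_b, wb)
  })

  prop_pos <- colMeans(d > 0)
  prop_neg <- colMeans(d < 0)
  structure(list(
    diff_mean = colMeans(d),
    prop_positive = prop_pos,
    prop_negative = prop_neg,
    significant = pmax(prop_pos, prop_neg) > 1 - alpha,
    p_two_sided = pmin(1, 2 * pmin(colMeans(d <= 0), colMeans(d >= 0))),
    n_iter = n_iter, n_resample = n_resample, alpha = alpha,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  ), class = "vigimem_boot_ts")
}

#' @export
print.vigimem_boot_ts <- function(x, ...) {
  cat(sprintf(
    "<bootstrap time-series comparison: %d iterations, N=%d per group>\n",
    x$n_iter, x$n_resample))
  cat(sprintf("  significant timepoints (%d%% sign criterion): %s\n",
              round(100 * (1 - x$alpha)),
              if (any(x$significant)) {
                paste(which(x$significant), collapse = ", ")
              } else "none"))
  invisible(x)
}

#' Bootstrap group test for unbalanced samples
#'
#' Confirms the reliability of a two-group mean comparison when sample
#' sizes are unbalanced. Per iteration, `n_resample` values (defaulting to
#' the smaller group's size) are drawn with replacement from each group
#' and the difference of means (a minus b) recorded; over `n_iter`
#' iterations the difference is deemed significant under the sign
#' criterion when more than `1 - alpha` of iterations share a sign. A
#' conventional two-sided bootstrap p-value,
#' `2 * min(P(diff <= 0), P(diff >= 0))`, is reported alongside.
#'
#' @param values_a,values_b numeric vectors (NAs dropped).
#' @param n_iter bootstrap iterations.
#' @param alpha significance level of the sign criterion.
#' @param n_resample resample size; default the smaller group.
#' @param seed integer seed.
#' @return object of class `vigimem_boot_test`: list with `diff_mean`
#'   (observed difference of means), `boot_diff_mean`, `prop_positive`,
#'   `prop_negative`, `significant` (sign criterion), `p_two_sided`,
#'   `n_iter`, `n_resample`, `alpha`, `seed`, `n_a`, `n_b`.
#' @examples
#' bootstrap_group_test(rnorm(13, 1), rnorm(73), n_iter = 1000, seed = 1)
#' @export
bootstrap_group_test <- function(values_a, values_b, n_iter = 10000,
                                 alpha = 0.05, n_resample = NULL,
                                 seed = NULL) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  n_resample <- n_resample %||% min(length(values_a), length(values_b))

  with_seed(seed, {
    ma <- crossprod(boot_weights(length(values_a), n_resample, n_iter),
                    values_a) / n_resample
    mb <- crossprod(boot_weights(length(values_b), n_resample, n_iter),
                    values_b) / n_resample
    d <- as.numeric(ma - mb)
  })

  prop_pos <- mean(d > 0)
  prop_neg <- mean(d < 0)
  structure(list(
    diff_mean = mean(values_a) - mean(values_b),
    boot_diff_mean = mean(d),
    prop_positive = prop_pos,
    prop_negative = prop_neg,
    significant = max(prop_pos, prop_neg) > 1 - alpha,
    p_two_sided = min(1, 2 * min(mean(d <= 0), mean(d >= 0))),
    n_iter = n_iter, n_resample = n_resample, alpha = alpha,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    n_a = length(values_a), n_b = length(values_b)
  ), class = "vigimem_boot_test")
}

#' @export
print.vigimem_boot_test <- function(x, ...) {
  cat(sprintf(
    "<bootstrap group test: n=%d vs %d, N=%d resampled, %d iterations>\n",
    x$n_a, x$n_b, x$n_resample, x$n_iter))
  cat(sprintf("  observed difference of means: %.4g\n", x$diff_mean))
  cat(sprintf("  sign proportions: %.3f positive / %.3f negative (criterion >%.2f: %s)\n",
              x$prop_positive, x$prop_negative, 1 - x$alpha,
              if (x$significant) "significant" else "not significant"))
  cat(sprintf("  two-sided bootstrap p: %.4g\n", x$p_two_sided))
  invisible(x)
}
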