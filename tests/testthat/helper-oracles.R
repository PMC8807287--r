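# Independent brute-force oracles, deliberately written in the most
# direct style possible and kept free of the package's own code paths.

oracle_f1 <- function(tp, fp, fn) {
  precision <- tp / (tp + fp)
  sensitivity <- tp / (tp + fn)
  if (tp == 0) {
    if (fp + fn == 0) return(NA_real_)
    return(0)
  }
  2 / (1 / precision + 1 / sensitivity)
}

oracle_trimmed_rt <- function(rts) {
  rts <- rts[!is.na(rts)]
  if (length(rts) == 0) return(list(mean_rt = NA_real_, n_excluded = 0L))
  if (length(rts) < 3) return(list(mean_rt = mean(rts), n_excluded = 0L))
  m <- sum(rts) / length(rts)
  s <- sqrt(sum((rts - m)^2) / (length(rts) - 1))
  kept <- c()
  dropped <- 0L
  for (r in rts) {
    if (r >= m - 2 * s && r <= m + 2 * s) kept <- c(kept, r)
    else dropped <- dropped + 1L
  }
  list(mean_rt = mean(kept), n_excluded = dropped)
}

oracle_chi2 <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

# High-resolution trapezoid quadrature of the JZS Bayes factor over the
# g mixing parameter, on a log-spaced grid.
oracle_jzs_bf10 <- function(t, n_eff, df, rscale = sqrt(2) / 2,
                            n_grid = 20000) {
  g <- exp(seq(log(1e-8), log(1e8), length.out = n_grid))
  prior <- (rscale^2 / 2)^0.5 / gamma(0.5) * g^-1.5 *
    exp(-rscale^2 / (2 * g))
  alt <- (1 + n_eff * g)^-0.5 *
    (1 + t^2 / ((1 + n_eff * g) * df))^(-(df + 1) / 2)
  null <- (1 + t^2 / df)^(-(df + 1) / 2)
  integrand <- alt * prior / null
  sum(diff(g) * (integrand[-1] + integrand[-n_grid]) / 2)
}

oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Direct loop implementation of the bootstrap sign-criterion time-series
# comparison (row indices drawn with replacement).
oracle_boot_ts_flags <- function(a, b, n_iter, n_resample, alpha = 0.05) {
  d <- matrix(NA_real_, n_iter, ncol(a))
  for (i in seq_len(n_iter)) {
    ia <- sample.int(nrow(a), n_resample, replace = TRUE)
    ib <- sample.int(nrow(b), n_resample, replace = TRUE)
    d[i, ] <- colMeans(a[ia, , drop = FALSE]) -
      colMeans(b[ib, , drop = FALSE])
  }
  apply(d, 2, function(col) {
    max(mean(col > 0), mean(col < 0)) > 1 - alpha
  })
}

# Binomial 99% bounds for an observed proportion under H0: p = p0
binom_bounds99 <- function(p0, n) {
  p0 + c(-1, 1) * stats::qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
}

# A small but complete hand-built trial table: one participant, known
# outcome counts per block.
make_tiny_trials <- function() {
  mk_block <- function(block, n_target_hit, n_target_miss, n_fa, n_cr,
                       rt_hit = 0.5) {
    n <- n_target_hit + n_target_miss + n_fa + n_cr
    is_target <- c(rep(TRUE, n_target_hit + n_target_miss),
                   rep(FALSE, n_fa + n_cr))
    responded <- c(rep(TRUE, n_target_hit), rep(FALSE, n_target_miss),
                   rep(TRUE, n_fa), rep(FALSE, n_cr))
    data.frame(participant_id = "p1", block_index = block,
               trial_index = seq_len(n) - 1L,
               stimulus_digit = ifelse(is_target, 0L, 5L),
               is_target = is_target, responded = responded,
               rt = ifelse(responded, rt_hit, NA_real_),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(0:9, function(b) mk_block(b, 10, 5, 2, 43)))
}
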