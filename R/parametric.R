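# Classical endpoints: pooled and one-sample t with JZS Bayes factors,
# Pearson chi-square, Spearman and partial rank correlations, PCA
# composites and Bonferroni adjustment.

new_ttest <- function(t, df, mean_diff, summaries, rscale, type) {
  p <- if (is.finite(t)) 2 * stats::pt(-abs(t), df) else 0
  bf <- jzs_bayes_factor(t, n1 = summaries$n[1],
                         n2 = if (type == "two_sample") summaries$n[2]
                              else NULL,
                         rscale = rscale)
  structure(list(t = t, df = df, p = p,
                 bf10 = bf[["bf10"]], bf01 = bf[["bf01"]],
                 mean_diff = mean_diff, summaries = summaries,
                 rscale = rscale, type = type),
            class = "vigimem_ttest")
}

#' @export
print.vigimem_ttest <- function(x, ...) {
  cat(sprintf("<%s t-test> t(%s) = %.2f, p = %.3g, BF10 = %.3g, BF01 = %.3g\n",
              gsub("_", "-", x$type),
              format(x$df), x$t, x$p, x$bf10, x$bf01))
  cat(sprintf("  mean difference: %.4g\n", x$mean_diff))
  invisible(x)
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Student's two-sample t with a pooled variance estimate and
#' `df = n_a + n_b - 2`, computed from group means, standard deviations
#' and sizes; it equals the t computed from any raw samples having those
#' summaries. This is the form under which every recomputable printed
#' group comparison in the accompanying analyses reproduces. (Published
#' tables sometimes print df = n - 1 for a two-sample test; this function
#' always reports the conventional n_a + n_b - 2, which does not affect
#' the t statistic.) A JZS Bayes factor (see [jzs_bayes_factor()]) is
#' attached.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries; `sd >= 0`,
#'   `n >= 2`.
#' @param welch use Welch's unequal-variance form instead of pooling.
#' @param rscale Cauchy prior scale for the Bayes factor.
#' @return object of class `vigimem_ttest` with fields `t`, `df`, `p`,
#'   `bf10`, `bf01`, `mean_diff`, `summaries`. With zero pooled variance,
#'   `t` is 0 for equal means and signed `Inf` otherwise.
#' @examples
#' pooled_t_from_summary(-12.3, 17.4, 53, -0.9, 29.1, 83)  # t ~ -2.6
#' @export
pooled_t_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                                  welch = FALSE, rscale = sqrt(2) / 2) {
  if (sd_a < 0 || sd_b < 0) stop("standard deviations must be >= 0",
                                 call. = FALSE)
  if (n_a < 2 || n_b < 2) stop("each group needs n >= 2", call. = FALSE)
  diff <- mean_a - mean_b
  if (welch) {
    se2 <- sd_a^2 / n_a + sd_b^2 / n_b
    df <- se2^2 / ((sd_a^2 / n_a)^2 / (n_a - 1) +
                     (sd_b^2 / n_b)^2 / (n_b - 1))
    se <- sqrt(se2)
  } else {
    df <- n_a + n_b - 2
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  }
  t <- if (se == 0) {
    if (diff == 0) 0 else {
      warning("zero pooled variance with unequal means; t is infinite",
              call. = FALSE)
      sign(diff) * Inf
    }
  } else diff / se
  new_ttest(t, df, diff,
            summaries = data.frame(group = c("a", "b"),
                                   mean = c(mean_a, mean_b),
                                   sd = c(sd_a, sd_b), n = c(n_a, n_b)),
            rscale = rscale, type = "two_sample")
}

#' Pooled-variance two-sample t-test from raw data
#'
#' Computes group summaries and delegates to [pooled_t_from_summary()],
#' so raw-data and summary-based results agree exactly.
#'
#' @param x,y numeric vectors (NAs dropped).
#' @inheritParams pooled_t_from_summary
#' @return object of class `vigimem_ttest`.
#' @export
pooled_t <- function(x, y, welch = FALSE, rscale = sqrt(2) / 2) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  pooled_t_from_summary(mean(x), stats::sd(x), length(x),
                        mean(y), stats::sd(y), length(y),
                        welch = welch, rscale = rscale)
}

#' One-sample t-test
#'
#' Standard one-sample t against `mu0` with `df = n - 1`, with a JZS
#' Bayes factor attached.
#'
#' @param values numeric vector (NAs dropped), `n >= 2`.
#' @param mu0 null value.
#' @param rscale Cauchy prior scale for the Bayes factor.
#' @return object of class `vigimem_ttest`.
#' @examples
#' one_sample_t(c(1, 2, 3), mu0 = 0)   # t = 3.4641
#' @export
one_sample_t <- function(values, mu0 = 0, rscale = sqrt(2) / 2) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need n >= 2 values", call. = FALSE)
  s <- stats::sd(values)
  diff <- mean(values) - mu0
  t <- if (s == 0) {
    if (diff == 0) 0 else {
      warning("zero variance with mean != mu0; t is infinite",
              call. = FALSE)
      sign(diff) * Inf
    }
  } else diff / (s / sqrt(n))
  new_ttest(t, n - 1, diff,
            summaries = data.frame(group = "sample", mean = mean(values),
                                   sd = s, n = n),
            rscale = rscale, type = "one_sample")
}

#' Jeffreys-Zellner-Siow Bayes factor for a t statistic
#'
#' Default-prior Bayes factor for a t contrast: a Cauchy prior with scale
#' `rscale` on the standardized effect size, equivalently a normal prior
#' whose variance `g` carries an inverse-gamma(1/2, rscale^2/2) mixing
#' distribution. BF10 is the ratio of the marginal likelihood of t under
#' the alternative to that under the null,
#' \deqn{BF_{10} = \frac{\int_0^\infty (1+Ng)^{-1/2}
#'   \left(1+\frac{t^2}{(1+Ng)\nu}\right)^{-(\nu+1)/2}
#'   \pi(g)\,dg}{\left(1+\frac{t^2}{\nu}\right)^{-(\nu+1)/2}}}
#' with effective sample size `N = n1*n2/(n1+n2)` for a two-sample test
#' (df `n1+n2-2`) or `N = n1` for a one-sample test (df `n1-1`). The
#' integral is evaluated by adaptive quadrature to a relative tolerance
#' of 1e-8. `bf10` favours the alternative; `bf01 = 1/bf10` the null.
#'
#' @param t observed t statistic.
#' @param n1 first (or only) sample size.
#' @param n2 second sample size, or NULL for a one-sample test.
#' @param rscale Cauchy prior scale (default `sqrt(2)/2`).
#' @return named numeric vector `c(bf10, bf01)`.
#' @examples
#' jzs_bayes_factor(2.72, n1 = 53, n2 = 83)
#' @export
jzs_bayes_factor <- function(t, n1, n2 = NULL, rscale = sqrt(2) / 2) {
  if (is.null(n2)) {
    n_eff <- n1
    df <- n1 - 1
  } else {
    n_eff <- n1 * n2 / (n1 + n2)
    df <- n1 + n2 - 2
  }
  if (df < 1) stop("need df >= 1", call. = FALSE)
  if (!is.finite(t)) return(c(bf10 = Inf, bf01 = 0))

  # log marginal density ratio per g, integrated against the
  # inverse-gamma(1/2, rscale^2/2) prior; worked on the log scale and
  # rescaled by its maximum for numerical stability.
  log_null <- -(df + 1) / 2 * log1p(t^2 / df)
  log_ratio <- function(g) {
    -0.5 * log1p(n_eff * g) -
      (df + 1) / 2 * log1p(t^2 / ((1 + n_eff * g) * df)) -
      log_null
  }
  log_prior <- function(g) {
    0.5 * log(rscale^2 / 2) - lgamma(0.5) - 1.5 * log(g) -
      rscale^2 / (2 * g)
  }
  log_f <- function(g) log_ratio(g) + log_prior(g)
  # locate the integrand mode on a log grid to set the rescaling constant
  gs <- exp(seq(log(1e-6), log(1e6), length.out = 200))
  c0 <- max(log_f(gs))
  integrand <- function(g) exp(log_f(g) - c0)
  quad <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-8,
                     subdivisions = 500L),
    error = function(e) {
      stop(sprintf("JZS quadrature failed to converge (t=%.3g, df=%g): %s",
                   t, df, conditionMessage(e)), call. = FALSE)
    })
  bf10 <- exp(log(quad$value) + c0)
  c(bf10 = bf10, bf01 = 1 / bf10)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson's chi-square without continuity correction (the form that
#' reproduces printed values), df = 1.
#'
#' @param counts 2x2 matrix of non-negative integer counts.
#' @return list with `chi2`, `df`, `p`. A zero row or column marginal
#'   gives `chi2 = NA` with a warning.
#' @examples
#' chi_square_2x2(matrix(c(23, 30, 31, 52), 2, byrow = TRUE))
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("need a 2x2 table",
                                           call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    warning("zero marginal; chi-square undefined", call. = FALSE)
    return(list(chi2 = NA_real_, df = 1L, p = NA_real_))
  }
  # the small-expected-count caveat applies to the asymptotic p-value,
  # which is documented as asymptotic; keep the statistic itself quiet
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = 1L, p = unname(ct$p.value))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n - 2 df,
#' two-tailed.
#'
#' @param x,y paired numeric vectors, `n >= 3` complete pairs.
#' @return list with `rho`, `p`, `n`.
#' @examples
#' spearman_cor(1:10, (1:10)^3)   # rho = 1
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero rank variance; correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Partial Spearman correlation
#'
#' Rank-transforms all variables, residualizes x and y on the covariates
#' by least squares, and correlates the residuals. The p-value uses the
#' t-approximation on `n - 2 - k` df for k covariates. With no
#' covariates this reduces to [spearman_cor()].
#'
#' @param x,y paired numeric vectors.
#' @param covariates data.frame or matrix of covariates (may be NULL or
#'   zero-column).
#' @return list with `rho`, `p`, `n`, `n_covariates`.
#' @examples
#' z <- rnorm(30)
#' partial_spearman(rnorm(30) + z, rnorm(30) + z, data.frame(z = z))
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0L ||
      (is.data.frame(covariates) && ncol(covariates) == 0L)) {
    return(c(spearman_cor(x, y), list(n_covariates = 0L)))
  }
  cv <- as.matrix(as.data.frame(covariates))
  ok <- stats::complete.cases(x, y, cv)
  x <- x[ok]; y <- y[ok]; cv <- cv[ok, , drop = FALSE]
  n <- length(x)
  k <- ncol(cv)
  if (n < k + 3) stop("too few complete cases for partial correlation",
                      call. = FALSE)
  rz <- apply(cv, 2, rank)
  design <- cbind(1, rz)
  if (qr(design)$rank < ncol(design)) {
    stop("covariate matrix is rank-deficient after ranking", call. = FALSE)
  }
  res <- function(v) stats::lm.fit(design, rank(v))$residuals
  ex <- res(x); ey <- res(y)
  if (stats::sd(ex) == 0 || stats::sd(ey) == 0) {
    stop("zero residual variance; partial correlation undefined",
         call. = FALSE)
  }
  rho <- stats::cor(ex, ey)
  df <- n - 2 - k
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt(df / (1 - rho^2))
    2 * stats::pt(-abs(tt), df)
  }
  list(rho = rho, p = p, n = n, n_covariates = k)
}

#' First-principal-component composite score
#'
#' Derives a global index from a table of measures: each column is
#' z-scored, the first principal component extracted, and its sign
#' oriented so the composite correlates positively with the row mean of
#' the z-scored inputs. Zero-variance columns are dropped with a warning;
#' rows with missing cells must be removed upstream (listwise).
#'
#' @param measures data.frame or matrix, participants x measures,
#'   at least 2 rows, no missing cells.
#' @return object of class `vigimem_composite`: list with `scores`
#'   (zero-mean), `loadings`, `variance_explained`, `measures_used`.
#' @examples
#' pca_composite(data.frame(a = rnorm(20), b = rnorm(20)))
#' @export
pca_composite <- function(measures) {
  m <- as.matrix(as.data.frame(measures))
  if (nrow(m) < 2) stop("need at least 2 participants", call. = FALSE)
  if (anyNA(m)) stop("missing cells; apply listwise deletion upstream",
                     call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(colnames(m)[sds == 0], collapse = ", ")),
            call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
  }
  if (ncol(m) == 0L) stop("no columns with variance remain", call. = FALSE)
  z <- scale(m)
  if (ncol(z) == 1L) {
    return(structure(list(scores = as.numeric(z),
                          loadings = stats::setNames(1, colnames(m)),
                          variance_explained = 1,
                          measures_used = colnames(m)),
                     class = "vigimem_composite"))
  }
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  if (stats::cor(scores, rowMeans(z)) < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  structure(list(scores = as.numeric(scores - mean(scores)),
                 loadings = loadings,
                 variance_explained =
                   unname(pc$sdev[1]^2 / sum(pc$sdev^2)),
                 measures_used = colnames(m)),
            class = "vigimem_composite")
}

#' @export
print.vigimem_composite <- function(x, ...) {
  cat(sprintf("<PCA composite of %d measures; %.1f%% variance explained>\n",
              length(x$loadings), 100 * x$variance_explained))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Bonferroni adjustment with an explicit family size
#'
#' `min(1, p * m)` where the family size `m` may exceed the number of
#' p-values passed (the test battery's full ledger of tests counts toward
#' the family even when only one p-value is being adjusted).
#'
#' @param p_values numeric vector of p-values.
#' @param m family size, at least `length(p_values)`.
#' @return adjusted p-values.
#' @examples
#' bonferroni_adjust(0.001, 29)   # 0.029
#' @export
bonferroni_adjust <- function(p_values, m) {
  if (m < length(p_values)) {
    stop("family size m must be >= number of tests", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}
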