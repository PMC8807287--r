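test_that("pooled t from summaries reproduces printed group comparisons", {
  # (mean, sd, n) per group -> t rounded to 1 decimal, half away from zero
  cases <- list(
    list(a = c(-12.3, 17.4, 53), b = c(-0.9, 29.1, 83), t = -2.6),
    list(a = c(-7.7, 10.3, 53), b = c(-3.0, 9.5, 83), t = -2.7),
    list(a = c(75.5, 19.2, 53), b = c(78.5, 20.2, 83), t = -0.9),
    list(a = c(-13.6, 21.4, 36), b = c(16.6, 56.9, 44), t = -3.0)
  )
  for (cs in cases) {
    tt <- pooled_t_from_summary(cs$a[1], cs$a[2], cs$a[3],
                                cs$b[1], cs$b[2], cs$b[3])
    expect_equal(round_half_away(tt$t, 1), cs$t)
    expect_equal(tt$df, cs$a[3] + cs$b[3] - 2)
    expect_true(tt$p >= 0 && tt$p <= 1)
  }
})

test_that("summary-based and raw-data pooled t agree exactly", {
  set.seed(14)
  for (i in 1:25) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    ts <- pooled_t_from_summary(mean(x), sd(x), length(x),
                                mean(y), sd(y), length(y))
    tr <- pooled_t(x, y)
    expect_equal(ts$t, tr$t)
    expect_equal(ts$t, oracle_pooled_t(x, y))
    # agrees with stats::t.test in its pooled-variance form
    expect_equal(tr$t, unname(t.test(x, y, var.equal = TRUE)$statistic))
  }
})

test_that("degenerate variance cases are handled in-band", {
  expect_equal(pooled_t_from_summary(1, 0, 5, 1, 0, 5)$t, 0)
  expect_warning(tt <- pooled_t_from_summary(2, 0, 5, 1, 0, 5),
                 "infinite")
  expect_true(is.infinite(tt$t) && tt$t > 0)
  expect_equal(one_sample_t(c(2, 2, 2), mu0 = 2)$t, 0)
})

test_that("one-sample t matches direct formula", {
  expect_equal(one_sample_t(c(1, 2, 3), mu0 = 2)$t, 0)
  tt <- one_sample_t(c(1, 2, 3), mu0 = 0)
  expect_equal(tt$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(tt$df, 2)
  set.seed(15)
  x <- rnorm(20, 1)
  expect_equal(one_sample_t(x)$t, unname(t.test(x)$statistic))
})

test_that("JZS Bayes factor matches a brute-force quadrature oracle", {
  bf <- jzs_bayes_factor(2.72, n1 = 53, n2 = 83)
  oracle <- oracle_jzs_bf10(2.72, n_eff = 53 * 83 / (53 + 83),
                            df = 53 + 83 - 2)
  expect_equal(bf[["bf10"]], oracle, tolerance = 1e-6)
  # identity and null-favouring at t = 0
  expect_equal(bf[["bf10"]] * bf[["bf01"]], 1, tolerance = 1e-9)
  bf0 <- jzs_bayes_factor(0, n1 = 30, n2 = 40)
  expect_lt(bf0[["bf10"]], 1)
  # random instances, one- and two-sample, varied scales
  set.seed(16)
  for (i in 1:60) {
    t <- runif(1, -4, 4)
    r <- sample(c(sqrt(2) / 2, 1), 1)
    if (runif(1) < 0.5) {
      n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
      got <- jzs_bayes_factor(t, n1, n2, rscale = r)[["bf10"]]
      want <- oracle_jzs_bf10(t, n1 * n2 / (n1 + n2), n1 + n2 - 2,
                              rscale = r)
    } else {
      n <- sample(5:80, 1)
      got <- jzs_bayes_factor(t, n, rscale = r)[["bf10"]]
      want <- oracle_jzs_bf10(t, n, n - 1, rscale = r)
    }
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("BF10 increases with |t| and is invariant to data rescaling", {
  ts <- seq(0, 5, by = 0.5)
  bfs <- vapply(ts, function(t) {
    jzs_bayes_factor(t, 25, 30)[["bf10"]]
  }, numeric(1))
  expect_true(all(diff(bfs) > 0))
  set.seed(17)
  x <- rnorm(20, 0.6); y <- rnorm(25)
  t1 <- pooled_t(x, y)
  t2 <- pooled_t(3.7 * x, 3.7 * y)
  expect_equal(t1$t, t2$t, tolerance = 1e-12)
  expect_equal(t1$bf10, t2$bf10, tolerance = 1e-9)
})

test_that("2x2 chi-square reproduces printed value and brute-force oracle", {
  gender <- matrix(c(23, 30, 31, 52), 2, byrow = TRUE)
  res <- chi_square_2x2(gender)
  expect_equal(round_half_away(res$chi2, 1), 0.5)
  expect_equal(res$df, 1L)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$chi2, 0)
  expect_warning(z <- chi_square_2x2(matrix(c(0, 0, 3, 4), 2,
                                            byrow = TRUE)),
                 "marginal")
  expect_true(is.na(z$chi2))
  set.seed(18)
  for (i in 1:1000) {
    tab <- matrix(rpois(4, 12) + 1, 2)
    expect_equal(chi_square_2x2(tab)$chi2, oracle_chi2(tab),
                 tolerance = 1e-12)
  }
})

test_that("Spearman correlation is rank-based with t-approximate p", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  # invariant under strictly monotone transforms
  set.seed(19)
  a <- rnorm(30); b <- rnorm(30) + 0.5 * a
  expect_equal(spearman_cor(a, b)$rho, spearman_cor(exp(a), b^3 + b)$rho)
  expect_equal(spearman_cor(a, b)$rho,
               unname(cor(a, b, method = "spearman")))
  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)), "zero rank variance")
  # null calibration: mean rho near zero over replicates
  rhos <- replicate(300, spearman_cor(rnorm(50), rnorm(50))$rho)
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(300))
})

test_that("partial Spearman residualizes ranks on covariates", {
  set.seed(20)
  x <- rnorm(40); y <- x + rnorm(40, 0, 1e-8)
  z <- rnorm(40)
  expect_equal(partial_spearman(x, y, data.frame(z))$rho, 1,
               tolerance = 1e-6)
  # no covariates reduces to the plain Spearman
  p0 <- partial_spearman(x, y, NULL)
  expect_equal(p0$rho, spearman_cor(x, y)$rho)
  # shared covariate induces spurious correlation that partialling removes
  rhos <- replicate(200, {
    c0 <- rnorm(60)
    partial_spearman(c0 + rnorm(60), c0 + rnorm(60),
                     data.frame(c0))$rho
  })
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(200))
  expect_error(partial_spearman(x, y, data.frame(z, z2 = z)),
               "rank-deficient")
})

test_that("PCA composite matches an eigen-decomposition oracle", {
  set.seed(22)
  m <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  m$b <- m$b + 0.7 * m$a
  comp <- pca_composite(m)
  ev <- eigen(cor(m))
  want <- ev$vectors[, 1]
  got <- comp$loadings
  expect_equal(abs(unname(got)), abs(want), tolerance = 1e-8)
  expect_equal(comp$variance_explained, ev$values[1] / 3,
               tolerance = 1e-10)
  expect_equal(mean(comp$scores), 0, tolerance = 1e-10)
  expect_gte(cor(comp$scores, rowMeans(scale(m))), 0)
  # single column: z-scores; duplicated column: all variance on PC1
  one <- pca_composite(m["a"])
  expect_equal(one$scores, as.numeric(scale(m$a)))
  expect_equal(one$variance_explained, 1)
  two <- pca_composite(data.frame(u = m$a, v = m$a))
  expect_equal(two$variance_explained, 1)
  expect_warning(pca_composite(data.frame(a = m$a, k = rep(1, 50))),
                 "zero-variance")
})

test_that("Bonferroni adjustment multiplies by the family size and caps", {
  expect_equal(bonferroni_adjust(0.001, 29), 0.029)
  expect_equal(bonferroni_adjust(0.5, 29), 1)
  expect_equal(bonferroni_adjust(0, 29), 0)
  p <- c(0.01, 0.2, 0.04)
  expect_true(all(bonferroni_adjust(p, 5) >= p))
  expect_error(bonferroni_adjust(p, 2), "family size")
})
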