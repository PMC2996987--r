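test_that("paired frame comparison handles degenerate differences", {
  same <- tibble::tibble(n2 = c(3, 1, 4), n3 = c(3, 1, 4))
  r <- paired_frame_test(same)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$direction, "none")
  shifted <- tibble::tibble(n2 = 0:99 + 1, n3 = 0:99)
  r2 <- paired_frame_test(shifted)
  expect_lt(r2$p, 1e-10)
  expect_equal(r2$direction, "+2")
  expect_error(paired_frame_test(tibble::tibble(n2 = 1, n3 = 0)),
               class = "oscan_input_error")
})

test_that("paired frame comparison matches t.test on noisy counts", {
  set.seed(7)
  d <- tibble::tibble(n2 = rpois(60, 6), n3 = rpois(60, 5))
  r <- paired_frame_test(d)
  ref <- t.test(d$n2, d$n3, paired = TRUE)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)
})

test_that("usage PCA normalises variance fractions and fixes signs", {
  set.seed(3)
  base <- matrix(runif(8), 1)
  rank1 <- matrix(rep(seq(0.5, 2, length.out = 10), each = 8) * as.numeric(base),
                  nrow = 10, byrow = TRUE)
  pc <- pca_usage(rank1)
  expect_equal(pc$variance_fractions[1], 1, tolerance = 1e-10)
  x <- matrix(rnorm(60), 10, 6)
  pc2 <- pca_usage(x)
  expect_equal(sum(pc2$variance_fractions), 1, tolerance = 1e-9)
  # orthonormal loadings
  expect_equal(crossprod(pc2$loadings), diag(ncol(pc2$loadings)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # sign convention: the dominant loading of each component is positive
  for (j in seq_len(ncol(pc2$loadings))) {
    expect_gt(pc2$loadings[which.max(abs(pc2$loadings[, j])), j], 0)
  }
  # undefined rows are dropped with a message
  x[1, 1] <- NA
  expect_message(pc3 <- pca_usage(x), "dropped")
  expect_equal(pc3$n_dropped, 1L)
})

test_that("regression recovers exact fits and flags rank deficiency", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10))
  r <- suppressWarnings(fit_regression(d, y ~ x))  # exact fit by design
  expect_equal(tidy(r)$estimate[2], 2, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)
  d$z <- d$x * 3
  expect_error(fit_regression(d, y ~ x + z), class = "oscan_input_error")
})

test_that("nested-model ANOVA p is large for a pure-noise addition", {
  set.seed(11)
  n <- 200
  d <- tibble::tibble(x = rnorm(n), noise = rnorm(n))
  d$y <- 3 * d$x + rnorm(n)
  r <- fit_regression(d, y ~ x + noise, reduced = y ~ x)
  expect_gt(r$anova_p, 0.05)
  ref <- anova(lm(y ~ x, d), lm(y ~ x + noise, d))$`Pr(>F)`[2]
  expect_equal(r$anova_p, ref)
})

test_that("PMVD shares decompose R^2 and respect orthogonality", {
  # single regressor: the share is the whole R^2
  set.seed(21)
  d1 <- tibble::tibble(x = rnorm(50))
  d1$y <- d1$x + rnorm(50)
  p1 <- pmvd_importance(d1, y ~ x, n_boot = 0)
  expect_equal(unname(p1$shares), p1$r_squared, tolerance = 1e-12)

  # exactly orthogonal centred design: shares equal marginal contributions
  # and PMVD coincides with LMG
  n <- 64
  x1 <- rep(c(-1, 1), each = n / 2)
  x2 <- rep(c(-1, 1), times = n / 2)
  set.seed(22)
  y <- 2 * x1 + 0.7 * x2 + rnorm(n)
  d2 <- tibble::tibble(y = y, x1 = x1, x2 = x2)
  pm <- pmvd_importance(d2, y ~ x1 + x2, n_boot = 0)
  lm_ <- pmvd_importance(d2, y ~ x1 + x2, n_boot = 0, method = "lmg")
  r2_1 <- summary(lm(y ~ x1, d2))$r.squared
  r2_12 <- summary(lm(y ~ x1 + x2, d2))$r.squared
  expect_equal(sum(pm$shares), r2_12, tolerance = 1e-9)
  expect_equal(unname(pm$shares["x1"]), r2_1, tolerance = 1e-9)
  expect_equal(unname(pm$shares["x2"]), r2_12 - r2_1, tolerance = 1e-9)
  expect_lt(max(abs(pm$shares - lm_$shares)), 1e-9)

  # correlated design: shares still sum to R^2, all non-negative
  set.seed(23)
  x3 <- x1 + rnorm(n, sd = 0.4)
  d3 <- tibble::tibble(y = y, x1 = x1, x3 = x3)
  pc <- pmvd_importance(d3, y ~ x1 + x3, n_boot = 50, seed = 9)
  expect_equal(sum(pc$shares), pc$r_squared, tolerance = 1e-9)
  expect_true(all(pc$shares >= 0))
  expect_equal(nrow(pc$ci), 2L)
  expect_true(all(pc$ci$lower <= pc$ci$share & pc$ci$share <= pc$ci$upper))

  expect_error(pmvd_importance(tibble::tibble(y = rnorm(5), k = rep(1, 5)),
                               y ~ k, n_boot = 0),
               class = "oscan_input_error")
})

test_that("PMVD gives zero share to a regressor with zero coefficient", {
  # exclusion property: x2 correlated with x1 but with no partial effect
  set.seed(24)
  n <- 400
  x1 <- rnorm(n)
  x2 <- 0.8 * x1 + rnorm(n, sd = 0.6)
  y <- x1 + rnorm(n, sd = 0.5)
  d <- tibble::tibble(y = y, x1 = x1, x2 = x2)
  pm <- pmvd_importance(d, y ~ x1 + x2, n_boot = 0)
  lmg <- pmvd_importance(d, y ~ x1 + x2, n_boot = 0, method = "lmg")
  # PMVD concentrates the shared variance on the regressor with the real
  # partial effect far more than LMG does
  expect_lt(unname(pm$shares["x2"]), unname(lmg$shares["x2"]) / 2)
})

test_that("Spearman correlation uses ranks with midrank ties", {
  x <- c(0.3, 1.1, 2.0, 3.5)
  expect_equal(spearman_corr(x, exp(x)), 1)
  expect_equal(spearman_corr(x, -x), -1)
  expect_equal(spearman_corr(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(r <- spearman_corr(c(1, 1, 1), c(1, 2, 3)))
  expect_true(is.na(r))
})

test_that("stepwise AIC keeps real effects and drops noise", {
  set.seed(31)
  n <- 500
  d <- tibble::tibble(x = rnorm(n), n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  d$y <- 2 * d$x + rnorm(n)
  sw <- stepwise_aic(d, y ~ x + n1 + n2 + n3)
  expect_true("x" %in% sw$selected)
  d2 <- tibble::tibble(x = 1:20, y = 3 * (1:20))
  sw2 <- suppressWarnings(stepwise_aic(d2, y ~ x))  # exact fit by design
  expect_identical(sw2$selected, "x")
  expect_error(stepwise_aic(d, y ~ 1), class = "oscan_input_error")
})

test_that("growth-temperature regression recovers a planted negative slope", {
  signs <- vapply(1:40, function(i) {
    d <- synth_ogt_dataset(n_genomes = 100, planted_slope = -0.01, seed = i)
    sign(ogt_regression(d)$ogt_coefficient)
  }, numeric(1))
  expect_gte(mean(signs == -1), 0.95)
  # with categories only, midpoints are substituted
  d <- synth_ogt_dataset(n_genomes = 80, planted_slope = -0.02, seed = 99)
  d$ogt <- NULL
  r <- ogt_regression(d)
  expect_lt(r$ogt_coefficient, 0)
  expect_true("ogt" %in% r$stepwise$selected)
})
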