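# ANOVA decomposition, the four ICC forms, confidence intervals, SEM and
# the interpretation bands.

test_that("descriptive statistics use n-1 SD and interpolated quartiles", {
  d <- descriptive_stats(c(1, 2, 3, 4, 5))
  expect_equal(d$mean, 3)
  expect_equal(d$sd, sqrt(2.5))
  expect_equal(d$median, 3)
  expect_equal(d$iqr, 2)
  expect_equal(d$min, 1)
  expect_equal(d$max, 5)
  d2 <- descriptive_stats(c(4, 4, 4))
  expect_equal(d2$sd, 0)
  expect_equal(d2$iqr, 0)
  expect_error(descriptive_stats(7), "2 values")
  expect_error(descriptive_stats(numeric(0)), "non-empty")
})

test_that("mean squares reproduce the hand-ANOVA worked examples", {
  ms1 <- anova_mean_squares(rbind(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(ms1$ms_rows, 8)
  expect_equal(ms1$ms_cols, 1.5)
  expect_equal(ms1$ms_error, 0)
  expect_equal(c(ms1$df_rows, ms1$df_cols, ms1$df_error), c(2, 1, 2))

  ms2 <- anova_mean_squares(rbind(c(1, 2), c(2, 2), c(4, 5)))
  expect_equal(ms2$ms_rows, 31 / 6, tolerance = 1e-12)
  expect_equal(ms2$ms_cols, 2 / 3, tolerance = 1e-12)
  expect_equal(ms2$ms_error, 1 / 6, tolerance = 1e-12)
})

test_that("adding a constant to one rater's column moves only the rater mean square", {
  set.seed(21)
  g <- matrix(rnorm(24), 6, 4)
  g2 <- g
  g2[, 2] <- g2[, 2] + 5
  a <- anova_mean_squares(g)
  b <- anova_mean_squares(g2)
  expect_equal(b$ms_rows, a$ms_rows)
  expect_equal(b$ms_error, a$ms_error)
  expect_gt(b$ms_cols, a$ms_cols)
})

test_that("the decomposition matches lm ANOVA and components sum to the total", {
  set.seed(22)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    k <- sample(2:5, 1)
    g <- matrix(rnorm(n * k, sd = 2), n, k)
    ms <- anova_mean_squares(g)
    df <- data.frame(y = as.vector(g),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
    tab <- anova(lm(y ~ subj + rater, data = df))
    expect_equal(ms$ms_rows, tab["subj", "Mean Sq"], tolerance = 1e-10)
    expect_equal(ms$ms_cols, tab["rater", "Mean Sq"], tolerance = 1e-10)
    expect_equal(ms$ms_error, tab["Residuals", "Mean Sq"], tolerance = 1e-10)
    expect_equal(ms$ms_rows * ms$df_rows + ms$ms_cols * ms$df_cols +
                   ms$ms_error * ms$df_error, ms$ss_total, tolerance = 1e-10)
  }
})

test_that("missing cells are reported by subject and rater", {
  g <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), c("r1", "r2")))
  g["b", "r2"] <- NA
  expect_error(anova_mean_squares(g), "'b'.*'r2'")
  expect_error(anova_mean_squares(matrix(1:2, 1, 2)), "at least 2")
})

test_that("ICC point estimates reproduce the hand-formula examples", {
  ms1 <- anova_mean_squares(rbind(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(icc(ms1, "single_consistency")$value, 1)
  expect_equal(icc(ms1, "single_agreement")$value, 8 / 9, tolerance = 1e-12)
  expect_true(is.infinite(icc(ms1, "single_consistency")$f_value))

  ms2 <- anova_mean_squares(rbind(c(1, 2), c(2, 2), c(4, 5)))
  expect_equal(icc(ms2, "single_consistency")$value, 0.9375, tolerance = 1e-12)
  expect_equal(icc(ms2, "single_agreement")$value, 15 / 17, tolerance = 1e-12)
})

test_that("all four forms agree with the independent sums-of-squares oracle", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    k <- sample(2:5, 1)
    g <- matrix(rnorm(n * k) + rnorm(n)[rep(seq_len(n), k)], n, k)
    for (form in ICC_FORMS) {
      expect_equal(icc(g, form)$value, icc_oracle(g, form), tolerance = 1e-10,
                   info = sprintf("%s n=%d k=%d rep=%d", form, n, k, i))
    }
  }
})

test_that("ICC orderings hold: single <= average, agreement <= consistency", {
  set.seed(24)
  for (i in 1:10) {
    g <- matrix(rnorm(20) + 2 * rnorm(5)[rep(1:5, 4)], 5, 4)
    g[, 2] <- g[, 2] + 1 # ensure rater variance above residual
    ms <- anova_mean_squares(g)
    v <- vapply(ICC_FORMS, function(f) icc(ms, f)$value, numeric(1))
    if (v[["single_consistency"]] > 0) {
      expect_lte(v[["single_consistency"]], v[["average_consistency"]])
      expect_lte(v[["single_agreement"]], v[["average_agreement"]])
    }
    if (ms$ms_cols >= ms$ms_error) {
      expect_lte(v[["single_agreement"]], v[["single_consistency"]])
      expect_lte(v[["average_agreement"]], v[["average_consistency"]])
    }
  }
})

test_that("consistency forms ignore per-rater shifts; agreement forms do not", {
  set.seed(25)
  g <- matrix(rnorm(18) + 3 * rnorm(6)[rep(1:6, 3)], 6, 3)
  g2 <- sweep(g, 2L, c(0, 4, -3), "+")
  for (form in c("single_consistency", "average_consistency")) {
    expect_equal(icc(g2, form)$value, icc(g, form)$value, tolerance = 1e-12)
  }
  for (form in c("single_agreement", "average_agreement")) {
    expect_lt(icc(g2, form)$value, icc(g, form)$value)
  }
})

test_that("average-measures consistency equals 1 - 1/F", {
  set.seed(26)
  for (i in 1:10) {
    g <- matrix(rnorm(24) + rnorm(6)[rep(1:6, 4)], 6, 4)
    res <- icc(g, "average_consistency")
    expect_equal(res$value, 1 - 1 / res$f_value, tolerance = 1e-12)
  }
})

test_that("confidence intervals contain the estimate and nest with the level", {
  set.seed(27)
  for (i in 1:10) {
    g <- matrix(rnorm(30) + 2 * rnorm(6)[rep(1:6, 5)], 6, 5)
    ms <- anova_mean_squares(g)
    for (form in ICC_FORMS) {
      v <- icc(ms, form)$value
      ci95 <- icc_confidence_interval(ms, form, level = 0.95)
      ci99 <- icc_confidence_interval(ms, form, level = 0.99)
      expect_lte(ci95[[1]], v)
      expect_gte(ci95[[2]], v)
      expect_lte(ci99[[1]], ci95[[1]])
      expect_gte(ci99[[2]], ci95[[2]])
    }
  }
})

test_that("a perfect-fit grid degenerates the interval to a point", {
  ms <- anova_mean_squares(rbind(c(1, 2), c(3, 4), c(5, 6)))
  ci <- icc_confidence_interval(ms, "single_consistency")
  expect_equal(unname(ci), c(1, 1))
})

test_that("SEM reproduces the SD*sqrt(1-ICC) identities", {
  expect_equal(sem_measurement(9.5, 0.990)$sem, 0.95, tolerance = 1e-12)
  expect_equal(round(sem_measurement(14.9, 0.994)$sem, 3), 1.154)
  expect_equal(sem_measurement(7, 1)$sem, 0)
  expect_error(sem_measurement(1, 1.2), "<= 1")
  expect_error(sem_measurement(-1, 0.5), ">= 0")
  # monotone decreasing in ICC at fixed SD; linear in SD at fixed ICC
  iccs <- seq(0, 1, by = 0.1)
  sems <- vapply(iccs, function(r) sem_measurement(5, r)$sem, numeric(1))
  expect_true(all(diff(sems) < 0))
  expect_equal(sem_measurement(6, 0.8)$sem, 3 * sem_measurement(2, 0.8)$sem)
})

test_that("ICC interpretation bands are left-closed at 0.5/0.75/0.9", {
  expect_identical(classify_icc(0.981), "excellent")
  expect_identical(classify_icc(0.6), "moderate")
  expect_identical(classify_icc(0.75), "good")
  expect_identical(classify_icc(0.9), "excellent")
  expect_identical(classify_icc(0.49), "poor")
  expect_identical(classify_icc(c(0.3, 0.5)), c("poor", "moderate"))
  expect_error(classify_icc(1.01), "exceed 1")
})
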