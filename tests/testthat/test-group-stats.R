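test_that("pooled two-sample t matches the textbook value and base R", {
  r <- studentT(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.0213, tolerance = 1e-2)
  b <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(r$t, unname(b$statistic))
  expect_equal(r$p, b$p.value)
  w <- studentT(c(1, 2, 3, 9), c(4, 5, 6), welch = TRUE)
  bw <- t.test(c(1, 2, 3, 9), c(4, 5, 6))
  expect_equal(w$t, unname(bw$statistic))
  expect_equal(w$df, unname(bw$parameter))
  expect_equal(w$p, bw$p.value)
})

test_that("t-test degenerate variance conventions", {
  same <- studentT(c(2, 2), c(2, 2))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  apart <- studentT(c(2, 2), c(3, 3))
  expect_identical(apart$t, -Inf); expect_equal(apart$p, 0)
  expect_error(studentT(1, c(1, 2)), "at least 2")
})

test_that("shifting one group shifts its mean exactly, linearity", {
  withr::with_seed(4, {
    x <- rnorm(6); y <- rnorm(6)
  })
  r0 <- studentT(x, y)
  r1 <- studentT(x + 2.5, y)
  expect_equal(r1$mean_x, r0$mean_x + 2.5)
  expect_equal(r1$mean_y, r0$mean_y)
})

test_that("Fisher exact: balanced table, enumeration oracle, symmetry", {
  r <- fisherExact2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p, 1)

  t2 <- matrix(c(12, 3, 5, 9), 2)
  r2 <- fisherExact2x2(t2)
  expect_equal(r2$p, fisherEnumOracle(12, 5, 3, 9), tolerance = 1e-12)
  expect_equal(r2$p, fisher.test(t2)$p.value, tolerance = 1e-12)
  expect_equal(fisherExact2x2(t(t2))$p, r2$p, tolerance = 1e-12)

  ## zero-cell conventions
  expect_identical(fisherExact2x2(matrix(c(3, 0, 0, 4), 2))$odds_ratio,
                   Inf)
  expect_true(is.nan(fisherExact2x2(matrix(c(0, 2, 0, 4),
                                           2))$odds_ratio))
  expect_error(fisherExact2x2(matrix(0, 2, 2)), "empty")
})

test_that("Fisher exact test is conservative under the null", {
  withr::with_seed(9, {
    rej <- 0
    for (i in 1:400) {
      x <- rbinom(1, 25, 0.4); y <- rbinom(1, 25, 0.4)
      if (fisherExact2x2(matrix(c(x, 25 - x, y, 25 - y), 2))$p < 0.05)
        rej <- rej + 1
    }
  })
  expect_lte(rej / 400, 0.05 + 0.02)
})

test_that("chi-square matches the hand-computed expected table", {
  tab <- matrix(c(42, 82, 678, 535), 2)  # rows: terminated vs not
  r <- chiSquare2x2(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r$statistic, sum((tab - E)^2 / E))
  expect_equal(r$statistic,
               unname(chisq.test(tab, correct = FALSE)$statistic))
  expect_equal(r$p, chisq.test(tab, correct = FALSE)$p.value)
  ry <- chiSquare2x2(tab, correction = TRUE)
  expect_equal(ry$statistic, unname(chisq.test(tab)$statistic))

  eq <- chiSquare2x2(matrix(c(10, 20, 30, 60), 2))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)

  ## swapping both rows and both columns leaves the statistic unchanged
  sw <- tab[2:1, 2:1]
  expect_equal(chiSquare2x2(sw)$statistic, r$statistic)
  expect_error(chiSquare2x2(matrix(c(0, 0, 3, 4), 2)), "expected")
})

test_that("chi-square is monotone in the observed-expected deviation", {
  stat <- function(a) chiSquare2x2(matrix(c(a, 50 - a, 50 - a, a),
                                          2))$statistic
  s <- vapply(25:35, stat, 0)
  expect_true(all(diff(s) > 0))
})

test_that("one-way ANOVA with Tukey HSD: hand decomposition and
          invariances", {
  r0 <- centralZoneTimecourse(list(a = c(1, 2, 3), b = c(1, 2, 3),
                                   c = c(1, 2, 3)))
  expect_equal(r0$F, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1)

  ## SSB = 76 on 2 df, SSW = 1.5 on 3 df -> F = 38 / 0.5 = 76
  r <- centralZoneTimecourse(list(a = c(1, 2), b = c(2, 3),
                                  c = c(9, 10)))
  expect_equal(r$F, 76)
  expect_equal(r$df, c(2, 3))
  expect_equal(nrow(r$tukey), 3)

  ## adding a constant to every observation changes nothing
  rc <- centralZoneTimecourse(list(a = c(1, 2) + 7, b = c(2, 3) + 7,
                                   c = c(9, 10) + 7))
  expect_equal(rc$F, r$F)
  expect_equal(rc$tukey$p_adj, r$tukey$p_adj)
  expect_equal(rc$tukey$diff, r$tukey$diff)

  expect_error(centralZoneTimecourse(list(a = c(1, 2))), "2 groups")
  expect_error(centralZoneTimecourse(list(a = 1, b = c(1, 2))),
               "2 values")
})
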