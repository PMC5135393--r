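# confidence intervals, group summaries, normality-routed comparisons

test_that("confidenceInterval reproduces published worked examples", {
  ci <- confidenceInterval(104, 6.7, 10, method = "normal_z")
  expect_equal(round(unname(ci), 2), c(90.87, 117.13))
  ci2 <- confidenceInterval(46, 2.44, 5, method = "student_t")
  expect_equal(round(unname(ci2), 1), c(39.2, 52.8))
  expect_equal(unname(confidenceInterval(10, 0, 5)), c(10, 10))
  expect_error(confidenceInterval(1, 1, 5, level = 1.2), "level")
  expect_error(confidenceInterval(1, 1, 1, method = "student_t"), "n >= 2")
  expect_error(confidenceInterval(1, -1, 5), "sem")
})

test_that("CI width grows with sem and, for student_t, shrinks with n", {
  widths <- vapply(c(1, 2, 5), function(s) diff(confidenceInterval(0, s, 10)),
                   numeric(1))
  expect_true(all(diff(widths) > 0))
  wt <- vapply(c(3, 5, 10, 30), function(n)
    diff(confidenceInterval(0, 1, n, method = "student_t")), numeric(1))
  expect_true(all(diff(wt) < 0))
})

test_that("summarizeGroup: hand-computed examples and Monte-Carlo mean", {
  g <- summarizeGroup(c(1, 1, 1))
  expect_equal(g@mean, 1); expect_equal(g@sem, 0); expect_equal(g@n, 3L)

  g2 <- summarizeGroup(c(2, 4))  # sd = sqrt(2), sem = 1
  expect_equal(g2@mean, 3); expect_equal(g2@sem, 1)

  set.seed(501)
  x <- stats::rnorm(1e4, 100, 15)
  g3 <- summarizeGroup(x)
  expect_lt(abs(g3@mean - 100), 3 * g3@sem)
  expect_error(summarizeGroup(numeric(0)), "empty")
})

test_that("identical groups give t = 0, p = 1", {
  res <- compareGroups(c(1, 2, 3), c(1, 2, 3))
  expect_identical(res@test_used, "unpaired_t")
  expect_equal(res@statistic, 0)
  expect_equal(res@p_value, 1)
})

test_that("routed t-test matches the hand-computed classical t formula", {
  set.seed(502)
  n_t <- 0
  for (i in 1:10) {
    a <- stats::rnorm(10, 100, 15); b <- stats::rnorm(12, 90, 15)
    res <- compareGroups(a, b)
    # the routing must agree with Shapiro-Wilk run independently
    both_normal <- stats::shapiro.test(a)$p.value > 0.05 &&
      stats::shapiro.test(b)$p.value > 0.05
    expect_identical(res@test_used,
                     if (both_normal) "unpaired_t" else "mann_whitney")
    if (!both_normal) next
    n_t <- n_t + 1
    # independent oracle: pooled-variance t statistic and p from first principles
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
    tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2)
    expect_equal(res@statistic, tstat, tolerance = 1e-6)
    expect_equal(res@p_value, p, tolerance = 1e-6)
  }
  expect_gte(n_t, 5)  # most normal pairs take the t route
})

test_that("skewed data routes the comparison to Mann-Whitney", {
  set.seed(7)
  a <- stats::rlnorm(12, 0, 1.5)  # strongly skewed
  b <- stats::rnorm(12, 1, 0.2)
  res <- compareGroups(a, b)
  expect_identical(res@test_used, "mann_whitney")
  expect_lte(res@normality_p_a, 0.05)
  # exact Mann-Whitney for combined n <= 20 without ties
  res2 <- compareGroups(a[1:8], b[1:8])
  expect_true(isTRUE(res2@exact) || res2@test_used == "unpaired_t")
})

test_that("zero-variance groups route to Mann-Whitney rather than erroring", {
  res <- compareGroups(c(5, 5, 5, 5), c(1, 2, 3, 9))
  expect_identical(res@test_used, "mann_whitney")
})

test_that("p-values are symmetric under argument exchange", {
  set.seed(503)
  a <- stats::rnorm(10); b <- stats::rnorm(10, 1)
  expect_equal(compareGroups(a, b)@p_value, compareGroups(b, a)@p_value)
  s <- stats::rlnorm(10, 0, 2)
  expect_equal(compareGroups(a, s)@p_value, compareGroups(s, a)@p_value)
  expect_error(compareGroups(c(1, 2), c(1, 2, 3)), "at least 3")
})
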