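test_that("descriptives use linear-interpolation percentiles", {
  d <- describe_periods(matrix(c(1, 2, 3, 4, 5), ncol = 1))
  expect_equal(d$median, 3)
  expect_equal(d$q25, 2)
  expect_equal(d$q75, 4)
  d2 <- describe_periods(matrix(c(5, NA, NA, NA), ncol = 1))
  expect_equal(unlist(d2[c("median", "q25", "q75")]), c(median = 5, q25 = 5, q75 = 5))
  expect_equal(describe_periods(matrix(1:4, ncol = 1))$median, 2.5)
  expect_equal(describe_periods(matrix(NA_real_, 2, 1))$n, 0L)
})

test_that("Friedman matches its closed form and the base-R implementation", {
  # all subjects identical across periods: complete ties, zero statistic
  tied <- matrix(5, nrow = 4, ncol = 3)
  ft <- friedman_cohort(tied)
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p.value, 1)

  # strictly increasing rows: ranks (1,2,3) everywhere -> chi^2 = 2n
  inc <- matrix(c(1, 2, 3, 2, 3, 4, 5, 6, 7), nrow = 3, byrow = TRUE)
  f <- friedman_cohort(inc)
  expect_equal(f$statistic, 6)
  expect_equal(f$df, 2L)

  set.seed(51)
  for (i in 1:20) {
    m <- matrix(rnorm(10 * 9), nrow = 10)   # continuous, untied
    expect_equal(friedman_cohort(m)$statistic,
                 unname(stats::friedman.test(m)$statistic), tolerance = 1e-10)
  }
})

test_that("Friedman holds its nominal type-I error", {
  set.seed(52)
  rej <- replicate(1000, friedman_cohort(matrix(rnorm(90), 10, 9))$p.value < 0.05)
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Friedman is invariant to strictly monotone transforms", {
  set.seed(53)
  m <- matrix(rexp(8 * 9) + 0.1, nrow = 8)
  base <- friedman_cohort(m)$statistic
  expect_equal(friedman_cohort(log(m))$statistic, base)
  expect_equal(friedman_cohort(3 * m + 7)$statistic, base)
})

test_that("Skillings-Mack equals Friedman on complete untied data", {
  inc <- matrix(c(1, 2, 3, 2, 3, 4, 5, 6, 7), nrow = 3, byrow = TRUE)
  expect_equal(skillings_mack(inc)$statistic, 6, tolerance = 1e-10)
  expect_equal(skillings_mack(matrix(5, 4, 3))$statistic, 0, tolerance = 1e-12)
  set.seed(54)
  for (i in 1:20) {
    m <- matrix(rnorm(8 * 5), nrow = 8)
    expect_equal(skillings_mack(m)$statistic, friedman_cohort(m)$statistic,
                 tolerance = 1e-10)
  }
})

test_that("Skillings-Mack uses incomplete rows that Friedman must drop", {
  set.seed(55)
  m <- matrix(rnorm(12 * 5, 100, 10), nrow = 12)
  m[cbind(1:4, c(1, 3, 5, 2))] <- NA
  sm <- skillings_mack(m)
  expect_equal(sm$n, 12L)
  expect_equal(sm$df, 4L)
  expect_true(sm$p.value >= 0 && sm$p.value <= 1)
  expect_equal(friedman_cohort(m)$n, 8L)
})

test_that("a disconnected observation pattern is refused with named blocks", {
  m <- matrix(NA_real_, 4, 4, dimnames = list(NULL, paste0("T", 1:4)))
  m[1:2, 1:2] <- rnorm(4)
  m[3:4, 3:4] <- rnorm(4)
  expect_error(skillings_mack(m), "disconnected.*T1.*T3")
})

test_that("post-hoc testing is gated on the omnibus result", {
  set.seed(56)
  m <- matrix(rnorm(6 * 4), nrow = 6, dimnames = list(NULL, paste0("T", 1:4)))
  ns <- list(p.value = 0.30)
  empty <- posthoc_periods(m, ns)
  expect_equal(nrow(empty), 0L)
  expect_match(attr(empty, "note"), "not significant")
})

test_that("pairwise Wilcoxon with Holm flags a strong injected effect", {
  set.seed(57)
  m <- matrix(rnorm(24 * 4, 100, 5), nrow = 24,
              dimnames = list(NULL, paste0("T", 1:4)))
  m[, "T4"] <- m[, "T4"] + 25
  ph <- posthoc_periods(m, friedman_cohort(m))
  t14 <- ph[ph$period_a == "T1" & ph$period_b == "T4", ]
  t12 <- ph[ph$period_a == "T1" & ph$period_b == "T2", ]
  expect_true(t14$significant)
  expect_false(t12$significant)
  # identical columns never reach significance
  m2 <- m; m2[, "T2"] <- m2[, "T1"]
  ph2 <- posthoc_periods(m2, friedman_cohort(m2))
  expect_equal(ph2[ph2$period_a == "T1" & ph2$period_b == "T2", "p_raw"], 1)
  # Holm adjustment is monotone in the raw p-values
  ord <- order(ph$p_raw)
  expect_true(all(diff(ph$p_adj[ord]) >= -1e-12))
  expect_true(all(ph$p_adj >= ph$p_raw - 1e-12))
})

test_that("the rank critical-difference variant agrees on the strong effect", {
  set.seed(58)
  m <- matrix(rnorm(24 * 4, 100, 5), nrow = 24,
              dimnames = list(NULL, paste0("T", 1:4)))
  m[, "T4"] <- m[, "T4"] + 25
  ph <- posthoc_periods(m, friedman_cohort(m), method = "rank-cd")
  expect_true(ph[ph$period_a == "T1" & ph$period_b == "T4", "significant"])
})

test_that("Mann-Whitney matches the exact enumeration on a tiny example", {
  res <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$statistic, 0)        # U for the first group
  expect_equal(res$p.value, 0.1)        # 2/20 arrangements, two-sided
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p.value, 0.9)
  expect_error(mann_whitney(numeric(0), 1:3), "empty group")
})

test_that("Mann-Whitney holds its nominal level", {
  set.seed(59)
  rej <- replicate(1000, mann_whitney(rnorm(12), rnorm(12))$p.value < 0.05)
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("cohort_matrix validates its shape", {
  expect_error(cohort_matrix(matrix(1, 3, 1)), ">= 2 periods")
  m <- matrix(c(1, NA, NA, 2, NA, NA), nrow = 3)
  expect_error(cohort_matrix(m), ">= 2 observed periods")
})
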