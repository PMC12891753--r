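test_that("Fisher p-values reproduce the printed cohort statistics", {
  human <- fisher_exact_2x2(3, 0, 16, 26)
  expect_equal(round(human$p_two_sided, 3), 0.068)
  expect_identical(human$or_sample, Inf)
  expect_equal(round(human$ci_conditional_exact[1], 2), 0.59)
  expect_identical(human$ci_conditional_exact[2], Inf)
  mouse <- fisher_exact_2x2(5, 7, 11, 23)
  expect_equal(round(mouse$p_two_sided, 2), 0.73)
  expect_equal(round(mouse$or_sample, 2), 1.49)
  expect_equal(round(mouse$ci_woolf, 2), c(0.39, 5.78))
})

test_that("Fisher p-values equal the binomial-coefficient enumeration oracle", {
  set.seed(3)
  for (i in 1:60) {
    tb <- rpois(4, 6)
    if (sum(tb) == 0) next
    got <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4], ci = FALSE)
    want <- enum_fisher(tb[1], tb[2], tb[3], tb[4])
    expect_equal(got$p_two_sided, want$p_two, tolerance = 1e-12)
    expect_equal(got$p_one_sided, want$p_one, tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "all-zero")
})

test_that("two-sided Fisher agrees with the reference implementation", {
  set.seed(11)
  for (i in 1:40) {
    tb <- matrix(rpois(4, 8), 2)
    if (sum(tb) == 0) next
    expect_equal(fisher_exact_2x2(tb, ci = FALSE)$p_two_sided,
                 fisher.test(tb)$p.value, tolerance = 1e-9)
  }
})

test_that("table symmetries behave: transpose keeps p/OR, row swap inverts OR", {
  tb <- matrix(c(9, 4, 3, 11), 2, byrow = TRUE)
  a <- fisher_exact_2x2(tb)
  b <- fisher_exact_2x2(t(tb))
  expect_equal(a$p_two_sided, b$p_two_sided)
  expect_equal(a$or_sample, b$or_sample)
  swapped <- fisher_exact_2x2(tb[2:1, ])
  expect_equal(swapped$or_sample, 1 / a$or_sample)
})

test_that("Woolf intervals are symmetric in log space and shrink with n", {
  sym <- woolf_ci(matrix(c(6, 6, 6, 6), 2))
  expect_equal(log(sym[1]), -log(sym[2]))
  small <- woolf_ci(matrix(c(10, 6, 5, 12), 2))
  big <- woolf_ci(matrix(c(10, 6, 5, 12) * 100, 2))
  expect_lt(diff(log(big)), diff(log(small)))
  expect_warning(woolf_ci(matrix(c(3, 0, 16, 26), 2, byrow = TRUE)),
                 "Haldane")
})

test_that("conditional-exact CI bounds match independent root finders", {
  tabs <- list(c(3, 0, 16, 26), c(9, 4, 3, 11), c(2, 8, 7, 3))
  for (tb in tabs) {
    m <- matrix(tb, 2, byrow = TRUE)
    ci <- conditional_exact_ci(m)
    # bisection oracle for the lower bound
    expect_equal(ci[1], bisect_exact_lo(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-4)
    # fisher.test inverts the same tails (its root finder is coarser)
    ref <- fisher.test(m)$conf.int
    expect_equal(ci[1], ref[1], tolerance = 0.005)
    if (is.finite(ref[2]))
      expect_equal(ci[2], ref[2], tolerance = 0.005)
    else expect_identical(ci[2], Inf)
  }
  expect_error(conditional_exact_ci(matrix(c(0, 3, 0, 26), 2,
                                           byrow = TRUE)),
               "degenerate")
})

test_that("Wilcoxon wrapper is exact for small untied samples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3)
  expect_gt(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 0.99)
  # large-sample normal approximation close to Monte-Carlo permutation
  set.seed(21)
  x <- rnorm(30); y <- rnorm(30, 0.4)
  p_approx <- wilcoxon_rank_sum(x, y)
  pooled <- c(x, y)
  mc <- replicate(2e4, {
    idx <- sample.int(60, 30)
    sum(rank(pooled)[idx])
  })
  obs <- sum(rank(pooled)[1:30])
  p_mc <- mean(abs(mc - mean(mc)) >= abs(obs - mean(mc)))
  expect_lt(abs(p_approx - p_mc), 0.01)
})

test_that("t-test and Cohen's d follow the pooled-variance formulas", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  r <- students_t(x, y)
  expect_equal(r$p, 1)
  expect_equal(cohens_d(x, y), 0)
  set.seed(5)
  a <- rnorm(12); b <- rnorm(15, 0.7)
  d <- cohens_d(a, b)
  sp <- sqrt(((11) * var(a) + (14) * var(b)) / 25)
  expect_equal(d, (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  expect_equal(students_t(a, b)$t, t.test(a, b, var.equal = TRUE)$statistic,
               ignore_attr = TRUE, tolerance = 1e-12)
  # unit shift at equal variance gives |d| = shift / sd
  expect_equal(cohens_d(a + 1, a), 1 / sd(a), tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("Jonckheere-Terpstra matches exhaustive enumeration on tiny data", {
  r <- jonckheere_terpstra(list(1, 2, 3))
  expect_equal(r$jt_statistic, 3)
  expect_equal(r$p_one_sided, 1 / 6)
  dec <- jonckheere_terpstra(list(3, 2, 1))
  expect_gte(dec$p_one_sided, 0.5)
  expect_lt(jonckheere_terpstra(list(3, 2, 1),
                                alternative = "decreasing")$p_one_sided,
            0.5)
  expect_error(jonckheere_terpstra(list(1:3)), "2 ordered groups")
})

test_that("two-group JT reduces to the one-sided Mann-Whitney test", {
  set.seed(9)
  x <- rnorm(5); y <- rnorm(6, 1)
  jt <- jonckheere_terpstra(list(x, y), exact = TRUE)
  expect_equal(jt$p_one_sided,
               wilcox.test(y, x, alternative = "greater",
                           exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("JT normal approximation tracks the exact tail", {
  set.seed(14)
  groups <- list(rnorm(4), rnorm(4, 0.8), rnorm(4, 1.6))
  ex <- jonckheere_terpstra(groups, exact = TRUE)
  ap <- jonckheere_terpstra(groups, exact = FALSE)
  expect_lt(abs(ex$p_one_sided - ap$p_one_sided), 0.05)
})

test_that("permutation association is seeded, bounded and degenerate-safe", {
  set.seed(2)
  v <- rnorm(12); lab <- rep(c(0, 1), 6)
  a <- permutation_assoc(v, lab, n_resamples = 500, seed = 10)
  b <- permutation_assoc(v, lab, n_resamples = 500, seed = 10)
  expect_identical(a, b)
  expect_gte(a$p_two_sided, 1 / 501)
  expect_warning(r0 <- permutation_assoc(rep(1, 10), rep(c(0, 1), 5),
                                         n_resamples = 100, seed = 1),
                 "degenerate")
  expect_equal(r0$p_two_sided, 1)
  expect_equal(r0$z, 0)
})

test_that("a strong planted association yields an extreme permutation p", {
  set.seed(8)
  lab <- rep(c(0, 1), each = 10)
  v <- rnorm(20) + 3 * lab
  r <- permutation_assoc(v, lab, n_resamples = 1999, seed = 3)
  expect_lt(r$p_two_sided, 0.01)
  expect_gt(r$z, 3)
})
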