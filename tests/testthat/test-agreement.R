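test_that("Pearson r is exact for affine relations and matches the hand formula", {
  expect_equal(pearson_r(paired_series(1:3, c(2, 4, 6), "EDV")), 1)
  expect_equal(pearson_r(paired_series(1:3, c(6, 4, 2), "EDV")), -1)
  a <- c(10, 12, 14, 20); b <- c(11, 11, 15, 19)
  want <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(paired_series(a, b, "ESV")), want, tolerance = 1e-12)
  expect_error(pearson_r(paired_series(c(5, 5, 5), 1:3, "EF")),
               class = "cardioseg_stats_error")
})

test_that("Pearson r is invariant under positive affine maps", {
  set.seed(61)
  a <- rnorm(20); b <- rnorm(20)
  s <- paired_series(a, b, "EDV")
  s2 <- paired_series(3 * a + 7, b, "EDV")
  expect_equal(pearson_r(s2), pearson_r(s))
})

test_that("the paired t-test matches hand computation on d = (-1, 1, -1)", {
  s <- paired_series(c(0, 1, 0), c(1, 0, 1), "EF")
  tt <- paired_t(s)
  expect_equal(tt$t, -0.5)
  expect_equal(tt$df, 2)
  expect_equal(tt$p_two_tailed, 2 * stats::pt(-0.5, df = 2))
  expect_equal(tt$p_two_tailed, 0.667, tolerance = 1e-3)
})

test_that("paired t is antisymmetric in the two methods and degenerate on ties", {
  set.seed(62)
  a <- rnorm(15, 100, 20); b <- a + rnorm(15, 2, 5)
  t1 <- paired_t(paired_series(a, b, "EDV"))
  t2 <- paired_t(paired_series(b, a, "EDV"))
  expect_equal(t2$t, -t1$t)
  expect_equal(t2$p_two_tailed, t1$p_two_tailed)
  # symmetric differences around zero give t = 0, p = 1
  s0 <- paired_series(c(1, 2, 3, 4), c(2, 1, 4, 3), "EF")
  expect_equal(paired_t(s0)$t, 0)
  expect_equal(paired_t(s0)$p_two_tailed, 1)
  expect_error(paired_t(paired_series(c(1, 2, 3), c(1, 2, 3) , "EF")),
               class = "cardioseg_stats_error")
})

test_that("the KS normality check accepts normal and rejects two-point data", {
  set.seed(63)
  x <- rnorm(200)
  expect_gt(ks_normality(x, mc_reps = 2000)$p, 0.05)
  y <- sample(c(0, 100), 200, replace = TRUE)
  expect_lt(ks_normality(y, mc_reps = 2000)$p, 0.01)
  expect_error(ks_normality(c(1, 2)), class = "cardioseg_stats_error")
  expect_error(ks_normality(rep(3, 10)), class = "cardioseg_stats_error")
})

test_that("the KS distance agrees with the nortest Lilliefors statistic", {
  skip_if_not_installed("nortest")
  set.seed(64)
  for (i in 1:5) {
    x <- rnorm(50, 10, 3)
    expect_equal(cardioseg:::lilliefors_D(x),
                 unname(nortest::lillie.test(x)$statistic), tolerance = 1e-12)
  }
})

test_that("Bland-Altman limits bracket the bias at 1.96 sample sd", {
  s <- paired_series(c(10, 20, 30), c(10, 20, 30), "EDV")
  ba <- bland_altman(s)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(0, 0))
  expect_equal(ba$coverage_fraction, 1)
  # differences (-4, 4, 0): sd = 4, limits at +/- 7.84
  s2 <- paired_series(c(6, 14, 10), c(10, 10, 10), "ESV")
  ba2 <- bland_altman(s2)
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$sd_diff, 4)
  expect_equal(ba2$loa_high, 7.84)
  expect_equal(ba2$loa_low, -7.84)
})

test_that("clinical relevance uses inclusive 10 mL / 3 percentage-point thresholds", {
  expect_false(clinical_relevance(1.1, "EF"))
  expect_false(clinical_relevance(-3.7, "ESV"))
  expect_true(clinical_relevance(10, "EDV"))
  expect_true(clinical_relevance(-10, "ESV"))
  expect_true(clinical_relevance(3, "EF"))
  expect_false(clinical_relevance(9.99, "EDV"))
  expect_error(clinical_relevance(5, "SV"), class = "cardioseg_stats_error")
})

test_that("compare_methods matches patients and reports all three parameters", {
  set.seed(65)
  n <- 20
  truth <- rnorm(n, 150, 40)
  df_a <- data.frame(patient_id = paste0("p", 1:n),
                     EDV_ml = truth + rnorm(n, -4, 10),
                     ESV_ml = truth / 2 + rnorm(n, -3, 8),
                     EF_percent = rnorm(n, 56, 8))
  df_b <- data.frame(patient_id = paste0("p", 1:n),
                     EDV_ml = truth, ESV_ml = truth / 2,
                     EF_percent = df_a$EF_percent + rnorm(n, 1, 3))
  rep <- compare_methods(df_a, df_b[sample(n), ], mc_reps = 500)
  expect_named(rep, c("EDV", "ESV", "EF"))
  expect_true(all(vapply(rep, function(r) abs(r$r) <= 1, logical(1))))
  expect_true(all(vapply(rep, function(r) r$loa_low <= r$bias &
                                          r$bias <= r$loa_high, logical(1))))
  # reports are reproducible for a fixed Monte-Carlo seed
  rep2 <- compare_methods(df_a, df_b, mc_reps = 500)
  expect_identical(rep$EDV$ks_p_a, rep2$EDV$ks_p_a)
})
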