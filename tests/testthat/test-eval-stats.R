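test_that("segmentation_eval matches pixel enumeration on canonical cases", {
  a <- blank_mask(8); a[2:4, 2:4] <- TRUE
  expect_equal(segmentation_eval(a, a)$iou, 1)

  b <- blank_mask(8); b[6:7, 6:7] <- TRUE
  expect_equal(segmentation_eval(a, b)$iou, 0)

  # 2x2 squares offset by one pixel in both directions
  g <- blank_mask(8); g[1:2, 1:2] <- TRUE
  i <- blank_mask(8); i[2:3, 2:3] <- TRUE
  ev <- segmentation_eval(g, i)
  expect_equal(ev$tp, 1)
  expect_equal(ev$fp, 3)
  expect_equal(ev$fn, 3)
  expect_equal(ev$iou, 1 / 7)
  expect_equal(sum(ev$confusion_map == "TP"), 1)
  expect_equal(sum(ev$confusion_map == "FP"), 3)
  expect_equal(sum(ev$confusion_map == "FN"), 3)

  expect_error(segmentation_eval(a, blank_mask(9)),
               class = "i3m_shape_mismatch_error")
  both_empty <- segmentation_eval(blank_mask(4), blank_mask(4))
  expect_equal(both_empty$iou, 1)
  expect_true(both_empty$degenerate)
})

test_that("IoU equals the brute-force set formula and is symmetric (property)", {
  set.seed(123)
  for (k in 1:200) {
    g <- matrix(runif(32 * 32) < runif(1, 0.05, 0.6), 32, 32)
    i <- matrix(runif(32 * 32) < runif(1, 0.05, 0.6), 32, 32)
    want <- sum(g & i) / sum(g | i)
    if (!is.finite(want)) want <- 1
    expect_identical(segmentation_eval(g, i)$iou, want)
    expect_identical(segmentation_eval(i, g)$iou, want)
  }
})

test_that("mae_sd returns mean and n-1 SD of absolute errors", {
  expect_equal(mae_sd(c(1, 2, 3), c(1, 2, 3)), c(mae = 0, sd_ae = 0))
  expect_equal(mae_sd(c(0.10, 0.10), c(0.12, 0.04))[["mae"]], 0.04)
  got <- mae_sd(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_equal(got[["mae"]], 2.5)
  expect_equal(got[["sd_ae"]], sqrt(5 / 3), tolerance = 1e-12)
  expect_error(mae_sd(1:3, 1:4), class = "i3m_shape_mismatch_error")
})

test_that("pearson_r matches the closed form with an integrated t p-value", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_r(x, 2 * x + 1)[["r"]], 1)
  expect_equal(pearson_r(x, -x)[["r"]], -1)
  got <- pearson_r(c(1, 2, 3), c(1, 3, 2))
  expect_equal(got[["r"]], 0.5, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 5)), class = "i3m_constant_series_error")

  set.seed(31)
  for (k in 1:25) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    got <- pearson_r(x, y)
    r <- pearson_closed_form(x, y)
    expect_equal(got[["r"]], r, tolerance = 1e-9)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(got[["p"]], t_p_integrate(tstat, n - 2), tolerance = 1e-6)
  }
})

test_that("paired_t_test matches the closed form with an integrated p-value", {
  got <- paired_t_test(c(1, -1, 1, -1), c(0, 0, 0, 0))
  expect_equal(got[["t"]], 0)
  expect_equal(got[["p"]], 1)

  got <- paired_t_test(c(1, 2, 3), c(0, 0, 0))
  expect_equal(got[["t"]], 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(got[["p"]], 0.0742, tolerance = 1e-3)
  expect_error(paired_t_test(1:4, 1:4), class = "i3m_constant_series_error")

  set.seed(32)
  for (k in 1:25) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n, 0.3)
    got <- paired_t_test(x, y)
    d <- x - y
    tstat <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(got[["t"]], tstat, tolerance = 1e-9)
    expect_equal(got[["p"]], t_p_integrate(tstat, n - 1), tolerance = 1e-6)
  }
})

test_that("mcnemar_test switches between exact and chi-square paths", {
  # 5/5 discordant: exact path, symmetric -> p = 1
  a <- c(rep("minor", 5), rep("adult", 5), rep("minor", 10))
  b <- c(rep("adult", 5), rep("minor", 5), rep("minor", 10))
  got <- mcnemar_test(a, b)
  expect_equal(got$method, "exact-binomial")
  expect_equal(got$p_value, 1)

  # 20/10 discordant: chi-square without continuity correction
  a2 <- c(rep("minor", 20), rep("adult", 10), rep("minor", 3))
  b2 <- c(rep("adult", 20), rep("minor", 10), rep("minor", 3))
  got2 <- mcnemar_test(a2, b2)
  expect_equal(got2$method, "chi-square")
  expect_equal(got2$statistic, 100 / 30, tolerance = 1e-12)
  expect_equal(got2$p_value, stats::pchisq(100 / 30, 1, lower.tail = FALSE))
  ref <- stats::mcnemar.test(table(factor(a2), factor(b2)), correct = FALSE)
  expect_equal(got2$statistic, unname(ref$statistic))
  expect_equal(got2$p_value, ref$p.value)

  expect_equal(mcnemar_test(a, a)$p_value, 1)

  set.seed(33)
  for (k in 1:25) {
    n <- sample(10:80, 1)
    a <- sample(c("minor", "adult"), n, replace = TRUE)
    b <- sample(c("minor", "adult"), n, replace = TRUE)
    got <- mcnemar_test(a, b)
    n01 <- sum(a == "adult" & b == "minor")
    n10 <- sum(a == "minor" & b == "adult")
    if (n01 + n10 >= 25) {
      expect_equal(got$p_value,
                   stats::pchisq((n01 - n10)^2 / (n01 + n10), 1, lower.tail = FALSE),
                   tolerance = 1e-9)
    } else if (n01 + n10 > 0) {
      expect_equal(got$p_value, binom_two_sided(n01, n01 + n10), tolerance = 1e-9)
    }
  }

  expect_error(mcnemar_test(c("a", "b", "c"), c("a", "b", "c")),
               class = "i3m_label_error")
})

test_that("decision_agreement is the fraction of equal labels", {
  expect_equal(decision_agreement(c("m", "a"), c("m", "a")), 1)
  expect_equal(decision_agreement(rep(c("m", "a"), c(54, 3)),
                                  rep("m", 57)), 54 / 57)
  expect_equal(round(100 * decision_agreement(rep(c("m", "a"), c(54, 3)),
                                              rep("m", 57)), 1), 94.7)
  expect_equal(decision_agreement(c("m", "m"), c("a", "a")), 0)
  expect_error(decision_agreement("m", c("m", "a")),
               class = "i3m_shape_mismatch_error")
})

test_that("compare_scores assembles the full battery as a tidy report", {
  set.seed(77)
  ref <- runif(40, 0.02, 0.3)
  est <- ref + rnorm(40, 0.005, 0.02)
  rep <- compare_scores(est, ref)
  td <- tidy(rep)
  expect_equal(td$n, 40)
  expect_equal(td$mae, mean(abs(est - ref)))
  expect_equal(td$pearson_r, cor(est, ref))
  expect_true(td$agreement_fraction >= 0 && td$agreement_fraction <= 1)
  expect_identical(tidy(rep), glance(rep))
})
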