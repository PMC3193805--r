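test_that("relative change is exact and rejects zero baselines", {
  expect_equal(relative_change(2, 2), 0)
  expect_equal(relative_change(1.0, 1.29), 29)
  expect_equal(relative_change(1.0, 0.74), -26)
  expect_error(relative_change(0, 1), "non-zero")
  # relative_change(pre, pre * (1 + delta)) = 100 * delta exactly
  for (delta in c(-0.5, -0.01, 0.2, 1.45)) {
    expect_equal(relative_change(3.7, 3.7 * (1 + delta)), 100 * delta)
  }
})

test_that("t-tests use the pooled Student form and survive degeneracy", {
  res <- group_ttest(c(1, 2, 3, 4, 5), c(3, 4, 5, 6, 7))
  expect_equal(res$t, -2)
  expect_equal(res$df, 8)

  # paired sample against itself: constant differences, flagged NaN
  expect_warning(self <- group_ttest(c(1, 2, 3), c(1, 2, 3), paired = TRUE),
                 "degenerate")
  expect_true(self$degenerate)
  expect_true(is.nan(self$p))

  expect_error(group_ttest(1, c(1, 2)), ">= 2")
  expect_error(group_ttest(c(1, 2), c(1, 2, 3), paired = TRUE), "equal length")
})

test_that("t-test type-I error is nominal under the null", {
  set.seed(101)
  rej <- mean(replicate(1000, {
    group_ttest(rnorm(9), rnorm(9))$p < 0.05
  }))
  expect_gt(rej, 0.032)
  expect_lt(rej, 0.068)
})

test_that("pearson matches closed forms and its invariances", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson(1:10, -(1:10))$r, -1)
  expect_error(pearson(1:2, 1:2), ">= 3")
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
  set.seed(31)
  x <- rnorm(12); y <- rnorm(12)
  r0 <- pearson(x, y)$r
  expect_equal(pearson(3 * x + 7, y)$r, r0)        # affine invariance
  expect_equal(pearson(x, -y)$r, -r0)              # sign flip
  expect_equal(pearson(x, y)$p,
               cor.test(x, y)$p.value)             # p from the t transform
})

test_that("cohort summaries compute both relative-change conventions", {
  tumors <- data.frame(
    group = rep(c("g1", "g2"), each = 3),
    A_pre = c(1, 2, 4, 1, 1, 1),
    A_post = c(2, 2, 4, 1.2, 1.3, 1.1),
    kel_pre = rep(0.3, 6), kel_post = rep(0.45, 6),
    hypoxic_fraction_pct = c(20, 22, 24, 10, 12, 14))
  s <- summarize_cohort(tumors)
  g1 <- s[s$group == "g1", ]
  # mean of per-tumor changes: (100 + 0 + 0) / 3
  expect_equal(g1$dA_pct_mean, 100 / 3)
  # relative change of group means: (8/3 - 7/3) / (7/3)
  expect_equal(g1$dA_of_means_pct, 100 / 7)
  expect_equal(g1$dkel_pct_mean, 50)
  expect_equal(g1$hypoxic_fraction_pct_mean, 22)
  expect_equal(g1$hypoxic_fraction_pct_sem, sd(c(20, 22, 24)) / sqrt(3))
  expect_equal(s$n, c(3, 3))
})

test_that("correlation table computes the five pairings and skips gaps", {
  sm <- data.frame(group = paste0("g", 1:5),
                   hypoxic_fraction_pct_mean = c(23, 21, 14, 15, 11),
                   dA_pct_mean = c(-18, -26, 4, 20, 29),
                   dkel_pct_mean = c(45, 85, 47, -27, -27),
                   dvol_pct_mean = c(150, 90, 40, 60, 20))
  tab <- build_correlation_table(sm)
  expect_equal(nrow(tab), 5L)
  expect_true(all(!tab$skipped))
  expect_true(all(abs(tab$r) <= 1))
  expect_equal(tab$r[tab$var_x == "hypoxic_fraction_pct" &
                       tab$var_y == "dA_pct"],
               cor(sm$hypoxic_fraction_pct_mean, sm$dA_pct_mean))

  # constructed noise-free coupling: exactly r = -1
  sm2 <- sm
  sm2$hypoxic_fraction_pct_mean <- 17 - 0.21 * sm2$dA_pct_mean
  tab2 <- build_correlation_table(sm2)
  expect_equal(tab2$r[1], -1)

  # a missing hypoxia mean disables the three hypoxia pairings
  sm3 <- sm; sm3$hypoxic_fraction_pct_mean[2] <- NA
  tab3 <- NULL
  w <- capture_warnings(tab3 <- build_correlation_table(sm3))
  expect_length(w, 3L)
  expect_match(w, "skipped", all = TRUE)
  expect_equal(sum(tab3$skipped), 3L)
  expect_equal(sum(!tab3$skipped), 2L)

  expect_error(build_correlation_table(sm[1:2, ]), ">= 3 groups")

  # round trip through CSV preserves the r values exactly
  csv <- file.path(tempdir(), "corr.csv")
  write.csv(sm, csv, row.names = FALSE)
  tab4 <- build_correlation_table(read.csv(csv))
  expect_equal(tab4$r, tab$r)
  unlink(csv)
})
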