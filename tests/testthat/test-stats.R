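test_that("describe gates on Shapiro-Wilk and formats accordingly", {
  d <- describe(c(1, 2, 3, 4, 5))
  expect_equal(d$method, "mean_sd")
  expect_equal(d$mean, 3)
  expect_gte(d$normality_p, 0.05)

  x <- with_seed_test(11, rexp(50))
  d2 <- describe(x)
  expect_equal(d2$method, "median_iqr")
  expect_equal(d2$median, unname(quantile(x, 0.5, type = 7)))
  expect_equal(d2$q25, unname(quantile(x, 0.25, type = 7)))

  expect_warning(d3 <- describe(rep(4, 10)), "constant")
  expect_equal(d3$sd, 0)
  expect_error(describe(c(1, 2)), "at least 3")
})

test_that("comparison test selection follows the normality gate", {
  a <- with_seed_test(1, rnorm(30, 0, 1))
  b <- with_seed_test(2, rnorm(30, 5, 1))
  r <- compare_groups(a, b)
  expect_equal(r$test_name, "t")
  expect_true(r$significant)

  hv <- with_seed_test(3, rcauchy(40))
  hv2 <- with_seed_test(4, rcauchy(40))
  r2 <- compare_groups(hv, hv2)
  expect_equal(r2$test_name, "mann-whitney-u")

  x <- with_seed_test(5, rnorm(20))
  r3 <- compare_groups(x, x, paired = TRUE)
  expect_equal(r3$test_name, "paired-t")
  expect_equal(r3$p_value, 1)
  expect_equal(r3$statistic, 0)

  skewp <- with_seed_test(6, rexp(30))
  r4 <- compare_groups(skewp, skewp * 0.2 + with_seed_test(7, rexp(30)) * 3,
                       paired = TRUE)
  expect_equal(r4$test_name, "wilcoxon")

  r5 <- compare_groups(a, b, bonferroni = TRUE, m = 20)
  expect_equal(r5$alpha_effective, 0.05 / 20)
  expect_error(compare_groups(1:4, 1:5, paired = TRUE), "equal-length")
})

test_that("Bland-Altman limits follow the 1.96 SD convention", {
  x <- c(1, 2, 3, 4)
  expect_equal(bland_altman(x, x), list(mean_diff = 0, loa_low = 0,
                                        loa_high = 0, sd_diff = 0))
  ba <- bland_altman(x, x + 2)
  expect_equal(ba$mean_diff, -2)
  expect_equal(ba$loa_low, -2)
  expect_equal(ba$loa_high, -2)
  ba2 <- bland_altman(c(-1, 0, 1), c(0, 0, 0))
  expect_equal(ba2$mean_diff, 0)
  expect_equal(ba2$loa_high, 1.96, tolerance = 1e-12)
  # antisymmetry
  y <- c(2, 1, 5, 3)
  f <- bland_altman(x, y); g <- bland_altman(y, x)
  expect_equal(f$mean_diff, -g$mean_diff)
  expect_equal(f$loa_low, -g$loa_high)
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("ICC(1,1) matches the one-way ANOVA mean squares exactly", {
  # hand-computed fixture: MSB = 8, MSW = 0.5 -> 7.5/8.5
  x <- c(1, 3, 5); y <- c(2, 4, 6)
  expect_equal(icc_1_1(x, y), 7.5 / 8.5, tolerance = 1e-12)

  # brute-force oracle through aov() on the long-format one-way layout
  icc_aov <- function(x, y) {
    n <- length(x)
    df <- data.frame(v = c(x, y), subj = factor(rep(seq_len(n), 2)))
    ms <- summary(aov(v ~ subj, data = df))[[1]]$`Mean Sq`
    (ms[1] - ms[2]) / (ms[1] + ms[2])
  }
  set.seed(9)
  for (rep in 1:5) {
    tr <- rnorm(8, 10, 3)
    xx <- tr + rnorm(8, 0, 1)
    yy <- tr + rnorm(8, 0, 1)
    expect_equal(icc_1_1(xx, yy), icc_aov(xx, yy), tolerance = 1e-10)
  }

  expect_equal(icc_1_1(c(1, 5, 9), c(1, 5, 9)), 1)
  xr <- with_seed_test(8, rnorm(200))
  yr <- with_seed_test(9, rnorm(200))
  expect_lt(abs(icc_1_1(xr, yr)), 0.15)
  expect_warning(icc_1_1(rep(1, 5), rep(1, 5)), "degenerate|variance")
})

test_that("similarity coding counts agreements and honours relational rows", {
  ch <- cohort_from_truth("human", 20, seed = 31)
  # identical cohorts: every simple row agrees, every ordering matches
  s_same <- similarity_table(ch, ch)
  expect_equal(attr(s_same, "score"), nrow(s_same))

  # planted differences through column shifts: the shifted rows disagree
  cb <- ch
  cb$species <- "synthetic"
  cb$L_MPA <- cb$L_MPA + 15
  cb$alpha <- cb$alpha - 25
  cb$n_side_lpa <- cb$n_side_lpa + 3L
  cb$n_side_rpa <- cb$n_side_rpa + 3L
  s <- similarity_table(cb, ch)
  expect_equal(s$code[s$row == "L_MPA"], "-")
  expect_equal(s$code[s$row == "angle"], "-")
  expect_equal(s$code[s$row == "side_branches"], "-")
  expect_equal(attr(s, "score"), nrow(s) - 3)

  # forcing a reversed within-species taper ordering flips its relational row
  cb2 <- ch
  cb2$T_RPA <- ch$T_LPA + 0.05
  s2 <- similarity_table(cb2, ch)
  expect_equal(s2$code[s2$row == "T_RPA_lt_T_LPA"], "-")

  expect_error(similarity_table(ch[, 1:4], ch), "missing parameter")
})
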