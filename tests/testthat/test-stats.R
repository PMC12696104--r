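test_that("one-way ANOVA matches hand calculations and the t-test identity", {
  g <- factor(rep(c("A", "B"), each = 3))
  # identical groups: no between-group variance
  r0 <- run_anovas(structure(
    data.frame(id = 1:6, group = g, x_var = "t", y_var = "a",
               form = "linear_increase", param = 1L,
               value = rep(c(1, 2, 3), 2), converged = TRUE, rss = 0),
    class = c("of_param_table", "data.frame")))
  expect_equal(r0$F, 0)
  expect_equal(r0$p_value, 1)
  # textbook case {1,2,3} vs {4,5,6}: F = 13.5
  tab <- structure(
    data.frame(id = 1:6, group = g, x_var = "t", y_var = "a",
               form = "linear_increase", param = 1L, value = c(1:3, 4:6),
               converged = TRUE, rss = 0),
    class = c("of_param_table", "data.frame"))
  r <- run_anovas(tab)
  expect_equal(r$F, 13.5)
  # two groups: F equals the squared pooled t statistic
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("two-group single-parameter sub-test, ANOVA and squared t agree", {
  set.seed(12)
  tab <- structure(
    data.frame(id = 1:20, group = rep(c("A", "B"), each = 10),
               x_var = "t", y_var = "a", form = "linear_increase", param = 1L,
               value = rnorm(20), converged = TRUE, rss = 0),
    class = c("of_param_table", "data.frame"))
  subs <- run_subtests(tab)
  anv <- run_anovas(tab)
  tt <- t.test(tab$value[1:10], tab$value[11:20], var.equal = TRUE)
  expect_equal(subs$p_value, anv$p_value, tolerance = 1e-9)
  expect_equal(anv$p_value, tt$p.value, tolerance = 1e-9)
})

test_that("MANOVA has the nominal type-I rate and detects real shifts", {
  set.seed(77)
  alpha <- 0.05
  rej <- replicate(200, {
    m <- matrix(rnorm(40 * 3), ncol = 3)
    g <- factor(rep(c("A", "B"), each = 20))
    run_manova(m, g)$p_value[1] < alpha
  })
  rate <- mean(rej)
  # binomial band around alpha at 200 replicates
  expect_gt(rate, alpha - 3 * sqrt(alpha * (1 - alpha) / 200))
  expect_lt(rate, alpha + 3 * sqrt(alpha * (1 - alpha) / 200))
  power <- mean(replicate(100, {
    m <- matrix(rnorm(60 * 2), ncol = 2)
    m[31:60, 1] <- m[31:60, 1] + 3
    g <- factor(rep(c("A", "B"), each = 30))
    run_manova(m, g)$p_value[1] < alpha
  }))
  expect_gte(power, 0.95)
  # determinism: identical input gives identical output
  m <- matrix(rnorm(30 * 2), ncol = 2)
  g <- factor(rep(c("A", "B"), each = 15))
  expect_identical(run_manova(m, g), run_manova(m, g))
})

test_that("pairwise t-tests report mean-difference coefficients and adjusted p", {
  v <- c(rep(0, 4), rep(1, 4)) + c(rnorm(8, 0, 1e-6))
  g <- rep(c("A", "B"), each = 4)
  out <- pairwise_ttests(v, g)
  expect_equal(out$coef, -1, tolerance = 1e-4)
  expect_lt(out$pvalue_hs, 1e-6)
  # identical groups: zero coefficient
  out0 <- pairwise_ttests(rep(c(1, 2, 3), 2), rep(c("A", "B"), 3))
  expect_equal(out0$coef, 0)
  # three groups: three pairs, adjusted >= raw, and monotone like Holm
  set.seed(5)
  v3 <- rnorm(30); g3 <- rep(c("A", "B", "C"), each = 10)
  out3 <- pairwise_ttests(v3, g3)
  expect_equal(nrow(out3), 3)
  expect_true(all(out3$pvalue_hs >= out3$p_value - 1e-12))
  # Holm-Sidak is never more conservative than Holm-Bonferroni
  expect_true(all(out3$pvalue_hs <= p.adjust(out3$p_value, "holm") + 1e-12))
  # under-filled groups are skipped with NA
  outna <- pairwise_ttests(c(1, 5, 6, 7), c("A", "B", "B", "B"))
  expect_true(is.na(outna$p_value))
})

test_that("run_tests orchestrates the ladder and writes a deterministic report", {
  set.seed(31)
  n <- 16
  g <- rep(c("A", "B"), each = n / 2)
  mk <- function(y_var, shift = 0) {
    do.call(rbind, lapply(1:2, function(j) {
      data.frame(id = 1:n, group = g, x_var = "time", y_var = y_var,
                 form = "linear_increase", param = j,
                 value = rnorm(n) + shift * (g == "B") * (j == 1),
                 converged = TRUE, rss = 0)
    }))
  }
  tab <- structure(rbind(mk("activity", shift = 4), mk("p_pp")),
                   class = c("of_param_table", "data.frame"))
  dir <- withr::local_tempdir()
  rep1 <- run_tests(tab, alpha = 0.05, out_dir = dir)
  expect_true(file.exists(file.path(dir, "stat_report.txt")))
  expect_true(all(file.exists(file.path(dir, c("full_manova.csv", "subtests.csv",
                                               "anovas.csv",
                                               "pairwise_ttests.csv")))))
  # the shifted parameter passes the significance chain; the null one doesn't
  sig <- rep1$anovas$sig_chain
  expect_true(sig[rep1$anovas$y_var == "activity" & rep1$anovas$param == 1])
  expect_false(any(sig[rep1$anovas$y_var == "p_pp"]))
  # byte-identical rerun
  dir2 <- withr::local_tempdir()
  run_tests(tab, alpha = 0.05, out_dir = dir2)
  expect_identical(readLines(file.path(dir, "stat_report.txt")),
                   readLines(file.path(dir2, "stat_report.txt")))
  # empty input reports nothing testable
  empty <- run_tests(structure(data.frame(), class = c("of_param_table",
                                                       "data.frame")))
  expect_match(empty$message, "[Nn]othing testable")
})
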