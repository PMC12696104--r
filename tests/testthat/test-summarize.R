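mk_df <- function(id, time, y, group = "g") {
  data.frame(id = id, group = group, time = time, activity = y,
             coverage = seq_along(time), percent_coverage = NA, pica = NA,
             pgca = NA, p_pp = NA, p_pm = NA, p_p0 = NA, p_0p = NA, p_00 = NA)
}

test_that("temporal summaries give per-timepoint mean and SEM", {
  a <- mk_df(1, 0:4, c(1, 2, 3, 4, 5))
  b <- mk_df(2, 0:4, c(3, 2, 3, 4, 5))
  s <- summarize_temporal(list(a, b), "activity")
  expect_equal(s$mean, c(2, 2, 3, 4, 5))
  expect_equal(s$sem[1], 1)          # values {1,3}: SD sqrt(2), / sqrt(2)
  expect_equal(s$sem[2], 0)
  # identical individuals: mean equals the series, SEM 0
  s2 <- summarize_temporal(list(a, a), "activity")
  expect_equal(s2$mean, a$activity)
  expect_true(all(s2$sem == 0))
  # oracle: per-column recomputation on random data
  set.seed(3)
  dfs <- lapply(1:5, function(i) mk_df(i, 0:9, rnorm(10)))
  s3 <- summarize_temporal(dfs, "activity")
  vals <- sapply(dfs, function(d) d$activity)
  expect_equal(s3$mean, rowMeans(vals))
  expect_equal(s3$sem, apply(vals, 1, sd) / sqrt(5))
})

test_that("equal-count binning pools, sorts and chunks tuples", {
  d <- mk_df(1, 0:9, rep(7, 10))
  d$coverage <- c(5, 3, 1, 8, 2, 9, 0, 4, 6, 7)
  s <- summarize_by_coverage(list(d), "coverage", "activity",
                             method = "n_points", n_points = 5)
  expect_equal(nrow(s), 2)
  expect_equal(s$n, c(5L, 5L))
  expect_true(all(s$mean == 7))      # constant y: every bin mean is 7, SEM 0
  expect_true(all(s$sem == 0))
  expect_equal(s$x, c(mean(0:4), mean(5:9)))
  # single individual with n_points = 1 returns the raw tuples, sorted
  s1 <- summarize_by_coverage(list(d), "coverage", "activity",
                              method = "n_points", n_points = 1)
  expect_equal(s1$x, sort(d$coverage))
  expect_true(all(is.na(s1$sem)))    # n = 1 bins report missing SEM
})

test_that("equal-width binning matches a hand oracle on pooled data", {
  set.seed(8)
  dfs <- lapply(1:3, function(i) {
    d <- mk_df(i, 0:49, rnorm(50))
    d$percent_coverage <- runif(50)
    d
  })
  s <- summarize_by_coverage(dfs, "percent_coverage", "activity",
                             method = "n_bins", n_bins = 4)
  x <- unlist(lapply(dfs, function(d) d$percent_coverage))
  y <- unlist(lapply(dfs, function(d) d$activity))
  orc <- oracle_bin_nbins(x, y, 4)
  expect_equal(s$x, unname(orc[, "center"]), tolerance = 1e-12)
  expect_equal(s$mean, unname(orc[, "mean"]), tolerance = 1e-12)
  expect_equal(as.numeric(s$n), unname(orc[, "n"]))
  # default method selection: percent coverage -> n_bins, coverage -> n_points
  expect_equal(attr(summarize_by_coverage(dfs, "percent_coverage", "activity",
                                          n_bins = 4), "method"), "n_bins")
  expect_equal(attr(summarize_by_coverage(dfs, "coverage", "activity",
                                          n_points = 10), "method"), "n_points")
})

test_that("equal-count binning matches the oracle on pooled random data", {
  set.seed(13)
  for (k in 1:10) {
    x <- runif(120); y <- rnorm(120)
    d <- mk_df(1, seq_along(x) - 1, y)
    d$coverage <- x
    s <- summarize_by_coverage(list(d), "coverage", "activity",
                               method = "n_points", n_points = 25)
    orc <- oracle_bin_npoints(x, y, 25)
    expect_equal(s$x, unname(orc[, "center"]))
    expect_equal(s$mean, unname(orc[, "mean"]))
  }
})

test_that("summaries export one CSV per relationship and round-trip", {
  cfg <- test_config()
  co <- make_cohort(3, explorer_params(duration_s = 120), 0.1, seed = 17)
  ms <- tracks_to_measures(co$tracks, cfg, test_defaults())
  sums <- summarize_all(ms, test_defaults())
  dir <- withr::local_tempdir()
  paths <- export_summaries(sums, dir)
  # grid: (2 x-vars) x (6 y-vars) + coverage~time, one group
  expect_length(paths, 13)
  s <- sums[["cohort|time~activity"]]
  back <- utils::read.csv(file.path(dir, "cohort__time__activity.csv"))
  expect_equal(back$mean, s$mean)
  expect_equal(back$x, s$x)
})
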