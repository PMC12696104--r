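form_truth <- list(
  exponential_decay = c(2, -0.01, 0.1),
  asymptotic_increase = c(-7, -0.005),
  linear_decrease = c(-0.01, 5),
  linear_increase = c(0.02, 1),
  sigmoidal_decay = c(1, -0.02, -300),
  sigmoidal_increase = c(1, 0.02, -300))

test_that("every registered form recovers noiseless parameters exactly", {
  x <- seq(0, 600, length.out = 50)
  for (fm in names(form_truth)) {
    p <- form_truth[[fm]]
    y <- get_model_form(fm)$fun(p, x)
    fit <- fit_curve(x, y, fm)
    expect_true(fit$converged, info = fm)
    expect_equal(fit$par, p, tolerance = 1e-6, info = fm)
  }
})

test_that("5% noise keeps the median relative error under 10%", {
  x <- seq(0, 600, length.out = 50)
  for (fm in names(form_truth)) {
    p <- form_truth[[fm]]
    y0 <- get_model_form(fm)$fun(p, x)
    sigma <- 0.05 * abs(p[1])
    rel <- sapply(1:100, function(s) {
      set.seed(s)
      fit <- fit_curve(x, y0 + rnorm(length(x), 0, sigma), fm)
      abs((fit$par - p) / p)
    })
    # median relative error pooled over the form's parameters and seeds
    expect_lt(median(rel), 0.10, label = sprintf("%s pooled median", fm))
  }
})

test_that("a constant series yields a degenerate but converged decay fit", {
  x <- seq(0, 100, length.out = 30)
  y <- rep(2, 30) + rnorm(30, 0, 1e-3)
  fit <- fit_curve(x, y, "exponential_decay")
  expect_true(fit$converged)
  # either no decaying component or no decay rate
  expect_true(min(abs(fit$par[1]), abs(fit$par[2])) < 1e-3)
  expect_lt(fit$rss, var(y) * length(y))
})

test_that("parameter bounds come from the naive-fit distribution", {
  tab <- data.frame(id = 1:2, group = "g", x_var = "time", y_var = "activity",
                    form = "linear_increase", param = 1L, value = c(1, 3),
                    converged = TRUE, rss = 0)
  b <- find_fit_bounds(tab, bound_level = 2)
  expect_equal(b$lower, max(2 - 2 * sqrt(2), 0))  # clipped at the sign bound
  expect_equal(b$upper, 2 + 2 * sqrt(2))
  # identical individuals collapse to an epsilon-widened point
  tab$value <- c(3, 3)
  b2 <- find_fit_bounds(tab, 2)
  expect_lt(b2$upper - b2$lower, 1e-10)
  expect_true(b2$lower <= 3 && b2$upper >= 3)
  # roughly 95% of naive parameters fall inside 2-SD bounds on normal data
  set.seed(6)
  vals <- rnorm(500, 5, 1)
  tab3 <- data.frame(id = 1:500, group = "g", x_var = "t", y_var = "a",
                     form = "linear_increase", param = 2L, value = vals,
                     converged = TRUE, rss = 0)
  b3 <- find_fit_bounds(tab3, 2)
  inside <- mean(vals >= b3$lower & vals <= b3$upper)
  expect_gt(inside, 0.92)
})

test_that("refits stay within bounds; insiders unchanged, outliers clipped", {
  set.seed(9)
  x <- seq(0, 600, length.out = 60)
  specs <- list("time~activity" = model_spec("time", "activity",
                                             "exponential_decay"))
  mk_df <- function(id, p, noise = 0.02) {
    y <- get_model_form("exponential_decay")$fun(p, x) + rnorm(60, 0, noise)
    data.frame(id = id, group = "g", time = x, activity = y,
               coverage = NA, percent_coverage = NA, pica = NA, pgca = NA,
               p_pp = NA, p_pm = NA, p_p0 = NA, p_0p = NA, p_00 = NA)
  }
  # nine typical individuals and one extreme outlier
  dfs <- c(lapply(1:9, function(i) mk_df(i, c(2 + 0.05 * i, -0.01, 0.1))),
           list(mk_df(10, c(40, -0.2, 3))))
  naive <- fit_all(dfs, specs)
  bounds <- find_fit_bounds(naive, 2)
  refit <- re_fit_all(dfs, specs, naive, bounds)
  for (j in 1:3) {
    vals <- refit$value[refit$param == j]
    expect_true(all(vals >= bounds$lower[bounds$param == j] - 1e-9))
    expect_true(all(vals <= bounds$upper[bounds$param == j] + 1e-9))
  }
  # insiders keep their naive estimates
  nv <- naive$value[naive$id == 5]
  rv <- refit$value[refit$id == 5]
  expect_equal(rv, nv, tolerance = 1e-4)
  # the outlier lands on at least one bound boundary
  out_r <- refit$value[refit$id == 10]
  b_lo <- bounds$lower[order(bounds$param)]
  b_hi <- bounds$upper[order(bounds$param)]
  expect_true(any(abs(out_r - b_hi) < 1e-6 | abs(out_r - b_lo) < 1e-6))
})

test_that("group fits on binned means recover shared parameters", {
  cfg <- test_config()
  co <- make_cohort(6, explorer_params(duration_s = 300), 0, seed = 23)
  ms <- tracks_to_measures(co$tracks, cfg, test_defaults())
  specs <- set_up_fits(cfg, test_defaults(y_vars = "activity"))
  fs <- suppressWarnings(fit_relationships(ms, specs, cfg))
  g <- fs$group
  act <- g[g$x_var == "time" & g$y_var == "activity", ]
  expect_true(all(act$converged))
  # group decay parameters near the generating values (a0=2, b0=-.008, c0=.2)
  expect_equal(act$value[act$param == 1], 2, tolerance = 0.35)
  expect_equal(act$value[act$param == 2], -0.008, tolerance = 0.5)
  # interpretability of the decay form: a ~ y(0) - c, c ~ y(infinity)
  fit <- attr(fs$group, "fits")[["cohort|time~activity"]]
  y0 <- predict(fit, 0)
  yinf <- predict(fit, 1e9)
  expect_equal(fit$par[1], y0 - fit$par[3], tolerance = 1e-8)
  expect_equal(fit$par[3], yinf, tolerance = 1e-8)
})

test_that("parameter export has the documented shape and round-trips", {
  set.seed(10)
  x <- seq(0, 100, length.out = 30)
  specs <- list("time~activity" = model_spec("time", "activity",
                                             "linear_decrease"))
  dfs <- lapply(1:3, function(i) {
    data.frame(id = i, group = c("A", "A", "B")[i], time = x,
               activity = -0.02 * x + 5 + rnorm(30, 0, 0.1),
               coverage = NA, percent_coverage = NA, pica = NA, pgca = NA,
               p_pp = NA, p_pm = NA, p_p0 = NA, p_0p = NA, p_00 = NA)
  })
  naive <- fit_all(dfs, specs)
  bounds <- find_fit_bounds(naive, 2)
  refit <- re_fit_all(dfs, specs, naive, bounds)
  fs <- list(naive = naive, refit = refit)
  out <- format_params(fs)
  # one row per converged individual per parameter
  expect_equal(nrow(out), 3 * 2)
  expect_named(out, c("id", "group", "x_var", "y_var", "form", "param_name",
                      "naive", "refit", "converged"))
  path <- withr::local_tempfile(fileext = ".csv")
  format_params(fs, path)
  back <- utils::read.csv(path)
  expect_equal(back$refit, out$refit)
  expect_equal(back$param_name, out$param_name)
})
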