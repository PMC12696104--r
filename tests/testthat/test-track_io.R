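write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("the four dialects parse, with counts, units and missing masks", {
  gen <- write_lines_tmp(c("time,x,y", paste(0:9, 1:10, 2:11, sep = ",")))
  raw <- read_track_files(gen, "generic")[[1]]
  expect_length(raw$t, 10)
  expect_equal(raw$x, 1:10)

  etho <- write_lines_tmp(c("Subject: fly1", "Arena: 3",
                            "time,x,y",
                            "0,0.0,0.0", "1,,", "2,-,-", "3,3.0,0.0"))
  raw <- read_track_files(etho, "ethovision-like")[[1]]
  expect_equal(raw$missing, c(FALSE, TRUE, TRUE, FALSE))

  am <- write_lines_tmp(c("Time,Centre position X,Centre position Y",
                          "0,1,1", "1,2,2", "2,3,3"))
  raw <- read_track_files(am, "anymaze-like")[[1]]
  expect_equal(raw$y, c(1, 2, 3))

  bt <- write_lines_tmp(c("# px_per_cm = 20", "0 20 40", "1 40 80", "2 60 120"))
  raw <- read_track_files(bt, "buritrack-like")[[1]]
  expect_equal(raw$units, "px")
  expect_equal(raw$px_per_cm, 20)
})

test_that("malformed files produce located errors", {
  bad <- write_lines_tmp(c("time,x,y", "0,1,1", "1,oops,2"))
  expect_error(read_track_files(bad, "generic"), ":3")
  dec <- write_lines_tmp(c("time,x,y", "0,1,1", "2,1,1", "1,1,1"))
  expect_error(read_track_files(dec, "generic"), "increasing")
  nocol <- write_lines_tmp(c("time,a,b", "0,1,1"))
  expect_error(read_track_files(nocol, "generic"), "x")
})

test_that("standardize is the identity on already-standard input", {
  n <- 20
  ang <- seq(0, 4 * pi, length.out = n)
  lines <- c("# center_x = 0", "# center_y = 0", "time,x,y",
             paste(0:(n - 1), format(3.9 * cos(ang), digits = 12),
                   format(3.9 * sin(ang), digits = 12), sep = ","))
  raw <- read_track_files(write_lines_tmp(lines), "generic")[[1]]
  cfg <- test_config(smooth_window = 1)
  tr <- standardize(raw, cfg)
  expect_equal(tr$x, 3.9 * cos(ang), tolerance = 1e-9)
  expect_equal(tr$y, 3.9 * sin(ang), tolerance = 1e-9)
  # determinism: same input, bit-identical output
  expect_identical(tr, standardize(raw, cfg))
})

test_that("pixel tracks are scaled by px_per_cm", {
  lines <- c("# px_per_cm = 20", "# center_x = 0", "# center_y = 0",
             paste(0:9, seq(20, 40, length.out = 10), 40))
  raw <- read_track_files(write_lines_tmp(lines), "buritrack-like")[[1]]
  cfg <- test_config(smooth_window = 1)
  tr <- standardize(raw, cfg)
  expect_equal(tr$x, seq(1, 2, length.out = 10), tolerance = 1e-9)
  expect_equal(tr$y, rep(2, 10))
})

test_that("interior gaps interpolate linearly; long-missing tracks are rejected", {
  lines <- c("center_x: 0", "center_y: 0", "time,x,y",
             "0,0,0", "1,,", "2,,", "3,,", "4,4,0", "5,4,1")
  raw <- read_track_files(write_lines_tmp(lines), "ethovision-like")[[1]]
  tr <- standardize(raw, test_config(smooth_window = 1))
  expect_equal(tr$x, c(0, 1, 2, 3, 4, 4))
  expect_equal(tr$y, c(0, 0, 0, 0, 0, 1))
  mostly <- c("time,x,y", "0,1,1", paste0(1:9, ",,"), "10,1,1")
  raw2 <- read_track_files(write_lines_tmp(mostly), "ethovision-like")[[1]]
  expect_error(standardize(raw2, test_config(smooth_window = 1)), "missing")
})

test_that("subsampling keeps every k-th frame and k = 1 is the identity", {
  n <- 61
  ang <- seq(0, 2 * pi, length.out = n)
  x <- 3.5 * cos(ang); y <- 3.5 * sin(ang)
  lines <- c("# center_x = 0", "# center_y = 0", "time,x,y",
             paste(seq(0, by = 0.5, length.out = n),
                   format(x, digits = 12), format(y, digits = 12), sep = ","))
  raw <- read_track_files(write_lines_tmp(lines), "generic")[[1]]
  cfg <- test_config(smooth_window = 1, sample_freq = 2)
  cfg$time_bin_size <- 1            # k = 2
  tr <- standardize(raw, cfg)
  expect_equal(tr$x, x[seq(1, n, by = 2)], tolerance = 1e-9)
  cfg$time_bin_size <- 0.5          # k = 1
  tr1 <- standardize(raw, cfg)
  expect_equal(tr1$x, x, tolerance = 1e-9)
})

test_that("smoothing is shift-equivariant", {
  set.seed(4)
  n <- 60
  x <- cumsum(rnorm(n, 0, 0.3)); y <- cumsum(rnorm(n, 0, 0.3))
  mk <- function(x, y, cx, cy) {
    lines <- c(sprintf("# center_x = %.10f", cx), sprintf("# center_y = %.10f", cy),
               "time,x,y",
               paste(0:(n - 1), format(x, digits = 12), format(y, digits = 12),
                     sep = ","))
    read_track_files(write_lines_tmp(lines), "generic")[[1]]
  }
  cfg <- test_config(arena_radius_cm = 50, edge_dist_cm = 50, smooth_window = 5)
  a <- standardize(mk(x, y, 0, 0), cfg)
  b <- standardize(mk(x + 7, y - 3, 7, -3), cfg)
  expect_equal(a$x, b$x, tolerance = 1e-9)
  expect_equal(a$y, b$y, tolerance = 1e-9)
})

test_that("arena center inference matches known geometry", {
  ang <- seq(0, 2 * pi, length.out = 50)[-50]
  ctr <- infer_arena_center(5 + 2 * cos(ang), 5 + 2 * sin(ang))
  expect_equal(as.numeric(ctr), c(5, 5), tolerance = 1e-6)
  expect_equal(attr(ctr, "radius"), 2, tolerance = 1e-6)
  # three non-collinear points (padded with interior copies) -> circumcenter
  p <- rbind(c(0, 0), c(2, 0), c(1, 2))
  cc <- c(1, 0.75)  # circumcenter of that triangle, by the standard formula
  pts <- rbind(p, p, p, p)
  got <- infer_arena_center(pts[, 1], pts[, 2])
  expect_equal(as.numeric(got), cc, tolerance = 1e-6)
  # half-disc of radius r: center recovered within r/10
  set.seed(9)
  r <- 3
  th <- runif(4000, 0, pi); rr <- r * sqrt(runif(4000))
  got <- infer_arena_center(rr * cos(th), rr * sin(th))
  expect_lt(sqrt(sum(as.numeric(got)^2)), r / 10)
  # collinear points fall back with a warning
  expect_warning(infer_arena_center(1:20, 2 * (1:20) + 1), "collinear")
})
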