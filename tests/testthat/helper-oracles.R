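# Independent brute-force oracles and shared fixtures.  Each oracle is a
# deliberately naive re-computation (plain loops, its own geometry) kept
# separate from the package implementation it checks.

test_config <- function(...) {
  args <- utils::modifyList(
    list(groups_and_types = c(cohort = "generic"),
         arena_radius_cm = 4.2, sample_freq = 1, edge_dist_cm = 1,
         time_bin_size = 1, inactivity_threshold = 0.05,
         group_colors = c(cohort = "black")),
    list(...))
  do.call(of_config, args)
}

test_defaults <- function(...) {
  args <- utils::modifyList(list(node_size = 15, n_points = 30, n_bins = 20),
                            list(...))
  do.call(of_defaults, args)
}

# per-pair Euclidean distances, one at a time
oracle_activity <- function(x, y) {
  n <- length(x)
  out <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    out[i] <- sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  }
  out
}

# entry-event visit counting with one-sector-at-a-time shorter-arc walking
oracle_visits <- function(track, node_size, edge_dist_cm) {
  M <- round(360 / node_size)
  R <- track$arena_radius_cm
  v <- integer(M)
  last <- NA
  for (i in seq_len(track$n)) {
    r <- sqrt(track$x[i]^2 + track$y[i]^2)
    if (r < R - edge_dist_cm - 1e-12) next
    ang <- atan2(track$y[i], track$x[i]) * 180 / pi
    if (ang < 0) ang <- ang + 360
    s <- min(floor(ang / node_size) + 1, M)
    if (is.na(last)) {
      v[s] <- v[s] + 1L
    } else if (s != last) {
      fwd <- (s - last) %% M        # counterclockwise sector steps
      bwd <- (last - s) %% M
      dir <- if (fwd <= bwd) 1L else -1L
      cur <- last
      while (cur != s) {
        cur <- ((cur - 1L + dir) %% M) + 1L
        v[cur] <- v[cur] + 1L
      }
    }
    last <- s
  }
  v
}

# decision-by-decision classification via explicit triangle geometry
oracle_transitions <- function(track, threshold, edge_dist_cm) {
  n <- track$n
  R <- track$arena_radius_cm
  out <- matrix(NA_character_, nrow = n - 2, ncol = 1)
  for (i in 2:(n - 1)) {
    r <- sqrt(track$x[i]^2 + track$y[i]^2)
    if (r < R - edge_dist_cm - 1e-12) next
    d1 <- sqrt((track$x[i] - track$x[i - 1])^2 + (track$y[i] - track$y[i - 1])^2)
    d2 <- sqrt((track$x[i + 1] - track$x[i])^2 + (track$y[i + 1] - track$y[i])^2)
    if (d1 < threshold) d1 <- 0
    if (d2 < threshold) d2 <- 0
    if (d1 > 0 && d2 > 0) {
      d3 <- sqrt((track$x[i + 1] - track$x[i - 1])^2 +
                   (track$y[i + 1] - track$y[i - 1])^2)
      cosphi <- (d1^2 + d2^2 - d3^2) / (2 * d1 * d2)
      cosphi <- max(-1, min(1, cosphi))
      theta <- 180 - acos(cosphi) * 180 / pi
      out[i - 1, 1] <- if (theta <= 90) "p_pp" else "p_pm"
    } else if (d1 > 0) {
      out[i - 1, 1] <- "p_p0"
    } else if (d2 > 0) {
      out[i - 1, 1] <- "p_0p"
    } else {
      out[i - 1, 1] <- "p_00"
    }
  }
  out[, 1]
}

# pooled-and-binned means by explicit sorting and chunking
oracle_bin_npoints <- function(x, y, np) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  starts <- seq(1, length(x), by = np)
  t(vapply(starts, function(s) {
    idx <- s:min(s + np - 1, length(x))
    c(center = mean(x[idx]), mean = mean(y[idx]), n = length(idx))
  }, numeric(3)))
}

oracle_bin_nbins <- function(x, y, nb) {
  lo <- min(x); hi <- max(x)
  w <- (hi - lo) / nb
  bin <- pmin(floor((x - lo) / w) + 1, nb)
  ub <- sort(unique(bin))
  t(vapply(ub, function(b) {
    c(center = lo + (b - 0.5) * w, mean = mean(y[bin == b]), n = sum(bin == b))
  }, numeric(3)))
}

# a random jittery track confined to the arena, with deliberate pauses
random_track <- function(n = 200, R = 4.2, pause_prob = 0.2, step_sd = 0.6,
                         seed = 1) {
  set.seed(seed)
  x <- numeric(n); y <- numeric(n)
  ang <- runif(1, 0, 2 * pi)
  x[1] <- 0.8 * R * cos(ang); y[1] <- 0.8 * R * sin(ang)
  for (i in 2:n) {
    if (runif(1) < pause_prob) {
      x[i] <- x[i - 1]; y[i] <- y[i - 1]
      next
    }
    repeat {
      nx <- x[i - 1] + rnorm(1, 0, step_sd)
      ny <- y[i - 1] + rnorm(1, 0, step_sd)
      if (nx^2 + ny^2 <= R^2) break
    }
    x[i] <- nx; y[i] <- ny
  }
  of_track(t = 0:(n - 1), x = x, y = y, group = "rand", arena_radius_cm = R)
}
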