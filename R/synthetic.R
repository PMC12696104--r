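# Synthetic tracks with known ground truth: a stochastic habituating
# edge-dwelling explorer, and deterministic scripted boundary walks.

#' Parameters of the synthetic habituating explorer
#'
#' The explorer emulates an edge-dwelling animal whose expected step
#' length decays exponentially with time, `E[step](t) = a0 e^(b0 t) + c0`
#' (cm per sample), whose directional persistence (probability of
#' continuing rather than reversing) decays over exploration, and which
#' pauses (exact zero steps) with a probability that rises toward
#' `pause_prob_final`.  The walker is confined to the arena disc and
#' biased to remain within the edge band of width `edge_width_cm`.
#'
#' Defaults emulate a fly-sized subject in an 8.4 cm diameter arena
#' recorded for 10 minutes, analysed at 1 Hz.
#'
#' @param a0 Initial excess step length, cm (> 0).
#' @param b0 Habituation rate, 1/s (< 0).
#' @param c0 Steady-state step length, cm (>= 0).
#' @param persistence_half_life Seconds over which the same-direction
#'   probability (and the pause probability ramp) halves/saturates.
#' @param pause_prob_final Asymptotic per-step pause probability.
#' @param arena_radius_cm Arena radius, cm.
#' @param edge_affinity Probability that an attempted excursion out of
#'   the edge band is turned back; time in the band is at least this
#'   fraction in expectation.
#' @param edge_width_cm Width of the edge band the affinity refers to.
#' @param sample_freq Samples per second of the generated track.
#' @param duration_s Track duration, seconds.
#' @param jitter_sd SD (cm) of Gaussian body-wobble jitter added to every
#'   sample; 0 keeps pauses as exact zero steps.
#' @param seed Integer seed; the same seed reproduces the same track.
#' @return An object of class `of_explorer_params`.
#' @export
explorer_params <- function(a0 = 2, b0 = -0.008, c0 = 0.2,
                            persistence_half_life = 150,
                            pause_prob_final = 0.4,
                            arena_radius_cm = 4.2,
                            edge_affinity = 0.9,
                            edge_width_cm = 1,
                            sample_freq = 1,
                            duration_s = 600,
                            jitter_sd = 0,
                            seed = 1L) {
  stopifnot(a0 >= 0, b0 <= 0, c0 >= 0,
            pause_prob_final >= 0, pause_prob_final <= 1,
            edge_affinity >= 0, edge_affinity <= 1,
            arena_radius_cm > 0, sample_freq > 0, duration_s > 0)
  p <- list(a0 = a0, b0 = b0, c0 = c0,
            persistence_half_life = persistence_half_life,
            pause_prob_final = pause_prob_final,
            arena_radius_cm = arena_radius_cm,
            edge_affinity = edge_affinity,
            edge_width_cm = edge_width_cm,
            sample_freq = sample_freq,
            duration_s = duration_s,
            jitter_sd = jitter_sd,
            seed = as.integer(seed))
  class(p) <- "of_explorer_params"
  p
}

#' Simulate one habituating explorer
#'
#' Generates a standardized track directly (no file round-trip).  At each
#' step the walker pauses with probability
#' `pause_prob_final * (1 - 2^(-t/half_life))`; otherwise it keeps its
#' heading (plus a turn of at most 60 degrees) with probability
#' `0.5 + 0.5 * 2^(-t/half_life)` and reverses otherwise, and draws a
#' step length with unconditional mean `a0 e^(b0 t) + c0`.  The arena
#' wall reflects; crossings of the inner edge-band boundary are turned
#' back with probability `edge_affinity`.
#'
#' @param params An [explorer_params()].
#' @return An [of_track()].
#' @export
simulate_explorer <- function(params) {
  stopifnot(inherits(params, "of_explorer_params"))
  set.seed(params$seed)
  R <- params$arena_radius_cm
  band_in <- max(0, R - params$edge_width_cm)
  dt <- 1 / params$sample_freq
  n <- as.integer(round(params$duration_s * params$sample_freq)) + 1L
  t <- (seq_len(n) - 1) * dt
  x <- numeric(n); y <- numeric(n)
  phi0 <- stats::runif(1, 0, 2 * pi)
  r0 <- (R + band_in) / 2
  x[1] <- r0 * cos(phi0); y[1] <- r0 * sin(phi0)
  heading <- phi0 + pi / 2
  hl <- params$persistence_half_life
  for (i in seq_len(n - 1L)) {
    ti <- t[i]
    decay <- 2^(-ti / hl)
    q <- params$pause_prob_final * (1 - decay)
    if (stats::runif(1) < q) {
      x[i + 1] <- x[i]; y[i + 1] <- y[i]
      next
    }
    p_cont <- 0.5 + 0.5 * decay
    turn <- stats::runif(1, -pi / 3, pi / 3)
    if (stats::runif(1) >= p_cont) turn <- turn + pi
    heading <- heading + turn
    m <- params$a0 * exp(params$b0 * ti) + params$c0
    m_cond <- m / (1 - q)
    len <- if (m_cond > 0) stats::rgamma(1, shape = 4, rate = 4 / m_cond) else 0
    nx <- x[i] + len * cos(heading)
    ny <- y[i] + len * sin(heading)
    r <- sqrt(nx^2 + ny^2)
    # reflect off the arena wall
    if (r > R) {
      fold <- max(2 * R - r, 0)
      if (fold > R) fold <- R
      nx <- nx * fold / r; ny <- ny * fold / r
      r <- fold
    }
    # edge affinity: a step ending below the band is folded back into it
    # with probability edge_affinity, so band occupancy is at least that
    # fraction in expectation
    if (r < band_in && stats::runif(1) < params$edge_affinity) {
      fold <- clamp(2 * band_in - r, band_in, R)
      if (r > 0) { nx <- nx * fold / r; ny <- ny * fold / r } else {
        nx <- fold * cos(heading); ny <- fold * sin(heading)
      }
    }
    if (nx != x[i] || ny != y[i]) heading <- atan2(ny - y[i], nx - x[i])
    x[i + 1] <- nx; y[i + 1] <- ny
  }
  if (params$jitter_sd > 0) {
    x <- x + stats::rnorm(n, 0, params$jitter_sd)
    y <- y + stats::rnorm(n, 0, params$jitter_sd)
    r <- sqrt(x^2 + y^2)
    over <- r > R
    if (any(over)) {
      x[over] <- x[over] * R / r[over]
      y[over] <- y[over] * R / r[over]
    }
  }
  of_track(t, x, y, group = "synthetic", arena_radius_cm = R,
           dialect = "generic")
}

#' Deterministic scripted boundary walk
#'
#' Builds a track that walks the arena boundary through an exact sector
#' sequence: first detection in `start_sector`, then `lap_count` full
#' circuits (one visit to every sector per lap), then an optional
#' `extra_path` of contiguous sectors.  Used as a ground-truth oracle for
#' visit counting and coverage.
#'
#' @param M Number of sectors.
#' @param start_sector First-detection sector (1..M).
#' @param lap_count Number of complete counterclockwise laps.
#' @param extra_path Ordered vector of sectors walked after the laps;
#'   each must be adjacent (mod M) to its predecessor.
#' @param arena_radius_cm Arena radius.
#' @param radius_frac Radius of the walk as a fraction of the arena
#'   radius (keep inside the edge band).
#' @param step_period Seconds per sector step.
#' @return An [of_track()] visiting exactly the scripted sectors.
#' @export
scripted_track <- function(M, start_sector, lap_count, extra_path = integer(0),
                           arena_radius_cm = 4.2, radius_frac = 0.95,
                           step_period = 1) {
  stopifnot(M >= 2, start_sector >= 1, start_sector <= M, lap_count >= 0)
  # one lap covers start+1 ... start+M-1; the start sector is re-entered
  # only between laps, so a single lap visits every sector exactly once
  # (first detection already credited the start sector)
  seq_sectors <- start_sector
  lap_body <- ((start_sector + seq_len(M - 1L) - 1L) %% M) + 1L
  for (k in seq_len(lap_count)) {
    if (k > 1) seq_sectors <- c(seq_sectors, start_sector)
    seq_sectors <- c(seq_sectors, lap_body)
  }
  if (length(extra_path)) {
    stopifnot(all(extra_path >= 1), all(extra_path <= M))
    prev <- utils::tail(seq_sectors, 1)
    for (s in extra_path) {
      gap <- min((s - prev) %% M, (prev - s) %% M)
      if (gap > 1) stop2("extra_path must be contiguous in sector adjacency")
      prev <- s
    }
    seq_sectors <- c(seq_sectors, extra_path)
  }
  node <- 360 / M
  ang <- (seq_sectors - 0.5) * node * pi / 180
  r <- arena_radius_cm * radius_frac
  k <- length(seq_sectors)
  if (k < 3) {  # pad by lingering in the final sector (lingering adds no visit)
    ang <- c(ang, rep(ang[length(ang)], 3 - k))
    k <- 3
  }
  of_track(t = (seq_len(k) - 1) * step_period,
           x = r * cos(ang), y = r * sin(ang),
           group = "scripted", arena_radius_cm = arena_radius_cm,
           dialect = "generic")
}

#' Simulate a cohort of explorers
#'
#' Draws `n` explorers whose activity parameters vary around `params`
#' with a log-normal between-individual coefficient of variation, and
#' returns both the tracks and the generating ground truth for recovery
#' tests.  Track `i` uses seed `seed + i`, so cohorts are reproducible.
#'
#' @param n Number of individuals (>= 2).
#' @param params Population-level [explorer_params()].
#' @param between_individual_sd Coefficient of variation of the
#'   individual multipliers on `a0`, `b0` and `c0` (0 = identical
#'   individuals).
#' @param seed Integer cohort seed.
#' @param group Group label assigned to the tracks.
#' @return List with `tracks` (list of [of_track()]) and `truth`
#'   (data.frame of per-individual generating parameters).
#' @export
make_cohort <- function(n, params = explorer_params(),
                        between_individual_sd = 0.1, seed = 1L,
                        group = "cohort") {
  stopifnot(n >= 2)
  set.seed(seed)
  mult <- function() exp(stats::rnorm(n, 0, between_individual_sd) -
                           between_individual_sd^2 / 2)
  a <- params$a0 * mult(); b <- params$b0 * mult(); c0 <- params$c0 * mult()
  truth <- data.frame(id = seq_len(n), a0 = a, b0 = b, c0 = c0)
  tracks <- vector("list", n)
  for (i in seq_len(n)) {
    pi_i <- params
    pi_i$a0 <- a[i]; pi_i$b0 <- b[i]; pi_i$c0 <- c0[i]
    pi_i$seed <- as.integer(seed + i)
    tracks[[i]] <- simulate_explorer(pi_i)
    tracks[[i]]$group <- group
    tracks[[i]]$arena <- i
  }
  list(tracks = tracks, truth = truth)
}

#' Write a cohort to generic-dialect track files
#'
#' Writes one `<group>__<index>.csv` per track in the `generic` dialect,
#' so the full pipeline can be exercised end-to-end from files.
#' Optional dropout blanks random interior samples to exercise the
#' interpolation path.
#'
#' @param tracks List of [of_track()].
#' @param dir Output directory (created if needed).
#' @param dropout_prob Per-sample probability of writing a blank
#'   coordinate (interior samples only).
#' @param seed Seed for the dropout draw.
#' @return Character vector of file paths.
#' @export
write_cohort <- function(tracks, dir, dropout_prob = 0, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  paths <- character(length(tracks))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    x <- formatC(tr$x, format = "g", digits = 10)
    y <- formatC(tr$y, format = "g", digits = 10)
    if (dropout_prob > 0 && tr$n > 2) {
      drop <- which(stats::runif(tr$n) < dropout_prob)
      drop <- setdiff(drop, c(1L, tr$n))
      x[drop] <- ""; y[drop] <- ""
    }
    path <- file.path(dir, sprintf("%s__%03d.csv", tr$group, i))
    lines <- c(sprintf("# group = %s", tr$group),
               sprintf("# arena = %s", i),
               "# center_x = 0", "# center_y = 0",
               "time,x,y",
               paste(formatC(tr$t, format = "g", digits = 10), x, y, sep = ","))
    writeLines(lines, path)
    paths[i] <- path
  }
  paths
}
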