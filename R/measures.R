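# Behavioral measures: activity, polar coordinates, sector visits,
# coverage and its rescalings, turn classification, motion probabilities.

#' Step-length (activity) series
#'
#' Activity at time i is the Euclidean step that begins at sample i:
#' `sqrt((x[i+1]-x[i])^2 + (y[i+1]-y[i])^2)`.  A thresholded copy sets
#' steps shorter than `inactivity_threshold` to exactly zero, which is
#' what "no displacement" means everywhere downstream.
#'
#' @param track An [of_track()].
#' @param inactivity_threshold Step length (cm) below which a step counts
#'   as zero.
#' @return List of class `of_activity` with `raw` and `dd` (thresholded),
#'   both of length `n - 1`.
#' @export
activity <- function(track, inactivity_threshold = 0) {
  dx <- diff(track$x); dy <- diff(track$y)
  raw <- sqrt(dx^2 + dy^2)
  dd <- raw
  dd[dd < inactivity_threshold] <- 0
  structure(list(raw = raw, dd = dd,
                 inactivity_threshold = inactivity_threshold),
            class = "of_activity")
}

#' Cartesian to polar coordinates
#'
#' @param x,y Arena-centered coordinates (cm).
#' @return List with `r` (cm) and `theta` (degrees counterclockwise from
#'   the +x axis, in `[0, 360)`); the origin maps to `r = 0`,
#'   `theta = 0`.
#' @export
cartesian_to_polar <- function(x, y) {
  r <- sqrt(x^2 + y^2)
  theta <- atan2(y, x) * 180 / pi
  theta <- theta %% 360
  theta[r == 0] <- 0
  list(r = r, theta = theta)
}

sector_of <- function(theta, node_size) {
  M <- as.integer(round(360 / node_size))
  s <- floor(theta / node_size) + 1L
  s[s > M] <- M
  as.integer(s)
}

#' Locate boundary-sector visits over time
#'
#' A visit is an entry event: a sample within the edge band (r at least
#' `arena_radius - edge_dist_cm`) credits its sector when it is the first
#' edge sample of the track or when the previous edge sample fell in a
#' different sector.  Lingering in one sector counts once.  When
#' successive edge samples land in non-adjacent sectors, every
#' intermediate sector on the shorter angular arc is also credited one
#' visit (the animal necessarily passed through them); exact half-circle
#' jumps are imputed counterclockwise.  Leaving the band radially and
#' returning to the same sector does not start a new visit unless a
#' different sector was entered in between.
#'
#' @param track An [of_track()].
#' @param node_size Sector central angle, degrees (must divide 360).
#' @param edge_dist_cm Edge-band width, cm.
#' @param coverage_sample_period Seconds between columns of the visit
#'   matrix.
#' @return List of class `of_visits`: `M`, `v` (final per-sector counts),
#'   `vmat` (M x length(times) cumulative counts), `times`, `edge_mask`
#'   (per sample), `sector` (per sample, NA outside the band).
#' @export
locate_sector_visits <- function(track, node_size, edge_dist_cm,
                                 coverage_sample_period = 1) {
  M <- as.integer(round(360 / node_size))
  if (abs(M * node_size - 360) > 1e-6) stop2("node_size must divide 360 evenly")
  pol <- cartesian_to_polar(track$x, track$y)
  edge <- pol$r >= track$arena_radius_cm - edge_dist_cm - 1e-12
  sector <- sector_of(pol$theta, node_size)
  sector_na <- ifelse(edge, sector, NA_integer_)
  ev_sector <- integer(0)
  ev_time <- numeric(0)
  last <- NA_integer_
  for (i in seq_len(track$n)) {
    if (!edge[i]) next
    s <- sector[i]
    if (is.na(last)) {
      ev_sector <- c(ev_sector, s); ev_time <- c(ev_time, track$t[i])
    } else if (s != last) {
      d_ccw <- (s - last) %% M
      d_cw <- (last - s) %% M
      if (d_ccw <= d_cw) {
        path <- ((last + seq_len(d_ccw) - 1L) %% M) + 1L
      } else {
        path <- ((last - seq_len(d_cw) - 1L) %% M) + 1L
      }
      ev_sector <- c(ev_sector, path)
      ev_time <- c(ev_time, rep(track$t[i], length(path)))
    }
    last <- s
  }
  times <- seq(track$t[1], track$t[track$n], by = coverage_sample_period)
  vmat <- matrix(0L, nrow = M, ncol = length(times))
  if (length(ev_sector)) {
    ord <- order(ev_time)
    ev_sector <- ev_sector[ord]; ev_time <- ev_time[ord]
    # cumulative counts per sector at each coverage sample time
    upto <- findInterval(times, ev_time)
    prev <- 0L
    counts <- integer(M)
    for (k in seq_along(times)) {
      if (upto[k] > prev) {
        idx <- (prev + 1L):upto[k]
        tb <- tabulate(ev_sector[idx], nbins = M)
        counts <- counts + tb
        prev <- upto[k]
      }
      vmat[, k] <- counts
    }
  }
  structure(list(M = M, v = vmat[, ncol(vmat)], vmat = vmat, times = times,
                 edge_mask = edge, sector = sector_na),
            class = "of_visits")
}

#' Coverage from per-sector visit counts
#'
#' Coverage is the minimum number of visits every sector has received
#' plus the fraction of sectors that have received more than that:
#' `C = v_min + (1/M) * #(sectors with v > v_min)`.
#'
#' @param v Integer vector of per-sector visit counts (length `M`).
#' @param M Number of sectors (default `length(v)`).
#' @return Coverage value (visits).
#' @export
coverage <- function(v, M = length(v)) {
  vmin <- min(v)
  vmin + sum(v > vmin) / M
}

#' Coverage series from a visit matrix
#'
#' Applies [coverage()] to every column of the cumulative visit matrix.
#'
#' @param visits An `of_visits` object (or a visit matrix).
#' @return Numeric series of coverage values, one per coverage sample
#'   time.
#' @export
coverage_series <- function(visits) {
  vmat <- if (inherits(visits, "of_visits")) visits$vmat else visits
  apply(vmat, 2, coverage)
}

#' Percent coverage
#'
#' Coverage divided by the maximum coverage achieved during the
#' recording; final value is exactly 1 when any coverage was achieved.
#'
#' @param C Coverage series.
#' @return Series in `[0, 1]`; an all-zero series is returned unchanged
#'   with a warning.
#' @export
percent_coverage <- function(C) {
  m <- max(C)
  if (m == 0) {
    warn2("coverage is identically zero; percent coverage undefined, returning zeros")
    return(C)
  }
  C / m
}

#' Individual coverage asymptote
#'
#' Fits the coverage-versus-time series with the configured asymptotic
#' form (default `y = a(e^(bt) - 1)`, a < 0, b < 0) by bounded least
#' squares and extracts the asymptote, `asymptote_sign *
#' params[asymptote_param]` (for the default form, `-a`).
#'
#' @param t Coverage sample times (s).
#' @param C Coverage series.
#' @param spec A [coverage_asymptote_spec()].
#' @return The asymptote (visits), or `NA` with a warning when the fit
#'   does not converge.
#' @export
individual_coverage_asymptote <- function(t, C, spec = coverage_asymptote_spec()) {
  if (length(C) < 4) {
    warn2("need at least 4 coverage samples to fit an asymptote")
    return(NA_real_)
  }
  form <- get_model_form(spec$f_name)
  fit <- fit_curve(t, C, form,
                   init = spec$initial_parameters,
                   lower = spec$parameter_bounds$lower,
                   upper = spec$parameter_bounds$upper,
                   max_f_eval = spec$max_f_eval)
  if (!fit$converged) {
    warn2("coverage asymptote fit did not converge; individual excluded from PICA")
    return(NA_real_)
  }
  spec$asymptote_sign * fit$par[spec$asymptote_param]
}

#' Rescale coverage by an asymptote
#'
#' PICA divides by the individual's fitted coverage asymptote, PGCA by
#' the group mean of the individual asymptotes; either may exceed 1 when
#' the fit underestimates the asymptote.
#'
#' @param C Coverage series.
#' @param A Asymptote (> 0); `NA` yields an all-`NA` series.
#' @return Rescaled series.
#' @export
pica <- function(C, A) {
  if (!is.finite(A) || A <= 0) return(rep(NA_real_, length(C)))
  C / A
}

#' @rdname pica
#' @export
pgca <- pica

#' Turning angle between two consecutive steps
#'
#' Uses the law of cosines on the triangle P1-P2-P3: with step lengths
#' `s1 = |P1P2|`, `s2 = |P2P3|` and chord `d = |P1P3|`, the interior
#' angle at P2 is `phi = acos((s1^2 + s2^2 - d^2) / (2 s1 s2))` (argument
#' clamped to `[-1, 1]`), and the turning angle is `theta = 180 - phi`
#' degrees: 0 for continuing straight, 180 for a full reversal.  A turn
#' is "positive" (same direction) when `|theta| <= 90`.  Undefined when
#' either step has zero length.
#'
#' @param p1,p2,p3 Numeric length-2 points.
#' @return Turning angle in degrees in `[0, 180]`, or `NA` if undefined.
#' @export
turning_angle <- function(p1, p2, p3) {
  s1 <- sqrt(sum((p2 - p1)^2))
  s2 <- sqrt(sum((p3 - p2)^2))
  if (s1 == 0 || s2 == 0) return(NA_real_)
  d <- sqrt(sum((p3 - p1)^2))
  arg <- clamp((s1^2 + s2^2 - d^2) / (2 * s1 * s2), -1, 1)
  180 - acos(arg) * 180 / pi
}

turning_angles <- function(track) {
  n <- track$n
  if (n < 3) return(numeric(0))
  x <- track$x; y <- track$y
  s1 <- sqrt(diff(x)^2 + diff(y)^2)[1:(n - 2)]
  s2 <- sqrt(diff(x)^2 + diff(y)^2)[2:(n - 1)]
  d <- sqrt((x[3:n] - x[1:(n - 2)])^2 + (y[3:n] - y[1:(n - 2)])^2)
  arg <- clamp((s1^2 + s2^2 - d^2) / (2 * s1 * s2), -1, 1)
  theta <- 180 - acos(arg) * 180 / pi
  theta[s1 == 0 | s2 == 0] <- NA_real_
  theta
}

#' Classify step-to-step decisions
#'
#' For n samples there are n-1 steps and n-2 decisions; the decision at
#' sample i sits between step i-1 and step i.  With thresholded step
#' lengths: both steps nonzero gives P_++ (turn angle at most 90
#' degrees) or P_+- (greater); previous nonzero and current zero gives
#' P_+0; previous zero gives P_0+ (moving) or P_00 (still) -- those
#' three are determined by step length alone.  Decisions at samples
#' outside the edge band are recorded as missing.
#'
#' @param track An [of_track()].
#' @param act An [activity()] result (thresholded).
#' @param edge_mask Logical per-sample edge indicator (from
#'   [locate_sector_visits()]); `NULL` means all samples count.
#' @return Object of class `of_transitions`: `ind` is an (n-2) x 5
#'   matrix of 0/1/NA indicators with columns `p_pp, p_pm, p_p0, p_0p,
#'   p_00`; plus `theta`, `times` and `edge`.
#' @export
classify_transitions <- function(track, act, edge_mask = NULL) {
  n <- track$n
  stopifnot(n >= 3)
  dd <- act$dd
  theta <- turning_angles(track)
  prev <- dd[1:(n - 2)]
  cur <- dd[2:(n - 1)]
  outcomes <- c("p_pp", "p_pm", "p_p0", "p_0p", "p_00")
  ind <- matrix(0L, nrow = n - 2, ncol = 5, dimnames = list(NULL, outcomes))
  ind[prev > 0 & cur > 0 & theta <= 90, "p_pp"] <- 1L
  ind[prev > 0 & cur > 0 & theta > 90, "p_pm"] <- 1L
  ind[prev > 0 & cur == 0, "p_p0"] <- 1L
  ind[prev == 0 & cur > 0, "p_0p"] <- 1L
  ind[prev == 0 & cur == 0, "p_00"] <- 1L
  edge <- if (is.null(edge_mask)) rep(TRUE, n - 2) else edge_mask[2:(n - 1)]
  ind[!edge, ] <- NA_integer_
  structure(list(ind = ind, theta = theta, times = track$t[2:(n - 1)],
                 edge = edge),
            class = "of_transitions")
}

#' Group motion probabilities
#'
#' Aggregates individual decision indicators into per-timepoint
#' probabilities.  Variants: `given_previous` conditions each outcome on
#' its precondition (denominator = individuals whose previous step
#' matched: moving for P_++/P_+-/P_+0, resting for P_0+/P_00), so
#' `P_++ + P_+- + P_+0 = 1` and `P_0+ + P_00 = 1` wherever defined;
#' `given_any` divides by individuals with any classified decision, so
#' all five sum to 1; `raw` divides by group size.
#'
#' @param trans_list List of `of_transitions`, one per individual.
#' @param variant `"given_previous"`, `"given_any"` or `"raw"`.
#' @return Object of class `of_mprob`: `prob` (T x 5 matrix), `num` and
#'   `denom` (counts), `times`, `variant`, `n_individuals`.
#' @export
motion_probabilities <- function(trans_list,
                                 variant = c("given_previous", "given_any", "raw")) {
  variant <- match.arg(variant)
  if (!length(trans_list)) stop2("empty group: no transition arrays")
  n_ind <- length(trans_list)
  Tmax <- max(vapply(trans_list, function(tr) nrow(tr$ind), 1L))
  outcomes <- c("p_pp", "p_pm", "p_p0", "p_0p", "p_00")
  num <- matrix(0L, nrow = Tmax, ncol = 5, dimnames = list(NULL, outcomes))
  any_cnt <- integer(Tmax)
  move_cnt <- integer(Tmax)
  rest_cnt <- integer(Tmax)
  for (tr in trans_list) {
    m <- nrow(tr$ind)
    ind <- tr$ind
    def <- !is.na(ind[, 1])
    num[1:m, ] <- num[1:m, ] + ifelse(is.na(ind), 0L, ind)
    any_cnt[1:m] <- any_cnt[1:m] + def
    move_cnt[1:m] <- move_cnt[1:m] +
      (def & (ind[, "p_pp"] | ind[, "p_pm"] | ind[, "p_p0"]))
    rest_cnt[1:m] <- rest_cnt[1:m] + (def & (ind[, "p_0p"] | ind[, "p_00"]))
  }
  denom <- switch(variant,
                  given_previous = cbind(p_pp = move_cnt, p_pm = move_cnt,
                                         p_p0 = move_cnt, p_0p = rest_cnt,
                                         p_00 = rest_cnt),
                  given_any = matrix(any_cnt, nrow = Tmax, ncol = 5,
                                     dimnames = list(NULL, outcomes)),
                  raw = matrix(n_ind, nrow = Tmax, ncol = 5,
                               dimnames = list(NULL, outcomes)))
  prob <- num / denom
  prob[denom == 0] <- NA_real_
  times <- trans_list[[which.max(vapply(trans_list, function(tr) nrow(tr$ind), 1L))]]$times
  structure(list(prob = prob, num = num, denom = denom, times = times,
                 variant = variant, n_individuals = n_ind),
            class = "of_mprob")
}

# carry a coverage-time series onto the track's sample grid (step function)
carry_forward <- function(cov_times, values, t) {
  idx <- findInterval(t, cov_times)
  idx[idx < 1] <- 1
  values[idx]
}

#' Compute all measures for one track
#'
#' Runs activity, sector visits, coverage and its rescalings (PGCA is
#' filled in later by [tracks_to_measures()] once the group asymptote is
#' known), and decision classification for a single standardized track.
#'
#' @param track An [of_track()].
#' @param config An [of_config()].
#' @param defaults An [of_defaults()].
#' @param asymptote_spec A [coverage_asymptote_spec()].
#' @return Object of class `of_measures`.
#' @export
track_measures <- function(track, config, defaults = of_defaults(),
                           asymptote_spec = coverage_asymptote_spec()) {
  act <- activity(track, config$inactivity_threshold)
  vis <- locate_sector_visits(track, defaults$node_size, config$edge_dist_cm,
                              defaults$coverage_sample_period)
  C <- coverage_series(vis)
  pc <- suppressWarnings(percent_coverage(C))
  A_ind <- individual_coverage_asymptote(vis$times, C, asymptote_spec)
  trans <- classify_transitions(track, act, vis$edge_mask)
  structure(list(track = track, group = track$group, activity = act,
                 visits = vis, coverage = C, cov_times = vis$times,
                 percent_coverage = pc, A_ind = A_ind,
                 pica = pica(C, A_ind), pgca = NULL, A_grp = NA_real_,
                 transitions = trans),
            class = "of_measures")
}

#' Compute measures for all tracks and group-level series
#'
#' Per-track measures first; then, once every track is standardized, the
#' group coverage asymptote (mean of the individuals' asymptotes) and
#' each track's PGCA; finally the group motion-probability series in the
#' requested variants.
#'
#' @param tracks List of [of_track()].
#' @param config An [of_config()].
#' @param defaults An [of_defaults()].
#' @param asymptote_spec A [coverage_asymptote_spec()].
#' @param variants Motion-probability variants to compute.
#' @return Object of class `of_measure_set`: `individuals` (list of
#'   `of_measures`), `groups` (per group: `A_grp`, `mprob` per variant,
#'   member indices).
#' @export
tracks_to_measures <- function(tracks, config, defaults = of_defaults(),
                               asymptote_spec = coverage_asymptote_spec(),
                               variants = c("given_previous", "given_any", "raw")) {
  ind <- lapply(tracks, track_measures, config = config, defaults = defaults,
                asymptote_spec = asymptote_spec)
  groups <- unique(vapply(ind, function(m) m$group, ""))
  ginfo <- list()
  for (g in groups) {
    members <- which(vapply(ind, function(m) m$group, "") == g)
    As <- vapply(ind[members], function(m) m$A_ind, 1)
    A_grp <- mean(As[is.finite(As)])
    for (i in members) {
      ind[[i]]$A_grp <- A_grp
      ind[[i]]$pgca <- pgca(ind[[i]]$coverage, A_grp)
    }
    mp <- lapply(stats::setNames(variants, variants), function(v) {
      motion_probabilities(lapply(ind[members], function(m) m$transitions), v)
    })
    ginfo[[g]] <- list(A_grp = A_grp, members = members, mprob = mp)
  }
  structure(list(individuals = ind, groups = ginfo,
                 config = config, defaults = defaults),
            class = "of_measure_set")
}

#' Per-sample measures table for one individual
#'
#' Long table with one row per track sample carrying every measure at
#' that time: activity (the step beginning there), the coverage-family
#' values carried forward from the coverage grid, and the five decision
#' indicators (NA outside the edge band or at the track ends).  This is
#' also the per-individual CSV export and the input to summarizing and
#' model fitting.
#'
#' @param m An `of_measures` object.
#' @param id Individual identifier stored in the `id` column.
#' @return A data.frame.
#' @export
measures_df <- function(m, id = NA) {
  tr <- m$track
  n <- tr$n
  t <- tr$t
  dd <- c(m$activity$dd, NA_real_)          # step beginning at sample i
  C <- carry_forward(m$cov_times, m$coverage, t)
  pcv <- carry_forward(m$cov_times, m$percent_coverage, t)
  pic <- carry_forward(m$cov_times, m$pica, t)
  pgc <- if (is.null(m$pgca)) rep(NA_real_, n) else carry_forward(m$cov_times, m$pgca, t)
  ind <- matrix(NA_integer_, nrow = n, ncol = 5,
                dimnames = list(NULL, colnames(m$transitions$ind)))
  ind[2:(n - 1), ] <- m$transitions$ind
  data.frame(id = id, group = m$group, time = t, activity = dd,
             coverage = C, percent_coverage = pcv, pica = pic, pgca = pgc,
             ind, check.names = FALSE)
}

#' Export per-group individual measures to CSV
#'
#' One file per group, rows = individual x time.
#'
#' @param mset An `of_measure_set`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
export_individual_measures <- function(mset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (g in names(mset$groups)) {
    members <- mset$groups[[g]]$members
    dfs <- lapply(members, function(i) measures_df(mset$individuals[[i]], id = i))
    df <- do.call(rbind, dfs)
    path <- file.path(dir, sprintf("%s__individual_measures.csv", g))
    utils::write.csv(df, path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
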