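# Group-level summaries: temporal means, and coverage-domain binning of
# pooled (x, y) tuples.

new_summary <- function(df, group, x_var, y_var, method) {
  attr(df, "group") <- group
  attr(df, "x_var") <- x_var
  attr(df, "y_var") <- y_var
  attr(df, "method") <- method
  class(df) <- c("of_summary", "data.frame")
  df
}

#' Temporal group summary
#'
#' Mean and SEM of a measure across individuals at each common time
#' point; all tracks share the sampling grid so the time column aligns
#' row-wise.  Time points with no data are omitted; SEM is missing when
#' only one individual contributes.
#'
#' @param dfs List of per-individual [measures_df()] tables (one group).
#' @param y_var Column to summarize.
#' @param group Group label recorded on the result.
#' @return A data.frame of class `of_summary` with columns
#'   `x, mean, sem, n`.
#' @export
summarize_temporal <- function(dfs, y_var, group = dfs[[1]]$group[1]) {
  times <- sort(unique(unlist(lapply(dfs, function(d) d$time))))
  vals <- vapply(dfs, function(d) {
    out <- rep(NA_real_, length(times))
    i <- match(round(d$time, 9), round(times, 9))
    out[i] <- d[[y_var]]
    out
  }, numeric(length(times)))
  vals <- matrix(vals, nrow = length(times))
  n <- rowSums(is.finite(vals))
  mean_y <- ifelse(n > 0, rowMeans(vals, na.rm = TRUE), NA_real_)
  sem_y <- apply(vals, 1, sem)
  keep <- n > 0
  new_summary(data.frame(x = times[keep], mean = mean_y[keep],
                         sem = sem_y[keep], n = n[keep]),
              group, "time", y_var, "temporal")
}

#' Coverage-domain group summary by tuple pooling
#'
#' Pools (x, y) tuples from every individual in the group, sorts by x
#' (ties broken by individual then time for determinism), and bins them
#' either into consecutive groups of `n_points` tuples (equal-count; bin
#' center = mean x in the bin; the last bin may be smaller) or into
#' `n_bins` equal-width bins spanning the observed x range (bin center =
#' bin midpoint; empty bins omitted).  Equal-count binning is the
#' default for coverage, PICA and PGCA; equal-width for percent
#' coverage.
#'
#' @param dfs List of per-individual [measures_df()] tables (one group).
#' @param x_var One of `coverage`, `percent_coverage`, `pica`, `pgca`.
#' @param y_var Measure column to average.
#' @param method `"n_points"` or `"n_bins"`; `NULL` picks the default
#'   for `x_var`.
#' @param n_points Tuples per equal-count bin.
#' @param n_bins Number of equal-width bins.
#' @param group Group label recorded on the result.
#' @return A data.frame of class `of_summary` with columns
#'   `x, mean, sem, n`.
#' @export
summarize_by_coverage <- function(dfs, x_var, y_var, method = NULL,
                                  n_points = 50, n_bins = 50,
                                  group = dfs[[1]]$group[1]) {
  if (is.null(method)) {
    method <- if (x_var == "percent_coverage") "n_bins" else "n_points"
  }
  method <- match.arg(method, c("n_points", "n_bins"))
  xs <- ys <- ids <- tms <- numeric(0)
  for (i in seq_along(dfs)) {
    d <- dfs[[i]]
    ok <- is.finite(d[[x_var]]) & is.finite(d[[y_var]])
    xs <- c(xs, d[[x_var]][ok]); ys <- c(ys, d[[y_var]][ok])
    ids <- c(ids, rep(i, sum(ok))); tms <- c(tms, d$time[ok])
  }
  if (!length(xs)) {
    return(new_summary(data.frame(x = numeric(0), mean = numeric(0),
                                  sem = numeric(0), n = integer(0)),
                       group, x_var, y_var, method))
  }
  ord <- order(xs, ids, tms)
  xs <- xs[ord]; ys <- ys[ord]
  if (method == "n_points") {
    if (length(xs) < n_points) {
      warn2("fewer tuples than one bin; returning a single bin")
      bin <- rep(1L, length(xs))
    } else {
      bin <- (seq_along(xs) - 1L) %/% as.integer(n_points) + 1L
    }
    centers <- tapply(xs, bin, mean)
  } else {
    rng <- range(xs)
    if (diff(rng) == 0) {
      bin <- rep(1L, length(xs))
      centers <- rng[1]
    } else {
      edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
      bin <- findInterval(xs, edges, rightmost.closed = TRUE)
      centers <- (edges[-1] + edges[-length(edges)]) / 2
      centers <- centers[sort(unique(bin))]
    }
  }
  mean_y <- as.numeric(tapply(ys, bin, mean))
  sem_y <- as.numeric(tapply(ys, bin, sem))
  n <- as.integer(tapply(ys, bin, length))
  new_summary(data.frame(x = as.numeric(centers), mean = mean_y,
                         sem = sem_y, n = n),
              group, x_var, y_var, method)
}

# group motion-probability series as a summary table (the group-level
# y data for motion-probability relationships)
mprob_summary <- function(mset, group, y_var, x_var = "time",
                          variant = "given_previous") {
  mp <- mset$groups[[group]]$mprob[[variant]]
  p <- mp$prob[, y_var]
  keep <- is.finite(p)
  if (x_var == "time") {
    x <- mp$times[keep]
  } else {
    # average of the members' x series at each decision time
    members <- mset$groups[[group]]$members
    xmat <- vapply(members, function(i) {
      d <- measures_df(mset$individuals[[i]], id = i)
      out <- rep(NA_real_, length(mp$times))
      j <- match(round(mp$times, 9), round(d$time, 9))
      out[!is.na(j)] <- d[[x_var]][j[!is.na(j)]]
      out
    }, numeric(length(mp$times)))
    x <- rowMeans(matrix(xmat, nrow = length(mp$times)), na.rm = TRUE)[keep]
  }
  n <- mp$denom[keep, y_var]
  new_summary(data.frame(x = x, mean = p[keep], sem = NA_real_, n = n),
              group, x_var, y_var, paste0("mprob_", variant))
}

#' Summarize every configured relationship for every group
#'
#' @param mset An `of_measure_set` from [tracks_to_measures()].
#' @param defaults An [of_defaults()]; decides the relationship grid and
#'   binning sizes.
#' @return Named list of `of_summary`, keyed `"group|x~y"`.
#' @export
summarize_all <- function(mset, defaults = mset$defaults) {
  out <- list()
  prob_vars <- c("p_pp", "p_pm", "p_p0", "p_0p", "p_00")
  for (g in names(mset$groups)) {
    members <- mset$groups[[g]]$members
    dfs <- lapply(members, function(i) measures_df(mset$individuals[[i]], id = i))
    ys <- defaults$y_vars
    if (isTRUE(defaults$fit_coverage)) ys <- union(ys, "coverage")
    for (x in union("time", defaults$x_vars)) {
      for (y in ys) {
        if (y == "coverage" && x != "time") next
        if (!(y %in% c(defaults$y_vars, "coverage"))) next
        if (!(x %in% defaults$x_vars) && !(y == "coverage" && x == "time")) next
        key <- sprintf("%s|%s~%s", g, x, y)
        if (y %in% prob_vars) {
          out[[key]] <- mprob_summary(mset, g, y, x, defaults$prob_variant)
        } else if (x == "time") {
          out[[key]] <- summarize_temporal(dfs, y, group = g)
        } else {
          out[[key]] <- summarize_by_coverage(
            dfs, x, y, n_points = defaults$n_points,
            n_bins = defaults$n_bins, group = g)
        }
      }
    }
  }
  out
}

#' Export group summaries as CSV files
#'
#' One `group__x__y.csv` per summary with columns `x, mean, sem, n`.
#'
#' @param summaries Named list from [summarize_all()] (or individual
#'   `of_summary` objects).
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
export_summaries <- function(summaries, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in summaries) {
    path <- file.path(dir, sprintf("%s__%s__%s.csv", attr(s, "group"),
                                   attr(s, "x_var"), attr(s, "y_var")))
    utils::write.csv(as.data.frame(s), path, row.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
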