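# Reading tracker export files and standardizing them into arena-centered,
# cm/second, evenly sampled, gap-free tracks.

#' Supported tracker dialects
#'
#' * `generic`: delimited text with a header line and columns
#'   `time,x,y` (seconds / cm).  Optional leading `# key = value` comment
#'   lines may carry `arena`, `group`, `center_x`, `center_y`.
#' * `ethovision-like`: a block of `Key: Value` metadata lines followed by
#'   a `time,x,y` header and rows; missing samples encoded as empty fields
#'   or `-`.  Treated as already smoothed.
#' * `anymaze-like`: CSV with header
#'   `Time,Centre position X,Centre position Y` (seconds / cm).
#' * `buritrack-like`: whitespace-delimited `t x y` in pixels, with the
#'   pixel scale given in a `# px_per_cm = <value>` metadata line.
#'
#' @return Character vector of dialect names.
#' @export
track_dialects <- function() {
  c("generic", "ethovision-like", "anymaze-like", "buritrack-like")
}

new_raw_track <- function(path, dialect, group, arena, t, x, y,
                          units = "cm", px_per_cm = NA_real_, center = NULL) {
  n <- length(t)
  if (length(x) != n || length(y) != n) {
    stop2(sprintf("%s: t, x, y must have equal length", path))
  }
  ok <- !is.na(t)
  if (any(diff(t[ok]) <= 0)) {
    stop2(sprintf("%s: timestamps must be strictly increasing", path))
  }
  structure(list(path = path, dialect = dialect, group = group,
                 arena = arena, t = t, x = x, y = y,
                 units = units, px_per_cm = px_per_cm, center = center,
                 missing = is.na(x) | is.na(y)),
            class = "of_raw_track")
}

#' Construct a standardized track
#'
#' Container for one animal's trajectory after standardization: time in
#' seconds on a uniform grid, coordinates in cm centered on the arena.
#'
#' @param t,x,y Numeric vectors (uniform t, finite x/y).
#' @param group Group label.
#' @param arena_radius_cm Arena radius in cm.
#' @param arena Arena identifier.
#' @param dialect Source dialect.
#' @param radius_tolerance Allowed fractional overshoot of the arena
#'   radius (default 0.05).
#' @return An object of class `of_track`.
#' @export
of_track <- function(t, x, y, group = "group", arena_radius_cm,
                     arena = NA, dialect = "generic",
                     radius_tolerance = 0.05) {
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n, n >= 3)
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-9) stop2("t must be uniformly spaced")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop2("x and y must be finite")
  rmax <- sqrt(max(x^2 + y^2))
  if (rmax > arena_radius_cm * (1 + radius_tolerance)) {
    stop2(sprintf("track exceeds arena radius: max r = %.3f cm > %.3f cm",
                  rmax, arena_radius_cm * (1 + radius_tolerance)))
  }
  structure(list(group = group, arena = arena,
                 arena_radius_cm = arena_radius_cm,
                 t = t, x = x, y = y, dialect = dialect, n = n),
            class = "of_track")
}

#' @export
print.of_track <- function(x, ...) {
  cat(sprintf("Standardized track: group '%s', %d samples, %.1f s at %.3g s spacing, arena radius %.2f cm\n",
              x$group, x$n, x$t[x$n] - x$t[1],
              if (x$n > 1) x$t[2] - x$t[1] else NA, x$arena_radius_cm))
  invisible(x)
}

parse_meta_comments <- function(lines) {
  meta <- list()
  for (line in lines) {
    m <- regmatches(line, regexec("^#\\s*([A-Za-z0-9_]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) == 3) {
      v <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(v)) trimws(m[3]) else v
    }
  }
  meta
}

num_or_na <- function(v, path, lineno_offset = 0L) {
  v <- trimws(v)
  v[v %in% c("", "-", "NA", "NaN")] <- NA
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad)) {
    stop2(sprintf("%s:%d: cannot parse value '%s'",
                  path, bad[1] + lineno_offset, v[bad[1]]))
  }
  out
}

read_one_track <- function(path, dialect, group) {
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  if (dialect %in% c("generic", "buritrack-like")) {
    is_comment <- grepl("^#", lines)
    meta <- parse_meta_comments(lines[is_comment])
    body <- lines[!is_comment & nzchar(trimws(lines))]
    offset <- utils::head(which(!grepl("^#", lines) & nzchar(trimws(lines))), 1) - 1L
    if (dialect == "generic") {
      header <- tolower(gsub("\\s", "", body[1]))
      cols <- strsplit(header, ",")[[1]]
      need <- c("time", "x", "y")
      if (!all(need %in% cols)) {
        stop2(sprintf("%s: missing required column(s): %s", path,
                      paste(setdiff(need, cols), collapse = ", ")))
      }
      rows <- strsplit(body[-1], ",")
      mat <- do.call(rbind, lapply(rows, function(r) r[seq_along(cols)]))
      t <- num_or_na(mat[, match("time", cols)], path, offset + 1L)
      x <- num_or_na(mat[, match("x", cols)], path, offset + 1L)
      y <- num_or_na(mat[, match("y", cols)], path, offset + 1L)
      units <- "cm"; ppc <- NA_real_
    } else {
      rows <- strsplit(trimws(body), "\\s+")
      if (any(lengths(rows) < 3)) {
        stop2(sprintf("%s: expected whitespace-delimited 't x y' rows", path))
      }
      mat <- do.call(rbind, lapply(rows, `[`, 1:3))
      t <- num_or_na(mat[, 1], path, offset)
      x <- num_or_na(mat[, 2], path, offset)
      y <- num_or_na(mat[, 3], path, offset)
      ppc <- meta$px_per_cm
      if (is.null(ppc)) {
        stop2(sprintf("%s: buritrack-like file lacks a '# px_per_cm = <value>' line", path))
      }
      units <- "px"
    }
  } else if (dialect == "ethovision-like") {
    hdr_i <- which(grepl("^\\s*time\\s*,", lines, ignore.case = TRUE))[1]
    if (is.na(hdr_i)) {
      stop2(sprintf("%s: no 'time,x,y' header found after metadata block", path))
    }
    for (line in lines[seq_len(hdr_i - 1)]) {
      m <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
      if (length(m) == 3) {
        key <- tolower(gsub("\\s", "_", trimws(m[2])))
        v <- suppressWarnings(as.numeric(m[3]))
        meta[[key]] <- if (is.na(v)) trimws(m[3]) else v
      }
    }
    cols <- tolower(gsub("\\s", "", strsplit(lines[hdr_i], ",")[[1]]))
    body <- lines[-seq_len(hdr_i)]
    body <- body[nzchar(trimws(body)) | grepl(",", body)]
    rows <- strsplit(body, ",")
    mat <- do.call(rbind, lapply(rows, function(r) {
      length(r) <- length(cols); r
    }))
    t <- num_or_na(mat[, match("time", cols)], path, hdr_i)
    x <- num_or_na(mat[, match("x", cols)], path, hdr_i)
    y <- num_or_na(mat[, match("y", cols)], path, hdr_i)
    units <- "cm"; ppc <- NA_real_
  } else if (dialect == "anymaze-like") {
    header <- strsplit(lines[1], ",")[[1]]
    norm <- tolower(trimws(header))
    it <- match("time", norm)
    ix <- match("centre position x", norm)
    iy <- match("centre position y", norm)
    if (any(is.na(c(it, ix, iy)))) {
      stop2(sprintf("%s: expected columns Time, Centre position X, Centre position Y", path))
    }
    rows <- strsplit(lines[-1][nzchar(trimws(lines[-1]))], ",")
    mat <- do.call(rbind, lapply(rows, function(r) r[seq_along(header)]))
    t <- num_or_na(mat[, it], path, 1L)
    x <- num_or_na(mat[, ix], path, 1L)
    y <- num_or_na(mat[, iy], path, 1L)
    units <- "cm"; ppc <- NA_real_
  } else {
    stop2(sprintf("unknown tracker dialect '%s'", dialect))
  }
  grp <- group %||% meta$group %||% sub("__.*$", "", basename(path))
  arena <- meta$arena %||% NA
  center <- if (!is.null(meta$center_x) && !is.null(meta$center_y)) {
    c(meta$center_x, meta$center_y)
  } else NULL
  new_raw_track(path, dialect, grp, arena, t, x, y,
                units = units, px_per_cm = ppc %||% NA_real_, center = center)
}

#' Read tracker output files
#'
#' Parses one or more files of a given dialect into raw track objects.
#' Non-coordinate metadata (group, arena number, pixel scale, explicit
#' arena center) is taken from header/comment lines where the dialect
#' provides them, else from the filename prefix `<group>__...`.
#'
#' @param paths Character vector of file paths.
#' @param dialect One of [track_dialects()].
#' @param group Group label to assign; `NULL` = infer from metadata or
#'   filename.
#' @param config An [of_config()] (currently unused during parsing but
#'   kept for dialect-specific options).
#' @return List of raw track objects.
#' @export
read_track_files <- function(paths, dialect, group = NULL, config = NULL) {
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files)) {
    stop2("file(s) not found: ", paste(missing_files, collapse = ", "))
  }
  lapply(paths, read_one_track, dialect = dialect, group = group)
}

circumcenter <- function(p1, p2, p3) {
  d <- 2 * (p1[1] * (p2[2] - p3[2]) + p2[1] * (p3[2] - p1[2]) +
              p3[1] * (p1[2] - p2[2]))
  if (abs(d) < 1e-12) return(NULL)
  ux <- (sum(p1^2) * (p2[2] - p3[2]) + sum(p2^2) * (p3[2] - p1[2]) +
           sum(p3^2) * (p1[2] - p2[2])) / d
  uy <- (sum(p1^2) * (p3[1] - p2[1]) + sum(p2^2) * (p1[1] - p3[1]) +
           sum(p3^2) * (p2[1] - p1[1])) / d
  c(ux, uy)
}

# smallest circle enclosing a small support set (<= ~6 points): enumerate
# pairs (diameter circles) and triples (circumcircles)
mec_of_support <- function(pts) {
  m <- nrow(pts)
  best <- NULL
  consider <- function(center, r) {
    if (is.null(center)) return()
    if (all(sqrt(colSums((t(pts) - center)^2)) <= r + 1e-9)) {
      if (is.null(best) || r < best$r) best <<- list(center = center, r = r)
    }
  }
  if (m == 1) return(list(center = pts[1, ], r = 0))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    c0 <- (pts[i, ] + pts[j, ]) / 2
    consider(c0, sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2)
  }
  if (is.null(best) && m >= 3) {
    for (i in seq_len(m - 2)) for (j in (i + 1):(m - 1)) for (k in (j + 1):m) {
      cc <- circumcenter(pts[i, ], pts[j, ], pts[k, ])
      if (!is.null(cc)) consider(cc, sqrt(sum((pts[i, ] - cc)^2)))
    }
  }
  best
}

#' Infer the arena center from observed points
#'
#' Center of the minimal enclosing circle of the observed coordinates,
#' used for zero-centering when the file carries no explicit arena
#' center.  Computed by iteratively growing a support set (the at most
#' three points that pin the circle) until no point lies outside.
#'
#' @param x,y Coordinate vectors in the source frame.
#' @return Numeric length-2 center `c(x, y)`; attribute `radius` holds
#'   the enclosing radius.  Degenerate (collinear) inputs fall back to
#'   the bounding-box center with a warning.
#' @export
infer_arena_center <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stop2("infer_arena_center needs at least 10 samples")
  pts <- unique(cbind(x, y))
  # collinearity check via the area spanned by the principal directions
  sv <- svd(scale(pts, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    warn2("points are collinear within tolerance; using bounding-box center")
    ctr <- c(mean(range(x)), mean(range(y)))
    attr(ctr, "radius") <- sqrt(diff(range(x))^2 + diff(range(y))^2) / 2
    return(ctr)
  }
  # start from the two mutually farthest of 4 extreme points
  ext <- unique(rbind(pts[which.min(pts[, 1]), ], pts[which.max(pts[, 1]), ],
                      pts[which.min(pts[, 2]), ], pts[which.max(pts[, 2]), ]))
  support <- ext
  for (iter in seq_len(100)) {
    circ <- mec_of_support(support)
    d2 <- (pts[, 1] - circ$center[1])^2 + (pts[, 2] - circ$center[2])^2
    i <- which.max(d2)
    if (sqrt(d2[i]) <= circ$r * (1 + 1e-12) + 1e-9) break
    support <- rbind(support, pts[i, , drop = FALSE])
    # keep only points on (or nearly on) the current boundary plus the new one
    circ2 <- mec_of_support(support)
    on_b <- abs(sqrt(colSums((t(support) - circ2$center)^2)) - circ2$r) < 1e-6 * (circ2$r + 1)
    if (sum(on_b) >= 2) support <- support[on_b, , drop = FALSE]
  }
  ctr <- circ$center
  names(ctr) <- NULL
  attr(ctr, "radius") <- circ$r
  ctr
}

#' Standardize a raw track
#'
#' Applies, in order: unit conversion to cm, zero-centering on the arena
#' center, smoothing (skipped for dialects whose source is already
#' smoothed, i.e. `ethovision-like`), subsampling to the analysis period
#' `time_bin_size` by taking the nearest frame to each target time, and
#' linear interpolation of interior gaps (leading/trailing missing
#' samples are trimmed).
#'
#' @param raw A raw track from [read_track_files()].
#' @param config An [of_config()].
#' @return An [of_track()].
#' @export
standardize <- function(raw, config) {
  x <- raw$x; y <- raw$y; t <- raw$t
  # unit conversion
  if (identical(raw$units, "px")) {
    x <- x / raw$px_per_cm
    y <- y / raw$px_per_cm
  }
  if (mean(is.na(x) | is.na(y)) > 0.5) {
    stop2(sprintf("%s: more than 50%% of samples missing", raw$path %||% "track"))
  }
  # zero-centering
  ctr <- raw$center
  if (is.null(ctr)) ctr <- infer_arena_center(x, y)
  x <- x - ctr[1]; y <- y - ctr[2]
  # smoothing (dialect-dependent; ethovision-like data arrives smoothed)
  if (!identical(raw$dialect, "ethovision-like")) {
    w <- config$smooth_window %||% max(3L, round(config$sample_freq / 6))
    if (w > 1) {
      x <- moving_average(x, w)
      y <- moving_average(y, w)
    }
  }
  # subsample: nearest frame to each target time
  t0 <- t[1]
  targets <- seq(t0, t[length(t)], by = config$time_bin_size)
  idx <- vapply(targets, function(tt) which.min(abs(t - tt)), 1L)
  idx <- idx[!duplicated(idx)]
  ts <- t0 + (seq_along(idx) - 1) * config$time_bin_size
  xs <- x[idx]; ys <- y[idx]
  # interpolate interior gaps, trim leading/trailing missing
  miss <- is.na(xs) | is.na(ys)
  keep <- which(!miss)
  if (length(keep) < 3) stop2(sprintf("%s: fewer than 3 usable samples", raw$path %||% "track"))
  lo <- keep[1]; hi <- keep[length(keep)]
  sel <- lo:hi
  ts <- ts[sel] - ts[lo]; xs <- xs[sel]; ys <- ys[sel]; miss <- miss[sel]
  if (any(miss)) {
    ok <- !miss
    xs <- stats::approx(ts[ok], xs[ok], xout = ts)$y
    ys <- stats::approx(ts[ok], ys[ok], xout = ts)$y
  }
  if (length(ts) < 3) stop2(sprintf("%s: track shorter than 3 samples after subsampling", raw$path %||% "track"))
  of_track(ts, xs, ys, group = raw$group,
           arena_radius_cm = max(config$arena_radius_cm),
           arena = raw$arena, dialect = raw$dialect)
}

#' Write a standardized track as CSV
#'
#' Debug/interchange dump with columns `t_s,x_cm,y_cm`.
#' @param track An [of_track()].
#' @param path Output path.
#' @export
write_standard_track <- function(track, path) {
  utils::write.csv(data.frame(t_s = track$t, x_cm = track$x, y_cm = track$y),
                   path, row.names = FALSE)
  invisible(path)
}
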