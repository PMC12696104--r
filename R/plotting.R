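# Plot generation: trajectories, individual relationships, solo-group,
# group-components and group-comparison figures (base graphics, PNG/PDF).

#' Plot settings
#'
#' @param group_colors Named character vector mapping every analysed
#'   group to a colour (mandatory).
#' @param marker_size Point size (cex).
#' @param show_model,show_equation,show_sem,show_individual_fits Layer
#'   toggles.
#' @param save Write files (otherwise draw on the active device).
#' @param dir Output directory root; files go to
#'   `dir/<category>/<group>__<x>__<y>.<ext>`.
#' @param format `"png"` (300 dpi) or `"pdf"`.
#' @return Object of class `of_plot_settings`.
#' @export
plot_settings <- function(group_colors, marker_size = 0.6,
                          show_model = TRUE, show_equation = TRUE,
                          show_sem = TRUE, show_individual_fits = FALSE,
                          save = TRUE, dir = "plots", format = c("png", "pdf")) {
  format <- match.arg(format)
  stopifnot(is.character(group_colors), !is.null(names(group_colors)))
  structure(list(group_colors = group_colors, marker_size = marker_size,
                 show_model = show_model, show_equation = show_equation,
                 show_sem = show_sem,
                 show_individual_fits = show_individual_fits,
                 save = save, dir = dir, format = format),
            class = "of_plot_settings")
}

open_device <- function(settings, category, name) {
  if (!settings$save) return(NULL)
  d <- file.path(settings$dir, category)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(d, paste0(name, ".", settings$format))
  if (settings$format == "png") {
    grDevices::png(path, width = 5, height = 5, units = "in", res = 300)
  } else {
    grDevices::pdf(path, width = 5, height = 5)
  }
  path
}

close_device <- function(settings) {
  if (settings$save) grDevices::dev.off()
}

axis_label <- function(v) {
  labs <- c(time = "time (s)", activity = "activity (cm)",
            coverage = "coverage (visits)", percent_coverage = "percent coverage",
            pica = "PICA", pgca = "PGCA",
            p_pp = "P++", p_pm = "P+-", p_p0 = "P+0", p_0p = "P0+", p_00 = "P00")
  if (v %in% names(labs)) labs[[v]] else v
}

#' Plot trajectories with the arena boundary
#'
#' One panel per track: the trajectory polyline inside a circle of the
#' arena radius.
#'
#' @param tracks List of [of_track()].
#' @param settings An [plot_settings()].
#' @return Paths of files written, invisibly.
#' @export
plot_traces <- function(tracks, settings) {
  paths <- character(0)
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    name <- sprintf("trace__%s__%03d", tr$group, i)
    p <- open_device(settings, "traces", name)
    R <- tr$arena_radius_cm
    col <- settings$group_colors[tr$group]
    if (is.na(col)) col <- "grey30"
    graphics::plot(NA, xlim = c(-R, R) * 1.05, ylim = c(-R, R) * 1.05,
                   asp = 1, xlab = "x (cm)", ylab = "y (cm)",
                   main = sprintf("%s track %d", tr$group, i))
    ang <- seq(0, 2 * pi, length.out = 361)
    graphics::lines(R * cos(ang), R * sin(ang), col = "grey60")
    graphics::lines(tr$x, tr$y, col = col, lwd = 0.8)
    close_device(settings)
    if (!is.null(p)) paths <- c(paths, p)
  }
  invisible(paths)
}

plot_fit_curve <- function(fit, xlim, col, spec = NULL, settings) {
  if (is.null(fit) || !isTRUE(fit$converged)) {
    if (settings$show_model) warn2("fit missing or unconverged; curve omitted")
    return(invisible(NULL))
  }
  xx <- seq(xlim[1], xlim[2], length.out = 200)
  graphics::lines(xx, predict(fit, xx), col = col, lwd = 2)
  if (settings$show_equation) {
    eq <- fit_equation(fit, spec$display_parts %||% NULL)
    graphics::mtext(eq, side = 3, line = 0.2, cex = 0.7)
  }
}

#' Per-individual relationship plots
#'
#' A scatter of one (x, y) measure pair per individual, optionally with
#' the fitted curve and its rendered equation.
#'
#' @param mset An `of_measure_set`.
#' @param fitset An `of_fit_set` (for curves; may be `NULL`).
#' @param settings An [plot_settings()].
#' @param relationships Keys `"x~y"` to plot (default: all fitted).
#' @return Paths written, invisibly.
#' @export
plot_individuals <- function(mset, fitset, settings,
                             relationships = names(fitset$specs)) {
  paths <- character(0)
  fits <- attr(fitset$refit, "fits")
  for (key in relationships) {
    spec <- fitset$specs[[key]]
    for (i in seq_along(mset$individuals)) {
      df <- measures_df(mset$individuals[[i]], id = i)
      xv <- df[[spec$x_var]]; yv <- df[[spec$y_var]]
      ok <- is.finite(xv) & is.finite(yv)
      if (!any(ok)) next
      g <- mset$individuals[[i]]$group
      name <- sprintf("%s__%03d__%s__%s", g, i, spec$x_var, spec$y_var)
      p <- open_device(settings, "individuals", name)
      graphics::plot(xv[ok], yv[ok], pch = 16, cex = settings$marker_size,
                     col = settings$group_colors[g],
                     xlab = axis_label(spec$x_var),
                     ylab = axis_label(spec$y_var),
                     main = sprintf("%s #%d", g, i))
      if (settings$show_model) {
        plot_fit_curve(fits[[paste0(key, "|", i)]], range(xv[ok]),
                       "grey20", spec, settings)
      }
      close_device(settings)
      if (!is.null(p)) paths <- c(paths, p)
    }
  }
  invisible(paths)
}

draw_summary_points <- function(s, col, settings, add = FALSE, ...) {
  if (!add) {
    graphics::plot(s$x, s$mean, pch = 16, cex = settings$marker_size,
                   col = col, xlab = axis_label(attr(s, "x_var")),
                   ylab = axis_label(attr(s, "y_var")), ...)
  } else {
    graphics::points(s$x, s$mean, pch = 16, cex = settings$marker_size, col = col)
  }
  if (settings$show_sem) {
    ok <- is.finite(s$sem) & s$sem > 0
    if (any(ok)) {
      graphics::arrows(s$x[ok], s$mean[ok] - s$sem[ok],
                       s$x[ok], s$mean[ok] + s$sem[ok],
                       angle = 90, code = 3, length = 0.02, col = col)
    }
  }
}

#' Solo-group, group-components and group-comparison plots
#'
#' `plot_solo_group` draws a group's binned means with SEM bars and the
#' group fit; `plot_group_components` adds the raw individual tuples
#' (and optionally the individual fits) behind the averages;
#' `plot_group_comparison` overlays all groups' means and fits in the
#' configured group colours.
#'
#' @param mset An `of_measure_set`.
#' @param fitset An `of_fit_set`.
#' @param settings An [plot_settings()].
#' @param relationships Keys `"x~y"` to plot (default: all fitted).
#' @return Paths written, invisibly.
#' @export
plot_solo_group <- function(mset, fitset, settings,
                            relationships = names(fitset$specs)) {
  paths <- character(0)
  gfits <- attr(fitset$group, "fits")
  for (skey in names(fitset$summaries)) {
    s <- fitset$summaries[[skey]]
    key <- sprintf("%s~%s", attr(s, "x_var"), attr(s, "y_var"))
    if (!key %in% relationships) next
    g <- attr(s, "group")
    p <- open_device(settings, "solo_groups",
                     sprintf("%s__%s__%s", g, attr(s, "x_var"), attr(s, "y_var")))
    draw_summary_points(s, settings$group_colors[g], settings, main = g)
    if (settings$show_model && nrow(s)) {
      plot_fit_curve(gfits[[skey]], range(s$x), "grey20",
                     fitset$specs[[key]], settings)
    }
    close_device(settings)
    if (!is.null(p)) paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname plot_solo_group
#' @export
plot_group_components <- function(mset, fitset, settings,
                                  relationships = names(fitset$specs)) {
  paths <- character(0)
  gfits <- attr(fitset$group, "fits")
  ifits <- attr(fitset$refit, "fits")
  for (skey in names(fitset$summaries)) {
    s <- fitset$summaries[[skey]]
    key <- sprintf("%s~%s", attr(s, "x_var"), attr(s, "y_var"))
    if (!key %in% relationships) next
    g <- attr(s, "group")
    spec <- fitset$specs[[key]]
    members <- mset$groups[[g]]$members
    p <- open_device(settings, "group_components",
                     sprintf("%s__%s__%s", g, attr(s, "x_var"), attr(s, "y_var")))
    xs <- ys <- numeric(0)
    for (i in members) {
      df <- measures_df(mset$individuals[[i]], id = i)
      ok <- is.finite(df[[spec$x_var]]) & is.finite(df[[spec$y_var]])
      xs <- c(xs, df[[spec$x_var]][ok]); ys <- c(ys, df[[spec$y_var]][ok])
    }
    graphics::plot(xs, ys, pch = 16, cex = settings$marker_size * 0.5,
                   col = grDevices::adjustcolor("grey60", 0.4),
                   xlab = axis_label(spec$x_var), ylab = axis_label(spec$y_var),
                   main = g)
    if (settings$show_individual_fits) {
      for (i in members) {
        f <- ifits[[paste0(key, "|", i)]]
        if (!is.null(f) && isTRUE(f$converged)) {
          xx <- seq(min(xs), max(xs), length.out = 100)
          graphics::lines(xx, predict(f, xx),
                          col = grDevices::adjustcolor("grey50", 0.5))
        }
      }
    }
    draw_summary_points(s, settings$group_colors[g], settings, add = TRUE)
    if (settings$show_model && nrow(s)) {
      plot_fit_curve(gfits[[skey]], range(s$x), "grey20", spec, settings)
    }
    close_device(settings)
    if (!is.null(p)) paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname plot_solo_group
#' @export
plot_group_comparison <- function(mset, fitset, settings,
                                  relationships = names(fitset$specs)) {
  paths <- character(0)
  gfits <- attr(fitset$group, "fits")
  for (key in relationships) {
    spec <- fitset$specs[[key]]
    skeys <- names(fitset$summaries)[
      grepl(paste0("\\|", spec$x_var, "~", spec$y_var, "$"),
            names(fitset$summaries))]
    if (!length(skeys)) next
    p <- open_device(settings, "group_comparisons",
                     sprintf("all__%s__%s", spec$x_var, spec$y_var))
    xr <- range(unlist(lapply(skeys, function(k) fitset$summaries[[k]]$x)),
                finite = TRUE)
    yr <- range(unlist(lapply(skeys, function(k) {
      s <- fitset$summaries[[k]]
      c(s$mean - ifelse(is.finite(s$sem), s$sem, 0),
        s$mean + ifelse(is.finite(s$sem), s$sem, 0))
    })), finite = TRUE)
    graphics::plot(NA, xlim = xr, ylim = yr, xlab = axis_label(spec$x_var),
                   ylab = axis_label(spec$y_var), main = "group comparison")
    for (k in skeys) {
      s <- fitset$summaries[[k]]
      g <- attr(s, "group")
      draw_summary_points(s, settings$group_colors[g], settings, add = TRUE)
      if (settings$show_model && nrow(s)) {
        f <- gfits[[k]]
        if (!is.null(f) && isTRUE(f$converged)) {
          xx <- seq(min(s$x), max(s$x), length.out = 200)
          graphics::lines(xx, predict(f, xx),
                          col = settings$group_colors[g], lwd = 2)
        }
      }
    }
    graphics::legend("topright", legend = names(settings$group_colors),
                     col = settings$group_colors, pch = 16, cex = 0.8)
    close_device(settings)
    if (!is.null(p)) paths <- c(paths, p)
  }
  invisible(paths)
}
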