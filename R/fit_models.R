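# Parametric model fitting: naive bounded fit per individual, parameter
# bounds from the cohort distribution, constrained refit, group fit.

default_init <- function(form, x, y) {
  rng <- range(x)
  span <- max(diff(rng), 1e-6)
  switch(form$name,
    exponential_decay = c(max(max(y) - min(y), 1e-6), -3 / span,
                          max(min(y), 1e-9)),
    asymptotic_increase = c(-max(max(y), 1e-6) * 1.05, -3 / span),
    linear_decrease = {
      cf <- stats::coef(stats::lm(y ~ x))
      c(min(cf[2], -1e-9), max(cf[1], 1e-9))
    },
    linear_increase = {
      cf <- stats::coef(stats::lm(y ~ x))
      c(max(cf[2], 1e-9), max(cf[1], 1e-9))
    },
    sigmoidal_decay = c(max(max(y), 1e-6), -4 / span, -stats::median(x)),
    sigmoidal_increase = c(max(max(y), 1e-6), 4 / span, -stats::median(x)),
    {
      # user-registered forms: start at the box midpoint, or one unit
      # inside a half-open box, or zero when unbounded
      lo <- form$lower; hi <- form$upper
      ifelse(is.finite(lo) & is.finite(hi), (lo + hi) / 2,
             ifelse(is.finite(lo), lo + 1, ifelse(is.finite(hi), hi - 1, 0)))
    }
  )
}

#' Bounded nonlinear least-squares curve fit
#'
#' Fits `y = f(x; params)` for a registered model form by
#' Levenberg-Marquardt least squares with box constraints
#' ([minpack.lm::nls.lm]).  Starting values default to data-driven
#' heuristics per form; bounds default to the form's sign constraints.
#'
#' @param x,y Numeric data (NA pairs dropped).
#' @param form An `of_model_form` (or its name).
#' @param init Starting parameters (`NULL` = data-driven).
#' @param lower,upper Bounds (`NULL` = the form's sign bounds).
#' @param max_f_eval Cap on function evaluations.
#' @return Object of class `of_fit` with elements `par`, `converged`,
#'   `rss`, `n`, `form`, `x`, `y`, `info`, `message`; or a
#'   non-converged stub when fewer than `arity + 1` finite points are
#'   available.
#' @export
fit_curve <- function(x, y, form, init = NULL, lower = NULL, upper = NULL,
                      max_f_eval = 5000L) {
  if (is.character(form)) form <- get_model_form(form)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  lower <- lower %||% form$lower
  upper <- upper %||% form$upper
  out <- list(form = form$name, par = rep(NA_real_, form$arity),
              converged = FALSE, rss = NA_real_, n = length(x),
              x = x, y = y, info = NA_integer_, message = "insufficient data",
              lower = lower, upper = upper)
  class(out) <- "of_fit"
  if (length(x) < form$arity + 1) return(out)
  init <- init %||% default_init(form, x, y)
  # keep the start strictly inside the box
  eps <- 1e-9
  init <- clamp(init, lower + ifelse(is.finite(lower), eps, 0),
                upper - ifelse(is.finite(upper), eps, 0))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = init,
                       fn = function(p) y - form$fun(p, x),
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxfev = max_f_eval, maxiter = 1000,
                         ftol = 1e-10, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out$message <- "solver error"
    return(out)
  }
  out$par <- unname(fit$par)
  out$info <- fit$info
  out$message <- fit$message
  out$converged <- fit$info %in% 1:4
  out$rss <- sum(fit$fvec^2)
  out
}

#' @export
print.of_fit <- function(x, ...) {
  cat(sprintf("Model fit: %s (%s)\n", x$form,
              if (x$converged) "converged" else "not converged"))
  cat("  parameters:", paste(signif(x$par, 6), collapse = ", "), "\n")
  cat(sprintf("  n = %d, RSS = %.6g\n", x$n, x$rss))
  invisible(x)
}

#' @export
coef.of_fit <- function(object, ...) object$par

#' @export
predict.of_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  get_model_form(object$form)$fun(object$par, x)
}

#' @export
residuals.of_fit <- function(object, ...) {
  object$y - predict(object)
}

#' Render a fitted equation from display parts
#'
#' Interleaves the model's display fragments with the fitted parameters
#' at 3 significant digits.
#'
#' @param fit An `of_fit`.
#' @param display_parts Text fragments (`arity + 1` of them); defaults
#'   to the registered form's.
#' @return A single string.
#' @export
fit_equation <- function(fit, display_parts = NULL) {
  form <- get_model_form(fit$form)
  parts <- display_parts %||% form$display_parts
  vals <- signif(fit$par, 3)
  out <- parts[1]
  for (i in seq_along(vals)) out <- paste0(out, vals[i], parts[i + 1])
  out
}

# (x, y) data for one individual and one model spec
spec_xy <- function(df, spec) {
  list(x = df[[spec$x_var]], y = df[[spec$y_var]])
}

#' Naive fit of one relationship for one individual
#'
#' Bounded least squares within the model form's wide sign bounds.
#'
#' @param x,y Data vectors.
#' @param spec An [model_spec()].
#' @return An `of_fit`.
#' @export
fit_individual_naive <- function(x, y, spec) {
  form <- get_model_form(spec$model)
  fit_curve(x, y, form,
            init = spec$initial_parameters,
            lower = spec$parameter_bounds$lower,
            upper = spec$parameter_bounds$upper,
            max_f_eval = spec$max_f_eval)
}

#' Naive fits for every individual and relationship
#'
#' @param dfs Named-by-id list of [measures_df()] tables.
#' @param specs Named list of [model_spec()] from [set_up_fits()].
#' @param groups Group label per individual (recycled from the tables if
#'   omitted).
#' @return Long data.frame of class `of_param_table`: one row per
#'   (id, relationship, parameter) with the naive estimate; fits kept in
#'   `attr(, "fits")`.
#' @export
fit_all <- function(dfs, specs, groups = NULL) {
  groups <- groups %||% vapply(dfs, function(d) as.character(d$group[1]), "")
  rows <- list()
  fits <- list()
  for (key in names(specs)) {
    spec <- specs[[key]]
    for (i in seq_along(dfs)) {
      xy <- spec_xy(dfs[[i]], spec)
      fit <- fit_individual_naive(xy$x, xy$y, spec)
      fits[[paste0(key, "|", i)]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        id = i, group = groups[i], x_var = spec$x_var, y_var = spec$y_var,
        form = spec$model, param = seq_along(fit$par), value = fit$par,
        converged = fit$converged, rss = fit$rss)
    }
  }
  tab <- do.call(rbind, rows)
  attr(tab, "fits") <- fits
  class(tab) <- c("of_param_table", "data.frame")
  tab
}

#' Parameter bounds from the cohort's naive fits
#'
#' For each (group, relationship, parameter), bounds span
#' `mean - bound_level * SD` to `mean + bound_level * SD` over the
#' converged individuals' naive estimates, intersected with the form's
#' sign bounds.  A single individual (SD undefined) or zero SD collapses
#' the interval, which is widened by 1e-12 so the solver has an
#' interior; relationships with no converged individuals are excluded
#' with a warning.
#'
#' @param naive An `of_param_table` from [fit_all()].
#' @param bound_level SD multiplier (default 2).
#' @return data.frame with columns `group, x_var, y_var, form, param,
#'   lower, upper, n_converged`.
#' @export
find_fit_bounds <- function(naive, bound_level = 2) {
  key <- interaction(naive$group, naive$x_var, naive$y_var, naive$form,
                     naive$param, drop = TRUE)
  rows <- lapply(split(naive, key), function(d) {
    form <- get_model_form(d$form[1])
    j <- d$param[1]
    vals <- d$value[d$converged & is.finite(d$value)]
    if (!length(vals)) {
      warn2(sprintf("no converged naive fits for %s %s~%s parameter %d; excluded",
                    d$group[1], d$x_var[1], d$y_var[1], j))
      return(NULL)
    }
    mu <- mean(vals)
    sdv <- if (length(vals) > 1) stats::sd(vals) else 0
    lo <- max(mu - bound_level * sdv, form$lower[j])
    hi <- min(mu + bound_level * sdv, form$upper[j])
    if (hi - lo < 1e-12) { lo <- lo - 1e-12; hi <- hi + 1e-12 }
    data.frame(group = d$group[1], x_var = d$x_var[1], y_var = d$y_var[1],
               form = d$form[1], param = j, lower = lo, upper = hi,
               n_converged = length(vals))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

bounds_for <- function(bounds, group, x_var, y_var, form) {
  b <- bounds[bounds$group == group & bounds$x_var == x_var &
                bounds$y_var == y_var & bounds$form == form, ]
  if (!nrow(b)) return(NULL)
  b <- b[order(b$param), ]
  list(lower = b$lower, upper = b$upper)
}

#' Constrained refit of one individual
#'
#' Least squares constrained to the cohort-derived bounds; started from
#' the naive estimate clipped into the box, so an individual whose naive
#' fit already lies inside the bounds refits to (numerically) the same
#' parameters, while outliers land on the bound boundary.
#'
#' @param x,y Data vectors.
#' @param spec An [model_spec()].
#' @param bounds List with `lower` and `upper` for this relationship.
#' @param naive_par Naive parameters used as the start (`NULL` =
#'   data-driven start).
#' @return An `of_fit` whose parameters lie within the bounds.
#' @export
refit_individual <- function(x, y, spec, bounds, naive_par = NULL) {
  form <- get_model_form(spec$model)
  init <- naive_par
  fit_curve(x, y, form, init = init,
            lower = bounds$lower, upper = bounds$upper,
            max_f_eval = spec$max_f_eval)
}

#' Refit every individual within the cohort bounds
#'
#' @param dfs Named list of [measures_df()] tables.
#' @param specs Named list of [model_spec()].
#' @param naive An `of_param_table` from [fit_all()].
#' @param bounds Bounds table from [find_fit_bounds()].
#' @return An `of_param_table` of refit parameters.
#' @export
re_fit_all <- function(dfs, specs, naive, bounds) {
  groups <- vapply(dfs, function(d) as.character(d$group[1]), "")
  rows <- list()
  fits <- list()
  for (key in names(specs)) {
    spec <- specs[[key]]
    for (i in seq_along(dfs)) {
      b <- bounds_for(bounds, groups[i], spec$x_var, spec$y_var, spec$model)
      if (is.null(b)) next
      nv <- naive$value[naive$id == i & naive$x_var == spec$x_var &
                          naive$y_var == spec$y_var & naive$form == spec$model]
      conv <- naive$converged[naive$id == i & naive$x_var == spec$x_var &
                                naive$y_var == spec$y_var &
                                naive$form == spec$model][1]
      if (!isTRUE(conv)) next  # non-converged individuals are excluded
      xy <- spec_xy(dfs[[i]], spec)
      fit <- refit_individual(xy$x, xy$y, spec, b, naive_par = nv)
      fits[[paste0(key, "|", i)]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        id = i, group = groups[i], x_var = spec$x_var, y_var = spec$y_var,
        form = spec$model, param = seq_along(fit$par), value = fit$par,
        converged = fit$converged, rss = fit$rss)
    }
  }
  tab <- do.call(rbind, rows)
  attr(tab, "fits") <- fits
  class(tab) <- c("of_param_table", "data.frame")
  tab
}

#' Group-level fits on binned means
#'
#' Applies the same constrained fit to the group-averaged summary of
#' each relationship, within the bounds derived from the individuals.
#'
#' @param summaries Named list from [summarize_all()].
#' @param specs Named list of [model_spec()].
#' @param bounds Bounds table from [find_fit_bounds()].
#' @return Long data.frame of group parameters with the fits in
#'   `attr(, "fits")`.
#' @export
group_fit_all <- function(summaries, specs, bounds) {
  rows <- list()
  fits <- list()
  for (skey in names(summaries)) {
    s <- summaries[[skey]]
    g <- attr(s, "group")
    key <- sprintf("%s~%s", attr(s, "x_var"), attr(s, "y_var"))
    spec <- specs[[key]]
    if (is.null(spec)) next
    b <- bounds_for(bounds, g, spec$x_var, spec$y_var, spec$model)
    if (is.null(b)) next
    fit <- fit_curve(s$x, s$mean, get_model_form(spec$model),
                     lower = b$lower, upper = b$upper,
                     max_f_eval = spec$max_f_eval)
    fits[[skey]] <- fit
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, x_var = spec$x_var, y_var = spec$y_var, form = spec$model,
      param = seq_along(fit$par), value = fit$par,
      converged = fit$converged, rss = fit$rss)
  }
  tab <- do.call(rbind, rows)
  attr(tab, "fits") <- fits
  tab
}

#' Fit every configured relationship: naive, bounds, refit, group
#'
#' Orchestrates the robust two-pass scheme: naive fits within sign
#' bounds, per-group parameter bounds at `bound_level` SDs, constrained
#' refits, and group fits on the binned means.
#'
#' @param mset An `of_measure_set`.
#' @param specs Named list from [set_up_fits()].
#' @param config An [of_config()] (supplies `bound_level`).
#' @param summaries Optional precomputed [summarize_all()] result.
#' @return Object of class `of_fit_set`: `naive`, `bounds`, `refit`,
#'   `group`, `specs`, `summaries`.
#' @export
fit_relationships <- function(mset, specs, config = mset$config,
                              summaries = NULL) {
  ids <- seq_along(mset$individuals)
  dfs <- lapply(ids, function(i) measures_df(mset$individuals[[i]], id = i))
  naive <- fit_all(dfs, specs)
  bounds <- find_fit_bounds(naive, config$bound_level)
  refit <- re_fit_all(dfs, specs, naive, bounds)
  summaries <- summaries %||% summarize_all(mset)
  gfit <- group_fit_all(summaries, specs, bounds)
  structure(list(naive = naive, bounds = bounds, refit = refit,
                 group = gfit, specs = specs, summaries = summaries),
            class = "of_fit_set")
}

#' Export individual parameters as a long CSV
#'
#' One row per (id, relationship, parameter) with the naive and refit
#' values; this file is the bridge to external statistics (e.g. two-way
#' designs analysed outside the package).
#'
#' @param fitset An `of_fit_set` (or the naive/refit pair).
#' @param path Output CSV path (`NULL` = return the data.frame only).
#' @return The long data.frame, invisibly when written.
#' @export
format_params <- function(fitset, path = NULL) {
  naive <- fitset$naive
  refit <- fitset$refit
  key <- function(d) paste(d$id, d$x_var, d$y_var, d$form, d$param)
  m <- match(key(naive), key(refit))
  out <- data.frame(id = naive$id, group = naive$group,
                    x_var = naive$x_var, y_var = naive$y_var,
                    form = naive$form,
                    param_name = paste0("p", naive$param),
                    naive = naive$value,
                    refit = refit$value[m],
                    converged = naive$converged & !is.na(m) &
                      refit$converged[m] %in% TRUE)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Export group parameters as a long CSV
#'
#' @param fitset An `of_fit_set`.
#' @param path Output CSV path (`NULL` = return only).
#' @return The long data.frame.
#' @export
format_group_params <- function(fitset, path = NULL) {
  g <- fitset$group
  out <- data.frame(group = g$group, x_var = g$x_var, y_var = g$y_var,
                    form = g$form, param_name = paste0("p", g$param),
                    value = g$value, converged = g$converged)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
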