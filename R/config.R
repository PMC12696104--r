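# Analysis configuration, model-form registry and default model assignments.

# registry of named model forms; user-registered forms are added here
.of_forms <- new.env(parent = emptyenv())

register_builtin_forms <- function() {
  register_model_form(
    "exponential_decay", arity = 3L,
    fun = function(p, x) p[1] * exp(p[2] * x) + p[3],
    lower = c(0, -Inf, 0), upper = c(Inf, 0, Inf),
    display_parts = c("y = ", " e^(", " x) + ", ""))
  register_model_form(
    "asymptotic_increase", arity = 2L,
    fun = function(p, x) p[1] * (exp(p[2] * x) - 1),
    lower = c(-Inf, -Inf), upper = c(0, 0),
    display_parts = c("y = ", " (e^(", " x) - 1)"))
  register_model_form(
    "linear_decrease", arity = 2L,
    fun = function(p, x) p[1] * x + p[2],
    lower = c(-Inf, 0), upper = c(0, Inf),
    display_parts = c("y = ", " x + ", ""))
  register_model_form(
    "linear_increase", arity = 2L,
    fun = function(p, x) p[1] * x + p[2],
    lower = c(0, 0), upper = c(Inf, Inf),
    display_parts = c("y = ", " x + ", ""))
  register_model_form(
    "sigmoidal_decay", arity = 3L,
    fun = function(p, x) p[1] / (1 + exp(-p[2] * (x + p[3]))),
    lower = c(0, -Inf, -Inf), upper = c(Inf, 0, 0),
    display_parts = c("y = ", " / (1 + e^(-", " (x + ", ")))"))
  register_model_form(
    "sigmoidal_increase", arity = 3L,
    fun = function(p, x) p[1] / (1 + exp(-p[2] * (x + p[3]))),
    lower = c(0, 0, -Inf), upper = c(Inf, Inf, 0),
    display_parts = c("y = ", " / (1 + e^(-", " (x + ", ")))"))
}

#' Register a model form for curve fitting
#'
#' Adds a named functional form to the registry used by [model_spec()] and
#' the fitting routines.  Six forms are built in: `exponential_decay`
#' (`y = a e^(bx) + c`, a>0 b<0 c>0), `asymptotic_increase`
#' (`y = a(e^(bx)-1)`, a<0 b<0), `linear_decrease`, `linear_increase`
#' (`y = ax + b`), and `sigmoidal_decay` / `sigmoidal_increase`
#' (`y = a / (1 + e^(-b(x+c)))`).  The `lower`/`upper` vectors encode the
#' expected parameter signs and act as the wide bounds of the naive fit.
#'
#' @param name Form name (identifier).
#' @param arity Number of parameters (2 or 3 for the built-ins).
#' @param fun Evaluator `function(params, x)`.
#' @param lower,upper Numeric sign bounds per parameter.
#' @param display_parts Character vector of `arity + 1` text fragments that
#'   interleave with fitted parameter values to render the fitted equation.
#' @return The registered form, invisibly.
#' @export
register_model_form <- function(name, arity, fun, lower, upper, display_parts) {
  stopifnot(is.function(fun), length(lower) == arity, length(upper) == arity,
            length(display_parts) == arity + 1)
  form <- list(name = name, arity = as.integer(arity), fun = fun,
               lower = lower, upper = upper, display_parts = display_parts)
  class(form) <- "of_model_form"
  assign(name, form, envir = .of_forms)
  invisible(form)
}

#' Look up a registered model form
#' @param name Form name.
#' @return An `of_model_form` object.
#' @export
get_model_form <- function(name) {
  if (!exists(name, envir = .of_forms, inherits = FALSE)) {
    stop2(sprintf("unknown model form '%s'; registered forms: %s",
                  name, paste(model_form_names(), collapse = ", ")))
  }
  get(name, envir = .of_forms, inherits = FALSE)
}

#' @rdname get_model_form
#' @export
model_form_names <- function() sort(ls(envir = .of_forms))

# x and y variable vocabularies; coverage is a y-variable against time only
.x_vars <- c("time", "coverage", "percent_coverage", "pica", "pgca")
.y_vars <- c("activity", "coverage", "p_pp", "p_pm", "p_p0", "p_0p", "p_00")

#' Analysis configuration
#'
#' Collects the experiment-level parameters of an open field analysis:
#' which groups were run and with which tracker dialect, the arena size,
#' the frame rate, the edge-region width, the target analysis period and
#' the inactivity threshold.
#'
#' @param groups_and_types Named character vector mapping each group label
#'   to a tracker dialect (one of [track_dialects()]).
#' @param arena_radius_cm Arena radius in cm (> 0).
#' @param sample_freq Recording frame rate in frames/second (> 0).
#' @param edge_dist_cm Width in cm of the edge band next to the arena wall
#'   inside which coverage and motion probabilities are evaluated;
#'   setting it to `arena_radius_cm` disables the edge restriction.
#' @param time_bin_size Target inter-sample period, seconds, after
#'   subsampling; must be at least `1/sample_freq`.
#' @param inactivity_threshold Step length (cm) below which a step counts
#'   as zero displacement, absorbing tracker jitter.
#' @param group_colors Named character vector mapping group label to a
#'   plotting colour.
#' @param bound_level SD multiplier for the refit parameter bounds
#'   (default 2).
#' @param smooth_window Moving-average window (samples) used when a
#'   dialect requires smoothing; `NULL` means `round(sample_freq / 6)`
#'   forced odd with minimum 3.
#' @param verbose,save_outputs Logical flags.
#' @return An object of class `of_config`.
#' @export
of_config <- function(groups_and_types,
                      arena_radius_cm,
                      sample_freq,
                      edge_dist_cm,
                      time_bin_size,
                      inactivity_threshold,
                      group_colors = NULL,
                      bound_level = 2,
                      smooth_window = NULL,
                      verbose = FALSE,
                      save_outputs = TRUE) {
  if (is.null(group_colors)) {
    group_colors <- stats::setNames(
      grDevices::hcl.colors(max(2L, length(groups_and_types)), "Dark 2")[
        seq_along(groups_and_types)],
      names(groups_and_types))
  }
  cfg <- list(groups_and_types = groups_and_types,
              arena_radius_cm = arena_radius_cm,
              sample_freq = sample_freq,
              edge_dist_cm = edge_dist_cm,
              time_bin_size = time_bin_size,
              inactivity_threshold = inactivity_threshold,
              group_colors = group_colors,
              bound_level = bound_level,
              smooth_window = smooth_window,
              verbose = verbose,
              save_outputs = save_outputs)
  class(cfg) <- "of_config"
  cfg
}

#' Default analysis settings
#'
#' Settings a typical user does not change between experiments: the sector
#' size used for coverage, the granularity of the coverage series, which
#' measures and relationships are analysed, and the summary binning sizes.
#'
#' @param node_size Sector central angle in degrees; must divide 360.
#'   Default 0.1 (3600 sectors); check that the resulting arc length is
#'   sensible relative to the subject's body length.
#' @param coverage_sample_period Seconds between coverage evaluations
#'   (default 1).
#' @param x_vars Independent variables to analyse; subset of
#'   `c("time", "coverage", "percent_coverage", "pica", "pgca")`.
#' @param y_vars Dependent variables; subset of `c("activity", "p_pp",
#'   "p_pm", "p_p0", "p_0p", "p_00")`.  Coverage-versus-time is always
#'   included when `fit_coverage` is `TRUE`.
#' @param fit_coverage Model the coverage-versus-time relationship
#'   (needed for PICA/PGCA).
#' @param prob_variant Motion-probability variant used for group series:
#'   `"given_previous"`, `"given_any"` or `"raw"`.
#' @param n_points Tuples per equal-count bin (coverage-like axes).
#' @param n_bins Number of equal-width bins (percent coverage axis).
#' @param alpha Significance level for the statistical ladder.
#' @return An object of class `of_defaults`.
#' @export
of_defaults <- function(node_size = 0.1,
                        coverage_sample_period = 1,
                        x_vars = c("time", "percent_coverage"),
                        y_vars = c("activity", "p_pp", "p_pm", "p_p0",
                                   "p_0p", "p_00"),
                        fit_coverage = TRUE,
                        prob_variant = "given_previous",
                        n_points = 50,
                        n_bins = 50,
                        alpha = 0.05) {
  d <- list(node_size = node_size,
            coverage_sample_period = coverage_sample_period,
            x_vars = x_vars, y_vars = y_vars,
            fit_coverage = fit_coverage,
            prob_variant = prob_variant,
            n_points = n_points, n_bins = n_bins, alpha = alpha)
  class(d) <- "of_defaults"
  d
}

#' Specification of the coverage-asymptote fit
#'
#' The asymptote of the coverage-versus-time relationship is the number of
#' visits to each boundary sector the animal needs to habituate fully; it
#' rescales coverage into PICA/PGCA.  By default the asymptotic increase
#' form `y = a(e^(bx) - 1)` is fitted with a < 0, b < 0, so the asymptote
#' is `-a`: `asymptote_param = 1`, `asymptote_sign = -1`.
#'
#' @param f_name Registered form name.
#' @param asymptote_param 1-based index of the asymptote parameter.
#' @param asymptote_sign +1 or -1.
#' @param initial_parameters Optional starting values (`NULL` =
#'   data-driven).
#' @param parameter_bounds Optional list with `lower` and `upper`.
#' @param max_f_eval Function-evaluation cap for the solver.
#' @return An object of class `of_asymptote_spec`.
#' @export
coverage_asymptote_spec <- function(f_name = "asymptotic_increase",
                                    asymptote_param = 1L,
                                    asymptote_sign = -1,
                                    initial_parameters = NULL,
                                    parameter_bounds = NULL,
                                    max_f_eval = 5000L) {
  form <- get_model_form(f_name)
  if (asymptote_param < 1 || asymptote_param > form$arity) {
    stop2("asymptote_param must index a parameter of '", f_name, "'")
  }
  if (!asymptote_sign %in% c(-1, 1)) stop2("asymptote_sign must be +1 or -1")
  spec <- list(f_name = f_name, asymptote_param = as.integer(asymptote_param),
               asymptote_sign = asymptote_sign,
               initial_parameters = initial_parameters,
               parameter_bounds = parameter_bounds,
               max_f_eval = as.integer(max_f_eval))
  class(spec) <- "of_asymptote_spec"
  spec
}

#' Specify the model for one (x, y) relationship
#'
#' @param x_var,y_var Variable names (see [of_defaults()]).
#' @param model Registered form name.
#' @param initial_parameters Optional starting values.
#' @param parameter_bounds Optional list(lower=, upper=) overriding the
#'   form's sign bounds for the naive fit.
#' @param display_parts Optional text fragments for equation rendering;
#'   defaults to the form's.
#' @param max_f_eval Solver evaluation cap.
#' @return An object of class `of_model_spec`.
#' @export
model_spec <- function(x_var, y_var, model,
                       initial_parameters = NULL,
                       parameter_bounds = NULL,
                       display_parts = NULL,
                       max_f_eval = 5000L) {
  if (!x_var %in% .x_vars) {
    stop2(sprintf("unknown x-variable '%s' (choose from %s)",
                  x_var, paste(.x_vars, collapse = ", ")))
  }
  if (!y_var %in% .y_vars) {
    stop2(sprintf("unknown y-variable '%s' (choose from %s)",
                  y_var, paste(.y_vars, collapse = ", ")))
  }
  if (y_var == "coverage" && x_var != "time") {
    stop2("coverage is a y-variable only against time")
  }
  form <- get_model_form(model)
  display_parts <- display_parts %||% form$display_parts
  if (length(display_parts) != form$arity + 1) {
    stop2("display_parts must have one more element than the form has parameters")
  }
  spec <- list(x_var = x_var, y_var = y_var, model = model,
               initial_parameters = initial_parameters,
               parameter_bounds = parameter_bounds,
               display_parts = display_parts,
               max_f_eval = as.integer(max_f_eval))
  class(spec) <- "of_model_spec"
  spec
}

# default form per y-variable; P_+0 is assigned exponential decay (the
# increase-in-pausing view assigns it asymptotic increase instead; override
# via set_up_fits(overrides=))
.default_forms <- c(activity = "exponential_decay",
                    coverage = "asymptotic_increase",
                    p_pp = "exponential_decay",
                    p_pm = "asymptotic_increase",
                    p_p0 = "exponential_decay",
                    p_0p = "asymptotic_increase",
                    p_00 = "asymptotic_increase")

#' Build the default grid of model specifications
#'
#' Creates one [model_spec()] per enabled (x, y) relationship.  Defaults
#' assign exponential decay to activity, P_++ and P_+0, and asymptotic
#' increase to coverage-versus-time, P_+-, P_0+ and P_00.
#'
#' @param config An [of_config()].
#' @param defaults An [of_defaults()].
#' @param overrides Optional named list of [model_spec()] objects keyed
#'   `"x~y"` (e.g. `"time~p_pp"`) replacing individual defaults.
#' @return Named list of `of_model_spec`, keyed `"x~y"`.
#' @export
set_up_fits <- function(config, defaults = of_defaults(), overrides = list()) {
  specs <- list()
  if (isTRUE(defaults$fit_coverage)) {
    specs[["time~coverage"]] <- model_spec("time", "coverage",
                                           .default_forms[["coverage"]])
  }
  ys <- setdiff(defaults$y_vars, "coverage")
  for (x in defaults$x_vars) {
    for (y in ys) {
      key <- paste0(x, "~", y)
      specs[[key]] <- model_spec(x, y, .default_forms[[y]])
    }
  }
  for (key in names(overrides)) {
    ov <- overrides[[key]]
    if (!inherits(ov, "of_model_spec")) stop2("overrides must be model_spec objects")
    specs[[key]] <- ov
  }
  specs
}

#' Validate a configuration
#'
#' Checks every invariant of the configuration and defaults and returns
#' all violations at once rather than stopping at the first.
#'
#' @param config An [of_config()].
#' @param defaults An [of_defaults()].
#' @return Character vector of human-readable error messages (empty when
#'   valid), invisibly; also signalled as a single error if
#'   `stop_on_error` is `TRUE`.
#' @param stop_on_error Raise an error when any check fails.
#' @export
validate_config <- function(config, defaults = of_defaults(),
                            stop_on_error = FALSE) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (length(config$groups_and_types) == 0 ||
      is.null(names(config$groups_and_types))) {
    add("groups_and_types must be a named map of group -> tracker dialect")
  } else {
    bad <- setdiff(unlist(config$groups_and_types), track_dialects())
    if (length(bad)) {
      add(sprintf("unknown tracker dialect(s): %s", paste(bad, collapse = ", ")))
    }
  }
  if (!is.numeric(config$arena_radius_cm) || any(config$arena_radius_cm <= 0)) {
    add("arena_radius_cm must be positive")
  }
  if (!is.numeric(config$sample_freq) || config$sample_freq <= 0) {
    add("sample_freq must be > 0 frames/second")
  }
  if (!is.numeric(config$edge_dist_cm) || config$edge_dist_cm <= 0 ||
      config$edge_dist_cm > max(config$arena_radius_cm)) {
    add("edge_dist_cm must satisfy 0 < edge_dist_cm <= arena_radius_cm")
  }
  if (!is.numeric(config$time_bin_size) ||
      config$time_bin_size * config$sample_freq < 1 - 1e-9) {
    add("time_bin_size must be at least 1/sample_freq (cannot upsample)")
  }
  if (!is.numeric(config$inactivity_threshold) || config$inactivity_threshold < 0) {
    add("inactivity_threshold must be >= 0 cm")
  }
  if (!is.numeric(config$bound_level) || config$bound_level <= 0) {
    add("bound_level must be positive")
  }
  miss <- setdiff(names(config$groups_and_types), names(config$group_colors))
  if (length(miss)) {
    add(sprintf("group_colors missing for group(s): %s", paste(miss, collapse = ", ")))
  }
  if (360 %% defaults$node_size > 1e-9 &&
      abs(360 %% defaults$node_size - defaults$node_size) > 1e-9) {
    add(sprintf("node_size %g does not divide 360 evenly", defaults$node_size))
  }
  if (defaults$coverage_sample_period <= 0) add("coverage_sample_period must be > 0")
  if (defaults$n_points < 2) add("n_points must be >= 2")
  if (defaults$n_bins < 2) add("n_bins must be >= 2")
  if (!all(defaults$x_vars %in% .x_vars)) {
    add(sprintf("unknown x-variable(s): %s",
                paste(setdiff(defaults$x_vars, .x_vars), collapse = ", ")))
  }
  if (!all(defaults$y_vars %in% .y_vars)) {
    add(sprintf("unknown y-variable(s): %s",
                paste(setdiff(defaults$y_vars, .y_vars), collapse = ", ")))
  }
  if (!defaults$prob_variant %in% c("given_previous", "given_any", "raw")) {
    add("prob_variant must be given_previous, given_any or raw")
  }
  if (stop_on_error && length(errs)) {
    stop2("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  invisible(errs)
}

#' Read / write a run configuration file
#'
#' The configuration travels as a single plain-text TOML document with an
#' `[experiment]` table (the [of_config()] fields), a `[colors]` table,
#' and a `[defaults]` table.  A validated configuration round-trips
#' through `write_config()` / `read_config()` unchanged.
#'
#' @param path File path.
#' @return `read_config()` returns `list(config=, defaults=)`.
#' @export
read_config <- function(path) {
  doc <- read_toml(path)
  ex <- doc[["experiment"]]
  if (is.null(ex)) stop2("config file has no [experiment] table")
  groups <- unlist(doc[["groups"]])
  colors <- unlist(doc[["colors"]])
  cfg <- of_config(
    groups_and_types = groups,
    arena_radius_cm = ex$arena_radius_cm,
    sample_freq = ex$sample_freq,
    edge_dist_cm = ex$edge_dist_cm,
    time_bin_size = ex$time_bin_size,
    inactivity_threshold = ex$inactivity_threshold,
    group_colors = colors,
    bound_level = ex$bound_level %||% 2,
    smooth_window = ex$smooth_window,
    verbose = ex$verbose %||% FALSE,
    save_outputs = ex$save_outputs %||% TRUE)
  de <- doc[["defaults"]] %||% list()
  defaults <- of_defaults(
    node_size = de$node_size %||% 0.1,
    coverage_sample_period = de$coverage_sample_period %||% 1,
    x_vars = de$x_vars %||% c("time", "percent_coverage"),
    y_vars = de$y_vars %||% c("activity", "p_pp", "p_pm", "p_p0", "p_0p", "p_00"),
    fit_coverage = de$fit_coverage %||% TRUE,
    prob_variant = de$prob_variant %||% "given_previous",
    n_points = de$n_points %||% 50,
    n_bins = de$n_bins %||% 50,
    alpha = de$alpha %||% 0.05)
  list(config = cfg, defaults = defaults)
}

#' @rdname read_config
#' @param config An [of_config()].
#' @param defaults An [of_defaults()].
#' @export
write_config <- function(config, defaults, path) {
  ex <- list(arena_radius_cm = config$arena_radius_cm,
             sample_freq = config$sample_freq,
             edge_dist_cm = config$edge_dist_cm,
             time_bin_size = config$time_bin_size,
             inactivity_threshold = config$inactivity_threshold,
             bound_level = config$bound_level,
             verbose = config$verbose,
             save_outputs = config$save_outputs)
  if (!is.null(config$smooth_window)) ex$smooth_window <- config$smooth_window
  doc <- list(
    experiment = ex,
    groups = as.list(config$groups_and_types),
    colors = as.list(config$group_colors),
    defaults = unclass(defaults))
  write_toml(doc, path)
}

#' @export
print.of_config <- function(x, ...) {
  cat("Open field analysis configuration\n")
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (%s)", names(x$groups_and_types),
                            x$groups_and_types), collapse = ", ")))
  cat(sprintf("  arena radius: %g cm; sample freq: %g Hz\n",
              max(x$arena_radius_cm), x$sample_freq))
  cat(sprintf("  edge band: %g cm; analysis period: %g s; inactivity threshold: %g cm\n",
              x$edge_dist_cm, x$time_bin_size, x$inactivity_threshold))
  invisible(x)
}
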