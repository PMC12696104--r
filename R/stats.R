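# Group comparison ladder: full MANOVA, per-relationship MANOVA
# sub-tests, per-parameter ANOVA, pairwise t-tests with Holm-Sidak
# adjustment, and the significance-chain interpretation rule.

# wide matrix of refit parameters: one row per individual (complete
# cases within the selected columns), columns named x~y~form~pK
param_wide <- function(refit) {
  col <- with(refit, paste0(x_var, "~", y_var, "~", form, "~p", param))
  ids <- sort(unique(refit$id))
  cols <- unique(col)
  mat <- matrix(NA_real_, nrow = length(ids), ncol = length(cols),
                dimnames = list(ids, cols))
  mat[cbind(match(refit$id, ids), match(col, cols))] <-
    ifelse(refit$converged, refit$value, NA_real_)
  groups <- refit$group[match(ids, refit$id)]
  list(mat = mat, groups = factor(groups), ids = ids)
}

#' One-way MANOVA on fitted parameters
#'
#' Each parameter is a dependent variable; the experimental group is the
#' independent variable.  Reports the Wilks' lambda statistic with its
#' Rao F approximation (the `Pr>F` users should read) and, for
#' reference, Pillai's trace.
#'
#' @param mat Numeric matrix, individuals x parameters; rows with any NA
#'   are dropped (complete cases).
#' @param groups Factor of group labels, one per row.
#' @return data.frame with columns `statistic, value, approx_F, df1,
#'   df2, p_value`, or rows of NA when the test cannot be run (too few
#'   complete rows or singular within-group covariance).
#' @export
run_manova <- function(mat, groups) {
  mat <- as.matrix(mat)
  cc <- stats::complete.cases(mat)
  mat <- mat[cc, , drop = FALSE]
  groups <- droplevels(factor(groups[cc]))
  na_row <- data.frame(statistic = c("Wilks", "Pillai"), value = NA_real_,
                       approx_F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                       p_value = NA_real_)
  if (nlevels(groups) < 2) return(na_row)
  if (ncol(mat) == 1) {
    # single dependent variable: the sub-test degenerates to an ANOVA
    a <- run_anova_one(mat[, 1], groups)
    return(data.frame(statistic = c("Wilks", "Pillai"), value = NA_real_,
                      approx_F = a$F, df1 = a$df1, df2 = a$df2,
                      p_value = a$p_value))
  }
  if (nrow(mat) < ncol(mat) + nlevels(groups)) return(na_row)
  res <- tryCatch({
    fit <- stats::manova(mat ~ groups)
    w <- summary(fit, test = "Wilks")$stats
    p <- summary(fit, test = "Pillai")$stats
    data.frame(statistic = c("Wilks", "Pillai"),
               value = c(w["groups", "Wilks"], p["groups", "Pillai"]),
               approx_F = c(w["groups", "approx F"], p["groups", "approx F"]),
               df1 = c(w["groups", "num Df"], p["groups", "num Df"]),
               df2 = c(w["groups", "den Df"], p["groups", "den Df"]),
               p_value = c(w["groups", "Pr(>F)"], p["groups", "Pr(>F)"]))
  }, error = function(e) {
    warn2("MANOVA failed (", conditionMessage(e),
          "); consider per-relationship sub-tests with fewer parameters")
    na_row
  })
  res
}

run_anova_one <- function(values, groups) {
  ok <- is.finite(values)
  values <- values[ok]
  groups <- droplevels(factor(groups[ok]))
  if (nlevels(groups) < 2 || length(values) <= nlevels(groups)) {
    return(data.frame(F = NA_real_, df1 = NA_real_, df2 = NA_real_,
                      p_value = NA_real_))
  }
  a <- stats::anova(stats::aov(values ~ groups))
  data.frame(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
             p_value = a$`Pr(>F)`[1])
}

#' Per-relationship MANOVA sub-tests
#'
#' Runs [run_manova()] restricted to the parameters of each fitted
#' (x, y) relationship; with a single parameter the sub-test is the
#' corresponding ANOVA.  Relationships with too little data report NA.
#'
#' @param refit An `of_param_table` of refit parameters.
#' @return data.frame, one row per relationship: `x_var, y_var, form,
#'   n_params, n_complete, p_value` (Wilks).
#' @export
run_subtests <- function(refit) {
  pw <- param_wide(refit)
  rel <- unique(refit[, c("x_var", "y_var", "form")])
  rows <- lapply(seq_len(nrow(rel)), function(k) {
    prefix <- paste0(rel$x_var[k], "~", rel$y_var[k], "~", rel$form[k], "~p")
    cols <- grep(prefix, colnames(pw$mat), fixed = TRUE)
    sub <- pw$mat[, cols, drop = FALSE]
    cc <- sum(stats::complete.cases(sub))
    res <- run_manova(sub, pw$groups)
    data.frame(x_var = rel$x_var[k], y_var = rel$y_var[k], form = rel$form[k],
               n_params = length(cols), n_complete = cc,
               p_value = res$p_value[res$statistic == "Wilks"])
  })
  do.call(rbind, rows)
}

#' Per-parameter one-way ANOVAs
#'
#' One ANOVA per fitted parameter; computed for every parameter, with
#' interpretation gated by the significance chain (a parameter counts as
#' significant only when its relationship's sub-test is also below
#' alpha).
#'
#' @param refit An `of_param_table` of refit parameters.
#' @return data.frame: `x_var, y_var, form, param, F, df1, df2,
#'   p_value`.
#' @export
run_anovas <- function(refit) {
  pw <- param_wide(refit)
  rows <- lapply(colnames(pw$mat), function(cn) {
    parts <- strsplit(cn, "~", fixed = TRUE)[[1]]
    a <- run_anova_one(pw$mat[, cn], pw$groups)
    data.frame(x_var = parts[1], y_var = parts[2], form = parts[3],
               param = as.integer(sub("^p", "", parts[4])),
               F = a$F, df1 = a$df1, df2 = a$df2, p_value = a$p_value)
  })
  do.call(rbind, rows)
}

# Holm-Sidak step-down adjustment across m p-values
p_adjust_holm_sidak <- function(p) {
  m <- length(p)
  if (m <= 1) return(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

#' Pairwise t-tests on one parameter
#'
#' Two-sided t-tests between every pair of groups; `coef` is
#' `mean(first group) - mean(second group)` and `pvalue_hs` is the
#' Holm-Sidak step-down adjusted p-value across the pairs.
#'
#' @param values Numeric vector of one parameter across individuals.
#' @param groups Factor of group labels.
#' @param pooled Use the pooled-variance t-test (default); `FALSE` gives
#'   Welch.
#' @return data.frame: `group1, group2, coef, t, df, p_value,
#'   pvalue_hs` (pairs with under 2 individuals per side report NA).
#' @export
pairwise_ttests <- function(values, groups, pooled = TRUE) {
  groups <- factor(groups)
  levs <- levels(groups)
  if (length(levs) < 2) {
    return(data.frame(group1 = character(0), group2 = character(0),
                      coef = numeric(0), t = numeric(0), df = numeric(0),
                      p_value = numeric(0), pvalue_hs = numeric(0)))
  }
  pairs <- utils::combn(levs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    v1 <- values[groups == g1 & is.finite(values)]
    v2 <- values[groups == g2 & is.finite(values)]
    if (length(v1) < 2 || length(v2) < 2) {
      return(data.frame(group1 = g1, group2 = g2,
                        coef = mean(v1) - mean(v2), t = NA_real_,
                        df = NA_real_, p_value = NA_real_))
    }
    tt <- tryCatch(stats::t.test(v1, v2, var.equal = pooled),
                   error = function(e) NULL)  # e.g. zero-variance data
    if (is.null(tt)) {
      return(data.frame(group1 = g1, group2 = g2,
                        coef = mean(v1) - mean(v2), t = NA_real_,
                        df = NA_real_, p_value = NA_real_))
    }
    data.frame(group1 = g1, group2 = g2, coef = mean(v1) - mean(v2),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$pvalue_hs <- NA_real_
  ok <- is.finite(out$p_value)
  out$pvalue_hs[ok] <- p_adjust_holm_sidak(out$p_value[ok])
  out
}

#' Run the full statistical ladder and write a report
#'
#' Full MANOVA on all parameters, per-relationship MANOVA sub-tests,
#' per-parameter ANOVAs, and pairwise t-tests per parameter, plus the
#' significance-chain flags: a parameter is flagged only when both its
#' relationship's sub-test and its own ANOVA fall below `alpha`.
#'
#' @param fitset An `of_fit_set` (its `refit` table is used) or an
#'   `of_param_table`.
#' @param alpha Significance level for the chain (default 0.05).
#' @param out_dir Directory for the text report and CSV twins (`NULL` =
#'   no files).
#' @return Object of class `of_stat_report`: `full_manova`, `subtests`,
#'   `anovas` (with `sig_chain` column), `pairwise` (named list per
#'   parameter), `alpha`.
#' @export
run_tests <- function(fitset, alpha = 0.05, out_dir = NULL) {
  refit <- if (inherits(fitset, "of_fit_set")) fitset$refit else fitset
  if (is.null(refit) || !nrow(refit)) {
    rep0 <- structure(list(full_manova = NULL, subtests = NULL, anovas = NULL,
                           pairwise = list(), alpha = alpha,
                           message = "nothing testable: no refit parameters"),
                      class = "of_stat_report")
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      writeLines("Nothing testable: no refit parameters.",
                 file.path(out_dir, "stat_report.txt"))
    }
    return(rep0)
  }
  pw <- param_wide(refit)
  full <- run_manova(pw$mat, pw$groups)
  subs <- run_subtests(refit)
  anovas <- run_anovas(refit)
  skey <- paste(subs$x_var, subs$y_var, subs$form)
  akey <- paste(anovas$x_var, anovas$y_var, anovas$form)
  anovas$subtest_p <- subs$p_value[match(akey, skey)]
  anovas$sig_chain <- !is.na(anovas$p_value) & !is.na(anovas$subtest_p) &
    anovas$p_value < alpha & anovas$subtest_p < alpha
  pairwise <- list()
  for (cn in colnames(pw$mat)) {
    pairwise[[cn]] <- pairwise_ttests(pw$mat[, cn], pw$groups)
  }
  report <- structure(list(full_manova = full, subtests = subs,
                           anovas = anovas, pairwise = pairwise,
                           alpha = alpha, message = NULL),
                      class = "of_stat_report")
  if (!is.null(out_dir)) write_stat_report(report, out_dir)
  report
}

write_stat_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  con <- file.path(out_dir, "stat_report.txt")
  lines <- c("Group comparison report",
             sprintf("alpha = %g", report$alpha), "",
             "== Full MANOVA ==",
             utils::capture.output(print(report$full_manova, row.names = FALSE)),
             "", "== MANOVA sub-tests (per relationship) ==",
             utils::capture.output(print(report$subtests, row.names = FALSE)),
             "", "== Per-parameter ANOVAs (sig_chain requires sub-test AND ANOVA < alpha) ==",
             utils::capture.output(print(report$anovas, row.names = FALSE)),
             "", "== Pairwise t-tests (pvalue_hs = Holm-Sidak adjusted) ==")
  for (cn in names(report$pairwise)) {
    lines <- c(lines, paste0("-- ", cn, " --"),
               utils::capture.output(print(report$pairwise[[cn]],
                                           row.names = FALSE)), "")
  }
  writeLines(lines, con)
  utils::write.csv(report$full_manova,
                   file.path(out_dir, "full_manova.csv"), row.names = FALSE)
  utils::write.csv(report$subtests,
                   file.path(out_dir, "subtests.csv"), row.names = FALSE)
  utils::write.csv(report$anovas,
                   file.path(out_dir, "anovas.csv"), row.names = FALSE)
  pw <- do.call(rbind, lapply(names(report$pairwise), function(cn) {
    cbind(parameter = cn, report$pairwise[[cn]])
  }))
  utils::write.csv(pw, file.path(out_dir, "pairwise_ttests.csv"),
                   row.names = FALSE)
  invisible(con)
}

#' @export
print.of_stat_report <- function(x, ...) {
  if (!is.null(x$message)) {
    cat(x$message, "\n")
    return(invisible(x))
  }
  cat("Statistical report (alpha =", x$alpha, ")\n")
  cat("Full MANOVA Wilks p =",
      signif(x$full_manova$p_value[x$full_manova$statistic == "Wilks"], 4), "\n")
  nsig <- sum(x$anovas$sig_chain)
  cat(sprintf("%d of %d parameters significant in both sub-test and ANOVA\n",
              nsig, nrow(x$anovas)))
  invisible(x)
}
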