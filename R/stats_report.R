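#' Normalise condition readouts to paired controls
#'
#' Elementwise 100 x condition / control for paired preparations. Pairs
#' with a zero (or non-finite) control are flagged and return NA.
#'
#' @param control,condition numeric vectors of equal length (paired).
#' @return data.frame: control, condition, normalized_pct, flagged.
#' @export
normalizeToControl <- function(control, condition) {
  stopIfNot(length(control) == length(condition),
            "control and condition must be paired (equal length)")
  flagged <- !is.finite(control) | control == 0
  pct <- ifelse(flagged, NA_real_, 100 * condition / control)
  data.frame(control = control, condition = condition,
             normalized_pct = pct, flagged = flagged)
}

#' Significance stars
#'
#' Tiers: p < 0.05 (*), < 0.01 (**), < 0.001 (***), < 0.0001 (****);
#' otherwise "ns".
#'
#' @param p p-value(s).
#' @return character vector of star labels.
#' @export
significanceStars <- function(p) {
  vapply(p, function(pi) {
    if (!is.finite(pi)) return(NA_character_)
    if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

#' Two-group comparison (Student's / Welch's t-test)
#'
#' Unpaired two-sided t-test (Welch correction by default). Degenerate
#' zero-variance groups fall back to an exact-equality check.
#'
#' @param x,y numeric vectors, n >= 2 each.
#' @param varEqual use the pooled-variance (classic Student) form.
#' @return list of class \code{"GroupComparison"}: statistic, df,
#'   p_value, stars, mean_x, mean_y, n_x, n_y, method.
#' @export
compareTwo <- function(x, y, varEqual = FALSE) {
  stopIfNot(length(x) >= 2 && length(y) >= 2, "need n >= 2 per group")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    res <- list(statistic = if (p == 1) 0 else Inf, df = NA_real_,
                p_value = p, method = "exact equality (zero variance)")
  } else {
    tt <- stats::t.test(x, y, var.equal = varEqual)
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, method = tt$method)
  }
  res$stars <- significanceStars(res$p_value)
  res$mean_x <- mean(x); res$mean_y <- mean(y)
  res$n_x <- length(x); res$n_y <- length(y)
  structure(res, class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("GroupComparison (%s): t = %.3f, p = %.4g %s\n",
              x$method, x$statistic, x$p_value, x$stars))
  invisible(x)
}

#' Multi-group comparison: one-way ANOVA with Tukey HSD post hoc
#'
#' @param groups named list of numeric vectors (>= 3 groups; with 2 use
#'   \code{\link{compareTwo}}).
#' @return list of class \code{"AnovaComparison"}: f_statistic, df,
#'   p_value, stars, tukey (data.frame: comparison, diff, p_adj, stars).
#' @export
compareMany <- function(groups) {
  stopIfNot(is.list(groups) && length(groups) >= 3,
            "need >= 3 groups (use compareTwo for 2)")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (stats::var(values) == 0) {
    cmb <- utils::combn(names(groups), 2)
    tuk <- data.frame(comparison = paste(cmb[2, ], cmb[1, ], sep = "-"),
                      diff = 0, p_adj = 1, stars = "ns")
    return(structure(list(f_statistic = 0, df = c(length(groups) - 1,
                                                  length(values) - length(groups)),
                          p_value = 1, stars = "ns", tukey = tuk),
                     class = "AnovaComparison"))
  }
  fit <- stats::aov(values ~ g)
  sm <- summary(fit)[[1]]
  f <- sm[["F value"]][1]
  p <- sm[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$g
  tuk <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                    p_adj = tk[, "p adj"],
                    stars = significanceStars(tk[, "p adj"]),
                    row.names = NULL)
  structure(list(f_statistic = f, df = unname(sm[["Df"]]), p_value = p,
                 stars = significanceStars(p), tukey = tuk),
            class = "AnovaComparison")
}

#' @export
print.AnovaComparison <- function(x, ...) {
  cat(sprintf("AnovaComparison: F(%d, %d) = %.3f, p = %.4g %s\n",
              x$df[1], x$df[2], x$f_statistic, x$p_value, x$stars))
  print(x$tukey)
  invisible(x)
}

#' Compare a condition readout against control
#'
#' Convenience wrapper: normalises the condition to paired controls and
#' tests condition vs control values.
#'
#' @param metric metric name (label only).
#' @param control,condition paired numeric vectors.
#' @param varEqual passed to \code{\link{compareTwo}}.
#' @return list of class \code{"ConditionComparison"}: metric,
#'   normalized (data.frame), mean_pct, sem_pct, test.
#' @export
conditionComparison <- function(metric, control, condition,
                                varEqual = FALSE) {
  norm <- normalizeToControl(control, condition)
  pct <- norm$normalized_pct[!norm$flagged]
  structure(list(metric = metric, normalized = norm,
                 mean_pct = mean(pct),
                 sem_pct = stats::sd(pct) / sqrt(length(pct)),
                 test = compareTwo(control, condition, varEqual = varEqual)),
            class = "ConditionComparison")
}

#' @export
print.ConditionComparison <- function(x, ...) {
  cat(sprintf("ConditionComparison [%s]: %.1f +/- %.1f %% of control, p = %.4g %s\n",
              x$metric, x$mean_pct, x$sem_pct, x$test$p_value, x$test$stars))
  invisible(x)
}
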