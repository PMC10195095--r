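#' Linear feature-conductivity relationship
#'
#' Ordinary least-squares regression of a conductivity on a tissue feature,
#' with the p-value from the F-test against the intercept-only model.
#' Effect sizes follow the coefficient of determination: weak for R^2 below
#' 0.3, moderate for R^2 between 0.3 and 0.5 (inclusive), strong above
#' 0.5. When two groups are supplied, control and MI are additionally fit
#' separately, and `reported_separately` is set when (a) significance at
#' p < 0.05 holds in exactly one group but not in the combined fit, or
#' (b) the two group R^2 values differ by more than 0.1.
#'
#' @param x feature values.
#' @param y conductivity values.
#' @param groups optional factor-like group labels (e.g. control/MI).
#' @return An object of class `feature_regression`: `combined` plus one
#'   entry per group, each a list with `slope`, `intercept`, `r_squared`,
#'   `p_value`, `effect_size`, `n`; and `reported_separately`.
#' @export
linear_relationship <- function(x, y, groups = NULL) {
  fit_one <- function(x, y, label) {
    if (length(x) < 3L)
      stop("need at least 3 points per fitted group", call. = FALSE)
    if (stats::var(x) == 0)
      myoconduct_error("myoconduct_degenerate_fit",
                       "zero variance in x: regression undefined")
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    r2 <- sm$r.squared
    fs <- sm$fstatistic
    p <- if (is.null(fs)) NA_real_ else
      stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
    if (is.na(p) && r2 >= 1 - 1e-12) p <- 0  # exactly collinear
    list(group = label,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, p_value = unname(p),
         effect_size = if (r2 < 0.3) "weak" else if (r2 <= 0.5) "moderate"
         else "strong",
         n = length(x))
  }
  out <- list(combined = fit_one(x, y, "all"))
  reported_separately <- FALSE
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (nlevels(groups) == 2L) {
      for (g in levels(groups)) {
        sel <- groups == g
        out[[g]] <- fit_one(x[sel], y[sel], g)
      }
    g1 <- out[[levels(groups)[1]]]; g2 <- out[[levels(groups)[2]]]
    sig <- c(g1$p_value < 0.05, g2$p_value < 0.05)
    rule_a <- sum(sig) == 1L && out$combined$p_value >= 0.05
    rule_b <- abs(g1$r_squared - g2$r_squared) > 0.1
    reported_separately <- isTRUE(rule_a || rule_b)
    }
  }
  structure(c(out, list(reported_separately = reported_separately)),
            class = "feature_regression")
}

#' @export
print.feature_regression <- function(x, ...) {
  cat("Linear feature-conductivity relationship\n")
  fits <- x[vapply(x, is.list, TRUE)]
  for (f in fits) {
    cat(sprintf("  %-8s n=%-3d slope %.4g  R^2 %.3f (%s)  p %.3g\n",
                f$group, f$n, f$slope, f$r_squared, f$effect_size, f$p_value))
  }
  if (isTRUE(x$reported_separately))
    cat("  (groups reported separately)\n")
  invisible(x)
}

#' Two-sample group comparison
#'
#' Student's two-sample t-test (pooled variance, two-sided) on a
#' conductivity or tissue feature between the control and MI groups, with
#' group summaries reported as mean +/- SD. Significance at p < 0.05.
#'
#' @param control,mi numeric vectors (at least 2 values each).
#' @return An object of class `group_comparison` with `t`, `df`, `p_value`,
#'   `significant`, and per-group `mean`/`sd`.
#' @export
group_compare <- function(control, mi) {
  if (length(control) < 2L || length(mi) < 2L)
    stop("need at least 2 values per group", call. = FALSE)
  tt <- stats::t.test(control, mi, var.equal = TRUE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, significant = tt$p.value < 0.05,
                 mean_control = mean(control), sd_control = stats::sd(control),
                 mean_mi = mean(mi), sd_mi = stats::sd(mi)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("control %.4g +/- %.4g vs MI %.4g +/- %.4g\n",
              x$mean_control, x$sd_control, x$mean_mi, x$sd_mi))
  cat(sprintf("  t = %.4g, df = %g, p = %.4g%s\n", x$t, x$df, x$p_value,
              if (x$significant) " (*)" else ""))
  invisible(x)
}
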