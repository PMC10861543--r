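# Group comparison with distribution-aware test selection, and correlation.

#' Compare groups with distribution-aware test selection
#'
#' Mirrors the standard clinical-statistics workflow: each group is screened
#' with the Shapiro-Wilk normality test at `alpha`. If every group is
#' consistent with normality, a parametric test is used (Welch two-sample
#' t-test for 2 groups, one-way ANOVA for more); otherwise the nonparametric
#' counterpart (Mann-Whitney U / Kruskal-Wallis). For more than two groups a
#' Bonferroni-corrected pairwise post-hoc table is included.
#'
#' @param samples Named (or unnamed) list of >= 2 numeric vectors, each of
#'   length >= 3.
#' @param alpha Significance level for both the normality screen and the
#'   reported `significant` flag.
#' @param var_equal Assume equal variances in the two-group t-test (default
#'   Welch).
#' @return An object of class `group_comparison`: list with `groups`
#'   (per-group n/mean/sd data frame), `normal` (logical), `test`,
#'   `statistic`, `p_value`, `significant`, `alpha`, and `posthoc` (pairwise
#'   p-value matrix or NULL).
#' @export
compare_groups <- function(samples, alpha = 0.05, var_equal = FALSE) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (any(vapply(samples, length, 1L) < 3))
    stop("each group needs at least 3 observations")
  nm <- names(samples)
  if (is.null(nm) || any(nm == ""))
    nm <- paste0("group", seq_along(samples))
  groups <- data.frame(group = nm,
                       n = vapply(samples, length, 1L),
                       mean = vapply(samples, mean, 1),
                       sd = vapply(samples, stats::sd, 1))
  # Shapiro-Wilk requires non-degenerate samples; a constant group is
  # trivially non-normal for test-selection purposes
  sw_p <- vapply(samples, function(x) {
    if (stats::sd(x) == 0) 0 else stats::shapiro.test(x)$p.value
  }, 1)
  normal <- all(sw_p > alpha)
  two <- length(samples) == 2
  if (normal && two) {
    ht <- stats::t.test(samples[[1]], samples[[2]], var.equal = var_equal)
    test <- if (var_equal) "t" else "t (Welch)"
  } else if (normal) {
    dat <- data.frame(y = unlist(samples),
                      g = factor(rep(nm, lengths(samples))))
    fit <- stats::aov(y ~ g, data = dat)
    tab <- summary(fit)[[1]]
    ht <- list(statistic = tab$`F value`[1], p.value = tab$`Pr(>F)`[1])
    test <- "ANOVA"
  } else if (two) {
    ht <- stats::wilcox.test(samples[[1]], samples[[2]], exact = FALSE)
    test <- "Mann-Whitney"
  } else {
    ht <- stats::kruskal.test(samples)
    test <- "Kruskal-Wallis"
  }
  posthoc <- NULL
  if (!two) {
    y <- unlist(samples)
    g <- factor(rep(nm, lengths(samples)), levels = nm)
    posthoc <- if (normal)
      stats::pairwise.t.test(y, g, p.adjust.method = "bonferroni",
                             pool.sd = FALSE)$p.value
    else
      stats::pairwise.wilcox.test(y, g, p.adjust.method = "bonferroni",
                                  exact = FALSE)$p.value
  }
  structure(list(groups = groups, shapiro_p = sw_p, normal = normal,
                 test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 significant = ht$p.value < alpha, alpha = alpha,
                 posthoc = posthoc),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  %-12s n = %2d, mean = %.4g, sd = %.4g\n",
                x$groups$group[i], x$groups$n[i], x$groups$mean[i],
                x$groups$sd[i]))
  cat(sprintf("  %s test: statistic = %.4g, p = %.4g (%ssignificant at %.2g)\n",
              x$test, x$statistic, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return The correlation coefficient r.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for zero-variance input")
  stats::cor(x, y, method = "pearson")
}
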