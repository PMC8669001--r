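#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples, the standard test for
#' per-object image measurements, which are rarely normal and tie often.
#' The p-value is computed by exact enumeration when
#' `min(n1, n2) <= 8` and the data are tie-free, and by the normal
#' approximation with mid-ranks and tie-corrected variance otherwise.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact enumeration
#'   path; `NULL` (default) selects it automatically as above.
#' @return A list with `U` (number of (x, y) pairs with x > y, counting
#'   ties as 1/2), `p_value` (two-tailed), `method` (`"exact"` or
#'   `"normal approximation"`), `n` (the two sample sizes).
#' @examples
#' mann_whitney_two_tailed(c(1, 2), c(3, 4))$p_value  # 1/3
#' @export
mann_whitney_two_tailed <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- !ties && min(length(x), length(y)) <= 8
  if (exact && ties)
    stop("exact enumeration requires tie-free samples")
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact))
  list(U = unname(wt$statistic), p_value = unname(wt$p.value),
       method = if (exact) "exact" else "normal approximation",
       n = c(length(x), length(y)))
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Kruskal-Wallis rank ANOVA (tie-corrected H) across three or more
#' groups, followed by Dunn's pairwise z-tests on the pooled mid-ranks
#' with tie-corrected variance and Bonferroni family-wise adjustment
#' over all pairs.
#'
#' @param groups named list of numeric samples (>= 3, each non-empty).
#' @return A `ComparisonResult` (see [summarize_metric()]) whose
#'   `pairwise` element holds one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @examples
#' kruskal_dunn(list(a = 1:3, b = 4:6, c = 7:9))$statistic  # H = 7.2
#' @export
kruskal_dunn <- function(groups) {
  if (length(groups) < 3) stop("need at least 3 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("every group must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  if (diff(range(pooled)) == 0) {
    # no rank variation at all: H = 0 by definition (kruskal.test
    # returns 0/0 because its tie-correction divisor vanishes)
    kw <- list(statistic = 0, p.value = 1)
  } else {
    kw <- kruskal.test(groups)
  }
  g <- rep(names(groups), sizes)
  N <- length(pooled)
  rk <- rank(pooled)  # mid-ranks
  rbar <- tapply(rk, g, mean)
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt(max(var_base, 0) * (1 / sizes[[a]] + 1 / sizes[[b]]))
    z[k] <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         z = z, p_value = p,
                         p_adjusted = p.adjust(p, method = "bonferroni"))
  structure(list(metric = NA_character_, groups = names(groups),
                 n = as.integer(sizes),
                 median = vapply(groups, median, numeric(1)),
                 iqr = t(vapply(groups, quantile, numeric(2),
                                probs = c(0.25, 0.75), names = FALSE)),
                 test = "Kruskal-Wallis with Dunn's post-hoc (Bonferroni)",
                 statistic = unname(kw$statistic),
                 p_value = kw$p.value, pairwise = pairwise,
                 alpha = 0.05),
            class = "ComparisonResult")
}

#' Summarize and compare a metric across groups
#'
#' Median and interquartile range per group with the per-group n (the
#' number of objects/cells analyzed), then the group comparison the
#' group count calls for: none (single group, descriptive output only),
#' the two-tailed Mann-Whitney U test (two groups), or Kruskal-Wallis
#' with Dunn's post-hoc comparisons (three or more).
#'
#' @param table a measurement data frame.
#' @param metric name of the numeric column to compare.
#' @param grouping name of the grouping column.
#' @param alpha significance level recorded in the result.
#' @return A `ComparisonResult`: `metric`, `groups`, `n`, `median`,
#'   `iqr` (rows = groups, columns = 25%/75%), `test`, `statistic`,
#'   `p_value`, optional `pairwise`, `alpha`.
#' @export
summarize_metric <- function(table, metric, grouping = "condition",
                             alpha = 0.05) {
  if (!metric %in% names(table)) stop("metric '", metric, "' not present")
  if (!grouping %in% names(table))
    stop("grouping column '", grouping, "' not present")
  vals <- table[[metric]]
  keep <- !is.na(vals) & !is.na(table[[grouping]])
  groups <- split(vals[keep], as.character(table[[grouping]][keep]),
                  drop = TRUE)
  if (length(groups) == 0) stop("no non-missing data for '", metric, "'")
  base <- list(metric = metric, groups = names(groups),
               n = as.integer(lengths(groups)),
               median = vapply(groups, median, numeric(1)),
               iqr = t(vapply(groups, quantile, numeric(2),
                              probs = c(0.25, 0.75), names = FALSE)),
               test = "none", statistic = NA_real_, p_value = NA_real_,
               alpha = alpha)
  if (length(groups) == 1) {
    return(structure(base, class = "ComparisonResult"))
  }
  if (length(groups) == 2) {
    mw <- mann_whitney_two_tailed(groups[[1]], groups[[2]])
    base$test <- paste0("two-tailed Mann-Whitney U (", mw$method, ")")
    base$statistic <- mw$U
    base$p_value <- mw$p_value
    return(structure(base, class = "ComparisonResult"))
  }
  res <- kruskal_dunn(groups)
  res$metric <- metric
  res$alpha <- alpha
  res
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat("ComparisonResult", if (!is.na(x$metric)) paste0(" [", x$metric, "]"),
      "\n", sep = "")
  for (i in seq_along(x$groups))
    cat(sprintf("  %s: n = %d, median = %.4g, IQR = [%.4g, %.4g]\n",
                x$groups[i], x$n[i], x$median[i], x$iqr[i, 1],
                x$iqr[i, 2]))
  if (x$test != "none")
    cat(sprintf("  %s: statistic = %.4g, p = %.4g\n", x$test,
                x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (Dunn, Bonferroni-adjusted):\n")
    for (k in seq_len(nrow(x$pairwise)))
      cat(sprintf("    %s vs %s: z = %.3f, adj. p = %.4g\n",
                  x$pairwise$group1[k], x$pairwise$group2[k],
                  x$pairwise$z[k], x$pairwise$p_adjusted[k]))
  }
  invisible(x)
}

#' @export
as.data.frame.ComparisonResult <- function(x, ...) {
  data.frame(metric = x$metric, group = x$groups, n = x$n,
             median = x$median, q25 = x$iqr[, 1], q75 = x$iqr[, 2],
             test = x$test, statistic = x$statistic,
             p_value = x$p_value, row.names = NULL)
}
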