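# Group summaries and unpaired two-sample t-tests, from raw ratios or from
# published summary statistics (n, mean, SE). The pooled (equal-variance)
# Student's t is the default variant; Welch is available by flag. Two-tailed
# throughout; significance threshold 0.05; no multiple-testing correction
# (the number of comparisons is reported instead).

#' Summarize one group of ratios
#'
#' Mean and standard error of the mean (sample SD with n-1 denominator over
#' sqrt(n)). Singleton groups are reported with `se = 0` and
#' `se_defined = FALSE`, matching how an n = 1 group is reported
#' descriptively without an SE.
#'
#' @param x numeric vector of per-ear ratios (or NULL when constructing from
#'   published summaries).
#' @param label group name.
#' @param n,mean,se supply these directly to wrap published summaries.
#' @return object of class `group_summary`: list(label, n, mean, se,
#'   se_defined).
#' @export
group_summary <- function(x = NULL, label = NA_character_, n = NULL,
                          mean = NULL, se = NULL) {
  if (is.null(x)) {
    stopifnot(!is.null(n), !is.null(mean), !is.null(se))
    if (n < 1) stop("n must be >= 1")
    if (se < 0) stop("se must be >= 0")
    return(structure(list(label = label, n = as.integer(n), mean = mean,
                          se = se, se_defined = n > 1L),
                     class = "group_summary"))
  }
  if (length(x) < 1L) stop("empty group")
  n <- length(x)
  se <- if (n > 1L) stats::sd(x) / sqrt(n) else 0
  structure(list(label = label, n = n, mean = base::mean(x), se = se,
                 se_defined = n > 1L),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary %s> n=%d mean=%.4g se=%s\n", x$label, x$n,
              x$mean,
              if (x$se_defined) sprintf("%.4g", x$se) else "NA (n = 1)"))
  invisible(x)
}

#' Summarize every group in a ratios table
#'
#' @param df data.frame with columns `label` (group) and `value` (ratio).
#' @return data.frame with label, n, mean, se, se_defined.
#' @export
summarize_groups <- function(df) {
  stopifnot(all(c("label", "value") %in% names(df)))
  out <- lapply(split(df$value, df$label), function(v) v)
  res <- do.call(rbind, lapply(names(out), function(lb) {
    g <- group_summary(out[[lb]], label = lb)
    data.frame(label = lb, n = g$n, mean = g$mean, se = g$se,
               se_defined = g$se_defined, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

ttest_result <- function(t, df, p, variant) {
  structure(list(t = t, df = df, p = p, variant = variant),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("<ttest_result %s> t=%.4g df=%.4g p=%.4g\n",
              x$variant, x$t, x$df, x$p))
  invisible(x)
}

#' Unpaired two-sample t-test from group summaries
#'
#' Reconstructs each group's sample variance as `s^2 = se^2 * n` and applies
#' the pooled (equal-variance) Student's t-test
#' `t = (m1 - m2) / (s_p * sqrt(1/n1 + 1/n2))`,
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`, `df = n1 + n2 - 2`,
#' or Welch's unequal-variance variant. Two-tailed p-value.
#'
#' @param g1,g2 [group_summary()] objects with `n >= 2` and `se > 0`.
#' @param variant "pooled" (default) or "welch".
#' @return `ttest_result` with `t`, `df`, `p`, `variant`.
#' @export
ttest_from_summary <- function(g1, g2, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  for (g in list(g1, g2)) {
    if (g$n < 2L) stop("both groups need n >= 2 for a t-test")
    if (g$se <= 0) stop("both groups need se > 0")
  }
  v1 <- g1$se^2 * g1$n; v2 <- g2$se^2 * g2$n   # sample variances
  if (variant == "pooled") {
    df <- g1$n + g2$n - 2
    sp2 <- ((g1$n - 1) * v1 + (g2$n - 1) * v2) / df
    t <- (g1$mean - g2$mean) / sqrt(sp2 * (1 / g1$n + 1 / g2$n))
  } else {
    a <- v1 / g1$n; b <- v2 / g2$n
    t <- (g1$mean - g2$mean) / sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (g1$n - 1) + b^2 / (g2$n - 1))
  }
  p <- 2 * stats::pt(-abs(t), df)
  ttest_result(t, df, p, variant)
}

#' Unpaired two-sample t-test from raw samples
#'
#' Identical to [ttest_from_summary()] applied to the samples' own
#' summaries; kept as a separate entry point for synthetic cohorts where the
#' raw per-ear ratios exist.
#'
#' @param x1,x2 numeric vectors, each of length >= 2.
#' @param variant "pooled" (default) or "welch".
#' @return `ttest_result`.
#' @export
ttest_from_samples <- function(x1, x2, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(x1) < 2L || length(x2) < 2L) stop("each sample needs n >= 2")
  if (stats::sd(x1) == 0 && stats::sd(x2) == 0)
    stop("degenerate zero-variance pair")
  ttest_from_summary(group_summary(x1), group_summary(x2), variant = variant)
}

#' All pairwise group comparisons with significance flags
#'
#' Pooled two-sample t-tests between every pair of groups with n >= 2;
#' singleton groups are listed descriptively and excluded from testing, as a
#' single-ear class can only be reported, not tested. Flags use alpha = 0.05
#' with no multiple-testing correction; `n_comparisons` records how many
#' tests were run.
#'
#' @param df data.frame with columns `label` and `value`.
#' @param variant "pooled" (default) or "welch".
#' @param alpha significance threshold.
#' @return list with `tests` (data.frame: group1, group2, t, df, p,
#'   significant), `summaries`, `descriptive_only` (labels of n = 1 groups),
#'   `n_comparisons`, `alpha`.
#' @export
compare_all <- function(df, variant = c("pooled", "welch"), alpha = 0.05) {
  variant <- match.arg(variant)
  summ <- summarize_groups(df)
  testable <- summ$label[summ$n >= 2L]
  if (length(testable) < 2L) {
    tests <- data.frame(group1 = character(0), group2 = character(0),
                        t = numeric(0), df = numeric(0), p = numeric(0),
                        significant = logical(0))
  } else {
    pairs <- utils::combn(testable, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      g1 <- with(summ[summ$label == a, ],
                 group_summary(n = n, mean = mean, se = se, label = a))
      g2 <- with(summ[summ$label == b, ],
                 group_summary(n = n, mean = mean, se = se, label = b))
      tt <- ttest_from_summary(g1, g2, variant = variant)
      data.frame(group1 = a, group2 = b, t = tt$t, df = tt$df, p = tt$p,
                 significant = tt$p < alpha, stringsAsFactors = FALSE)
    }))
    rownames(tests) <- NULL
  }
  list(tests = tests, summaries = summ,
       descriptive_only = summ$label[summ$n < 2L],
       n_comparisons = nrow(tests), alpha = alpha)
}
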