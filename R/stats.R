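# Group-comparison statistics for feature tables: Shapiro-Wilk normality
# screening, pairwise Student's t tests, Bonferroni correction and
# significance flagging. Each eye is one observation. The substantive tests
# are base R (shapiro.test, t.test, chisq.test, aov); this module supplies
# the pipeline and flag bookkeeping around them.

#' Shapiro-Wilk normality screen
#'
#' @param values numeric sample, n >= 3, not constant.
#' @return The Shapiro-Wilk p value.
#' @export
shapiro_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3L)
    stop("Shapiro-Wilk needs at least 3 observations", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("constant sample: normality test is degenerate", call. = FALSE)
  stats::shapiro.test(values)$p.value
}

#' Unpaired two-sided Student's t test
#'
#' Classical pooled-variance (equal-variance) two-sample t test, two-sided.
#' Welch's unequal-variance form is available behind `welch = TRUE`.
#'
#' @param a,b numeric samples, each n >= 2.
#' @param welch use Welch's correction instead of pooled variance.
#' @return List with `t` (statistic), `p` (two-sided p value), `df`.
#' @export
pairwise_ttest <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  ht <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value, df = unname(ht$parameter))
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m` for `m` comparisons, reported at 4 decimals (0.05 over the
#' three group pairs gives the conventional 0.0167).
#'
#' @param alpha family-wise significance level.
#' @param m number of comparisons (>= 1).
#' @return Corrected threshold, rounded to 4 decimals.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 3L) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be a positive integer", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  round(alpha / m, 4)
}

star_flag <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
}

#' Pairwise group comparison of one feature
#'
#' Runs the unpaired two-sided Student's t test on every pair of groups for
#' the chosen feature column, reporting the mean difference, percent change
#' of the second group relative to the first, the p value, star flags at
#' 0.05 / 0.01 / 0.001 and the Bonferroni dagger at `alpha / n_pairs`.
#' Missing (flagged) feature values are dropped per comparison with a count
#' in the result.
#'
#' @param table a data frame with a `group` column and feature columns (see
#'   [simulate_cohort()] or [quantify_batch()] plus a group assignment).
#' @param feature feature column name, e.g. `"A_PID"`.
#' @param alpha family-wise level for the star and dagger flags.
#' @param welch use Welch's t test instead of pooled-variance.
#' @return A `data.frame`, one row per group pair: `feature`, `group1`,
#'   `group2`, `mean1`, `mean2`, `mean_diff`, `percent_change`, `t`, `p`,
#'   `stars`, `bonferroni` (logical dagger), `n_dropped`.
#' @export
compare_groups <- function(table, feature, alpha = 0.05, welch = FALSE) {
  if (!feature %in% names(table))
    stop(sprintf("feature column '%s' not present", feature), call. = FALSE)
  if (!"group" %in% names(table))
    stop("table needs a 'group' column", call. = FALSE)
  groups <- unique(as.character(table$group))
  if (length(groups) < 2L)
    stop("need at least 2 groups to compare", call. = FALSE)
  groups <- sort(groups)  # row-order invariance
  pairs <- utils::combn(groups, 2)
  thr <- bonferroni_threshold(alpha, ncol(pairs))
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    x1 <- table[[feature]][table$group == g1]
    x2 <- table[[feature]][table$group == g2]
    dropped <- sum(is.na(x1)) + sum(is.na(x2))
    tt <- pairwise_ttest(x1, x2, welch = welch)
    m1 <- mean(x1, na.rm = TRUE); m2 <- mean(x2, na.rm = TRUE)
    data.frame(feature = feature, group1 = g1, group2 = g2,
               mean1 = m1, mean2 = m2, mean_diff = m2 - m1,
               percent_change = 100 * (m2 - m1) / m1,
               t = tt$t, p = tt$p, stars = star_flag(tt$p),
               bonferroni = !is.na(tt$p) && tt$p < thr,
               n_dropped = dropped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "bonferroni_threshold") <- thr
  out
}

#' Pearson chi-squared test on a contingency table
#'
#' Uncorrected by default (no Yates continuity correction); the corrected
#' form is available behind `correct = TRUE`.
#'
#' @param counts a 2 x K matrix of counts.
#' @param correct apply Yates continuity correction.
#' @return List with `statistic`, `p`, `df`.
#' @export
categorical_chi2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate contingency table", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' One-way ANOVA across groups
#'
#' @param samples named list of numeric vectors (>= 2 groups, >= 2 values
#'   each).
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_groups <- function(samples) {
  if (length(samples) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(samples, function(s) sum(!is.na(s)), 0L) < 2L))
    stop("each group needs at least 2 observations", call. = FALSE)
  df <- data.frame(
    y = unlist(samples, use.names = FALSE),
    g = factor(rep(names(samples) %||% seq_along(samples),
                   vapply(samples, length, 0L))))
  fit <- stats::aov(y ~ g, data = df)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df_between = s[["Df"]][1], df_within = s[["Df"]][2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full comparison report over all seven features
#'
#' Runs [compare_groups()] for each feature column present and binds the
#' results.
#'
#' @inheritParams compare_groups
#' @param features character vector of feature columns (default: the seven
#'   standard biomarkers found in the table).
#' @return A `data.frame` of all pairwise comparisons.
#' @export
compare_all_features <- function(table,
                                 features = intersect(
                                   c("AA", "VA", "AVAR", "T_PID", "A_PID",
                                     "V_PID", "AV_PIDR"), names(table)),
                                 alpha = 0.05, welch = FALSE) {
  out <- do.call(rbind, lapply(features, function(f)
    compare_groups(table, f, alpha = alpha, welch = welch)))
  rownames(out) <- NULL
  out
}
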