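#' Container for a statistical test result
#'
#' @param test test name.
#' @param statistic test statistic.
#' @param p_value two-sided p-value in `[0, 1]`.
#' @param p_adjusted multiplicity-adjusted p-value (>= `p_value`), or `NA`.
#' @param effect_size optional effect-size estimate.
#' @param category optional effect-size category label.
#' @param comparison label of the groups/timepoints compared.
#' @param extra optional list of additional elements (e.g. fitted curves).
#' @return object of class `stat_result`.
#' @export
stat_result <- function(test, statistic, p_value, p_adjusted = NA_real_,
                        effect_size = NULL, category = NULL,
                        comparison = "", extra = NULL) {
  stopifnot(p_value >= 0, p_value <= 1,
            is.na(p_adjusted) || (p_adjusted >= p_value && p_adjusted <= 1))
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), p_adjusted = p_adjusted,
                 effect_size = effect_size, category = category,
                 comparison = comparison, extra = extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s%s: statistic = %.4g, p = %.4g", x$test,
              if (nzchar(x$comparison)) paste0(" [", x$comparison, "]") else "",
              x$statistic, x$p_value))
  if (!is.na(x$p_adjusted)) cat(sprintf(", adj. p = %.4g", x$p_adjusted))
  if (!is.null(x$effect_size))
    cat(sprintf(", effect = %.3g (%s)", x$effect_size,
                x$category %||% ""))
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with midrank ties. The p-value is exact (full
#' enumeration of the permutation distribution) when the combined sample
#' size is at most 12 and there are no ties -- group sizes in this study
#' design (6-10 eyes) make exact inference feasible at test scale -- and
#' a tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param x,y numeric samples (each non-empty).
#' @param comparison label stored in the result.
#' @return a [stat_result()] whose `statistic` is the U of the first
#'   sample.
#' @export
mann_whitney_u <- function(x, y, comparison = "") {
  if (length(x) < 1 || length(y) < 1) stopf("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))  # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  exact <- (n1 + n2 <= 12) && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  stat_result("Mann-Whitney U", u, ht$p.value, comparison = comparison)
}

check_blocks <- function(block_matrix) {
  m <- as.matrix(block_matrix)
  if (!is.numeric(m) || nrow(m) < 2 || ncol(m) < 2)
    stopf("block matrix must be numeric with >= 2 subjects and >= 2 treatments")
  if (anyNA(m))
    stopf("incomplete blocks: the Friedman test requires complete subject x treatment blocks")
  m
}

#' Friedman test on complete blocks
#'
#' Nonparametric repeated-measures test from within-block (subject)
#' midranks across treatments (here typically timepoints).
#'
#' @param block_matrix numeric matrix, subjects in rows, treatments in
#'   columns; no missing cells.
#' @param comparison label stored in the result.
#' @return a [stat_result()] with the Friedman chi-squared statistic.
#' @seealso [friedman_posthoc()] for Bonferroni-corrected pairwise
#'   follow-up.
#' @export
friedman_test <- function(block_matrix, comparison = "") {
  m <- check_blocks(block_matrix)
  ht <- friedman.test(m)
  stat <- ht$statistic; p <- ht$p.value
  if (!is.finite(stat)) {  # every block fully tied: no evidence at all
    stat <- 0; p <- 1
  }
  stat_result("Friedman", stat, p, comparison = comparison)
}

#' Bonferroni-corrected pairwise post hoc for the Friedman test
#'
#' Pairwise Wilcoxon signed-rank tests between all treatment columns,
#' with p-values multiplied by the number of comparisons and clipped at 1
#' (Bonferroni).
#'
#' @param block_matrix as in [friedman_test()].
#' @return data frame with columns `a`, `b`, `p_value`, `p_adjusted`.
#' @export
friedman_posthoc <- function(block_matrix) {
  m <- check_blocks(block_matrix)
  cn <- colnames(m) %||% paste0("T", seq_len(ncol(m)))
  pairs <- utils::combn(seq_len(ncol(m)), 2)
  p <- apply(pairs, 2, function(ij)
    suppressWarnings(wilcox.test(m[, ij[1]], m[, ij[2]],
                                 paired = TRUE))$p.value)
  data.frame(a = cn[pairs[1, ]], b = cn[pairs[2, ]], p_value = p,
             p_adjusted = p.adjust(p, method = "bonferroni"),
             stringsAsFactors = FALSE)
}

#' Pearson correlation with effect-size category
#'
#' Sample correlation coefficient with two-sided p-value via the t
#' transform, categorized by the conventional cut-offs `|r| >= 0.1`
#' (small), `>= 0.3` (medium), `>= 0.5` (large).
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @param comparison label stored in the result.
#' @return a [stat_result()] with `effect_size = r`.
#' @export
pearson_corr <- function(x, y, comparison = "") {
  if (length(x) != length(y) || length(x) < 3)
    stopf("x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0) stopf("constant input has no correlation")
  ht <- cor.test(x, y, method = "pearson")
  r <- unname(ht$estimate)
  category <- if (abs(r) >= 0.5) "large" else if (abs(r) >= 0.3) "medium"
    else if (abs(r) >= 0.1) "small" else "negligible"
  stat_result("Pearson correlation", r, ht$p.value, effect_size = r,
              category = category, comparison = comparison)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS statistic against a normal distribution with the
#' sample's own mean and standard deviation, with the standard asymptotic
#' p-value. Because the parameters are estimated from the data, the
#' p-value is conservative (the Lilliefors situation); the result is
#' advisory only -- the analysis workflow proceeds nonparametrically
#' regardless.
#'
#' @param x numeric vector of length >= 3.
#' @param comparison label stored in the result.
#' @return a [stat_result()] with the KS D statistic.
#' @export
ks_normality <- function(x, comparison = "") {
  if (length(x) < 3) stopf("need at least 3 observations")
  if (sd(x) == 0) stopf("constant sample")
  ht <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  stat_result("Kolmogorov-Smirnov normality", ht$statistic, ht$p.value,
              comparison = comparison)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Estimates per-group survival by the Kaplan-Meier method and compares
#' groups with the log-rank test.
#'
#' @param times follow-up times (>= 0).
#' @param events event indicators (1 = event, 0 = censored).
#' @param groups group labels (at least two distinct).
#' @param comparison label stored in the result.
#' @return a [stat_result()] with the log-rank chi-squared statistic; the
#'   fitted `survival::survfit` curves are in `$extra$fit`.
#' @export
km_logrank <- function(times, events, groups, comparison = "") {
  stopifnot(length(times) == length(events), length(times) == length(groups))
  if (any(times < 0)) stopf("times must be >= 0")
  if (!all(events %in% c(0, 1))) stopf("events must be binary 0/1")
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stopf("need at least two groups for the log-rank test")
  if (sum(events) == 0)
    stopf("log-rank statistic undefined: no events observed")
  s <- survival::Surv(times, events)
  sd_ <- survival::survdiff(s ~ groups)
  df <- length(sd_$n) - 1
  p <- pchisq(sd_$chisq, df, lower.tail = FALSE)
  fit <- survival::survfit(s ~ groups)
  stat_result("log-rank", sd_$chisq, p, comparison = comparison,
              extra = list(fit = fit, df = df,
                           observed = sd_$obs, expected = sd_$exp))
}

#' Per-timepoint group comparisons of a cohort table
#'
#' For every timepoint and every pair of groups, runs [mann_whitney_u()]
#' on the chosen variable; optionally screens the pooled variable with
#' [ks_normality()]. This is the workhorse used in analysis reports.
#'
#' @param cohort a long-format cohort table ([generate_cohort()] format).
#' @param variable outcome column name.
#' @param groups the two group labels to compare; default all pairs.
#' @return data frame with one row per timepoint x pair: `day`, `a`, `b`,
#'   `u`, `p_value`.
#' @export
compare_groups <- function(cohort, variable, groups = NULL) {
  stopifnot(is.data.frame(cohort),
            all(c("group", "day", variable) %in% names(cohort)))
  gs <- groups %||% unique(cohort$group)
  if (length(gs) < 2) stopf("need at least two groups")
  pairs <- utils::combn(gs, 2)
  out <- list()
  for (d in sort(unique(cohort$day))) {
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      xa <- cohort[[variable]][cohort$group == a & cohort$day == d]
      xb <- cohort[[variable]][cohort$group == b & cohort$day == d]
      if (length(xa) == 0 || length(xb) == 0) next
      r <- mann_whitney_u(xa, xb,
                          comparison = sprintf("%s vs %s, day %s", a, b, d))
      out[[length(out) + 1L]] <-
        data.frame(day = d, a = a, b = b, u = r$statistic,
                   p_value = r$p_value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
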