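te_test_result <- function(statistic_name, statistic, df, p_value,
                           method, note = NA_character_, extra = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(statistic_name = statistic_name,
                 statistic = unname(statistic),
                 df = if (is.null(df)) NA_real_ else unname(df),
                 p_value = unname(p_value), method = method, note = note,
                 extra = extra),
            class = "te_test")
}

#' @export
print.te_test <- function(x, ...) {
  cat(sprintf("%s: %s = %.6g%s, p = %.4g%s\n", x$method, x$statistic_name,
              x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %g", x$df),
              x$p_value,
              if (is.na(x$note)) "" else paste0("  [", x$note, "]")))
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' H statistic with tie correction and chi-squared p-value on k - 1 degrees
#' of freedom (delegates to [stats::kruskal.test()]).  Used for the
#' three-species copy-number and frequency-distribution comparisons.
#'
#' @param groups list of two or more numeric vectors.
#' @return a `te_test` (statistic_name `"H"`).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("kruskal_wallis needs at least two groups")
  stopifnot(all(vapply(groups, length, 1L) > 0L))
  kt <- stats::kruskal.test(groups)
  te_test_result("H", kt$statistic, kt$parameter, kt$p.value,
                 "Kruskal-Wallis rank sum test")
}

#' Wilcoxon signed rank test on paired observations
#'
#' V = sum of ranks of positive differences; zero differences are dropped
#' before ranking; large samples use the normal approximation with optional
#' continuity correction (delegates to [stats::wilcox.test()]).  Used for
#' the paired between-species copy-number comparison.
#'
#' @param paired_a,paired_b numeric vectors of equal length.
#' @param continuity apply the continuity correction in the normal
#'   approximation.
#' @return a `te_test` (statistic_name `"V"`); all-zero differences give a
#'   degenerate result flagged in `note` with `p_value = NA`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, continuity = TRUE) {
  stopifnot(length(paired_a) == length(paired_b))
  if (all(paired_a == paired_b))
    return(te_test_result("V", 0, NULL, NA_real_,
                          "Wilcoxon signed rank test",
                          note = "degenerate: all differences zero"))
  wt <- suppressWarnings(stats::wilcox.test(paired_a, paired_b,
                                            paired = TRUE,
                                            correct = continuity))
  te_test_result("V", wt$statistic, NULL, wt$p.value, wt$method)
}

#' Mann-Whitney rank-sum test for two groups
#'
#' U statistic of the first group (number of (a, b) pairs with a > b,
#' counting ties as half) with tie-corrected normal approximation (delegates
#' to [stats::wilcox.test()]).  Used for the arms-versus-pericentromere
#' density comparisons.
#'
#' @param group_a,group_b numeric vectors.
#' @param continuity apply the continuity correction.
#' @return a `te_test` (statistic_name `"U"`, convention: U of `group_a`).
#' @export
rank_sum <- function(group_a, group_b, continuity = TRUE) {
  stopifnot(length(group_a) > 0L, length(group_b) > 0L)
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            correct = continuity,
                                            exact = FALSE))
  te_test_result("U", wt$statistic, NULL, wt$p.value, wt$method)
}

#' Poisson regression of counts on a categorical group
#'
#' Log-link Poisson GLM `count ~ group`; each non-baseline coefficient is
#' log(mean_group / mean_baseline) at the MLE, with Wald z statistics.  Used
#' for near-gene insertion-count comparisons between species.
#'
#' @param counts non-negative integer counts.
#' @param group_labels group label per count (>= 2 groups); the first factor
#'   level is the baseline.
#' @return list with `baseline`, `coefficients` (data.table: group,
#'   estimate, z, p_value, flagged), and `fit` (the glm object).  Groups
#'   whose mean is zero have `estimate = -Inf` and are flagged.
#' @export
poisson_glm_counts <- function(counts, group_labels) {
  stopifnot(length(counts) == length(group_labels),
            all(counts >= 0), all(counts == round(counts)))
  g <- factor(group_labels)
  if (nlevels(g) < 2L) stop("poisson_glm_counts needs at least two groups")
  fit <- stats::glm(counts ~ g, family = stats::poisson())
  sm <- summary(fit)$coefficients
  lv <- levels(g)[-1L]
  rows <- paste0("g", lv)
  means <- tapply(counts, g, mean)
  co <- data.table::data.table(
    group = lv,
    estimate = unname(sm[rows, "Estimate"]),
    z = unname(sm[rows, "z value"]),
    p_value = unname(sm[rows, "Pr(>|z|)"]),
    flagged = FALSE)
  zero <- means[lv] == 0
  if (any(zero)) {
    co[zero, `:=`(estimate = -Inf, flagged = TRUE)]
  }
  if (means[[1L]] == 0)
    warning("baseline group mean is zero; coefficients are unstable")
  list(baseline = levels(g)[1L], coefficients = co[], fit = fit)
}
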