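# Group-comparison statistics used throughout the quantification:
# two-sided Student t-test, one-way ANOVA with Bonferroni-adjusted
# pairwise post tests, chi-squared on contingency tables.

#' Compare groups with the study's standard tests
#'
#' * `two_group`: two-sided Student's t-test (equal variances by
#'   default; set `var_equal = FALSE` for Welch).
#' * `multi_group`: one-way ANOVA, followed by pairwise equal-variance
#'   t-tests with Bonferroni adjustment.
#' * `categorical`: chi-squared test on a contingency table (no
#'   continuity correction by default).
#'
#' @param values_by_group For the numeric designs, a named list of
#'   numeric vectors (one per group); for `categorical`, a contingency
#'   table or matrix of counts.
#' @param design `"two_group"`, `"multi_group"` or `"categorical"`.
#' @param var_equal Use the classic equal-variance t statistic.
#' @param correct Continuity correction for the chi-squared test.
#' @return A `comparison_result`: `test`, `statistic`, `p_value`, group
#'   summaries (mean, SEM, n) and, for `multi_group`, the
#'   Bonferroni-adjusted pairwise p-value matrix in `$pairwise`.
#' @export
#' @examples
#' compare_groups(list(a = rnorm(8), b = rnorm(8)))$p_value
compare_groups <- function(values_by_group,
                           design = c("two_group", "multi_group",
                                      "categorical"),
                           var_equal = TRUE, correct = FALSE) {
  design <- match.arg(design)

  if (design == "categorical") {
    tab <- as.matrix(values_by_group)
    if (any(tab < 0) || length(tab) < 4)
      stop("categorical design requires a contingency table of counts",
           call. = FALSE)
    ht <- chisq.test(tab, correct = correct)
    return(structure(list(test = "chi-squared", statistic =
                            unname(ht$statistic),
                          p_value = ht$p.value, groups = NULL,
                          adjustment = "none"),
                     class = "comparison_result"))
  }

  stopifnot(is.list(values_by_group))
  if (is.null(names(values_by_group)))
    names(values_by_group) <- paste0("g", seq_along(values_by_group))
  ns <- lengths(values_by_group)
  if (any(ns < 2)) stop("each group needs at least 2 observations",
                        call. = FALSE)
  vars <- vapply(values_by_group, var, numeric(1))
  if (all(vars == 0)) stop("all groups have zero variance", call. = FALSE)
  summaries <- data.frame(
    group = names(values_by_group), n = as.integer(ns),
    mean = vapply(values_by_group, mean, numeric(1)),
    sem = sqrt(vars / ns))

  if (design == "two_group") {
    if (length(values_by_group) != 2)
      stop("two_group design requires exactly 2 groups", call. = FALSE)
    ht <- t.test(values_by_group[[1]], values_by_group[[2]],
                 var.equal = var_equal)
    return(structure(list(test = if (var_equal) "Student t" else "Welch t",
                          statistic = unname(ht$statistic),
                          p_value = ht$p.value, groups = summaries,
                          adjustment = "none"),
                     class = "comparison_result"))
  }

  if (length(values_by_group) < 3)
    stop("multi_group design requires at least 3 groups", call. = FALSE)
  values <- unlist(values_by_group, use.names = FALSE)
  grp <- factor(rep(names(values_by_group), ns),
                levels = names(values_by_group))
  fit <- aov(values ~ grp)
  an <- summary(fit)[[1]]
  cmb <- utils::combn(names(values_by_group), 2)
  raw <- apply(cmb, 2, function(pr)
    t.test(values_by_group[[pr[1]]], values_by_group[[pr[2]]],
           var.equal = var_equal)$p.value)
  pairwise <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                         p_raw = raw,
                         p_adjusted = p.adjust(raw, method = "bonferroni"))
  structure(list(test = "one-way ANOVA + Bonferroni",
                 statistic = an[["F value"]][1],
                 p_value = an[["Pr(>F)"]][1],
                 groups = summaries, pairwise = pairwise,
                 adjustment = "bonferroni"),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>", x$test, "\n")
  cat(sprintf("  statistic = %.4g, p = %.4g (adjustment: %s)\n",
              x$statistic, x$p_value, x$adjustment))
  if (!is.null(x$groups)) print(x$groups, digits = 4)
  invisible(x)
}
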