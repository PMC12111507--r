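#' Two-sample t test from summary statistics
#'
#' Computes the Student or Welch two-sample t test directly from per-group
#' `(n, mean, sd)` summaries, as needed when only a published table is
#' available. The Welch variant (default) uses the Satterthwaite degrees
#' of freedom; the pooled variant uses the classical `n1 + n2 - 2`.
#'
#' @param a,b per-group summaries: numeric vectors or lists with elements
#'   `n`, `mean`, `sd` (`n >= 2`, `sd >= 0`).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return list with `t`, `df` and two-sided `p`.
#' @examples
#' t_test_from_summary(c(n = 12, mean = 15.5, sd = 1.56),
#'                     c(n = 11, mean = 13.36, sd = 2.57))
#' @export
t_test_from_summary <- function(a, b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  a <- as.list(a); b <- as.list(b)
  for (s in list(a, b)) {
    if (!all(c("n", "mean", "sd") %in% names(s))) stop("summaries need n, mean, sd")
    if (s$n < 2) stop("each group needs n >= 2")
    if (s$sd < 0) stop("sd must be >= 0")
  }
  if (a$sd == 0 && b$sd == 0 && a$mean == b$mean)
    stop("both groups degenerate: zero sd and equal means")
  if (variant == "welch") {
    v1 <- a$sd^2 / a$n; v2 <- b$sd^2 / b$n
    t <- (a$mean - b$mean) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (a$n - 1) + v2^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Mann-Whitney U test
#'
#' Exact enumeration (via the null U distribution) when `n1 * n2 <= 400`
#' and the data carry no ties, otherwise the tie-corrected normal
#' approximation without continuity correction. Two-sided.
#'
#' @param x,y nonempty numeric vectors.
#' @param method `"auto"` (default rule above), `"exact"` or
#'   `"normal_approx"`.
#' @return list with the `U` statistic (for `x`) and two-sided `p`.
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "normal_approx")) {
  method <- match.arg(method)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- switch(method,
                  auto = length(x) * length(y) <= 400 && !ties,
                  exact = TRUE, normal_approx = FALSE)
  if (exact && ties)
    stop("exact method is unavailable with ties; use normal_approx")
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p = min(wt$p.value, 1))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test with the minimum-likelihood two-sided rule:
#' the p-value sums the probabilities of every table with the observed
#' margins whose probability does not exceed that of the observed table
#' (within a 1e-7 relative tolerance). `alternative = "less"`/`"greater"`
#' give the one-sided tail sums.
#'
#' @param tab 2x2 matrix of nonnegative integer counts, not all zero.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return the p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(7, 1, 5, 10), 2)) # ~0.027
#' @export
fisher_exact_2x2 <- function(tab, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("'tab' must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  if (sum(tab) == 0) stop("all-zero table")
  m <- sum(tab[1L, ]); nn <- sum(tab[2L, ]); k <- sum(tab[, 1L])
  x <- tab[1L, 1L]
  lo <- max(0L, k - nn); hi <- min(k, m)
  support <- lo:hi
  d <- stats::dhyper(support, m, nn, k)
  switch(alternative,
         two.sided = sum(d[d <= d[support == x] * (1 + 1e-7)]),
         less = stats::phyper(x, m, nn, k),
         greater = stats::phyper(x - 1, m, nn, k, lower.tail = FALSE))
}

#' Chi-square test with automatic Fisher fallback
#'
#' Computes the expected counts of the 2x2 table; if any expected count is
#' below 5, the two-sided Fisher exact test ([fisher_exact_2x2()]) is used,
#' otherwise the Pearson chi-square test without continuity correction.
#' The branch taken is reported.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return list with `p`, `method` (`"fisher"` or `"chisq"`) and, for the
#'   chi-square branch, the `statistic`.
#' @export
chi2_or_fisher <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("'tab' must be 2x2")
  if (sum(tab) == 0) stop("all-zero table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    list(p = fisher_exact_2x2(tab), method = "fisher", statistic = NA_real_)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(p = ct$p.value, method = "chisq", statistic = unname(ct$statistic))
  }
}

#' Group-comparison table for a two-group sample sheet
#'
#' Builds the standard clinical "Table 1": continuous variables as
#' mean +/- SD compared by t test, count/skewed variables as
#' median (min-max) compared by Mann-Whitney, categorical variables as
#' n (%) compared by chi-square with Fisher fallback. Percentages are
#' computed within group. Missing variables are listed in the result
#' attribute `missing` and the remaining rows still computed.
#'
#' @param sheet sample sheet data.frame containing `group_col`.
#' @param variables named character vector mapping variable name to type:
#'   `"continuous"`, `"count"` or `"categorical"`.
#' @param group_col name of the two-level grouping column.
#' @param t_variant passed to [t_test_from_summary()].
#' @return data.frame: `variable`, `type`, per-group summary strings,
#'   `test`, `p`, `significant`.
#' @export
table1_report <- function(sheet, variables, group_col = "group",
                          t_variant = "welch") {
  if (!group_col %in% names(sheet)) stop("grouping column '", group_col, "' absent")
  g <- as.factor(sheet[[group_col]])
  if (nlevels(g) != 2L) stop("grouping column must have exactly two levels")
  if (any(table(g) < 2L)) stop("each group needs at least 2 samples")
  lv <- levels(g)
  missing_v <- setdiff(names(variables), names(sheet))
  vars <- variables[setdiff(names(variables), missing_v)]
  rows <- lapply(names(vars), function(v) {
    type <- vars[[v]]
    x1 <- sheet[[v]][g == lv[1L]]; x2 <- sheet[[v]][g == lv[2L]]
    row <- data.frame(variable = v, type = type, g1 = NA_character_,
                      g2 = NA_character_, test = NA_character_, p = NA_real_,
                      stringsAsFactors = FALSE)
    if (type == "continuous") {
      tt <- t_test_from_summary(
        list(n = length(x1), mean = mean(x1), sd = stats::sd(x1)),
        list(n = length(x2), mean = mean(x2), sd = stats::sd(x2)), t_variant)
      row$g1 <- sprintf("%.2f ± %.2f", mean(x1), stats::sd(x1))
      row$g2 <- sprintf("%.2f ± %.2f", mean(x2), stats::sd(x2))
      row$test <- paste0("t_", t_variant); row$p <- tt$p
    } else if (type == "count") {
      mw <- mann_whitney(x1, x2, method = if (anyDuplicated(c(x1, x2))) "normal_approx" else "auto")
      row$g1 <- sprintf("%g (%g-%g)", stats::median(x1), min(x1), max(x1))
      row$g2 <- sprintf("%g (%g-%g)", stats::median(x2), min(x2), max(x2))
      row$test <- "mann_whitney"; row$p <- mw$p
    } else if (type == "categorical") {
      pos <- if (is.numeric(sheet[[v]])) sheet[[v]] != 0 else
        sheet[[v]] == sort(unique(sheet[[v]]))[length(unique(sheet[[v]]))]
      tab <- rbind(c(sum(pos[g == lv[1L]]), sum(!pos[g == lv[1L]])),
                   c(sum(pos[g == lv[2L]]), sum(!pos[g == lv[2L]])))
      cf <- chi2_or_fisher(tab)
      row$g1 <- sprintf("%d (%.0f%%)", tab[1L, 1L], 100 * tab[1L, 1L] / length(x1))
      row$g2 <- sprintf("%d (%.0f%%)", tab[2L, 1L], 100 * tab[2L, 1L] / length(x2))
      row$test <- cf$method; row$p <- cf$p
    } else stop("unknown variable type '", type, "'")
    row
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "g1"] <- lv[1L]
  names(out)[names(out) == "g2"] <- lv[2L]
  out$significant <- out$p < 0.05
  attr(out, "missing") <- missing_v
  if (length(missing_v))
    message("variable(s) absent from sheet: ", paste(missing_v, collapse = ", "))
  out
}
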