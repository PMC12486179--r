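# Two-group comparison statistics with the classical clinical routing:
# Kolmogorov-Smirnov normality screening (Lilliefors-corrected by
# default), then pooled-variance t-test for parametric data or
# Mann-Whitney U (asymptotic, tie-corrected, no continuity correction,
# matching the common SPSS readout) otherwise; categorical variables by
# Pearson chi-squared (uncorrected by default) with Yates and Fisher
# variants available.

#' Normality screen of one sample
#'
#' One-sample Kolmogorov-Smirnov test against a normal with estimated
#' mean and SD. The default uses the Lilliefors correction (the p-value
#' accounts for the estimated parameters); `method = "ks"` gives the
#' uncorrected one-sample KS p (the classic SPSS one-sample KS readout).
#'
#' @param x numeric sample (n >= 5 for the Lilliefors variant; n >= 4 for
#'   the uncorrected variant).
#' @param alpha routing threshold.
#' @param method `"lilliefors"` or `"ks"`.
#' @return one-row tibble: `statistic`, `p`, `is_normal`.
#' @export
normality <- function(x, alpha = 0.05, method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  nmin <- if (method == "lilliefors") 5L else 4L
  if (length(x) < nmin)
    stop("normality screening needs at least ", nmin, " observations (got ",
         length(x), ")")
  if (stats::sd(x) == 0) stop("constant sample: normality undefined")
  ht <- if (method == "lilliefors") nortest::lillie.test(x)
        else suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  tibble::tibble(statistic = unname(ht$statistic), p = ht$p.value,
                 is_normal = ht$p.value >= alpha)
}

#' Compare a continuous variable between two groups
#'
#' Routes to a two-sided independent-samples t-test (pooled variance by
#' default) when both samples pass the normality screen, and to the
#' two-sided Mann-Whitney U test (normal approximation with tie
#' correction) otherwise. Samples too small to screen (n < 5) take the t
#' route.
#'
#' @param a,b numeric samples (n >= 2 each; NAs dropped).
#' @param alpha significance / routing threshold.
#' @param welch use Welch's unequal-variance t statistic instead of the
#'   pooled one.
#' @param normality_method passed to [normality()].
#' @return one-row tibble of class `comparison_result`: `test` (`"t"` or
#'   `"mann_whitney"`), `statistic`, `p`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `n_a`, `n_b`, `summary_a`, `summary_b` (formatted
#'   `"mean (SD)"`), `significant`.
#' @export
compare_continuous <- function(a, b, alpha = 0.05, welch = FALSE,
                               normality_method = "lilliefors") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples need at least 2 observations")
  screen <- function(x) {
    if (length(x) < 5L || stats::sd(x) == 0) return(TRUE)   # unscreenable -> parametric
    normality(x, alpha = alpha, method = normality_method)$is_normal
  }
  parametric <- screen(a) && screen(b)
  if (parametric) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      stat <- 0; p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      ht <- stats::t.test(a, b, var.equal = !welch)
      stat <- unname(ht$statistic); p <- ht$p.value
    }
    test <- "t"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
    stat <- unname(ht$statistic); p <- ht$p.value
    test <- "mann_whitney"
  }
  out <- tibble::tibble(
    test = test, statistic = stat, p = p,
    mean_a = mean(a), sd_a = stats::sd(a),
    mean_b = mean(b), sd_b = stats::sd(b),
    n_a = length(a), n_b = length(b),
    summary_a = sprintf("%.2f (%.2f)", mean(a), stats::sd(a)),
    summary_b = sprintf("%.2f (%.2f)", mean(b), stats::sd(b)),
    significant = p < alpha
  )
  class(out) <- c("comparison_result", class(out))
  out
}

#' Compare a categorical variable between two groups
#'
#' Default (`"auto"`) is the uncorrected Pearson chi-squared test, falling
#' back to Fisher's exact test when any expected cell count is below 1;
#' Yates-corrected chi-squared and Fisher are available explicitly.
#'
#' @param tab 2 x k matrix of non-negative integer counts (groups in
#'   rows). Levels absent from both groups (all-zero columns) are dropped
#'   with a warning.
#' @param method `"auto"`, `"chi2"`, `"chi2_yates"` or `"fisher"`.
#' @param alpha significance threshold.
#' @return one-row tibble of class `comparison_result`: `test`,
#'   `statistic` (`NA` for Fisher), `p`, `significant`.
#' @export
compare_categorical <- function(tab, method = c("auto", "chi2", "chi2_yates", "fisher"),
                                alpha = 0.05) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L) stop("`tab` must have exactly 2 rows (the groups)")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0)) stop("both groups must have observations")
  zero <- colSums(tab) == 0
  if (any(zero)) {
    warning(sum(zero), " level(s) absent in both groups dropped")
    tab <- tab[, !zero, drop = FALSE]
  }
  if (ncol(tab) < 2L) stop("need at least 2 levels with observations")

  if (method == "auto") {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    method <- if (any(expected < 1)) "fisher" else "chi2"
  }
  res <- switch(method,
    chi2 = {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      list(test = "chi2", statistic = unname(ht$statistic), p = ht$p.value)
    },
    chi2_yates = {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
      list(test = "chi2_yates", statistic = unname(ht$statistic), p = ht$p.value)
    },
    fisher = {
      ht <- stats::fisher.test(tab)
      list(test = "fisher", statistic = NA_real_, p = ht$p.value)
    })
  out <- tibble::tibble(test = res$test, statistic = res$statistic, p = res$p,
                        significant = res$p < alpha)
  class(out) <- c("comparison_result", class(out))
  out
}

#' Build a baseline-characteristics comparison table
#'
#' One comparison per variable: numeric columns are routed through
#' [compare_continuous()] (summaries `"mean (SD)"`), factor/character
#' columns through [compare_categorical()] on the group-by-level count
#' table (summaries `"n (pct)"` of the last level, e.g. `"5 (11.11)"`).
#' Missing values are deleted pairwise; the per-variable n is reported.
#'
#' @param subjects tibble with a two-level group column and the variables.
#' @param variables character vector of columns to compare (default: all
#'   except the group and any `subject` id column).
#' @param group_col name of the group column.
#' @param alpha two-tailed significance threshold.
#' @param categorical_method passed to [compare_categorical()].
#' @return a tibble of class `cysthead_table`, one row per variable:
#'   `variable`, `type`, `summary_a`, `summary_b`, `n_a`, `n_b`, `test`,
#'   `statistic`, `p`, `significant`.
#' @export
build_table <- function(subjects, variables = NULL, group_col = "group",
                        alpha = 0.05, categorical_method = "auto") {
  if (!group_col %in% names(subjects)) stop("no column `", group_col, "`")
  g <- factor(subjects[[group_col]])
  if (nlevels(g) != 2L) stop("the group column must have exactly two levels")
  if (is.null(variables))
    variables <- setdiff(names(subjects), c(group_col, "subject"))

  rows <- purrr::map_dfr(variables, function(v) {
    x <- subjects[[v]]
    if (is.numeric(x)) {
      ok <- !is.na(x)
      cmp <- compare_continuous(x[ok & g == levels(g)[1]],
                                x[ok & g == levels(g)[2]], alpha = alpha)
      tibble::tibble(variable = v, type = "continuous",
                     summary_a = cmp$summary_a, summary_b = cmp$summary_b,
                     n_a = cmp$n_a, n_b = cmp$n_b,
                     test = cmp$test, statistic = cmp$statistic, p = cmp$p,
                     significant = cmp$significant)
    } else {
      x <- factor(x)
      ok <- !is.na(x)
      tab <- table(g[ok], x[ok])
      cmp <- compare_categorical(unclass(tab), method = categorical_method,
                                 alpha = alpha)
      lev <- utils::tail(colnames(tab), 1)
      fmt <- function(i) sprintf("%d (%.2f)", tab[i, lev],
                                 100 * tab[i, lev] / sum(tab[i, ]))
      tibble::tibble(variable = v, type = "categorical",
                     summary_a = fmt(1), summary_b = fmt(2),
                     n_a = sum(tab[1, ]), n_b = sum(tab[2, ]),
                     test = cmp$test, statistic = cmp$statistic, p = cmp$p,
                     significant = cmp$significant)
    }
  })
  class(rows) <- c("cysthead_table", class(rows))
  rows
}

#' Write a comparison table as CSV and markdown
#'
#' @param tbl a `cysthead_table` ([build_table()]).
#' @param path output path; `.csv` is written as given, and a sibling
#'   `.md` with a markdown rendering.
#' @return paths, invisibly.
#' @export
write_comparison_table <- function(tbl, path) {
  readr::write_csv(tbl, path)
  md <- sub("\\.csv$", ".md", path)
  lines <- c(
    "| Variable | Group A | Group B | Test | p |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %s |", tbl$variable, tbl$summary_a,
            tbl$summary_b, tbl$test,
            ifelse(tbl$p < 0.001, "< 0.001", sprintf("%.3f", tbl$p)))
  )
  writeLines(lines, md)
  invisible(c(path, md))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.comparison_result <- function(x, ...) {
  cols <- intersect(c("test", "statistic", "p", "significant"), names(x))
  out <- x[, cols]
  class(out) <- setdiff(class(out), "comparison_result")
  out
}

#' @export
glance.cysthead_table <- function(x, ...) {
  tibble::tibble(
    n_variables = nrow(x),
    n_significant = sum(x$significant),
    n_continuous = sum(x$type == "continuous"),
    n_categorical = sum(x$type == "categorical")
  )
}
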