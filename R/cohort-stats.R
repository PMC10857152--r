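#' Descriptive demographic summary
#'
#' Mean and sample standard deviation (n - 1) of age plus tallies of sex,
#' pathology and surgical position for a cohort table.
#'
#' @param data A data frame with columns `sex`, `age`, `pathology`,
#'   `position`.
#' @return A list of class `demographics_summary` with `n`, `age_mean`,
#'   `age_sd` (`NA` for a single subject) and tally tibbles `sex`,
#'   `pathology`, `position`.
#' @examples
#' demographics_summary(cohort_demographics())
#' @export
demographics_summary <- function(data) {
  needed <- c("sex", "age", "pathology", "position")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0("demographics table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  tally <- function(col) {
    dplyr::arrange(dplyr::count(data, .data[[col]], name = "n"),
                   dplyr::desc(.data$n))
  }
  structure(
    list(n = nrow(data),
         age_mean = mean(data$age),
         age_sd = if (nrow(data) > 1) sd(data$age) else NA_real_,
         sex = tally("sex"),
         pathology = tally("pathology"),
         position = tally("position")),
    class = "demographics_summary")
}

#' @export
print.demographics_summary <- function(x, ...) {
  cat(sprintf("<demographics_summary> n = %d, age %.1f +/- %s years\n",
              x$n, x$age_mean,
              if (is.na(x$age_sd)) "NA" else sprintf("%.1f", x$age_sd)))
  cat("sex:", paste(x$sex[[1]], x$sex$n, sep = "=", collapse = ", "), "\n")
  cat("positions:",
      paste(x$position[[1]], x$position$n, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Compare a metric across surgical-position groups
#'
#' Omnibus Kruskal-Wallis test across groups and, optionally, all pairwise
#' two-sided Mann-Whitney (Wilcoxon rank-sum) tests with a
#' Bonferroni-adjusted significance threshold `alpha / n_pairs` (with
#' three position groups: 0.05 / 3 = 0.017). Pairwise tests use the exact
#' rank-sum distribution when sample sizes allow and there are no ties,
#' the tie-corrected normal approximation otherwise.
#'
#' @param data A data frame.
#' @param metric Name of the numeric metric column.
#' @param group Name of the grouping column (default `"position"`).
#' @param pairwise Run the post hoc pairwise tests.
#' @param alpha Overall significance level before correction.
#' @return A `group_comparison` list: `metric`, per-group `groups` tibble
#'   (n, mean, sd), `omnibus_p`, `pairwise` tibble and `alpha_adjusted`.
#' @examples
#' df <- data.frame(position = rep(c("supine", "prone", "lateral"), each = 5),
#'                  tre = c(rnorm(5, 2.9), rnorm(5, 3.1), rnorm(5, 3.0)))
#' compare_positions(df, "tre")
#' @export
compare_positions <- function(data, metric, group = "position",
                              pairwise = TRUE, alpha = 0.05) {
  stopifnot(metric %in% names(data), group %in% names(data))
  values <- data[[metric]]
  g <- factor(data[[group]])
  if (nlevels(g) < 2) abort("need at least 2 groups to compare")
  sizes <- table(g)
  if (any(sizes < 2)) {
    abort(paste0("group with fewer than 2 observations: ",
                 paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  groups <- dplyr::summarise(
    dplyr::group_by(tibble(value = values, group = g), .data$group),
    n = dplyr::n(), mean = mean(.data$value), sd = sd(.data$value),
    .groups = "drop")
  omnibus <- kruskal.test(values, g)
  pairs_tbl <- NULL
  n_pairs <- choose(nlevels(g), 2)
  if (pairwise) {
    combos <- utils::combn(levels(g), 2, simplify = FALSE)
    pairs_tbl <- purrr::map_dfr(combos, function(pr) {
      a <- values[g == pr[1]]
      b <- values[g == pr[2]]
      p <- suppressWarnings(
        wilcox.test(a, b, alternative = "two.sided",
                    exact = length(a) + length(b) <= 20 &&
                      !anyDuplicated(c(a, b)))$p.value)
      tibble(group1 = pr[1], group2 = pr[2], p = p,
             significant = p < alpha / n_pairs)
    })
  }
  structure(
    list(metric = metric, groups = groups,
         omnibus_p = unname(omnibus$p.value),
         pairwise = pairs_tbl,
         alpha_adjusted = alpha / n_pairs),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: Kruskal-Wallis p = %.3f\n",
              x$metric, x$omnibus_p))
  print(x$groups)
  if (!is.null(x$pairwise)) {
    cat(sprintf("pairwise Mann-Whitney (Bonferroni alpha = %.3f):\n",
                x$alpha_adjusted))
    print(x$pairwise)
  }
  invisible(x)
}

#' Spearman rank correlation between two metrics
#'
#' Tie-corrected Spearman rho with a two-sided p-value (the asymptotic
#' t approximation is used in the presence of ties).
#'
#' @param data A data frame.
#' @param x,y Names of the two numeric columns.
#' @return A one-row tibble: `pair`, `rho`, `p`, `n`.
#' @examples
#' correlate(data.frame(a = 1:10, b = (1:10)^2), "a", "b")  # rho = 1
#' @export
correlate <- function(data, x, y) {
  stopifnot(x %in% names(data), y %in% names(data))
  xv <- data[[x]]
  yv <- data[[y]]
  if (length(xv) < 3) abort("correlation needs at least 3 observations")
  if (length(unique(xv)) < 2 || length(unique(yv)) < 2) {
    abort("rank correlation is undefined for a constant vector")
  }
  ct <- suppressWarnings(cor.test(xv, yv, method = "spearman",
                                  alternative = "two.sided", exact = FALSE))
  tibble(pair = paste0(x, "-", y),
         rho = unname(ct$estimate), p = unname(ct$p.value),
         n = length(xv))
}

#' Median-split subgroup comparison
#'
#' Splits observations at the median of a lesion characteristic
#' (above-median vs at-or-below-median; ties go to the lower group) and
#' compares the accuracy metric between the two subgroups with a
#' two-sided Mann-Whitney test.
#'
#' @param data A data frame.
#' @param metric Name of the accuracy-metric column.
#' @param characteristic Name of the characteristic column split at its
#'   median.
#' @return A one-row tibble with subgroup means/SDs and the Mann-Whitney
#'   p-value.
#' @export
median_split <- function(data, metric, characteristic) {
  stopifnot(metric %in% names(data), characteristic %in% names(data))
  values <- data[[metric]]
  ch <- data[[characteristic]]
  if (length(values) < 4) abort("median split needs at least 4 observations")
  if (length(unique(ch)) < 2) {
    abort("all characteristic values are identical; median split undefined")
  }
  med <- median(ch)
  hi <- values[ch > med]
  lo <- values[ch <= med]
  if (length(hi) < 1 || length(lo) < 1) {
    abort("median split produced an empty subgroup")
  }
  p <- suppressWarnings(
    wilcox.test(hi, lo, alternative = "two.sided",
                exact = length(values) <= 20 && !anyDuplicated(values)))
  # a metric with no variation at all carries no evidence of a difference
  p_value <- if (length(unique(values)) == 1) 1 else p$p.value
  tibble(characteristic = characteristic, metric = metric,
         median = med,
         n_above = length(hi), n_below = length(lo),
         mean_above = mean(hi), sd_above = sd(hi),
         mean_below = mean(lo), sd_below = sd(lo),
         p = p_value)
}
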