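# Contingency-table testing with the expected-count selection rule, plus
# rank-sum and correlation tests.

#' Construct a 2x2 contingency table
#'
#' Counts follow the layout `(a, b, c, d)` = (group-1 positive, group-1
#' negative, group-2 positive, group-2 negative); e.g. for an
#' alteration-vs-contrast-enhancement screen, group 1 = altered and
#' "positive" = CE+.
#'
#' @param a,b,c,d nonnegative integer counts, `a + b + c + d > 0`.
#' @param labels optional list with `rows` and `cols` character vectors of
#'   length 2.
#' @return a `contingency_table` (2x2 integer matrix, rows = groups,
#'   columns = positive/negative).
#' @export
contingency_table <- function(a, b, c, d, labels = NULL) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (sum(counts) == 0) stop("empty table")
  m <- matrix(as.integer(counts), 2, 2, byrow = TRUE)
  dimnames(m) <- if (is.null(labels)) {
    list(group = c("group1", "group2"), status = c("positive", "negative"))
  } else list(labels$rows, labels$cols)
  structure(m, class = c("contingency_table", class(m)))
}

as_table_matrix <- function(table) {
  m <- unclass(table)
  if (!identical(dim(m), c(2L, 2L))) stop("need a 2x2 table")
  m
}

#' Expected cell counts under independence
#'
#' `row_total * column_total / N` per cell; the quantities driving the
#' chi-square-versus-Fisher selection rule.
#'
#' @param table a [contingency_table()] or 2x2 matrix.
#' @return 2x2 matrix of expected counts.
#' @export
expected_counts <- function(table) {
  m <- as_table_matrix(table)
  outer(rowSums(m), colSums(m)) / sum(m)
}

#' Select the contingency test by the expected-count rule
#'
#' Fisher's exact test is used when any of the four expected cell counts is
#' below 5; the chi-square test of independence otherwise.
#'
#' @param table a [contingency_table()] or 2x2 matrix.
#' @return `"fisher_exact"` or `"chi_square"`.
#' @export
select_test <- function(table) {
  if (any(expected_counts(table) < 5)) "fisher_exact" else "chi_square"
}

test_result <- function(test, statistic, p, notes = "") {
  structure(list(test = test, statistic = statistic,
                 p_two_sided = p, notes = notes),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: p = %.4g%s%s\n", x$test, x$p_two_sided,
              if (is.na(x$statistic)) "" else
                sprintf(" (statistic %.4g)", x$statistic),
              if (nzchar(x$notes)) paste0(" [", x$notes, "]") else ""))
  invisible(x)
}

#' Chi-square test of independence on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) statistic
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` referred to the chi-square law
#' with one degree of freedom.
#'
#' @param table a [contingency_table()] or 2x2 matrix with no zero marginal.
#' @return a `test_result` with the statistic and two-sided p-value.
#' @export
chi_square_test <- function(table) {
  m <- as_table_matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-square test undefined with a zero marginal")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  test_result("chi_square", unname(ct$statistic), unname(ct$p.value))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-mass method: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table.
#'
#' @param table a [contingency_table()] or 2x2 matrix.
#' @return a `test_result` (no statistic for the exact test).
#' @export
fisher_exact_test <- function(table) {
  m <- as_table_matrix(table)
  p <- stats::fisher.test(m)$p.value
  test_result("fisher_exact", NA_real_, min(p, 1))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided comparison of two independent groups. Uses the exact rank-sum
#' distribution when the combined sample size is at most 20 and there are
#' no ties, and the normal approximation with the tie-corrected variance
#' otherwise.
#'
#' @param x,y numeric vectors, both nonempty.
#' @return a `test_result` with the rank-sum `W` statistic.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  if (length(unique(c(x, y))) == 1) {
    return(test_result("wilcoxon", NA_real_, 1, "all values identical"))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = FALSE))
  test_result("wilcoxon", unname(wt$statistic), unname(wt$p.value),
              if (exact) "exact" else "normal approximation")
}

#' Pearson correlation with a two-sided p-value
#'
#' Linear correlation `r` with the p-value from the t transform
#' `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return a `test_result` whose statistic is `r`; the estimate is also in
#'   `$estimate`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  out <- test_result("pearson", unname(ct$estimate), unname(ct$p.value))
  out$estimate <- unname(ct$estimate)
  out
}

#' Screen binary features for association with a binary label
#'
#' For each feature, builds the 2x2 table of feature-positive /
#' feature-negative against label-positive / label-negative, applies the
#' expected-count selection rule ([select_test()]) and reports counts, the
#' test used and the two-sided p-value, sorted by p.
#'
#' @param features a [feature_matrix()] or binary matrix (samples x
#'   features).
#' @param labels binary vector aligned with the rows of `features` (e.g.
#'   contrast enhancement, 1 = CE+).
#' @param bh append a Benjamini-Hochberg adjusted column (off by default;
#'   nominal p is the primary readout).
#' @return data frame with columns `feature`, `n_pos_lab1`, `n_pos`,
#'   `n_neg_lab1`, `n_neg`, `test`, `p`, ordered by increasing `p`.
#' @export
association_screen <- function(features, labels, bh = FALSE) {
  X <- unclass_matrix(features)
  if (nrow(X) != length(labels)) stop("features and labels are not aligned")
  if (!all(X %in% c(0, 1))) stop("association screen needs binary features")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  rows <- lapply(colnames(X), function(f) {
    v <- X[, f]
    tab <- contingency_table(sum(v == 1 & labels == 1),
                             sum(v == 1 & labels == 0),
                             sum(v == 0 & labels == 1),
                             sum(v == 0 & labels == 0))
    test <- select_test(tab)
    res <- if (test == "chi_square") chi_square_test(tab)
           else fisher_exact_test(tab)
    data.frame(feature = f,
               n_pos_lab1 = tab[1, 1], n_pos = sum(tab[1, ]),
               n_neg_lab1 = tab[2, 1], n_neg = sum(tab[2, ]),
               test = test, p = res$p_two_sided,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$feature), , drop = FALSE]
  if (bh) out$p_bh <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}
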