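#' Cross-tabulate two ordinal severity ratings
#'
#' Builds the k x k agreement table of two methods rated on scales with the
#' same number of levels: rows are method A's level, columns method B's.
#'
#' @param levels_a,levels_b integer vectors of zero-based ordinals
#'   (equal length).
#' @param k number of levels per scale (>= 2).
#' @param row_labels,col_labels optional level names (length `k`).
#' @return Object of class `crosstab`: `counts` (k x k integer matrix),
#'   `k`, `n`, `row_labels`, `col_labels`.
#' @export
crosstab <- function(levels_a, levels_b, k,
                     row_labels = NULL, col_labels = NULL) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  a <- as.integer(levels_a); b <- as.integer(levels_b)
  if (length(a) != length(b)) stop("levels_a and levels_b differ in length")
  if (length(a) && (any(a < 0L | a >= k) || any(b < 0L | b >= k)))
    stop("ordinals must lie in [0, k)")
  counts <- matrix(0L, k, k)
  for (i in seq_along(a))
    counts[a[i] + 1L, b[i] + 1L] <- counts[a[i] + 1L, b[i] + 1L] + 1L
  if (is.null(row_labels)) row_labels <- paste0("level", 0:(k - 1))
  if (is.null(col_labels)) col_labels <- row_labels
  dimnames(counts) <- list(row_labels, col_labels)
  structure(list(counts = counts, k = k, n = length(a),
                 row_labels = row_labels, col_labels = col_labels),
            class = "crosstab")
}

#' Build a crosstab directly from a count matrix
#'
#' Convenience constructor for published agreement tables where only the
#' cell counts are printed.
#'
#' @param counts k x k matrix of non-negative integer counts.
#' @inheritParams crosstab
#' @return A `crosstab`.
#' @export
crosstab_from_counts <- function(counts, row_labels = rownames(counts),
                                 col_labels = colnames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || nrow(counts) < 2L)
    stop("counts must be a square matrix, k >= 2")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  k <- nrow(counts)
  storage.mode(counts) <- "integer"
  if (is.null(row_labels)) row_labels <- paste0("level", 0:(k - 1))
  if (is.null(col_labels)) col_labels <- row_labels
  dimnames(counts) <- list(row_labels, col_labels)
  structure(list(counts = counts, k = k, n = sum(counts),
                 row_labels = row_labels, col_labels = col_labels),
            class = "crosstab")
}

#' Expand a crosstab back to paired ordinal vectors
#'
#' Inverse of [crosstab()] up to case order: returns one row per case.
#'
#' @param tab a `crosstab`.
#' @return list with integer vectors `a` and `b` (zero-based ordinals).
#' @export
crosstab_pairs <- function(tab) {
  stopifnot(inherits(tab, "crosstab"))
  idx <- which(tab$counts > 0, arr.ind = TRUE)
  reps <- tab$counts[idx]
  list(a = rep(idx[, 1] - 1L, reps), b = rep(idx[, 2] - 1L, reps))
}

#' @export
print.crosstab <- function(x, ...) {
  cat("crosstab (n = ", x$n, "):\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Exact / off-by-one match summary of a crosstab
#'
#' Summarises ordinal agreement: exact matches (diagonal), one-level
#' differences (|i - j| = 1), and larger discrepancies. Percentages are kept
#' at full precision; display rounding to whole percent (half-up, as the
#' published tables report) is available via `print()`.
#'
#' @param tab a `crosstab` with `n > 0`.
#' @return Object of class `match_summary` with counts `exact_n`,
#'   `off_one_n`, `off_more_n` and percentages `exact_pct`, `off_one_pct`,
#'   `off_more_pct`.
#' @export
match_summary <- function(tab) {
  stopifnot(inherits(tab, "crosstab"))
  if (tab$n == 0L) stop("cannot summarise an empty crosstab (n = 0)")
  dlev <- abs(row(tab$counts) - col(tab$counts))
  exact <- sum(tab$counts[dlev == 0])
  off1 <- sum(tab$counts[dlev == 1])
  offm <- tab$n - exact - off1
  structure(list(exact_n = exact, off_one_n = off1, off_more_n = offm,
                 exact_pct = 100 * exact / tab$n,
                 off_one_pct = 100 * off1 / tab$n,
                 off_more_pct = 100 * offm / tab$n,
                 n = tab$n),
            class = "match_summary")
}

# round-half-up to whole percent for display
.round_half_up <- function(x) floor(x + 0.5)

#' @export
print.match_summary <- function(x, ...) {
  cat(sprintf("exact match      %d of %d (%d%%)\n", x$exact_n, x$n,
              .round_half_up(x$exact_pct)))
  cat(sprintf("1 level apart    %d of %d (%d%%)\n", x$off_one_n, x$n,
              .round_half_up(x$off_one_pct)))
  cat(sprintf(">1 level apart   %d of %d (%d%%)\n", x$off_more_n, x$n,
              .round_half_up(x$off_more_pct)))
  invisible(x)
}

#' Pearson correlation with two-tailed p value
#'
#' Sample Pearson r between paired index values; the two-tailed p value comes
#' from the t transform with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-zero variance.
#' @return Object of class `correlation_result`: `r`, `p_two_tailed`, `n`.
#' @export
pearson_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_two_tailed = ct$p.value,
                 n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (%s), two-tailed p = %.3g, n = %d\n",
              x$r, interpret_r(x$r), x$p_two_tailed, x$n))
  invisible(x)
}

#' Interpret a correlation coefficient
#'
#' Standard qualitative bands on |r|: negligible (0.00-0.30), low
#' (0.30-0.50), moderate (0.50-0.70), high (0.70-0.90), very high
#' (0.90-1.00). The published band ranges overlap at their endpoints; a
#' boundary value is assigned to the higher band.
#'
#' @param r correlation coefficient, |r| <= 1.
#' @return Band label (character).
#' @export
interpret_r <- function(r) {
  if (!is.finite(r) || abs(r) > 1) stop("r must be finite with |r| <= 1")
  bands <- c("negligible", "low", "moderate", "high", "very high")
  bands[findInterval(abs(r), c(0.30, 0.50, 0.70, 0.90)) + 1L]
}

#' Mann-Whitney U test (two-tailed)
#'
#' Rank-sum comparison of two independent samples, e.g. measurement
#' durations of two methods. Uses midranks for ties; the p value is exact
#' when both samples are small (`n1 * n2 <= 400`) and tie-free, otherwise a
#' normal approximation with tie and continuity correction. The switch can
#' be forced with `exact`.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact logical or `NULL` (auto; see above).
#' @return Object of class `rank_test_result`: `u_statistic` (U for the
#'   first sample), `p_two_tailed`, `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (is.null(exact)) exact <- length(x) * length(y) <= 400
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  structure(list(u_statistic = unname(wt$statistic),
                 p_two_tailed = min(1, wt$p.value),
                 n1 = length(x), n2 = length(y)),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, two-tailed p = %.4g (n1 = %d, n2 = %d)\n",
              x$u_statistic, x$p_two_tailed, x$n1, x$n2))
  invisible(x)
}
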