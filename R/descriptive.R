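#' Categorize counts into the study's three bands
#'
#' Bins partition the non-negative integers as `[0, 50]`, `[51, 200]` and
#' `[201, Inf)`, labelled `"<50"`, `"51-200"` and `">200"`.  The boundary
#' value 50 falls in the first band, keeping the bins a true partition.
#'
#' @param counts non-negative integers.
#' @return a factor with the three band labels as levels.
#' @examples
#' table(categorize_counts(c(0, 49, 50, 51, 200, 201, 958)))
#' @export
categorize_counts <- function(counts) {
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("`counts` must be non-negative integers without NA", call. = FALSE)
  }
  cut(counts, breaks = c(-0.5, 50.5, 200.5, Inf),
      labels = count_category_labels())
}

count_category_labels <- function() c("<50", "51-200", ">200")

#' Factor-by-count-band contingency table
#'
#' Cross-tabulates a categorical council attribute (residence or zone)
#' against the three count bands, with cell percentages taken out of the
#' grand total (so a cell holding 112 of 184 councils shows 60.87).
#'
#' @param records council data frame.
#' @param factor `"residence"` or `"zone"`.
#' @param count_column which count to band: `"count_5_59"`,
#'   `"count_60plus"` or `"total"`.
#' @return an object of class `"count_xtab"`: a list with `counts`
#'   (levels x bands integer matrix), `percentages`, `total`, `row_factor`,
#'   `count_column`.
#' @export
count_xtab <- function(records, factor = c("residence", "zone"),
                       count_column = c("count_5_59", "count_60plus", "total")) {
  factor <- match.arg(factor)
  count_column <- match.arg(count_column)
  validate_council_records(records)
  counts <- response_vector(records, if (count_column == "total") "total" else count_column)
  keep <- !is.na(counts) & !is.na(records[[factor]])
  if (!any(keep)) stop("no usable records", call. = FALSE)
  lv <- if (factor == "residence") residence_levels() else zone_levels()
  # display order: alphabetical as in the published tables (reference level
  # ordering only matters for the regression design)
  lv <- sort(lv)
  f <- base::factor(records[[factor]][keep], levels = lv)
  band <- categorize_counts(counts[keep])
  tab <- table(f, band)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  total <- sum(m)
  structure(
    list(counts = m, percentages = 100 * m / total, total = total,
         row_factor = factor, count_column = count_column),
    class = "count_xtab"
  )
}

#' @export
print.count_xtab <- function(x, ...) {
  cat("Contingency table:", x$row_factor, "x count band (",
      x$count_column, "), n =", x$total, "\n")
  disp <- matrix(sprintf("%d (%.2f)", x$counts, x$percentages),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Chi-square test of independence
#'
#' Pearson chi-square on an r x c table without continuity correction and
#' without an exact-test fallback, \eqn{\sum (O - E)^2 / E} with
#' \eqn{df = (r-1)(c-1)} and an upper-tail chi-square p-value.  A flag is
#' raised when any expected cell count falls below 5 (the asymptotic
#' approximation is then questionable, but the statistic is still the one
#' reported).
#'
#' @param table a `"count_xtab"` or a numeric count matrix with at least
#'   two rows and columns.
#' @return a list with `statistic`, `df`, `p_value`, `expected`,
#'   `small_expected_warning`.
#' @examples
#' chi2_independence(matrix(c(93, 38, 8, 7, 22, 16), 2, byrow = TRUE))
#' @export
chi2_independence <- function(table) {
  m <- if (inherits(table, "count_xtab")) table$counts else as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least a 2 x 2 table", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: zero row or column margin", call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value),
    expected = ht$expected,
    small_expected_warning = any(ht$expected < 5)
  )
}

#' Dispersion summary of a count sample
#'
#' Sample mean, unbiased variance, their ratio (the dispersion index; 1
#' under Poisson, \eqn{\vartheta^2} under a GP law), moment skewness and
#' histogram bin counts — the ingredients of the usual first look at
#' whether count data are over-dispersed and right-skewed.
#'
#' @param counts at least two non-negative counts.
#' @param bin_width histogram bin width (default 50).
#' @return a list with `n`, `mean`, `variance`, `ratio`, `skewness`,
#'   `histogram` (named vector of bin counts).
#' @export
dispersion_summary <- function(counts, bin_width = 50) {
  counts <- counts[!is.na(counts)]
  if (length(counts) < 2L) stop("need at least two observations", call. = FALSE)
  m <- mean(counts)
  v <- var(counts)
  brk <- seq(0, max(counts) + bin_width, by = bin_width)
  h <- table(cut(counts, breaks = brk, right = FALSE, include.lowest = TRUE))
  list(
    n = length(counts), mean = m, variance = v,
    ratio = if (m > 0) v / m else 0,
    skewness = moment_skewness(counts),
    histogram = setNames(as.integer(h), names(h))
  )
}
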