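#' Median and interquartile-range width
#'
#' The study reports continuous summaries as a median with a single IQR
#' number, the width Q3 - Q1. The default quartile rule is Tukey's hinges
#' (inclusive-of-the-median halves, as in [stats::fivenum()]); the rule is
#' configurable because reporting conventions differ (`"linear"` uses
#' [stats::quantile()] type 7).
#'
#' @param values Non-empty numeric vector (`NA` removed).
#' @param quartile_rule `"tukey"` (default) or `"linear"`.
#' @return Named numeric vector `c(median, iqr)`.
#' @export
#' @examples
#' median_iqr(c(1, 2, 3, 4, 5))  # median 3, hinges 2 and 4, width 2
median_iqr <- function(values, quartile_rule = c("tukey", "linear")) {
  quartile_rule <- match.arg(quartile_rule)
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("median_iqr needs a non-empty sample",
                                call. = FALSE)
  if (quartile_rule == "tukey") {
    fn <- fivenum(values)
    c(median = fn[3], iqr = fn[4] - fn[2])
  } else {
    q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
    c(median = q[2], iqr = q[3] - q[1])
  }
}

#' Mann-Whitney rank-sum test
#'
#' Two-sample rank-sum comparison as used for the interval and
#' length-of-stay outcomes. `U` is computed from midranks. For small
#' tie-free samples (`min(n) <= 8`, no ties in the pooled data) the
#' two-sided p comes from the exact null distribution of U (doubled smaller
#' tail, capped at 1); otherwise the normal approximation is used with
#' tie-corrected variance and a 0.5 continuity correction. The z-score is
#' always reported, signed so that smaller ranks in `x` give negative z.
#' If every pooled value is identical the variance degenerates and the test
#' returns `z = 0, p = 1`.
#'
#' @param x,y Numeric samples, each non-empty.
#' @return List of class `rank_sum_result`: `u_statistic` (U for `x`),
#'   `z_score`, `p_two_sided`, `n_x`, `n_y`, `tie_correction_applied`,
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)
  n <- nx + ny
  mu <- nx * ny / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    z <- 0
  } else {
    cc <- if (u == mu) 0 else 0.5 * sign(u - mu)
    z <- (u - mu - cc) / sqrt(sigma2)
  }
  exact <- !has_ties && min(nx, ny) <= 8
  if (exact) {
    # null distribution of U via stats::pwilcox; doubled smaller tail
    lower <- pwilcox(u, nx, ny)
    upper <- 1 - pwilcox(u - 1, nx, ny)
    p <- min(1, 2 * min(lower, upper))
  } else {
    p <- if (sigma2 <= 0) 1 else min(1, 2 * pnorm(-abs(z)))
  }
  structure(
    list(u_statistic = u, z_score = z, p_two_sided = p, n_x = nx, n_y = ny,
         tie_correction_applied = has_ties,
         method = if (exact) "exact" else "normal_approx"),
    class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney rank-sum (%s): U = %g, Z = %.3f, p = %.4g (n = %d, %d)\n",
              x$method, x$u_statistic, x$z_score, x$p_two_sided, x$n_x, x$n_y))
  invisible(x)
}

#' 2x2 contingency test
#'
#' Categorical group comparisons use Pearson's chi-square test without
#' continuity correction unless any expected cell count falls below 5, in
#' which case Fisher's exact test is used (two-sided by summation of all
#' tables at most as probable as the observed one; `fisher_method =
#' "doubling"` doubles the smaller hypergeometric tail instead).
#'
#' @param a,b,c,d Non-negative integer counts, row-wise:
#'   `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#' @param fisher_method `"tail_sum"` (default) or `"doubling"`.
#' @param force Optionally force `"pearson_chi_square"` or `"fisher_exact"`.
#' @return List of class `contingency_result`: `table`, `statistic`
#'   (chi-square statistic, or the sample odds ratio for Fisher),
#'   `p_two_sided`, `method`, `expected`.
#' @export
#' @examples
#' contingency_test(204, 116, 173, 101)  # two groups, same male proportion
contingency_test <- function(a, b, c, d,
                             fisher_method = c("tail_sum", "doubling"),
                             force = NULL) {
  fisher_method <- match.arg(fisher_method)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  tab <- matrix(as.numeric(counts), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("a row or column of the 2x2 table sums to 0; test undefined",
         call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  method <- force %||%
    (if (any(expected < 5)) "fisher_exact" else "pearson_chi_square")
  if (method == "pearson_chi_square") {
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    statistic <- unname(ht$statistic)
    p <- unname(ht$p.value)
  } else {
    if (fisher_method == "tail_sum") {
      ht <- fisher.test(tab)
      p <- unname(ht$p.value)
    } else {
      m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
      lower <- stats::phyper(tab[1, 1], m, n2, k)
      upper <- 1 - stats::phyper(tab[1, 1] - 1, m, n2, k)
      p <- min(1, 2 * min(lower, upper))
    }
    statistic <- (tab[1, 1] * tab[2, 2]) / max(tab[1, 2] * tab[2, 1], .Machine$double.xmin)
  }
  structure(
    list(table = tab, statistic = statistic, p_two_sided = p,
         method = method, expected = expected),
    class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("2x2 %s: statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_two_sided))
  invisible(x)
}

#' Per-element missingness of assessments
#'
#' For each of the seven core MEWS elements, the number and percentage of
#' assessments in which the element was not recorded.
#'
#' @param assessments Assessments tibble.
#' @param by Optional stratifier: `NULL`, `"arm"` or `"source_label"`.
#' @return Tibble: (group), `element`, `n_assessments`, `n_missing`,
#'   `percent_missing`.
#' @export
missingness_by_element <- function(assessments, by = NULL) {
  groups <- if (is.null(by)) list(all = assessments) else
    split(assessments, assessments[[by]])
  out <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    n <- nrow(d)
    res <- lapply(core_elements(), function(el) {
      miss <- if (n == 0) 0L else sum(is.na(d[[tolower(el)]]))
      tibble::tibble(element = el, n_assessments = n, n_missing = miss,
                     percent_missing = if (n == 0) NA_real_ else 100 * miss / n)
    })
    res <- dplyr::bind_rows(res)
    if (!is.null(by)) res <- tibble::add_column(res, !!by := g, .before = 1)
    res
  })
  dplyr::bind_rows(out)
}

#' 24-hour pattern of assessments
#'
#' Counts assessments by the hour of day of their anchor time. On this unit
#' the pattern shows three peaks, at the daily nursing rounds.
#'
#' @param assessments Assessments tibble.
#' @return Tibble with `hour` (0-23) and `n`; `sum(n)` equals the number of
#'   assessments.
#' @export
hourly_pattern <- function(assessments) {
  anchor_hour <- as.integer(format(assessments$anchor_time, "%H", tz = "UTC"))
  counts <- as.integer(table(factor(anchor_hour, levels = 0:23)))
  tibble::tibble(hour = 0:23, n = counts)
}

#' Half-up percentage rounding
#'
#' Proportions are reported to one decimal place with halves rounded up,
#' matching the study's tables (R's `round()` rounds half to even).
#' `percent_from_counts()` computes the rounded percentage directly from
#' integer counts, which keeps exact halves (e.g. 204/320 = 63.75%) on the
#' intended side of the boundary despite binary floating point.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' percent_from_counts(204, 320)  # 63.8
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5 + 1e-9 * abs(x * s)) / s
}

#' @rdname round_half_up
#' @param numerator,denominator Integer counts.
#' @export
percent_from_counts <- function(numerator, denominator, digits = 1) {
  s <- 10^digits
  floor((100 * s * numerator) / denominator + 0.5) / s
}
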