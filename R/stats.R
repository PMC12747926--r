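# Contingency statistics and small-count suppression.

as_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m) || any(m < 0)) abort("counts must be non-negative numbers")
  m
}

#' Pearson chi-squared test of independence
#'
#' No continuity correction by default (override via `correct`).
#'
#' @param table Matrix (at least 2x2) of non-negative counts.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return A tibble: `statistic`, `df`, `p_value`.
#' @export
chi_squared <- function(table, correct = FALSE) {
  m <- as_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("chi-squared test undefined with a zero row or column margin")
  }
  fit <- suppressWarnings(chisq.test(m, correct = correct))
  tibble::tibble(statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p_value = unname(fit$p.value))
}

#' Fisher's exact test (two-sided) for a 2x2 table
#'
#' Two-sided p-value by hypergeometric enumeration: the sum of probabilities
#' of all tables with the observed margins whose probability does not exceed
#' that of the observed table.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return A tibble: `p_value`.
#' @export
fisher_exact <- function(table) {
  m <- as_2x2(table)
  if (!all(dim(m) == c(2, 2))) abort("fisher_exact requires a 2x2 table")
  fit <- fisher.test(m)
  tibble::tibble(p_value = fit$p.value)
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = (a d) / (b c)` for a 2x2 table `[[a, b], [c, d]]`; when any cell is
#' zero, 0.5 is added to every cell (Haldane-Anscombe correction, reported via
#' the `corrected` column).
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return A tibble: `or`, `ci_low`, `ci_high`, `corrected`.
#' @export
odds_ratio <- function(table) {
  m <- as_2x2(table)
  if (!all(dim(m) == c(2, 2))) abort("odds_ratio requires a 2x2 table")
  corrected <- any(m == 0)
  if (corrected) {
    inform("zero cell: applying 0.5 continuity correction to all cells")
    m <- m + 0.5
  }
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  se <- sqrt(sum(1 / m))
  z <- qnorm(0.975)
  tibble::tibble(or = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se),
                 corrected = corrected)
}

#' Suppress small counts
#'
#' Masks every non-zero count below three (i.e. 1 and 2); zeros and counts of
#' three or more are shown.  Masked cells display as `"\u22643"` following the
#' custodian's table convention.  Idempotent: suppressing a suppressed table
#' changes nothing.
#'
#' @param counts Integer vector (or data frame column) of counts.
#' @param mask_string Display string for masked cells.
#' @return A tibble: `count` (NA where masked), `masked`, `display`.
#' @export
suppress_counts <- function(counts, mask_string = "\u22643") {
  counts <- as.integer(counts)
  masked <- !is.na(counts) & counts > 0 & counts < 3
  tibble::tibble(
    count = ifelse(masked, NA_integer_, counts),
    masked = masked,
    display = dplyr::case_when(
      is.na(counts) ~ mask_string,   # already-masked input stays masked
      masked ~ mask_string,
      TRUE ~ as.character(counts)
    )
  )
}

#' Choose and run the comparison test for a contingency table
#'
#' Fisher's exact test when any expected cell count is below 5 (and the table
#' is 2x2), otherwise the chi-squared test; the test actually used is
#' reported.
#'
#' @param table Matrix of counts.
#' @param expected_threshold Expected-count threshold for switching to
#'   Fisher's exact test (default 5).
#' @return A tibble: `test`, `p_value`.
#' @export
compare_groups <- function(table, expected_threshold = 5) {
  m <- as_2x2(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < expected_threshold) && all(dim(m) == c(2, 2))) {
    tibble::tibble(test = "fisher_exact", p_value = fisher_exact(m)$p_value)
  } else {
    tibble::tibble(test = "chi_squared", p_value = chi_squared(m)$p_value)
  }
}
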