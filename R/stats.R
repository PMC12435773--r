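#' Chi-squared comparison of two zone tallies
#'
#' 2x3 contingency chi-squared (no continuity correction) of zone counts
#' between two conditions, the test used for all zoning comparisons.  Zones
#' empty in both tallies are dropped with a matching reduction in degrees of
#' freedom, and the result is flagged when any expected count falls below 5.
#'
#' @param tally_a,tally_b Single-row [zone_tally()] data frames (or anything
#'   with `n1`, `n2`, `n3`).
#' @return A `TestResult` list: `statistic`, `dof`, `p_raw`, `p_adjusted`
#'   (equal to `p_raw` here), `correction`, `comparison`, `flags`.
#' @export
zone_chisq <- function(tally_a, tally_b) {
  ca <- as.numeric(c(tally_a$n1, tally_a$n2, tally_a$n3))
  cb <- as.numeric(c(tally_b$n1, tally_b$n2, tally_b$n3))
  if (sum(ca) == 0 || sum(cb) == 0) stop("empty tally", call. = FALSE)
  tab <- rbind(ca, cb)
  keep <- colSums(tab) > 0
  flags <- character()
  if (!all(keep)) {
    tab <- tab[, keep, drop = FALSE]
    flags <- c(flags, "zero-margin zone dropped (dof reduced)")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 5)) flags <- c(flags, "expected count < 5")
  label <- paste(tally_label(tally_a), "vs", tally_label(tally_b))
  test_result(unname(ht$statistic), unname(ht$parameter), unname(ht$p.value),
              comparison = label, flags = flags)
}

tally_label <- function(x) {
  if (!is.null(x$condition)) as.character(x$condition)[1] else "?"
}

test_result <- function(statistic, dof, p_raw, p_adjusted = p_raw,
                        correction = "none", comparison = "", flags = character()) {
  structure(list(statistic = statistic, dof = dof, p_raw = p_raw,
                 p_adjusted = p_adjusted, correction = correction,
                 comparison = comparison, flags = flags),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("<TestResult> %s: statistic %.4g (df %s), p %.3g (adjusted %.3g, %s)\n",
              x$comparison, x$statistic, format(x$dof), x$p_raw, x$p_adjusted,
              x$correction))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Bonferroni correction over a family of tests
#'
#' `p_adj = min(1, p * m_tests)` with an explicit family size, as used for
#' time-course comparisons where `m_tests` is the number of time points.
#'
#' @param p_values Raw p values.
#' @param m_tests Family size (must be >= the number of p values supplied).
#' @return Adjusted p values, order preserved.
#' @export
bonferroni <- function(p_values, m_tests = length(p_values)) {
  if (m_tests < length(p_values)) {
    stop("'m_tests' must be at least the number of p values", call. = FALSE)
  }
  pmin(1, p_values * m_tests)
}

#' Welch's unequal-variance t test
#'
#' Two-sample t statistic with Welch-Satterthwaite degrees of freedom (the
#' comparison used for SPB-distance measurements), delegated to
#' [stats::t.test()].
#'
#' @param sample_a,sample_b Numeric samples, each of length >= 2.
#' @return A `TestResult`.
#' @export
welch_t <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2L, length(sample_b) >= 2L)
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    stop("zero variance in both samples", call. = FALSE)
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  test_result(unname(ht$statistic), unname(ht$parameter), unname(ht$p.value),
              comparison = "Welch t")
}
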