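# 2x2 categorical endpoint tests.
#
# Arm-by-event tables are compared with the Pearson chi-square statistic
# WITHOUT continuity correction -- this is the form that reproduces the
# trial's printed p-values from its printed counts (the Yates-corrected
# form does not) -- or, for sparse tables, with the exact hypergeometric
# test under the two-sided "probability mass <= observed" rule.

as_table2x2 <- function(t) {
  if (is.matrix(t)) {
    check_that(all(dim(t) == c(2, 2)), "table", "must be 2x2")
    t <- c(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  }
  check_that(is.numeric(t) && length(t) == 4, "table",
             "must be a 2x2 matrix or length-4 vector (a, b, c, d)")
  check_that(all(t >= 0) && all(t == round(t)), "table",
             "cell counts must be non-negative integers")
  check_that(t[1] + t[2] > 0 && t[3] + t[4] > 0, "table",
             "row totals must be positive")
  matrix(t, nrow = 2, byrow = TRUE,
         dimnames = list(arm = c("row1", "row2"),
                         outcome = c("event", "no_event")))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Two-sided Pearson chi-square test without continuity correction, 1
#' degree of freedom.  Rows are arms, columns event yes/no.
#'
#' @param t a 2x2 integer matrix (rows = arms) or length-4 vector
#'   `c(a, b, c, d)` read row-wise.
#' @return List with `statistic`, `p_value`, `df`, `expected`.
#' @examples
#' chi_square_2x2(c(8, 97, 3, 103))$p_value   # 0.118 (no-reflow)
#' @seealso [fisher_exact_2x2()] for sparse tables.
#' @export
chi_square_2x2 <- function(t) {
  m <- as_table2x2(t)
  if (any(colSums(m) == 0)) {
    stop("degenerate table: a column marginal is zero; ",
         "use fisher_exact_2x2() for sparse tables", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  check_that(all(ht$expected > 0), "table", "expected cell counts must be > 0")
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = 1L, expected = ht$expected)
}

#' Exact hypergeometric test for a 2x2 table
#'
#' Two-sided exact test with both margins fixed: the p-value is the sum
#' of hypergeometric probabilities of every table in the margin class
#' whose probability does not exceed that of the observed table (with a
#' 1e-7 relative tolerance for ties, as is conventional).
#'
#' @inheritParams chi_square_2x2
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(c(3, 102, 2, 104))   # 0.683 (30-day mortality)
#' fisher_exact_2x2(c(1, 104, 0, 106))   # 0.498
#' @export
fisher_exact_2x2 <- function(t) {
  m <- as_table2x2(t)
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  dens <- dhyper(support, r1, r2, c1)
  d_obs <- dhyper(m[1, 1], r1, r2, c1)
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}
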