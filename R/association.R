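# Contingency-table association statistics: two-sided Fisher exact test for
# 2x2 tables by the point-probability (minimum-likelihood) rule, and Pearson
# chi-square for r x c tables without continuity correction. The Fisher
# p-value is the sum of hypergeometric probabilities, over all tables with
# the observed margins, that do not exceed the probability of the observed
# table; the hypergeometric pmf is evaluated in log space so that the test is
# stable at cohort-scale totals.

#' Cross-tabulate two annotation variables
#'
#' Builds a contingency table over the samples with evaluable (non-"na")
#' values on both variables; the per-variable "na" counts are reported as an
#' attribute and never tested.
#'
#' @param ann a [sample_annotation()].
#' @param var_row,var_col annotation columns (`"hla_i"`, `"hla_ii"`, `"ebv"`,
#'   `"subtype"`).
#' @param drop_na drop samples that are "na" on either variable (default
#'   TRUE; FALSE keeps "na" as a category, for display only).
#' @return a [contingency_table()] with attribute `"n_na"` giving the number
#'   of excluded samples.
#' @export
build_contingency <- function(ann, var_row, var_col, drop_na = TRUE) {
  stopifnot(inherits(ann, "sample_annotation"),
            var_row %in% names(ANNOTATION_LEVELS),
            var_col %in% names(ANNOTATION_LEVELS))
  r <- ann[[var_row]]
  c_ <- ann[[var_col]]
  if (drop_na) {
    keep <- r != "na" & c_ != "na"
    n_na <- sum(!keep)
    r <- r[keep]; c_ <- c_[keep]
  } else n_na <- 0L
  if (!length(r)) stop("no samples left after dropping na values")
  rl <- intersect(ANNOTATION_LEVELS[[var_row]], unique(r))
  cl <- intersect(ANNOTATION_LEVELS[[var_col]], unique(c_))
  if (length(rl) < 2L || length(cl) < 2L)
    stop("need >= 2 observed levels on each variable (got ", length(rl),
         " x ", length(cl), ")")
  counts <- table(factor(r, rl), factor(c_, cl))
  out <- contingency_table(matrix(as.integer(counts), nrow = length(rl),
                                  dimnames = list(rl, cl)))
  attr(out, "n_na") <- n_na
  out
}

# log hypergeometric pmf of cell (1,1) = a for margins r1, r2 (rows) and c1
# (first column): P(a) = C(r1, a) C(r2, c1 - a) / C(N, c1)
.log_hyper_pmf <- function(a, r1, r2, c1) {
  lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability rule: with the table's
#' margins fixed, the p-value sums the hypergeometric probabilities of every
#' table whose probability is at most that of the observed table (ties
#' admitted with relative tolerance 1e-7). The odds ratio is the sample
#' cross-product ratio ad/bc (infinite when bc = 0).
#'
#' @param t a 2x2 [contingency_table()] (plain 2x2 count matrices are
#'   accepted).
#' @return object of class `association_result`: list with `table`, `method`
#'   (`"fisher_2x2"`), `p_value`, `odds_ratio`.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 7, 6, 79), 2))$p_value  # ~0.0038
#' @export
fisher_exact_2x2 <- function(t) {
  t <- unclass(as.matrix(t))
  if (!all(dim(t) == c(2L, 2L))) stop("Fisher exact test requires a 2x2 table")
  if (any(t < 0) || any(t != round(t))) stop("counts must be nonnegative integers")
  r1 <- sum(t[1, ]); r2 <- sum(t[2, ]); c1 <- sum(t[, 1])
  support <- max(0L, c1 - r2):min(r1, c1)
  logp <- .log_hyper_pmf(support, r1, r2, c1)
  log_obs <- .log_hyper_pmf(t[1, 1], r1, r2, c1)
  # p <= p_obs * (1 + 1e-7), compared in log space
  p <- sum(exp(logp[logp <= log_obs + log1p(1e-7)]))
  p <- min(p, 1)
  or <- (t[1, 1] * t[2, 2]) / (t[1, 2] * t[2, 1])
  structure(list(table = t, method = "fisher_2x2", p_value = p,
                 odds_ratio = or),
            class = "association_result")
}

#' Pearson chi-square test for an r x c table
#'
#' Uncorrected Pearson statistic (no Yates continuity correction) with
#' `(r-1)(c-1)` degrees of freedom.
#'
#' @param t an r x c [contingency_table()] (plain count matrices accepted);
#'   every expected count must be positive.
#' @return object of class `association_result`: list with `table`, `method`
#'   (`"chi_square"`), `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_rxc(matrix(c(3, 66, 3, 12, 2, 1), 2))$p_value  # ~0.0004
#' @export
chi_square_rxc <- function(t) {
  t <- unclass(as.matrix(t))
  if (nrow(t) < 2L || ncol(t) < 2L) stop("table must be at least 2 x 2")
  if (any(t < 0) || any(t != round(t))) stop("counts must be nonnegative integers")
  expected <- outer(rowSums(t), colSums(t)) / sum(t)
  if (any(expected == 0))
    stop("zero expected count (empty row or column); merge categories first")
  stat <- sum((t - expected)^2 / expected)
  df <- (nrow(t) - 1L) * (ncol(t) - 1L)
  structure(list(table = t, method = "chi_square", statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result>", x$method, "\n")
  print(x$table)
  if (x$method == "chi_square")
    cat("X-squared =", format(x$statistic, digits = 5), ", df =", x$df, "\n")
  if (x$method == "fisher_2x2")
    cat("odds ratio =", format(x$odds_ratio, digits = 5), "\n")
  cat("p-value =", format(x$p_value, digits = 5), "\n")
  invisible(x)
}
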