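#' Paired t test with d_z effect size
#'
#' Standard two-sided paired t test on `x1 - x2` (condition 1 minus
#' condition 2) with `n - 1` degrees of freedom, plus the within-design
#' effect size `d_z = t / sqrt(n)`.  The degenerate case of exactly equal
#' vectors returns `t = 0, p = 1, dz = 0` (the limit of a vanishing effect);
#' zero-variance differences with a nonzero mean are an error, since the
#' statistic diverges.
#'
#' @param x1,x2 Per-participant values in condition 1 and condition 2
#'   (equal length, >= 2).
#' @return A list of class `paired_result`: `t`, `df`, `p`, `dz`, `n`,
#'   `mean_diff`.
#' @examples
#' paired_t(c(2, 4, 6), c(1, 2, 3))
#' @export
paired_t <- function(x1, x2) {
  stopifnot(is.numeric(x1), is.numeric(x2))
  if (length(x1) != length(x2)) {
    stop("x1 and x2 must have equal length", call. = FALSE)
  }
  n <- length(x1)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x1 - x2
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(structure(list(t = 0, df = n - 1L, p = 1, dz = 0, n = n,
                            mean_diff = 0), class = "paired_result"))
    }
    stop("degenerate-test error: differences have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(x1, x2, paired = TRUE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, dz = unname(tt$statistic) / sqrt(n),
                 n = n, mean_diff = unname(tt$estimate)),
            class = "paired_result")
}

#' @export
print.paired_result <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.4g, d_z = %.3f (n = %d)\n",
              x$df, x$t, x$p, x$dz, x$n))
  invisible(x)
}

#' Percentage of significant results
#'
#' `100 * mean(p < alpha)` over a vector of p-values: the Monte-Carlo power
#' (or, under a null design, type-I-error rate) of a test.
#'
#' @param pvalues Numeric vector of p-values.
#' @param alpha Significance level in (0, 1).  Default .05.
#' @return Percentage in `[0, 100]`.
#' @export
percent_significant <- function(pvalues, alpha = 0.05) {
  stopifnot(length(pvalues) > 0L, all(is.finite(pvalues)),
            length(alpha) == 1L, alpha > 0, alpha < 1)
  100 * mean(pvalues < alpha)
}

#' Between-condition correlation of a cell-level measure
#'
#' Pearson correlation across participants between the condition-1 and
#' condition-2 values of one column of a cell table.  High values are the
#' signature of realistic within-participants data (stable individual
#' differences) and drive the power advantage of paired tests.
#'
#' @param cells A [aggregate_trials()] or [compute_measures()] result with
#'   both conditions present for every participant.
#' @param column Name of the numeric column to correlate.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
condition_correlation <- function(cells, column) {
  stopifnot(column %in% names(cells))
  wide <- split_by_condition(cells, column)
  if (stats::sd(wide$x1) == 0 || stats::sd(wide$x2) == 0) {
    stop("undefined correlation: column is constant within a condition",
         call. = FALSE)
  }
  stats::cor(wide$x1, wide$x2)
}

# per-participant condition-1/condition-2 vectors, participants aligned
split_by_condition <- function(cells, column) {
  conds <- sort(unique(cells$condition))
  if (length(conds) != 2L) {
    stop("cell table must contain exactly two conditions", call. = FALSE)
  }
  c1 <- cells[cells$condition == conds[1L], , drop = FALSE]
  c2 <- cells[cells$condition == conds[2L], , drop = FALSE]
  c1 <- c1[order(c1$participant), , drop = FALSE]
  c2 <- c2[order(c2$participant), , drop = FALSE]
  if (!identical(as.character(c1$participant), as.character(c2$participant))) {
    stop("every participant must appear in both conditions", call. = FALSE)
  }
  list(x1 = c1[[column]], x2 = c2[[column]], participant = c1$participant)
}

#' Partial eta squared from sums of squares
#'
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param ss_effect,ss_error Non-negative sums of squares, not both zero.
#' @return Proportion in `[0, 1]`.
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  stopifnot(all(ss_effect >= 0), all(ss_error >= 0))
  if (any(ss_effect + ss_error == 0)) {
    stop("undefined: ss_effect and ss_error are both zero", call. = FALSE)
  }
  ss_effect / (ss_effect + ss_error)
}
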