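#' Group summary record
#'
#' Mean, standard deviation and size of one group, as printed in a
#' demographic table.
#'
#' @param mean group mean.
#' @param sd group standard deviation (`>= 0`).
#' @param n group size (`>= 2`).
#' @return list of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

as_group_summary <- function(g) {
  if (inherits(g, "group_summary")) return(g)
  if (is.list(g) && all(c("mean", "sd", "n") %in% names(g)))
    return(group_summary(g$mean, g$sd, g$n))
  stop_validation("expected a group_summary (mean, sd, n)")
}

test_result <- function(statistic, df, p, method) {
  structure(list(statistic = statistic, df = df, p = p, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  df <- if (length(x$df) == 2)
    sprintf("(%s, %s)", format(x$df[1]), format(x$df[2])) else
      format(round(x$df, 2))
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic, df, x$p))
  invisible(x)
}

#' Welch two-sample t test from group summaries
#'
#' Unequal-variance t test computed from printed means, SDs and sizes:
#' `t = (m2 - m1) / sqrt(sd1^2/n1 + sd2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. The sign convention is
#' second-group minus first-group, so pass the groups in the order whose
#' difference you want.
#'
#' @param g1,g2 [group_summary()]s (or lists with `mean`, `sd`, `n`).
#' @return a `test_result` with `statistic`, fractional `df`, `p`.
#' @export
welch_t <- function(g1, g2) {
  g1 <- as_group_summary(g1); g2 <- as_group_summary(g2)
  v1 <- g1$sd^2 / g1$n
  v2 <- g2$sd^2 / g2$n
  se <- sqrt(v1 + v2)
  if (se == 0) stop_validation("both groups have zero variance")
  t <- (g2$mean - g1$mean) / se
  df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  test_result(t, df, 2 * pt(-abs(t), df), "Welch two-sample t")
}

#' Chi-square test for a 2x2 table
#'
#' Pearson chi-square with the Yates continuity correction,
#' `sum(max(0, |O - E| - 0.5)^2 / E)` on 1 degree of freedom. The cells are
#' given row-wise: `(a, b)` is the first row, `(c, d)` the second.
#'
#' @param a,b,c,d non-negative integer cell counts; all margins must be
#'   positive.
#' @param correct apply the continuity correction (default `TRUE`).
#' @return a `test_result`.
#' @export
chi2_2x2 <- function(a, b, c, d, correct = TRUE) {
  o <- base::c(a, b, c, d) # `c` is a cell-count argument here
  if (anyNA(o) || any(o < 0) || any(o %% 1 != 0))
    stop_validation("cell counts must be non-negative integers")
  O <- matrix(o, 2, 2, byrow = TRUE)
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop_validation("all table margins must be positive")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  adj <- pmax(0, abs(O - E) - if (correct) 0.5 else 0)
  stat <- sum(adj^2 / E)
  test_result(stat, 1, pchisq(stat, df = 1, lower.tail = FALSE),
              if (correct) "Chi-square (Yates-corrected)" else "Chi-square")
}

#' Two-sided variance-ratio F test from group summaries
#'
#' `F` is the larger sample variance over the smaller, with numerator
#' degrees of freedom from the larger-variance group; the two-sided p-value
#' is twice the smaller tail probability (capped at 1).
#'
#' @param sd1,n1 SD and size of the first group.
#' @param sd2,n2 SD and size of the second group.
#' @return a `test_result` with `df = c(df_num, df_den)`.
#' @export
variance_ratio_f <- function(sd1, n1, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (sd1 <= 0 || sd2 <= 0)
    stop_validation("standard deviations must be positive")
  if (sd1^2 >= sd2^2) {
    f <- sd1^2 / sd2^2; df <- c(n1 - 1, n2 - 1)
  } else {
    f <- sd2^2 / sd1^2; df <- c(n2 - 1, n1 - 1)
  }
  p <- min(1, 2 * min(pf(f, df[1], df[2], lower.tail = FALSE),
                      pf(f, df[1], df[2])))
  test_result(f, df, p, "Variance-ratio F (two-sided)")
}
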