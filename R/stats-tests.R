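#' Mann-Whitney U test (two-sided)
#'
#' Computes the Mann-Whitney U statistic with midrank ties and a two-sided
#' p-value.  The reported `U` is `min(U1, U2)`, the convention used when
#' comparing score distributions between decoy clusters.  The p-value is
#' exact (by enumeration of the rank distribution) when `min(n1, n2) <= 8`
#' and there are no ties, and otherwise uses the normal approximation with
#' tie and continuity corrections.
#'
#' @param x,y Numeric samples.
#' @return A one-row tibble: `U`, `U1`, `p`, `n1`, `n2`, `exact` (logical),
#'   `degenerate` (`TRUE` when all values across both samples are identical,
#'   in which case `p = 1`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact two-sided p = 1/3
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- n1 * n2 + n1 * (n1 + 1) / 2 - sum(r[seq_len(n1)])
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- anyDuplicated(c(x, y)) > 0
  degenerate <- length(unique(c(x, y))) == 1
  if (degenerate) {
    p <- 1
    exact <- FALSE
  } else {
    exact <- !ties && min(n1, n2) <= 8
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
    )
  }
  tibble(U = u, U1 = u1, p = min(p, 1), n1 = n1, n2 = n2,
         exact = exact, degenerate = degenerate)
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the comparison count `m` and caps at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param m Number of comparisons in the family; must be at least
#'   `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (m < 1) abort("m must be >= 1")
  if (m < length(p_values)) {
    abort(sprintf("m (%d) is smaller than the number of p-values (%d)",
                  m, length(p_values)))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  pmin(1, m * p_values)
}

#' Rank-biserial effect size from a Mann-Whitney U statistic
#'
#' The default mode computes `EF = 1 - 2U / (n1 * n2)`, the rank-biserial
#' correlation: 0 for fully overlapping samples, 1 (or -1) for complete
#' separation.  An `"as_printed"` mode is also provided that computes
#' `1 - 2U / (n1 - n2)`; that form is undefined for equal sample sizes and
#' raises an explicit division-by-zero error there.
#'
#' @param U Mann-Whitney statistic.
#' @param n1,n2 Sample sizes.
#' @param mode `"rank_biserial"` (default) or `"as_printed"`.
#' @return The effect size (numeric scalar).
#' @export
effect_size <- function(U, n1, n2, mode = c("rank_biserial", "as_printed")) {
  mode <- match.arg(mode)
  if (n1 < 1 || n2 < 1) abort("n1 and n2 must be >= 1")
  if (mode == "rank_biserial") {
    1 - 2 * U / (n1 * n2)
  } else {
    if (n1 == n2) {
      abort("as-printed effect size divides by n1 - n2, which is zero here")
    }
    1 - 2 * U / (n1 - n2)
  }
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of a sample against a normal distribution with the
#' sample's own mean and standard deviation.  Because the reference
#' parameters are estimated from the same data, the asymptotic p-value is
#' conservative (a Lilliefors-type caveat); the returned `caveat` flag
#' records this.
#'
#' @param x Numeric sample, `n >= 4`, non-zero variance.
#' @return One-row tibble: `D`, `p`, `n`, `caveat`.
#' @export
ks_normality <- function(x) {
  if (length(x) < 4) abort("ks_normality needs n >= 4")
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("sample has zero variance")
  res <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), s))
  tibble(D = unname(res$statistic), p = res$p.value, n = length(x),
         caveat = "reference parameters estimated from the sample; asymptotic p")
}
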