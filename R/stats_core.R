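#' Empirical normal quantile (rank-normal) transformation
#'
#' Maps a numeric vector onto standard-normal quantiles through its ranks,
#' using the Blom offset: \eqn{\Phi^{-1}((r - c)/(n - 2c + 1))} with
#' \eqn{c = 0.375}. Ties receive average ranks, so the transform is monotone
#' in the input and tied inputs map to identical outputs.
#'
#' @param x numeric vector, length >= 2, all finite.
#' @param offset rank offset constant; 0.375 (Blom) by default.
#' @return numeric vector of the same length on the standard-normal scale.
#' @examples
#' rank_normal_transform(c(5, 1, 3))  # middle value maps to 0
#' @export
rank_normal_transform <- function(x, offset = 0.375) {
  .assert(is.numeric(x) && length(x) >= 2, "need a numeric vector of length >= 2")
  .assert(all(is.finite(x)), "all values must be finite")
  .assert(length(unique(x)) > 1, "constant vector: rank-normal transform undefined")
  n <- length(x)
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Cliff's delta effect size
#'
#' \eqn{\delta = (\#\{x_i > y_j\} - \#\{x_i < y_j\}) / (|x||y|)}: the
#' probability that a value from `x` exceeds one from `y`, minus the reverse.
#' Computed from midranks in O((n+m) log(n+m)), which handles ties exactly as
#' the pairwise count does (ties contribute zero).
#'
#' @param x,y non-empty numeric vectors (e.g. case and control values).
#' @return A number in \[-1, 1\].
#' @examples
#' cliffs_delta(c(1, 2, 3), c(4, 5, 6))  # -1, complete separation
#' @export
cliffs_delta <- function(x, y) {
  .assert(length(x) > 0 && length(y) > 0, "both vectors must be non-empty")
  .assert(is.numeric(x) && is.numeric(y), "inputs must be numeric")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  # Mann-Whitney U with half-credit for ties, then delta = 2U/(nx*ny) - 1
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  2 * u / (nx * ny) - 1
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the pooled sample is tie-free with at most 12
#' observations; otherwise the normal approximation with tie correction (no
#' continuity correction, so null p-values are calibrated rather than
#' conservative).
#'
#' @param x,y numeric vectors with at least 2 observations each.
#' @return Two-sided p-value.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))  # 1/3 by exact enumeration
#' @export
rank_sum_test <- function(x, y) {
  .assert(length(x) >= 2 && length(y) >= 2, "each group needs >= 2 observations")
  pooled <- c(x, y)
  exact <- length(pooled) <= 12 && !anyDuplicated(pooled)
  if (exact) {
    stats::wilcox.test(x, y, exact = TRUE, alternative = "two.sided")$p.value
  } else {
    suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE,
                         alternative = "two.sided")$p.value
    )
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity, clipped at 1; input
#' order is preserved. Thin validated wrapper over [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  .assert(is.numeric(pvals), "p-values must be numeric")
  .assert(!anyNA(pvals) && all(pvals >= 0 & pvals <= 1),
          "p-values must all lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' p = the sum of hypergeometric probabilities, over all tables with the
#' observed margins, of tables no more probable than the observed one.
#'
#' @param t 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(2, 0, 0, 2), 2, 2))  # 1/3
#' @export
fisher_exact <- function(t) {
  .assert(is.matrix(t) && all(dim(t) == 2), "need a 2x2 matrix")
  .assert(all(t >= 0), "entries must be non-negative")
  .assert(all(abs(t - round(t)) < 1e-8), "entries must be integer counts")
  .assert(sum(t) >= 1, "grand total must be >= 1")
  stats::fisher.test(round(t), alternative = "two.sided")$p.value
}
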