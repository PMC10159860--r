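#' Chao1 richness estimator (bias-corrected)
#'
#' \eqn{S_{obs} + F_1(F_1-1)/(2(F_2+1))}, where \eqn{F_1}/\eqn{F_2} are the
#' singleton/doubleton counts. The +1 bias-corrected form stays finite when no
#' doubletons are observed. Requires integer counts: the estimator is
#' undefined on relative abundances.
#'
#' @param counts non-negative integer count vector.
#' @return Estimated richness (>= observed richness).
#' @examples
#' chao1(c(rep(5, 10), 1, 1, 1, 1, 2, 2))  # 16 + 4*3/6 = 18
#' @export
chao1 <- function(counts) {
  .assert(is.numeric(counts) && all(counts >= 0), "counts must be non-negative")
  .assert(all(abs(counts - round(counts)) < 1e-8),
          "Chao1 needs integer counts; it is undefined on relative abundances")
  counts <- round(counts)
  if (all(counts == 0)) {
    warning("all-zero count vector: Chao1 = 0")
    return(0)
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity
#'
#' \eqn{-\sum q_i \log q_i} over the renormalized positive entries; reported
#' in nats by default.
#'
#' @param p abundance vector with at least one positive entry (any scale;
#'   renormalized internally).
#' @param base logarithm base (`exp(1)` for nats, 2 for bits).
#' @return Shannon diversity.
#' @examples
#' shannon(rep(1, 4))  # log(4)
#' @export
shannon <- function(p, base = exp(1)) {
  .assert(is.numeric(p) && all(p >= 0), "abundances must be non-negative")
  .assert(any(p > 0), "need at least one positive entry")
  q <- p[p > 0]
  q <- q / sum(q)
  -sum(q * log(q)) / log(base)
}

#' Canberra distance
#'
#' \eqn{\sum_i |x_i - y_i| / (x_i + y_i)} over coordinates where
#' \eqn{x_i + y_i > 0}; double-zero coordinates contribute 0. This is the
#' plain (unscaled) sum, sensitive to changes in rare features.
#'
#' @param x,y non-negative vectors of equal length.
#' @return Canberra distance.
#' @export
canberra <- function(x, y) {
  .assert(length(x) == length(y), "vectors must have equal length")
  .assert(all(x >= 0) && all(y >= 0), "entries must be non-negative")
  s <- x + y
  keep <- s > 0
  if (!any(keep)) return(0)
  sum(abs(x[keep] - y[keep]) / s[keep])
}

#' All-pairs sample distance matrix for a feature table
#'
#' @param table [feature_table] or numeric matrix (samples x features).
#' @param metric distance metric (`"canberra"` by default; any method
#'   understood by [stats::dist()]).
#' @return Symmetric distance matrix with sample names and a `metric`
#'   attribute.
#' @export
sample_distance <- function(table, metric = "canberra") {
  m <- .ft_values(table)
  d <- as.matrix(stats::dist(m, method = metric))
  attr(d, "metric") <- metric
  d
}

#' @keywords internal
#' @noRd
.check_dist <- function(d) {
  .assert(is.matrix(d) && nrow(d) == ncol(d), "need a square distance matrix")
  .assert(max(abs(d - t(d))) < 1e-10, "distance matrix is not symmetric")
  .assert(all(diag(d) == 0), "distance matrix diagonal must be zero")
  .assert(all(d >= 0), "distances must be non-negative")
  .assert(!is.null(rownames(d)), "distance matrix must carry sample names")
  invisible(d)
}

#' Within-group beta-diversity comparison
#'
#' Collects all within-group pairwise distances for each of two groups and
#' compares the two collections with a two-sided Wilcoxon rank-sum test —
#' the usual test of whether one group's community composition is more
#' heterogeneous than the other's.
#'
#' @param d symmetric distance matrix with sample names (see
#'   [sample_distance()]). `NA` entries are dropped.
#' @param groups named vector (names = sample ids) with exactly two distinct
#'   group labels; every sample in `d` must be assigned.
#' @return A list with `distances` (named list of within-group distance
#'   vectors), `medians`, and `p` (rank-sum p-value).
#' @export
within_group_beta <- function(d, groups) {
  .check_dist(d)
  ids <- rownames(d)
  .assert(all(ids %in% names(groups)), "unknown group id: sample(s) missing from `groups`")
  g <- groups[ids]
  lv <- unique(as.character(g))
  .assert(length(lv) == 2, "need exactly two groups (got %d)", length(lv))
  pull <- function(level) {
    idx <- which(g == level)
    .assert(length(idx) >= 2, "group '%s' needs >= 2 samples", level)
    v <- d[idx, idx][upper.tri(diag(length(idx)))]
    v[!is.na(v)]
  }
  dists <- stats::setNames(lapply(lv, pull), lv)
  p <- if (all(lengths(dists) >= 2)) rank_sum_test(dists[[1]], dists[[2]]) else NA_real_
  list(distances = dists,
       medians = vapply(dists, stats::median, numeric(1)),
       p = p)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F from
#' among/within sums of squared distances, with a permutation p-value
#' \eqn{(1 + \#\{F_{perm} \ge F\})/(1 + n_{perm})}. Labels are permuted
#' freely (no strata). Thin seeded wrapper over [vegan::adonis2()].
#'
#' @param d symmetric distance matrix with sample names.
#' @param labels named group vector (>= 2 groups of >= 2 samples each).
#' @param n_perm number of permutations (>= 1; default 999).
#' @param seed integer seed for the permutations.
#' @return A list with `f` (pseudo-F), `p`, and `n_perm`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed) {
  .check_dist(d)
  .assert(n_perm >= 1, "n_perm must be >= 1")
  ids <- rownames(d)
  .assert(all(ids %in% names(labels)), "unknown group id in distance matrix")
  g <- factor(labels[ids])
  tab <- table(g)
  .assert(length(tab) >= 2 && all(tab >= 2), "need >= 2 groups with >= 2 samples each")
  .assert(any(d[upper.tri(d)] > 1e-12),
          "all samples identical: pseudo-F undefined")
  df <- data.frame(group = g)
  res <- .with_seed(seed, vegan::adonis2(stats::as.dist(d) ~ group, data = df,
                                         permutations = n_perm))
  list(f = res$F[1], p = res$`Pr(>F)`[1], n_perm = n_perm)
}
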