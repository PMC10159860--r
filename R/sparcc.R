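#' Prevalence and abundance filter for relative-abundance tables
#'
#' Keeps features whose prevalence (fraction of samples with non-zero
#' abundance) is at least `min_prev` AND whose mean relative abundance is at
#' least `min_abund`. Both thresholds are inclusive.
#'
#' @param table a relative-scale [feature_table].
#' @param min_prev minimum prevalence (default 10%).
#' @param min_abund minimum mean relative abundance (default 0.01%).
#' @return The filtered [feature_table].
#' @export
prevalence_filter <- function(table, min_prev = 0.10, min_abund = 0.0001) {
  .assert(is_feature_table(table), "`table` must be a feature_table")
  .assert(attr(table, "scale") == "relative", "prevalence filter needs a relative-scale table")
  v <- .ft_values(table)
  eps <- 1e-12
  keep <- colMeans(v > 0) >= min_prev - eps & colMeans(v) >= min_abund - eps
  .assert(any(keep), "filter removed all features")
  feature_table(v[, keep, drop = FALSE], attr(table, "kingdom"), attr(table, "scale"))
}

# one SparCC basis estimate from a single composition draw
#' @keywords internal
#' @noRd
.sparcc_one <- function(comp, exclusion_iters, exclusion_threshold) {
  L <- log(comp)
  C <- stats::cov(L)
  v <- diag(C)
  D <- length(v)
  Tm <- outer(v, v, "+") - 2 * C      # t_ij = Var(log x_i / x_j)
  inc <- matrix(TRUE, D, D)
  diag(inc) <- FALSE
  rho <- NULL
  for (it in 0:exclusion_iters) {
    deg <- rowSums(inc)
    G <- diag(deg) + inc
    Ti <- rowSums(Tm * inc)
    omega <- tryCatch(solve(G, Ti), error = function(e) rep(mean(v), D))
    omega <- pmax(omega, 1e-10)
    rho <- (outer(omega, omega, "+") - Tm) / (2 * sqrt(outer(omega, omega)))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (it == exclusion_iters) break
    cand <- abs(rho)
    cand[!inc] <- 0
    m <- max(cand)
    if (m <= exclusion_threshold) break
    idx <- which(cand == m, arr.ind = TRUE)[1, ]
    # never strip a feature below 3 partners (system would degenerate)
    if (deg[idx[1]] <= 3 || deg[idx[2]] <= 3) break
    inc[idx[1], idx[2]] <- inc[idx[2], idx[1]] <- FALSE
  }
  rho
}

#' SparCC compositional correlation inference
#'
#' Estimates correlations between the unobserved basis abundances underlying
#' compositional data. Per Dirichlet resample of each sample's composition:
#' the log-ratio variance matrix \eqn{t_{ij} = Var(\log x_i/x_j)} is computed,
#' basis variances \eqn{\omega} are solved from the sparsity-approximated
#' linear system \eqn{\sum_{j\ne i} t_{ij} = (D-2)\omega_i + \sum_j \omega_j},
#' correlations are formed as
#' \eqn{\rho_{ij} = (\omega_i + \omega_j - t_{ij}) / (2\sqrt{\omega_i\omega_j})}
#' (clipped to \[-1, 1\]), and the most strongly correlated pair above
#' `exclusion_threshold` is iteratively removed from the system and the
#' system re-solved. The reported matrix is the elementwise median over
#' Dirichlet draws.
#'
#' Samples are always renormalized to fractions and resampled from a
#' Dirichlet posterior with unit pseudocount at a nominal depth, which makes
#' the estimate exactly invariant to per-sample scaling of the input.
#'
#' @param table [feature_table] or matrix (samples x features, >= 4 features).
#' @param n_dirichlet number of Dirichlet resamples (median taken across).
#' @param exclusion_iters maximum strongly-correlated-pair exclusions.
#' @param exclusion_threshold |rho| above which a pair is excluded from the
#'   basis-variance system.
#' @param seed integer seed.
#' @param nominal_depth pseudo-depth used for the Dirichlet posterior.
#' @return Symmetric correlation matrix with unit diagonal and feature names.
#' @references Friedman & Alm (2012) Inferring correlation networks from
#'   genomic survey data. PLoS Comput Biol 8:e1002687.
#' @export
sparcc <- function(table, n_dirichlet = 20, exclusion_iters = 10,
                   exclusion_threshold = 0.1, seed, nominal_depth = 1e5) {
  v <- .ft_values(table)
  .assert(is.matrix(v) && ncol(v) >= 4,
          "SparCC needs >= 4 features (the basis approximation is invalid below)")
  .assert(all(v >= 0), "abundances must be non-negative")
  D <- ncol(v)
  frac <- v / rowSums(v)
  alpha <- frac * nominal_depth + 1
  const <- which(apply(v, 2, function(col) max(col) == min(col)))
  if (length(const)) {
    warning(sprintf("feature(s) with zero variance excluded: %s",
                    paste(colnames(v)[const], collapse = ", ")))
  }
  .with_seed(seed, {
    draws <- array(NA_real_, c(D, D, n_dirichlet))
    for (k in seq_len(n_dirichlet)) {
      comp <- .rdirichlet(alpha)
      draws[, , k] <- .sparcc_one(comp, exclusion_iters, exclusion_threshold)
    }
    rho <- apply(draws, c(1, 2), stats::median)
    rho <- (rho + t(rho)) / 2
    diag(rho) <- 1
    if (length(const)) {
      rho[const, ] <- NA_real_
      rho[, const] <- NA_real_
      diag(rho) <- 1
    }
    dimnames(rho) <- list(colnames(v), colnames(v))
    rho
  })
}

#' Permutation pseudo-p-values for SparCC correlations
#'
#' Each permutation shuffles every feature's samples independently (breaking
#' all inter-feature dependence while keeping marginals) and recomputes
#' SparCC; the two-sided pseudo-p for each pair is
#' \eqn{(1 + \#\{|\rho_{perm}| \ge |\rho_{obs}|\}) / (1 + n_{boot})}.
#'
#' @param table the table `rho_obs` was computed from.
#' @param rho_obs observed SparCC correlation matrix.
#' @param n_boot number of permutations (>= 1).
#' @param seed integer seed.
#' @inheritParams sparcc
#' @return Symmetric p-value matrix (diagonal `NA`).
#' @export
pseudo_pvalues <- function(table, rho_obs, n_boot = 100, seed,
                           n_dirichlet = 20, exclusion_iters = 10,
                           exclusion_threshold = 0.1, nominal_depth = 1e5) {
  v <- .ft_values(table)
  .assert(n_boot >= 1, "n_boot must be >= 1")
  .assert(all(dim(rho_obs) == ncol(v)), "rho_obs does not match the table")
  n <- nrow(v)
  seeds <- .child_seeds(seed, n_boot + 1)
  count <- matrix(0, ncol(v), ncol(v))
  for (b in seq_len(n_boot)) {
    perm <- .with_seed(seeds[b], apply(v, 2, sample, size = n))
    rownames(perm) <- rownames(v)
    rho_p <- sparcc(perm, n_dirichlet = n_dirichlet,
                    exclusion_iters = exclusion_iters,
                    exclusion_threshold = exclusion_threshold,
                    seed = seeds[n_boot + 1], nominal_depth = nominal_depth)
    count <- count + (abs(rho_p) >= abs(rho_obs))
  }
  p <- (1 + count) / (1 + n_boot)
  p <- (p + t(p)) / 2
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(rho_obs)
  p
}
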