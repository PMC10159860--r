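# Independent brute-force / closed-form oracles used to validate the
# elementary statistics. These deliberately avoid the code paths they check.

# two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins
oracle_fisher <- function(t) {
  r1 <- sum(t[1, ]); c1 <- sum(t[, 1]); n <- sum(t)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(t[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumeration of all C(n, nx) group assignments
# (tie-free inputs only)
oracle_ranksum_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  mu <- nx * (nx + ny + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Cliff's delta by direct pairwise counting
oracle_cliff <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1 else if (xi < yj) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}

# BH step-up by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

oracle_canberra <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) {
    if (x[i] + y[i] > 0) s <- s + abs(x[i] - y[i]) / (x[i] + y[i])
  }
  s
}

# small helpers for fixtures
random_2x2 <- function(max_total = 40) {
  repeat {
    t <- matrix(rpois(4, 3), 2, 2)
    if (sum(t) >= 1 && sum(t) <= max_total) return(t)
  }
}

make_ft <- function(m, kingdom = "bacteria", scale = "relative") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("f%02d", seq_len(ncol(m)))
  feature_table(m, kingdom, scale)
}

# quick null cohort at reduced size for module tests
small_null_cohort <- function(seed, n_bact = 30, n_vir = 0, n_metab = 0,
                              n_cases = 25, n_controls = 25) {
  generate_cohort(n_cases = n_cases, n_controls = n_controls,
                  n_bacteria = n_bact, n_viruses = n_vir,
                  n_metabolites = n_metab,
                  truth = null_truth_config(n_phenotypes = 2), seed = seed)
}
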