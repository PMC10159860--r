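# vectorized two-sided rank-sum p (normal approximation, tie-corrected, no
# continuity correction) and Cliff's delta for every column of `values`
#' @keywords internal
#' @noRd
.ranksum_cliff_cols <- function(values, status) {
  nx <- sum(status == 1); ny <- sum(status == 0)
  N <- nx + ny
  res <- matrix(NA_real_, ncol(values), 2,
                dimnames = list(colnames(values), c("p", "delta")))
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    r <- rank(v, ties.method = "average")
    u <- sum(r[status == 1]) - nx * (nx + 1) / 2
    res[j, 2] <- 2 * u / (nx * ny) - 1
    tie <- table(v)
    tie_term <- sum(tie^3 - tie) / (N * (N - 1))
    s2 <- nx * ny / 12 * ((N + 1) - tie_term)
    if (s2 <= 0) { res[j, 1] <- 1; next }
    z <- (u - nx * ny / 2) / sqrt(s2)
    res[j, 1] <- 2 * stats::pnorm(-abs(z))
  }
  res
}

#' Univariate case/control screen
#'
#' Drops features below a prevalence floor, then tests every remaining
#' feature's abundance against disease status with a two-sided Wilcoxon
#' rank-sum test, reports Cliff's delta (case vs control) as effect size, and
#' Benjamini-Hochberg-adjusts across the retained features.
#'
#' @param table [feature_table] (samples x features).
#' @param meta [sample_metadata] covering the table's samples.
#' @param min_prevalence minimum fraction of samples with non-zero abundance
#'   (default 10%).
#' @return data.frame with `feature_id`, `effect_size` (Cliff's delta),
#'   `p_raw`, `p_adj`, and prevalence overall / in cases / in controls.
#' @export
univariate_screen <- function(table, meta, min_prevalence = 0.10) {
  .assert(min_prevalence >= 0 && min_prevalence <= 1, "min_prevalence must be in [0,1]")
  meta <- .align_meta(table, meta)
  status <- meta$status
  .assert(sum(status == 1) >= 3 && sum(status == 0) >= 3,
          "need >= 3 samples in each status group (single-status cohorts cannot be screened)")
  v <- .ft_values(table)
  prev <- colMeans(v > 0)
  keep <- prev >= min_prevalence - 1e-12
  .assert(any(keep), "prevalence filter removed all features")
  v <- v[, keep, drop = FALSE]
  st <- .ranksum_cliff_cols(v, status)
  data.frame(feature_id = colnames(v),
             effect_size = st[, "delta"],
             p_raw = st[, "p"],
             p_adj = bh_adjust(st[, "p"]),
             prevalence_total = colMeans(v > 0),
             prevalence_case = colMeans(v[status == 1, , drop = FALSE] > 0),
             prevalence_control = colMeans(v[status == 0, , drop = FALSE] > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

# association test between a rank-normalized abundance and one covariate
#' @keywords internal
#' @noRd
.covariate_assoc_p <- function(ab_rn, z) {
  if (.is_binary(z)) {
    if (min(sum(z == 1), sum(z == 0)) < 2) return(NA_real_)
    rank_sum_test(ab_rn[z == 1], ab_rn[z == 0])
  } else {
    suppressWarnings(stats::cor.test(ab_rn, z, method = "spearman",
                                     alternative = "two.sided")$p.value)
  }
}

#' Confounder status label for one screened feature
#'
#' Mirrors nested-linear-model post-hoc confounder checking: the abundance is
#' rank-normalized; covariates associated with the feature (univariate test,
#' BH within covariates, alpha) are collected; for each associated covariate
#' Z two nested comparisons are run — LRT1: `abundance ~ Z` vs
#' `abundance ~ Z + status`, and LRT2: `abundance ~ status` vs
#' `abundance ~ status + Z`. The label is:
#' \describe{
#'   \item{OK_nc}{no covariate is feature-associated (no confounding
#'     candidate).}
#'   \item{OK_d}{status survives (LRT1 significant) for every associated
#'     covariate — the disease signal is deconfounded.}
#'   \item{C:<Z,...>}{for some covariate Z, status does not survive while Z
#'     does (LRT2 significant, LRT1 not) — the signal is confounded by Z.}
#'   \item{AD}{ambiguous: neither status nor the covariate cleanly wins.}
#' }
#' Constant covariates are skipped; a covariate collinear with status
#' (|r| > 0.99) yields `AD` with a warning rather than an error.
#'
#' @param abundance numeric abundance vector for one feature.
#' @param status 0/1 disease status.
#' @param covariates data.frame of numeric/binary covariates (same sample
#'   order).
#' @param alpha significance level for the covariate-association gate and the
#'   nested-model tests (default 0.05).
#' @return A status label string.
#' @export
confounder_label <- function(abundance, status, covariates, alpha = 0.05) {
  .assert(length(abundance) == length(status), "abundance/status length mismatch")
  .assert(is.data.frame(covariates) && nrow(covariates) == length(abundance),
          "covariates must be a data.frame aligned to the samples")
  ab <- rank_normal_transform(abundance)
  keep <- vapply(covariates, function(z) length(unique(z)) > 1, logical(1))
  covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0) return("OK_nc")
  for (nm in names(covariates)) {
    r <- suppressWarnings(stats::cor(status, covariates[[nm]]))
    if (is.finite(r) && abs(r) > 0.99) {
      warning(sprintf("covariate '%s' collinear with status (|r| > 0.99): label AD", nm))
      return("AD")
    }
  }
  p_assoc <- vapply(covariates, function(z) .covariate_assoc_p(ab, z), numeric(1))
  ok <- !is.na(p_assoc)
  p_adj <- rep(NA_real_, length(p_assoc))
  p_adj[ok] <- bh_adjust(p_assoc[ok])
  assoc <- names(covariates)[ok & p_adj < alpha]
  if (length(assoc) == 0) return("OK_nc")

  status_survives <- logical(0)
  confounders <- character(0)
  for (nm in assoc) {
    z <- covariates[[nm]]
    d <- data.frame(ab = ab, z = z, status = status)
    lrt1 <- stats::anova(stats::lm(ab ~ z, d), stats::lm(ab ~ z + status, d))$`Pr(>F)`[2]
    lrt2 <- stats::anova(stats::lm(ab ~ status, d), stats::lm(ab ~ status + z, d))$`Pr(>F)`[2]
    s_ok <- is.finite(lrt1) && lrt1 < alpha
    status_survives <- c(status_survives, s_ok)
    if (!s_ok && is.finite(lrt2) && lrt2 < alpha) confounders <- c(confounders, nm)
  }
  if (all(status_survives)) return("OK_d")
  if (length(confounders) > 0) return(paste0("C:", paste(confounders, collapse = ",")))
  "AD"
}

#' Deconfounded differential abundance
#'
#' Full screen-and-label pipeline: univariate rank-sum screen with BH
#' correction, then a confounder status label for every feature passing the
#' significance threshold. Features with `p_adj >=` `sig_threshold` are
#' labelled `NS`.
#'
#' @inheritParams univariate_screen
#' @param covariates character vector of covariate column names in `meta`
#'   (default: the metadata's declared covariates).
#' @param sig_threshold adjusted-p significance threshold (default 0.05).
#' @param alpha gate/nested-test level passed to [confounder_label()].
#' @return The [univariate_screen()] table plus a `status_label` column.
#' @export
deconfound <- function(table, meta, covariates = attr(meta, "covariates"),
                       min_prevalence = 0.10, sig_threshold = 0.05, alpha = 0.05) {
  meta_al <- .align_meta(table, meta)
  screen <- univariate_screen(table, meta, min_prevalence)
  v <- .ft_values(table)
  cov_df <- as.data.frame(meta_al)[, covariates, drop = FALSE]
  screen$status_label <- "NS"
  hits <- which(screen$p_adj < sig_threshold)
  for (i in hits) {
    screen$status_label[i] <- confounder_label(v[, screen$feature_id[i]],
                                               meta_al$status, cov_df, alpha)
  }
  .log_stage("differential", n_samples = nrow(v), n_features = nrow(screen),
             n_significant = length(hits))
  screen
}

#' Covariate-adjusted association scan
#'
#' For every (feature, target) pair, fits the linear model
#' `target ~ feature + covariates` with both feature and target
#' rank-normalized, and reports the signed standardized feature coefficient
#' with its p-value; BH correction is applied within each target family.
#' For metabolic-trait targets set `adjust_bmi = FALSE` to drop BMI from the
#' covariate set (BMI is itself the phenotype of interest there).
#'
#' @param features [feature_table] or numeric matrix (samples x features).
#' @param targets named numeric matrix/data.frame of outcome variables
#'   (samples x targets), same sample order as `features`.
#' @param covariates data.frame of adjustment covariates, same sample order.
#' @param adjust_bmi include a `bmi` covariate column if present
#'   (default TRUE).
#' @param feature_transform `"rank"` (default) rank-normalizes features;
#'   `"none"` enters them as-is (for binary features such as deletion
#'   genotypes).
#' @return data.frame with `feature`, `target`, `beta`, `p`, `p_adj`.
#' @export
association_scan <- function(features, targets, covariates,
                             adjust_bmi = TRUE,
                             feature_transform = c("rank", "none")) {
  feature_transform <- match.arg(feature_transform)
  fm <- .ft_values(features)
  tm <- as.matrix(targets)
  .assert(is.numeric(tm), "targets must be numeric")
  .assert(nrow(fm) == nrow(tm), "features/targets sample mismatch")
  cov_df <- as.data.frame(covariates)
  .assert(nrow(cov_df) == nrow(fm), "covariates not aligned to samples")
  if (!adjust_bmi) cov_df <- cov_df[, setdiff(names(cov_df), c("bmi", "BMI")), drop = FALSE]
  n <- nrow(fm)
  X <- stats::model.matrix(~ ., data = cov_df)
  .assert(n > ncol(X) + 1,
          "rank deficiency: n = %d samples but %d regressors", n, ncol(X) + 1)
  .assert(qr(X)$rank == ncol(X), "rank deficiency: collinear covariates")
  Q <- qr.Q(qr(X))
  df_resid <- n - ncol(X) - 1

  transform_cols <- function(m, how) {
    out <- m
    for (j in seq_len(ncol(m))) {
      col <- m[, j]
      if (how == "rank" && length(unique(col)) > 1) out[, j] <- rank_normal_transform(col)
    }
    out
  }
  F_t <- transform_cols(fm, feature_transform)
  T_t <- transform_cols(tm, "rank")
  const_f <- apply(fm, 2, function(col) length(unique(col)) == 1)
  if (any(const_f)) warning(sprintf("constant feature(s) skipped: %s",
                                    paste(colnames(fm)[const_f], collapse = ", ")))
  RF <- F_t - Q %*% (t(Q) %*% F_t)     # residualize on covariates
  RT <- T_t - Q %*% (t(Q) %*% T_t)
  rf2 <- colSums(RF^2)

  out <- vector("list", ncol(tm))
  for (k in seq_len(ncol(tm))) {
    ry <- RT[, k]
    num <- as.numeric(crossprod(RF, ry))
    beta <- num / rf2
    sse <- sum(ry^2) - beta * num
    se <- sqrt(pmax(sse, 0) / df_resid / rf2)
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), df_resid)
    p[const_f | rf2 < 1e-12] <- NA_real_
    okp <- !is.na(p)
    p_adj <- rep(NA_real_, length(p))
    p_adj[okp] <- bh_adjust(p[okp])
    out[[k]] <- data.frame(feature = colnames(fm), target = colnames(tm)[k],
                           beta = ifelse(okp, beta, NA_real_), p = p, p_adj = p_adj,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[!is.na(res$p), , drop = FALSE]
}
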