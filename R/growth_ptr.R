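# circular moving median over a window, ignoring masked bins
#' @keywords internal
#' @noRd
.circ_moving_median <- function(x, masked, window) {
  n <- length(x)
  half <- window %/% 2
  out <- rep(NA_real_, n)
  idx_ring <- c(seq_len(n), seq_len(n), seq_len(n))   # padded index ring
  for (i in seq_len(n)) {
    win <- idx_ring[(n + i - half):(n + i + half)]
    vals <- x[win][!masked[win]]
    if (length(vals) > 0) out[i] <- stats::median(vals)
  }
  out
}

#' Smooth a circular coverage profile
#'
#' Masks zero-coverage bins and outlier bins (outside median +/- 3 MAD of the
#' positive bins), then applies a circular moving median whose window spans
#' `window_frac` of the genome. The moving median is robust to residual
#' mapping artefacts a mean filter would smear out.
#'
#' @param p a [coverage_profile()] or numeric coverage vector.
#' @param window_frac window width as a fraction of the number of bins
#'   (default 5%; at least 3 bins — wide enough to reject mapping artefacts,
#'   narrow enough not to flatten the coverage extrema the PTR is read from).
#' @param max_masked_frac above this masked fraction the profile is flagged
#'   unusable (`qc_pass = FALSE`).
#' @return A list of class `smoothed_coverage`: `smoothed` (vector, `NA`
#'   where no data fall in the window), `masked` (logical), `covered_fraction`
#'   and `qc_pass`.
#' @export
smooth_coverage <- function(p, window_frac = 0.05, max_masked_frac = 0.40) {
  cov <- if (inherits(p, "coverage_profile")) p$coverage else as.numeric(p)
  n <- length(cov)
  window <- max(3L, as.integer(round(window_frac * n)))
  if (window %% 2 == 0) window <- window + 1L
  .assert(window >= 3, "smoothing window must cover >= 3 bins")
  pos <- cov[cov > 0]
  masked <- cov == 0
  if (length(pos) > 0) {
    med <- stats::median(pos)
    mad3 <- 3 * stats::mad(pos)
    if (mad3 > 0) masked <- masked | abs(cov - med) > mad3
  }
  covered <- mean(!masked)
  structure(list(smoothed = .circ_moving_median(cov, masked, window),
                 masked = masked,
                 covered_fraction = covered,
                 qc_pass = covered >= 1 - max_masked_frac),
            class = "smoothed_coverage")
}

# total squared error of per-sample linear fits of log2 coverage on the
# arm-position predictor, for a grid of (peak, trough) candidates
#' @keywords internal
#' @noRd
.pair_sse <- function(Y, W, pairs, n_bins) {
  Yw <- Y * W
  Sy <- rowSums(Yw)
  Syy <- rowSums(Yw^2)
  sse <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    u <- .arm_position(seq_len(n_bins), pairs[k, 1], pairs[k, 2], n_bins)
    Sw <- as.numeric(W %*% rep(1, n_bins))
    Su <- as.numeric(W %*% u)
    Suu <- as.numeric(W %*% u^2)
    Suy <- as.numeric(Yw %*% u)
    det <- Sw * Suu - Su^2
    slope <- (Sw * Suy - Su * Sy) / det
    # coverage is maximal at the peak: the log2 trend must not increase with
    # distance from it (otherwise peak and trough roles are mirror-swapped)
    slope <- pmin(slope, 0)
    icpt <- (Sy - slope * Su) / Sw
    sse_s <- Syy - 2 * slope * Suy - 2 * icpt * Sy +
      slope^2 * Suu + 2 * slope * icpt * Su + icpt^2 * Sw
    sse[k] <- sum(sse_s[is.finite(sse_s)])
  }
  sse
}

#' Locate the replication origin and terminus from multiple samples
#'
#' Grid search over circular (peak, trough) candidate pairs whose separation
#' lies in `[min_separation, max_separation]` of the genome. For each pair,
#' every sample's log2 smoothed coverage is fit piecewise-linearly in the
#' normalized circular distance from the peak (maximum at the peak, minimum
#' at the trough, linear on both arms); the pair minimizing total squared
#' error summed over samples wins.
#'
#' @param profiles list of [coverage_profile()]s of one species (>= 2 usable
#'   after smoothing QC).
#' @param min_separation,max_separation allowed circular peak-trough
#'   separation as a fraction of the genome (default 45-55%, the
#'   bidirectional-replication geometry).
#' @param window_frac smoothing window (see [smooth_coverage()]).
#' @return A list with `ori`, `ter` (1-based bin indices), `sse`,
#'   `indeterminate` (TRUE when all candidate pairs fit equally well — e.g.
#'   flat, non-replicating profiles), and `n_profiles_used`.
#' @export
fit_ori_ter <- function(profiles, min_separation = 0.45, max_separation = 0.55,
                        window_frac = 0.05) {
  .assert(length(profiles) >= 2, "need >= 2 profiles")
  n_bins <- length(profiles[[1]]$coverage)
  .assert(all(vapply(profiles, function(p) length(p$coverage), 0L) == n_bins),
          "profiles have differing bin counts")
  sm <- lapply(profiles, smooth_coverage, window_frac = window_frac)
  usable <- vapply(sm, function(s) s$qc_pass, logical(1))
  if (!all(usable)) warning(sprintf("%d unusable profile(s) dropped", sum(!usable)))
  .assert(sum(usable) >= 2, "need >= 2 usable profiles after QC")
  sm <- sm[usable]

  Y <- t(vapply(sm, function(s) log2(s$smoothed), numeric(n_bins)))
  W <- t(vapply(sm, function(s) as.numeric(is.finite(log2(s$smoothed))), numeric(n_bins)))
  Y[!is.finite(Y)] <- 0

  smin <- max(1L, as.integer(round(min_separation * n_bins)))
  smax <- as.integer(round(max_separation * n_bins))
  .assert(smin <= smax && smax < n_bins,
          "no candidate pair satisfies the separation window on this genome")
  seps <- smin:smax
  pairs <- cbind(rep(seq_len(n_bins), each = length(seps)),
                 as.integer((rep(seq_len(n_bins), each = length(seps)) +
                               rep(seps, n_bins) - 1L) %% n_bins + 1L))
  sse <- .pair_sse(Y, W, pairs, n_bins)
  best <- which.min(sse)
  spread <- max(sse) - min(sse)
  indeterminate <- !is.finite(spread) || spread <= 1e-9 * max(abs(sse), 1)
  list(ori = pairs[best, 1], ter = pairs[best, 2], sse = sse[best],
       indeterminate = indeterminate, n_profiles_used = sum(usable))
}

#' Peak-to-trough ratio of one coverage profile
#'
#' PTR = smoothed coverage at the predicted origin divided by that at the
#' predicted terminus (linear, not log, scale). When the raw ratio falls
#' below 1 the reciprocal is reported and `flipped` is set. The estimate
#' passes QC only if the profile's covered fraction is at least
#' `min_covered_fraction` and the smoothed trough coverage is positive.
#'
#' @param p a [coverage_profile()].
#' @param ori,ter 1-based bin indices from [fit_ori_ter()].
#' @param window_frac smoothing window.
#' @param min_covered_fraction QC floor on the unmasked-bin fraction.
#' @return One-row data.frame: `species_id`, `sample_id`, `ptr`, `peak_bin`,
#'   `trough_bin`, `qc_pass`, `covered_fraction`, `flipped`.
#' @export
compute_ptr <- function(p, ori, ter, window_frac = 0.05,
                        min_covered_fraction = 0.6) {
  .assert(inherits(p, "coverage_profile"), "`p` must be a coverage_profile")
  n <- length(p$coverage)
  .assert(ori >= 1 && ori <= n && ter >= 1 && ter <= n, "ori/ter outside the genome")
  sm <- smooth_coverage(p, window_frac = window_frac)
  peak <- sm$smoothed[ori]
  trough <- sm$smoothed[ter]
  ok <- is.finite(peak) && is.finite(trough) && trough > 0 &&
    sm$covered_fraction >= min_covered_fraction
  ptr <- NA_real_
  flipped <- FALSE
  if (ok) {
    ptr <- peak / trough
    if (ptr < 1) { ptr <- 1 / ptr; flipped <- TRUE }
  }
  data.frame(species_id = p$species_id, sample_id = p$sample_id,
             ptr = ptr, peak_bin = ori, trough_bin = ter,
             qc_pass = ok, covered_fraction = sm$covered_fraction,
             flipped = flipped, stringsAsFactors = FALSE)
}

#' Cohort-level replication-rate comparison
#'
#' For every species: locates ori/ter across its samples, computes per-sample
#' PTRs, keeps species with QC-passing estimates in at least `min_samples`
#' samples, and compares PTR between the two status groups with a two-sided
#' rank-sum test (BH across species). Also compares the per-sample median PTR
#' across retained species between groups.
#'
#' @param profile_sets named list: species id -> list of
#'   [coverage_profile()]s (the `sample_id` fields link to metadata).
#' @param meta [sample_metadata].
#' @param min_samples retention threshold on QC-passing estimates
#'   (default 20).
#' @return A list with `estimates` (long per-species per-sample PTR table),
#'   `species_tests` (per-species rank-sum p and BH adjustment, plus median
#'   PTR per group), and `cohort_test` (rank-sum on per-sample median PTR).
#' @export
cohort_ptr <- function(profile_sets, meta, min_samples = 20) {
  .assert(length(profile_sets) >= 1, "no species supplied")
  .assert(min_samples <= nrow(meta),
          "min_samples (%d) exceeds the cohort size (%d)", min_samples, nrow(meta))
  est <- list()
  for (sp in names(profile_sets)) {
    profs <- profile_sets[[sp]]
    fit <- tryCatch(fit_ori_ter(profs), error = function(e) NULL)
    if (is.null(fit) || fit$indeterminate) next
    rows <- do.call(rbind, lapply(profs, compute_ptr, ori = fit$ori, ter = fit$ter))
    rows <- rows[rows$qc_pass, , drop = FALSE]
    if (nrow(rows) >= min_samples) est[[sp]] <- rows
  }
  .assert(length(est) > 0, "no species retained at min_samples = %d", min_samples)
  est_all <- do.call(rbind, est)
  rownames(est_all) <- NULL
  status <- stats::setNames(meta$status, meta$sample_id)
  est_all$status <- status[est_all$sample_id]

  tests <- do.call(rbind, lapply(split(est_all, est_all$species_id), function(df) {
    x <- df$ptr[df$status == 1]; y <- df$ptr[df$status == 0]
    p <- if (length(x) >= 2 && length(y) >= 2) rank_sum_test(x, y) else NA_real_
    data.frame(species_id = df$species_id[1], n_case = length(x), n_control = length(y),
               median_case = stats::median(x), median_control = stats::median(y),
               p = p, stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  okp <- !is.na(tests$p)
  tests$p_adj <- NA_real_
  tests$p_adj[okp] <- bh_adjust(tests$p[okp])

  med_by_sample <- tapply(est_all$ptr, est_all$sample_id, stats::median)
  sm <- status[names(med_by_sample)]
  cohort_test <- if (sum(sm == 1) >= 2 && sum(sm == 0) >= 2)
    list(p = rank_sum_test(med_by_sample[sm == 1], med_by_sample[sm == 0]),
         median_case = stats::median(med_by_sample[sm == 1]),
         median_control = stats::median(med_by_sample[sm == 0]))
  else list(p = NA_real_, median_case = NA_real_, median_control = NA_real_)

  .log_stage("ptr", n_species = length(est), n_estimates = nrow(est_all))
  list(estimates = est_all, species_tests = tests, cohort_test = cohort_test)
}

#' Read per-species binned coverage from TSV
#'
#' Expects columns `sample`, `bin_index` (1-based), `coverage`.
#'
#' @param path TSV path.
#' @param species_id species identifier for the profiles.
#' @param bin_size bin width in bp.
#' @return List of [coverage_profile()]s, one per sample.
#' @export
read_coverage_tsv <- function(path, species_id = basename(path), bin_size = 10000) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE)
  .assert(all(c("sample", "bin_index", "coverage") %in% names(df)),
          "coverage TSV needs columns sample, bin_index, coverage")
  lapply(split(df, df$sample), function(d) {
    d <- d[order(d$bin_index), ]
    coverage_profile(species_id, as.character(d$sample[1]), d$coverage, bin_size)
  })
}
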