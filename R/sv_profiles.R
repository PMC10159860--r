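#' Per-sample deletion calls from a 1-kbp coverage matrix
#'
#' Coverage is normalized per sample by that sample's median bin coverage for
#' the species; a (sample, bin) cell is called deleted when the normalized
#' coverage falls below `deletion_coverage_frac`. Samples whose median
#' coverage is below `min_median_coverage` (default 1x) are masked — too
#' little evidence to call anything.
#'
#' @param coverage samples x bins numeric matrix (row/col names required).
#' @param deletion_coverage_frac normalized-coverage threshold below which a
#'   cell is deleted (default 0.25).
#' @param min_median_coverage mask samples with species median coverage below
#'   this (default 1).
#' @return A list with `deleted` (samples x bins logical; `NA` rows for
#'   masked samples), `masked` (logical per sample) and `normalized`
#'   (coverage / per-sample median), or `NULL` with a warning when every
#'   sample is masked.
#' @export
call_deletions <- function(coverage, deletion_coverage_frac = 0.25,
                           min_median_coverage = 1) {
  .assert(is.matrix(coverage) && is.numeric(coverage), "coverage must be a numeric matrix")
  .assert(!is.null(rownames(coverage)) && !is.null(colnames(coverage)),
          "coverage needs sample row names and bin column names")
  med <- apply(coverage, 1, stats::median)
  masked <- med < min_median_coverage
  if (all(masked)) {
    warning("all samples below the median-coverage mask: species skipped")
    return(NULL)
  }
  normalized <- coverage / med
  deleted <- normalized < deletion_coverage_frac
  deleted[masked, ] <- NA
  list(deleted = deleted, masked = masked, normalized = normalized)
}

# merge runs of equal class labels into regions
#' @keywords internal
#' @noRd
.merge_runs <- function(class_per_bin, gap = 0) {
  r <- rle(class_per_bin)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  regions <- data.frame(start = starts, end = ends, class = r$values,
                        stringsAsFactors = FALSE)
  if (gap > 0 && nrow(regions) > 2) {
    # bridge small runs of a different class between two same-class runs
    i <- 2
    while (i < nrow(regions)) {
      if (regions$class[i - 1] == regions$class[i + 1] &&
          regions$class[i] != regions$class[i - 1] &&
          regions$end[i] - regions$start[i] + 1 <= gap) {
        regions$end[i - 1] <- regions$end[i + 1]
        regions <- regions[-c(i, i + 1), ]
      } else i <- i + 1
    }
  }
  regions
}

#' Classify genomic bins into variable and deletion structural variants
#'
#' Computes, over unmasked samples, the population deletion rate of every bin
#' and applies the canonical rule: rate < 25% = variable SV (vSV), 25-75%
#' inclusive = deletion SV (dSV), > 75% = excluded from analysis. Adjacent
#' same-class bins merge into regions. A sample carries a dSV region when
#' more than 50% of the region's bins are deleted in it; a vSV region's value
#' in a sample is the across-sample z-scored normalized coverage averaged
#' over the region's bins.
#'
#' @param calls result of [call_deletions()].
#' @param species_id identifier stored on the profile.
#' @param min_unmasked minimum number of unmasked samples (default 10;
#'   mirrors a 10% prevalence rule at cohort scale).
#' @param gap merge regions of the same class separated by at most this many
#'   bins of another class (default 0 = plain adjacency).
#' @return An `sv_profile`: list with `regions` (start/end bins, class,
#'   population deletion rate), `dsv_matrix` (samples x dSV regions, 0/1, NA
#'   for masked samples), `vsv_matrix` (samples x vSV regions, standardized
#'   coverage), `masked`, `species_id`; or `NULL` with a warning when fewer
#'   than `min_unmasked` samples are available.
#' @export
classify_regions <- function(calls, species_id = "species", min_unmasked = 10,
                             gap = 0) {
  if (is.null(calls)) return(NULL)
  del <- calls$deleted
  unm <- !calls$masked
  if (sum(unm) < min_unmasked) {
    warning(sprintf("only %d unmasked samples (< %d): species skipped",
                    sum(unm), min_unmasked))
    return(NULL)
  }
  rate <- colMeans(del[unm, , drop = FALSE])
  eps <- 1e-9
  cls <- ifelse(rate < 0.25 - eps, "vSV",
                ifelse(rate <= 0.75 + eps, "dSV", "excluded"))
  regions <- .merge_runs(cls, gap = gap)
  regions$population_deletion_rate <- vapply(seq_len(nrow(regions)), function(i) {
    mean(rate[regions$start[i]:regions$end[i]])
  }, numeric(1))
  kept <- regions[regions$class != "excluded", , drop = FALSE]
  rownames(kept) <- NULL

  n_samp <- nrow(del)
  dsv_rows <- which(kept$class == "dSV")
  vsv_rows <- which(kept$class == "vSV")
  region_name <- function(i) sprintf("%s:%d-%d", species_id, kept$start[i], kept$end[i])

  dsv <- matrix(NA_real_, n_samp, length(dsv_rows),
                dimnames = list(rownames(del), vapply(dsv_rows, region_name, "")))
  for (j in seq_along(dsv_rows)) {
    bins <- kept$start[dsv_rows[j]]:kept$end[dsv_rows[j]]
    frac_del <- rowMeans(del[, bins, drop = FALSE])
    dsv[, j] <- as.numeric(frac_del > 0.5)
  }
  vsv <- matrix(NA_real_, n_samp, length(vsv_rows),
                dimnames = list(rownames(del), vapply(vsv_rows, region_name, "")))
  if (length(vsv_rows) > 0) {
    norm <- calls$normalized
    zs <- norm
    zs[!unm, ] <- NA
    mu <- colMeans(zs, na.rm = TRUE)
    sdv <- apply(zs, 2, stats::sd, na.rm = TRUE)
    sdv[sdv < 1e-12] <- 1
    zs <- sweep(sweep(zs, 2, mu), 2, sdv, "/")
    for (j in seq_along(vsv_rows)) {
      bins <- kept$start[vsv_rows[j]]:kept$end[vsv_rows[j]]
      vsv[, j] <- rowMeans(zs[, bins, drop = FALSE])
    }
  }
  structure(list(species_id = species_id, regions = kept,
                 dsv_matrix = dsv, vsv_matrix = vsv,
                 masked = calls$masked, n_unmasked = sum(unm)),
            class = "sv_profile")
}

#' Drop species profiled in too few samples
#'
#' Species whose unmasked-sample count is below `min_frac` of the cohort are
#' removed (the threshold is inclusive: exactly 10% is kept).
#'
#' @param profiles named list of `sv_profile`s.
#' @param cohort_size total number of samples in the cohort (>= 10).
#' @param min_frac minimum fraction of samples (default 10%).
#' @return The filtered list.
#' @export
sv_prevalence_filter <- function(profiles, cohort_size, min_frac = 0.10) {
  .assert(cohort_size >= 10, "cohort size must be >= 10")
  keep <- vapply(profiles, function(p) {
    !is.null(p) && p$n_unmasked >= min_frac * cohort_size - 1e-9
  }, logical(1))
  profiles[keep]
}

# per-species feature block: dSV 0/1 columns + vSV standardized columns
# shifted non-negative by per-feature minimum subtraction
#' @keywords internal
#' @noRd
.sv_feature_block <- function(p) {
  blocks <- list()
  if (ncol(p$dsv_matrix) > 0) blocks <- c(blocks, list(p$dsv_matrix))
  if (ncol(p$vsv_matrix) > 0) {
    v <- p$vsv_matrix
    mins <- apply(v, 2, min, na.rm = TRUE)
    blocks <- c(blocks, list(sweep(v, 2, mins)))
  }
  if (length(blocks) == 0) return(NULL)
  do.call(cbind, blocks)
}

#' Structural-variant beta diversity
#'
#' Builds per-sample SV genotype vectors (dSV presence/absence plus vSV
#' standardized coverage shifted non-negative) and computes pairwise Canberra
#' distances over the species both samples of a pair are profiled in
#' (pairwise-complete). Pairs sharing no species get `NA` with a warning and
#' are excluded from the group comparison.
#'
#' @param profiles named list of `sv_profile`s (see [classify_regions()]).
#' @param meta [sample_metadata] (used for the group comparison).
#' @return A list with `distance` (samples x samples matrix, possibly with
#'   `NA`) and `comparison` (see [within_group_beta()]).
#' @export
sv_beta_diversity <- function(profiles, meta) {
  profiles <- profiles[!vapply(profiles, is.null, logical(1))]
  .assert(length(profiles) > 0, "no SV profiles supplied")
  ids <- meta$sample_id
  blocks <- lapply(profiles, .sv_feature_block)
  ok <- !vapply(blocks, is.null, logical(1))
  blocks <- blocks[ok]
  profiles <- profiles[ok]
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  avail <- vapply(profiles, function(p) !p$masked[ids], logical(n))
  if (is.null(dim(avail))) avail <- matrix(avail, nrow = n)
  any_na <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- which(avail[i, ] & avail[j, ])
      if (length(shared) == 0) {
        d[i, j] <- d[j, i] <- NA_real_
        any_na <- TRUE
        next
      }
      xi <- unlist(lapply(blocks[shared], function(b) b[ids[i], ]))
      xj <- unlist(lapply(blocks[shared], function(b) b[ids[j], ]))
      keep <- !is.na(xi) & !is.na(xj)
      d[i, j] <- d[j, i] <- canberra(xi[keep], xj[keep])
    }
  }
  if (any_na) warning("sample pair(s) sharing no profiled species: distance recorded as NA")
  groups <- stats::setNames(ifelse(meta$status == 1, "case", "control"), ids)
  comparison <- tryCatch(within_group_beta(d, groups), error = function(e) NULL)
  list(distance = d, comparison = comparison)
}

#' Associations between SV genotypes and host phenotypes
#'
#' Delegates to [association_scan()]: dSV features enter as binary
#' regressors, vSV features are rank-normalized; BH correction within each
#' phenotype. Only the species' unmasked samples are used; constant features
#' are skipped with a warning.
#'
#' @param profile an `sv_profile`.
#' @param meta [sample_metadata] carrying the phenotype columns.
#' @param phenotypes character vector of phenotype column names.
#' @param covariates character vector of covariate column names.
#' @param adjust_bmi passed to [association_scan()].
#' @return Association table (`feature`, `target`, `beta`, `p`, `p_adj`).
#' @export
sv_association <- function(profile, meta, phenotypes = attr(meta, "phenotypes"),
                           covariates = attr(meta, "covariates"),
                           adjust_bmi = TRUE) {
  .assert(inherits(profile, "sv_profile"), "`profile` must be an sv_profile")
  ids <- rownames(profile$dsv_matrix)
  unm <- ids[!profile$masked]
  meta_sub <- as.data.frame(meta)[match(unm, meta$sample_id), , drop = FALSE]
  targets <- as.matrix(meta_sub[, phenotypes, drop = FALSE])
  cov_df <- meta_sub[, covariates, drop = FALSE]
  res <- list()
  if (ncol(profile$dsv_matrix) > 0) {
    dsv <- profile$dsv_matrix[unm, , drop = FALSE]
    res <- c(res, list(association_scan(dsv, targets, cov_df,
                                        adjust_bmi = adjust_bmi,
                                        feature_transform = "none")))
  }
  if (ncol(profile$vsv_matrix) > 0) {
    vsv <- profile$vsv_matrix[unm, , drop = FALSE]
    res <- c(res, list(association_scan(vsv, targets, cov_df,
                                        adjust_bmi = adjust_bmi,
                                        feature_transform = "rank")))
  }
  .assert(length(res) > 0, "profile has no SV features")
  out <- do.call(rbind, res)
  # re-adjust BH within each phenotype across the combined dSV+vSV features
  for (t in unique(out$target)) {
    sel <- out$target == t
    out$p_adj[sel] <- bh_adjust(out$p[sel])
  }
  rownames(out) <- NULL
  out
}
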