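test_that("deletion calling recovers planted zero-coverage regions", {
  planted <- data.frame(start = 11, end = 20, fraction = 1)
  pop <- generate_sv_population(30, 50, planted, seed = 5, depth = 50)
  calls <- call_deletions(pop$coverage)
  expect_true(all(calls$deleted[!calls$masked, 11:20]))
  # uniform coverage -> no deletions
  uni <- matrix(50, 10, 30, dimnames = list(sprintf("s%02d", 1:10),
                                            sprintf("b%02d", 1:30)))
  expect_false(any(call_deletions(uni)$deleted))
  # low-coverage samples are masked; all-masked species is skipped
  low <- uni * 0.001
  expect_warning(expect_null(call_deletions(low)), "skipped")
})

test_that("deletion calls agree with generator truth at 50x depth", {
  planted <- data.frame(start = c(11, 31), end = c(20, 35), fraction = c(0.5, 0.3))
  pop <- generate_sv_population(120, 60, planted, seed = 6, depth = 50)
  calls <- call_deletions(pop$coverage)
  truth_cells <- cbind(pop$deleted[, 1] %o% rep(TRUE, 10),
                       pop$deleted[, 2] %o% rep(TRUE, 5))
  called_cells <- calls$deleted[, c(11:20, 31:35)]
  expect_gte(mean(called_cells == truth_cells, na.rm = TRUE), 0.98)
})

test_that("region classification applies the 25/75 rule with inclusive bounds", {
  # craft a deleted matrix with exact per-bin rates over 100 samples
  n <- 100
  rates <- c(0.10, 0.25, 0.50, 0.75, 0.80)
  del <- sapply(rates, function(r) rep(c(TRUE, FALSE), c(r * n, n - r * n)))
  dimnames(del) <- list(sprintf("s%03d", 1:n), sprintf("b%d", 1:5))
  calls <- list(deleted = del, masked = rep(FALSE, n),
                normalized = matrix(1, n, 5, dimnames = dimnames(del)))
  prof <- classify_regions(calls, "sp")
  cls <- character(5)
  for (i in seq_len(nrow(prof$regions)))
    cls[prof$regions$start[i]:prof$regions$end[i]] <- prof$regions$class[i]
  expect_equal(cls, c("vSV", "dSV", "dSV", "dSV", ""))  # 0.80 excluded
  expect_true(all(prof$regions$population_deletion_rate[prof$regions$class == "dSV"] >= 0.25 &
                    prof$regions$population_deletion_rate[prof$regions$class == "dSV"] <= 0.75))
  # too few unmasked samples -> species skipped
  calls$masked[1:95] <- TRUE
  calls$deleted[1:95, ] <- NA
  expect_warning(expect_null(classify_regions(calls, "sp")), "skipped")
})

test_that("per-sample dSV genotype follows the majority rule", {
  n <- 20
  del <- matrix(FALSE, n, 4, dimnames = list(sprintf("s%02d", 1:n), paste0("b", 1:4)))
  del[1:10, ] <- TRUE              # rate 0.5 everywhere -> one dSV region of 4 bins
  del[11, 1:3] <- TRUE             # 75% of region bins -> deleted
  del[12, 1:2] <- TRUE             # 50% -> not deleted (> 50% required)
  calls <- list(deleted = del, masked = rep(FALSE, n),
                normalized = matrix(1, n, 4, dimnames = dimnames(del)))
  prof <- classify_regions(calls, "sp", min_unmasked = 10)
  expect_equal(ncol(prof$dsv_matrix), 1)
  expect_equal(unname(prof$dsv_matrix[11, 1]), 1)
  expect_equal(unname(prof$dsv_matrix[12, 1]), 0)
})

test_that("prevalence filter on SV profiles is inclusive at the threshold", {
  mk <- function(n_unm) structure(list(n_unmasked = n_unm), class = "sv_profile")
  profs <- list(a = mk(5), b = mk(10), c = mk(40))
  kept <- sv_prevalence_filter(profs, cohort_size = 100)
  expect_setequal(names(kept), c("b", "c"))
})

test_that("SV beta diversity separates groups with disjoint deletion patterns", {
  set.seed(50)
  n <- 30
  ids <- c(sprintf("case_%03d", 1:15), sprintf("ctrl_%03d", 1:15))
  status <- rep(c(1, 0), each = 15)
  # deletions present (rate ~ 0.5) only among cases in region 1, only among
  # controls in region 2; shared noise elsewhere
  cov <- matrix(rlnorm(n * 40, log(50), 0.2), n, 40,
                dimnames = list(ids, sprintf("b%02d", 1:40)))
  cov[sample(which(status == 1), 8), 5:10] <- 0.1
  cov[sample(which(status == 0), 8), 25:30] <- 0.1
  prof <- classify_regions(call_deletions(cov), "sp")
  meta <- sample_metadata(data.frame(sample_id = ids, status = status))
  res <- sv_beta_diversity(list(sp = prof), meta)
  d <- res$distance
  between <- d[1:15, 16:30]
  within <- c(d[1:15, 1:15][upper.tri(diag(15))], d[16:30, 16:30][upper.tri(diag(15))])
  expect_gt(median(between), median(within))
  expect_equal(d, t(d))
  # identical profiles across samples -> all-zero distances
  cov0 <- matrix(50, 20, 30, dimnames = list(sprintf("x%02d", 1:20), sprintf("b%02d", 1:30)))
  prof0 <- classify_regions(call_deletions(cov0), "sp0", min_unmasked = 5)
  meta0 <- sample_metadata(data.frame(sample_id = sprintf("x%02d", 1:20),
                                      status = rep(c(1, 0), each = 10)))
  res0 <- sv_beta_diversity(list(sp0 = prof0), meta0)
  expect_true(all(res0$distance == 0))
})

test_that("planted dSV effect on a phenotype is the top association", {
  set.seed(51)
  n <- 80
  ids <- sprintf("s%03d", 1:n)
  cov <- matrix(rlnorm(n * 30, log(50), 0.2), n, 30,
                dimnames = list(ids, sprintf("b%02d", 1:30)))
  carriers <- sample(n, 40)
  cov[carriers, 11:14] <- 0.1
  prof <- classify_regions(call_deletions(cov), "sp")
  genotype <- prof$dsv_matrix[, 1]
  pheno <- 1.2 * genotype + rnorm(n)
  meta <- sample_metadata(data.frame(sample_id = ids, status = rep(c(1, 0), n / 2),
                                     age = rnorm(n, 24, 4), score = pheno),
                          covariates = "age", phenotypes = "score")
  res <- sv_association(prof, meta)
  top <- res[which.min(res$p), ]
  expect_equal(top$feature, colnames(prof$dsv_matrix)[1])
  expect_gt(top$beta, 0)
})
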