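test_that("univariate screen recovers complete separation and filters prevalence", {
  set.seed(30)
  n <- 40
  m <- matrix(runif(n * 3, 0.1, 1), n)
  status <- rep(c(1, 0), each = n / 2)
  m[status == 0, 1] <- 0                      # feature 1 only in cases
  m[1:(n - 1), 3] <- 0                        # feature 3: prevalence 1/40
  rownames(m) <- sprintf("s%02d", 1:n); colnames(m) <- c("only_cases", "noise", "rare")
  ft <- make_ft(m / rowSums(m))
  meta <- sample_metadata(data.frame(sample_id = rownames(m), status = status))
  scr <- univariate_screen(ft, meta, min_prevalence = 0.10)
  expect_false("rare" %in% scr$feature_id)
  expect_equal(scr$effect_size[scr$feature_id == "only_cases"], 1)
  expect_equal(scr$prevalence_control[scr$feature_id == "only_cases"], 0)

  meta1 <- sample_metadata(data.frame(sample_id = rownames(m), status = rep(1, n)))
  expect_error(univariate_screen(ft, meta1), "single-status|status group")
})

test_that("screen agrees with the scalar rank-sum and Cliff operations", {
  coh <- small_null_cohort(7, n_bact = 12)
  scr <- univariate_screen(coh$bacteria, coh$metadata)
  st <- coh$metadata$status
  for (f in scr$feature_id[1:5]) {
    v <- coh$bacteria[, f]
    expect_equal(scr$p_raw[scr$feature_id == f], rank_sum_test(v[st == 1], v[st == 0]))
    expect_equal(scr$effect_size[scr$feature_id == f],
                 cliffs_delta(v[st == 1], v[st == 0]))
  }
  # permuting sample order leaves the records unchanged
  perm <- sample(nrow(coh$bacteria))
  ft_p <- feature_table(unclass(coh$bacteria)[perm, ], "bacteria", "relative")
  scr_p <- univariate_screen(ft_p, coh$metadata)
  expect_equal(scr, scr_p)
})

test_that("confounder labels: medication-driven feature is flagged, constants skipped", {
  set.seed(31)
  n <- 150
  status <- rep(c(1, 0), each = n / 2)
  med <- rbinom(n, 1, ifelse(status == 1, 0.65, 0.05))
  conf_feature <- exp(rnorm(n) + 1.8 * med)         # depends on medication only
  covs <- data.frame(age = rnorm(n, 24, 4), smoking = rbinom(n, 1, 0.2),
                     medication = med)
  expect_match(confounder_label(conf_feature, status, covs), "^C:.*medication")
  # a constant covariate is skipped: result identical to omitting it
  covs2 <- cbind(covs, flat = 1)
  expect_identical(confounder_label(conf_feature, status, covs2),
                   confounder_label(conf_feature, status, covs))
  # collinear covariate yields AD with a warning, not a crash
  covs3 <- data.frame(copy = status)
  expect_warning(lab <- confounder_label(conf_feature, status, covs3), "collinear")
  expect_identical(lab, "AD")
  # a genuine status signal with independent covariates stays OK_*
  true_feature <- exp(rnorm(n) + 1.2 * status)
  expect_match(confounder_label(true_feature, status, covs), "^OK")
})

test_that("deconfound labels partition features and NS tracks the threshold", {
  coh <- generate_cohort(n_cases = 40, n_controls = 40, n_bacteria = 30,
                         n_viruses = 0, n_metabolites = 0,
                         truth = truth_config(n_differential = 3, n_confounded = 2,
                                              n_mediation = 0), seed = 8)
  rec <- deconfound(coh$bacteria, coh$metadata)
  expect_equal(nrow(rec), 30)
  expect_true(all((rec$status_label == "NS") == (rec$p_adj >= 0.05)))
  expect_true(all(rec$p_adj >= rec$p_raw))
})

test_that("association scan matches lm and kills covariate-driven signals", {
  set.seed(32)
  n <- 120
  covs <- data.frame(age = rnorm(n), bmi = rnorm(n), smoking = rbinom(n, 1, 0.3))
  f <- matrix(exp(rnorm(n * 4)), n, dimnames = list(NULL, paste0("f", 1:4)))
  y <- cbind(t1 = rnorm(n), t2 = rnorm(n))
  res <- association_scan(f, y, covs)
  # oracle: explicit lm on the same transformed variables
  for (k in 1:4) {
    d <- data.frame(y = rank_normal_transform(y[, 1]),
                    x = rank_normal_transform(f[, k]), covs)
    fit <- summary(lm(y ~ x + age + bmi + smoking, d))$coefficients
    row <- res[res$feature == paste0("f", k) & res$target == "t1", ]
    expect_equal(row$beta, fit["x", "Estimate"], tolerance = 1e-10)
    expect_equal(row$p, fit["x", "Pr(>|t|)"], tolerance = 1e-10)
  }
  # self-association: target = copy of a feature
  y2 <- cbind(self = f[, 2])
  res2 <- association_scan(f, y2, covs)
  expect_equal(res2$feature[which.min(res2$p)], "f2")
  expect_equal(res2$beta[res2$feature == "f2"], 1, tolerance = 0.05)
  # covariate-driven association disappears under adjustment
  set.seed(33)
  z <- rnorm(n)
  f3 <- matrix(exp(0.8 * z + rnorm(n, 0, 0.6)), n, dimnames = list(NULL, "fz"))
  y3 <- cbind(t = 0.8 * z + rnorm(n, 0, 0.6))
  with_cov <- association_scan(f3, y3, data.frame(z = z))
  without_cov <- association_scan(f3, y3, data.frame(age = rnorm(n)))
  expect_gt(with_cov$p_adj, 0.1)
  expect_lt(without_cov$p_adj, 0.001)
  # rank deficiency is reported
  expect_error(association_scan(f[1:4, ], y[1:4, ], covs[1:4, ]), "rank deficiency")
})
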