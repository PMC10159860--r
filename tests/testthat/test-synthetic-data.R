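test_that("cohort generation is deterministic and compositionally closed", {
  c1 <- generate_cohort(n_cases = 10, n_controls = 10, n_bacteria = 15,
                        n_viruses = 5, n_metabolites = 5, seed = 42,
                        truth = truth_config(n_differential = 3,
                                             n_confounded = 2, n_mediation = 1))
  c2 <- generate_cohort(n_cases = 10, n_controls = 10, n_bacteria = 15,
                        n_viruses = 5, n_metabolites = 5, seed = 42,
                        truth = truth_config(n_differential = 3,
                                             n_confounded = 2, n_mediation = 1))
  expect_identical(c1$bacteria, c2$bacteria)
  expect_identical(c1$metabolites, c2$metabolites)
  expect_identical(as.data.frame(c1$metadata), as.data.frame(c2$metadata))
  # byte-identical on disk too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(c1, d1); write_cohort(c2, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "bacteria.tsv"))),
                   unname(tools::md5sum(file.path(d2, "bacteria.tsv"))))

  expect_true(all(abs(rowSums(c1$bacteria) - 1) < 1e-9))
  expect_true(all(abs(rowSums(c1$viruses) - 1) < 1e-9))
  # every id recorded in truth exists in the generated tables
  expect_true(all(c1$truth$differential_features$feature_id %in% colnames(c1$bacteria)))
  expect_true(all(c1$truth$mediation_paths$mediator %in% colnames(c1$metabolites)))
  expect_true(all(c1$truth$mediation_paths$outcome %in% names(c1$metadata)))
})

test_that("impossible truth configurations are rejected", {
  expect_error(generate_cohort(n_cases = 5, n_controls = 5, n_bacteria = 4,
                               n_viruses = 0, n_metabolites = 0,
                               truth = truth_config(n_differential = 5,
                                                    n_confounded = 0,
                                                    n_mediation = 0), seed = 1),
               "more planted features")
  expect_error(generate_cohort(n_cases = 2, n_controls = 5, n_bacteria = 4,
                               n_viruses = 0, n_metabolites = 0,
                               truth = null_truth_config(), seed = 1),
               ">= 3 samples")
})

test_that("planted Cliff effects rank the true features on top", {
  # delta ~ 0.6 on 6 features: they should lead the |effect| ranking
  hits <- 0
  for (s in 1:5) {
    coh <- generate_cohort(n_cases = 70, n_controls = 70, n_bacteria = 60,
                           n_viruses = 0, n_metabolites = 0,
                           truth = truth_config(n_differential = 6,
                                                n_confounded = 0,
                                                n_mediation = 0), seed = s)
    scr <- univariate_screen(coh$bacteria, coh$metadata)
    top <- scr$feature_id[order(-abs(scr$effect_size))][1:10]
    hits <- hits + all(coh$truth$differential_features$feature_id %in% top)
  }
  expect_gte(hits, 4)
})

test_that("coverage generator hits the closed-form expectation", {
  gs <- genome_sim(1e6, ori_position = 0, ter_position = 5e5, true_ptr = 2,
                   read_depth = 100)
  sim <- generate_coverage(gs, 1, seed = 1, expected = TRUE)
  cov <- sim$profiles[[1]]$coverage
  expect_equal(cov[sim$ori_bin] / cov[sim$ter_bin], 2.0, tolerance = 1e-12)

  gs1 <- genome_sim(1e6, 0, 5e5, 1, 100)
  flat <- generate_coverage(gs1, 1, seed = 1, expected = TRUE)$profiles[[1]]$coverage
  expect_equal(max(flat) / min(flat), 1, tolerance = 1e-12)

  # Poisson draws concentrate on the expectation
  sim2 <- generate_coverage(genome_sim(1e6, 0, 5e5, 1.5, 200), 50, seed = 2)
  mean_cov <- colMeans(do.call(rbind, lapply(sim2$profiles, `[[`, "coverage")))
  expec <- generate_coverage(genome_sim(1e6, 0, 5e5, 1.5, 200), 1, seed = 1,
                             expected = TRUE)$profiles[[1]]$coverage
  expect_lt(max(abs(mean_cov - expec) / expec), 0.05)

  expect_error(genome_sim(1e6, 0, 5e5, 0.8, 100), "true_ptr")
  expect_error(genome_sim(1e6, 0, 2e5, 2, 100), "separation")
})

test_that("SV population generator reproduces planted deletion fractions", {
  planted <- data.frame(start = c(10, 40), end = c(19, 49), fraction = c(0.5, 0))
  pop <- generate_sv_population(100, 60, planted, seed = 3, depth = 50)
  rate <- mean(pop$deleted[, 1])
  expect_lt(abs(rate - 0.5), 0.1)
  expect_equal(sum(pop$deleted[, 2]), 0)
  expect_true(all(pop$coverage[pop$deleted[, 1], 10:19] < 5))
  expect_error(generate_sv_population(10, 60,
                                      data.frame(start = c(1, 5), end = c(6, 9),
                                                 fraction = 0.5), seed = 1),
               "overlap")
})
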