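test_that("mediate recovers the linear-Gaussian closed form a*b", {
  set.seed(60)
  n <- 500
  t_v <- rnorm(n)
  m_v <- 0.5 * t_v + sqrt(1 - 0.25) * rnorm(n)
  y_v <- 0.4 * m_v + 0.3 * t_v + sqrt(1 - 0.16 - 0.09 - 2 * .5 * .4 * .3) * rnorm(n)
  res <- mediate(t_v, m_v, y_v, n_sims = 2000, seed = 1)
  expect_lt(abs(res$acme - 0.20), 0.05)
  expect_lt(abs(res$ade - 0.30), 0.10)
  expect_lt(abs(res$prop_mediated - 0.4), 0.1)
  # total = acme + ade within Monte-Carlo tolerance
  expect_lte(abs(res$total - res$acme - res$ade), 3 * res$total_se)
  expect_lt(res$p_acme, 0.01)
})

test_that("mediate is null-calibrated when the mediator path is absent", {
  set.seed(61)
  sig <- 0
  for (r in 1:10) {
    n <- 200
    t_v <- rnorm(n)
    m_v <- 0.5 * t_v + rnorm(n)       # a != 0 but b = 0
    y_v <- 0.3 * t_v + rnorm(n)
    res <- mediate(t_v, m_v, y_v, n_sims = 500, seed = r)
    expect_lte(abs(res$acme), 2 * res$acme_se + 0.05)
    sig <- sig + (res$p_acme < 0.05)
  }
  expect_lte(sig, 1)
})

test_that("mediate results are bit-reproducible under a fixed seed and guarded", {
  set.seed(62)
  t_v <- rnorm(60); m_v <- rnorm(60); y_v <- rnorm(60)
  r1 <- mediate(t_v, m_v, y_v, n_sims = 200, seed = 9)
  r2 <- mediate(t_v, m_v, y_v, n_sims = 200, seed = 9)
  expect_identical(r1, r2)
  expect_error(mediate(t_v[1:6], m_v[1:6], y_v[1:6], n_sims = 10, seed = 1),
               "too few")
})

test_that("triplet screen returns exactly the triply-gated triplets", {
  coh <- generate_cohort(n_cases = 60, n_controls = 60, n_bacteria = 20,
                         n_viruses = 0, n_metabolites = 6,
                         truth = truth_config(n_differential = 0, n_confounded = 0,
                                              n_mediation = 2), seed = 70)
  m <- as.data.frame(coh$metadata)
  ph <- as.matrix(m[, attr(coh$metadata, "phenotypes")])
  covs <- m[, c("age", "bmi", "smoking", "medication")]
  tri <- triplet_screen(coh$bacteria, coh$metabolites, ph, covs, p_gate = 0.1)
  # every returned triplet actually passes its three gates
  expect_true(all(tri$p_adj_tm < 0.1 & tri$p_adj_my < 0.1 & tri$p_adj_ty < 0.1))
  # planted paths are found
  tp <- coh$truth$mediation_paths
  found <- paste(tri$treatment, tri$mediator, tri$outcome)
  expect_true(all(paste(tp$treatment, tp$mediator, tp$outcome) %in% found))
  # p_gate = 0 closes the screen
  expect_equal(nrow(triplet_screen(coh$bacteria, coh$metabolites, ph, covs,
                                   p_gate = 0)), 0)
})

test_that("screen-then-test runs the mediation engine only on survivors", {
  coh <- generate_cohort(n_cases = 60, n_controls = 60, n_bacteria = 15,
                         n_viruses = 0, n_metabolites = 5,
                         truth = truth_config(n_differential = 0, n_confounded = 0,
                                              n_mediation = 1), seed = 71)
  m <- as.data.frame(coh$metadata)
  ph <- as.matrix(m[, attr(coh$metadata, "phenotypes")])
  covs <- m[, c("age", "bmi", "smoking", "medication")]
  res <- run_mediation(coh$bacteria, coh$metabolites, ph, covs,
                       n_sims = 200, seed = 72)
  expect_equal(length(res$results), nrow(res$triplets))
  # every exported network edge has a direction-1 verdict behind it
  d1 <- sum(vapply(res$results, function(r) r$verdict == "direction1", logical(1)))
  expect_equal(nrow(res$network), 2 * d1)
})

test_that("mediation network export counts edges and handles emptiness", {
  expect_equal(nrow(mediation_network(list())), 0)
  fake <- function(t, mname) {
    list(verdict = "direction1",
         dir1 = structure(list(treatment = t, mediator = mname, outcome = "y",
                               acme = 0.2, prop_mediated = 0.4),
                          class = "mediation_result"))
  }
  net <- mediation_network(list(fake("t1", "m1"), fake("t2", "m2")))
  expect_equal(nrow(net), 4)
})
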