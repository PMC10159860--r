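test_that("prevalence filter keeps exactly the hand-counted survivors", {
  m <- matrix(0, 20, 5, dimnames = list(sprintf("s%02d", 1:20), paste0("f", 1:5)))
  m[1, 1] <- 0.4                      # prevalence 5% -> dropped
  m[1:2, 2] <- 0.3                    # exactly 10% -> kept (inclusive)
  m[1:10, 3] <- 0.1                   # abundant, prevalent -> kept
  m[1:20, 4] <- 1e-6                  # prevalent but mean 1e-6 < 1e-4 -> dropped
  m[1:20, 5] <- 0.01
  ft <- feature_table(m, "virus", "relative")
  kept <- colnames(prevalence_filter(ft))
  expect_setequal(kept, c("f2", "f3", "f5"))
  expect_error(prevalence_filter(ft, min_prev = 0.9, min_abund = 0.9), "removed all")
})

test_that("sparcc output is symmetric, unit-diagonal and scale-invariant", {
  coh <- small_null_cohort(40, n_bact = 10, n_cases = 30, n_controls = 30)
  v <- unclass(coh$bacteria)
  rho <- sparcc(v, seed = 1)
  expect_equal(rho, t(rho))
  expect_equal(diag(rho), rep(1, 10), ignore_attr = TRUE)
  expect_true(all(abs(rho) <= 1))
  v2 <- v; v2[4, ] <- v2[4, ] * 1234   # per-sample scaling is compositional no-op
  expect_lt(max(abs(sparcc(v2, seed = 1) - rho)), 1e-6)
  expect_error(sparcc(v[, 1:3], seed = 1), ">= 4")
})

test_that("sparcc flags perfect dependence between duplicated features", {
  coh <- small_null_cohort(41, n_bact = 8, n_cases = 40, n_controls = 40)
  v <- unclass(coh$bacteria)
  v <- cbind(v, dup = v[, 1])
  v <- v / rowSums(v)
  rho <- sparcc(v, seed = 2)
  expect_gt(abs(rho["bact_001", "dup"]), 0.9)
})

test_that("pseudo p-values are structurally sound and detect planted pairs", {
  bc <- data.frame(feature1 = "bact_001", feature2 = "bact_002", rho = 0.8)
  coh <- generate_cohort(n_cases = 100, n_controls = 100, n_bacteria = 10,
                         n_viruses = 0, n_metabolites = 0,
                         truth = null_truth_config(basis_correlations = bc,
                                                   n_phenotypes = 1), seed = 9)
  rho <- sparcc(coh$bacteria, seed = 3)
  p <- pseudo_pvalues(coh$bacteria, rho, n_boot = 49, seed = 4)
  expect_equal(p, t(p))
  expect_true(all(is.na(diag(p))))
  expect_equal(p["bact_001", "bact_002"], 1 / 50)   # minimum attainable
  expect_error(pseudo_pvalues(coh$bacteria, rho, n_boot = 0, seed = 1), "n_boot")
})

test_that("network construction matches hand enumeration and edge monotonicity", {
  ids <- c("b1", "b2", "v1")
  rho <- matrix(c(1, .5, .1, .5, 1, -.4, .1, -.4, 1), 3, dimnames = list(ids, ids))
  p <- matrix(c(NA, .01, .2, .01, NA, .03, .2, .03, NA), 3, dimnames = list(ids, ids))
  kg <- c(b1 = "bacteria", b2 = "bacteria", v1 = "virus")
  net <- build_network(rho, p, kg)
  expect_setequal(paste(net$edges$node1, net$edges$node2),
                  c("b1 b2", "b2 v1"))
  expect_equal(net$n_pos, 1); expect_equal(net$n_neg, 1)
  expect_equal(build_network(rho, p, kg, rho_min = 1.01)$edges |> nrow(), 0)
  cross <- build_network(rho, p, kg, cross_kingdom_only = TRUE)
  expect_equal(nrow(cross$edges), 1)
  expect_equal(cross$tested_pairs, 2)
  all_bact <- build_network(rho[1:2, 1:2], p[1:2, 1:2], kg[1:2],
                            cross_kingdom_only = TRUE)
  expect_equal(nrow(all_bact$edges), 0)
  expect_error(build_network(rho, p, kg[1:2]), "kingdom tag missing")
  # monotonicity in the thresholds
  e1 <- nrow(build_network(rho, p, kg, rho_min = 0.2)$edges)
  e2 <- nrow(build_network(rho, p, kg, rho_min = 0.45)$edges)
  expect_gte(e1, e2)
  e3 <- nrow(build_network(rho, p, kg, p_max = 0.01)$edges)
  expect_lte(e3, e1)
})

test_that("network comparison equals the hypergeometric oracle", {
  mk <- function(n_edges, tested, tag) {
    structure(list(nodes = data.frame(id = "x", kingdom = "bacteria"),
                   edges = data.frame(rho = rep(0.5, n_edges)),
                   n_pos = n_edges, n_neg = 0, tested_pairs = tested,
                   filters = list(cross_kingdom_only = TRUE), group = tag),
              class = "correlation_network")
  }
  cmp <- compare_networks(mk(50, 1000, "A"), mk(10, 1000, "B"))
  expect_equal(cmp$p, oracle_fisher(matrix(c(50, 950, 10, 990), 2, byrow = TRUE)))
  same <- compare_networks(mk(7, 100, "A"), mk(7, 100, "B"))
  expect_equal(same$p, 1)
  expect_error(compare_networks(mk(5, 100, "A"), mk(5, 200, "B")), "universe")
})

test_that("zeroing cross-kingdom basis correlations empties the network", {
  # group A has 3 strong planted virus-bacteria correlations, group B none
  bc <- data.frame(feature1 = c("bact_001", "bact_002", "bact_003"),
                   feature2 = c("vir_001", "vir_002", "vir_003"),
                   rho = 0.8)
  edges <- function(corr, seed) {
    coh <- generate_cohort(n_cases = 40, n_controls = 40, n_bacteria = 8,
                           n_viruses = 4, n_metabolites = 0,
                           truth = null_truth_config(basis_correlations = corr,
                                                     n_phenotypes = 1),
                           seed = seed)
    net <- trans_kingdom_network(coh$bacteria, coh$viruses, seed = seed + 100,
                                 n_boot = 30)
    nrow(net$edges)
  }
  wins <- 0
  for (s in 1:5) wins <- wins + (edges(bc, s) > edges(NULL, s + 50))
  expect_gte(wins, 4)
})
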