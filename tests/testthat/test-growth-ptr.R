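test_that("smoothing is idempotent on constants and removes spikes", {
  const <- smooth_coverage(rep(100, 60))
  expect_equal(const$smoothed, rep(100, 60))
  expect_true(const$qc_pass)

  base <- rep(100, 100); base[37] <- 1000      # 10x spike in flat background
  sm <- smooth_coverage(base)
  expect_lt(max(abs(sm$smoothed - 100) / 100), 0.05)

  # piecewise-linear noiseless profile: smoothing twice ~ smoothing once
  gs <- genome_sim(1e6, 0, 5e5, 2, 200)
  cov <- generate_coverage(gs, 1, seed = 1, expected = TRUE)$profiles[[1]]$coverage
  s1 <- smooth_coverage(cov)$smoothed
  s2 <- smooth_coverage(s1)$smoothed
  expect_lt(max(abs(s2 - s1) / s1), 0.01)

  # heavily masked profile fails QC
  holey <- rep(c(100, 0), 50)
  expect_false(smooth_coverage(holey)$qc_pass)
})

test_that("ori/ter recovery, mirror symmetry and the flat degenerate case", {
  gs <- genome_sim(1e6, ori_position = 2.3e5, ter_position = 7.4e5,
                   true_ptr = 2, read_depth = 200)
  sim <- generate_coverage(gs, 30, seed = 11)
  fit <- fit_ori_ter(sim$profiles)
  n <- 100
  circ <- function(a, b) min(abs(a - b), n - abs(a - b))
  expect_lte(circ(fit$ori, sim$ori_bin), 2)
  expect_lte(circ(fit$ter, sim$ter_bin), 2)
  expect_false(fit$indeterminate)

  # strand flip: recovered positions mirror
  revp <- lapply(sim$profiles, function(p)
    coverage_profile(p$species_id, p$sample_id, rev(p$coverage), p$bin_size))
  fit_r <- fit_ori_ter(revp)
  expect_lte(circ(fit_r$ori, n + 1 - sim$ori_bin), 2)
  expect_lte(circ(fit_r$ter, n + 1 - sim$ter_bin), 2)

  flat <- generate_coverage(genome_sim(1e6, 2.3e5, 7.4e5, 1, 200), 5,
                            seed = 2, expected = TRUE)
  expect_true(fit_ori_ter(flat$profiles)$indeterminate)
})

test_that("PTR is exact on noiseless profiles and scale-invariant", {
  gs <- genome_sim(1e6, 0, 5e5, 2, 200)
  prof <- generate_coverage(gs, 1, seed = 1, expected = TRUE)$profiles[[1]]
  est <- compute_ptr(prof, 1, 51)
  # the moving median shaves ~1% off each extremum of the noiseless tent
  expect_equal(est$ptr, 2, tolerance = 0.04)
  expect_true(est$qc_pass)
  # global coverage scaling leaves the ratio unchanged
  scaled <- coverage_profile("sp", "s", prof$coverage * 7.7, prof$bin_size)
  expect_equal(compute_ptr(scaled, 1, 51)$ptr, est$ptr, tolerance = 1e-12)
  # flat profile -> ptr 1
  flat <- coverage_profile("sp", "s", rep(80, 100))
  expect_equal(compute_ptr(flat, 1, 51)$ptr, 1)
  # swapped ori/ter is flipped back above 1
  sw <- compute_ptr(prof, 51, 1)
  expect_true(sw$flipped)
  expect_gte(sw$ptr, 1)
})

test_that("cohort PTR comparison finds a planted group shift", {
  set.seed(12)
  make_species <- function(ptr_case, ptr_ctrl, seed, id) {
    gs_case <- genome_sim(8e5, 0, 4e5, ptr_case, 150)
    gs_ctrl <- genome_sim(8e5, 0, 4e5, ptr_ctrl, 150)
    pc <- generate_coverage(gs_case, 15, seed = seed, species_id = id)$profiles
    pt <- generate_coverage(gs_ctrl, 15, seed = seed + 1, species_id = id)$profiles
    for (i in seq_along(pc)) pc[[i]]$sample_id <- sprintf("case_%03d", i)
    for (i in seq_along(pt)) pt[[i]]$sample_id <- sprintf("ctrl_%03d", i)
    c(pc, pt)
  }
  sets <- list(shifted = make_species(2.0, 1.4, 100, "shifted"),
               null = make_species(1.6, 1.6, 200, "null"))
  meta <- sample_metadata(data.frame(
    sample_id = c(sprintf("case_%03d", 1:15), sprintf("ctrl_%03d", 1:15)),
    status = rep(c(1, 0), each = 15)))
  res <- cohort_ptr(sets, meta, min_samples = 20)
  tst <- res$species_tests
  expect_lt(tst$p[tst$species_id == "shifted"], 0.01)
  expect_gt(tst$median_case[tst$species_id == "shifted"],
            tst$median_control[tst$species_id == "shifted"])
  expect_gt(tst$p[tst$species_id == "null"], 0.01)
  expect_error(cohort_ptr(sets, meta, min_samples = 99), "exceeds the cohort")
})
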