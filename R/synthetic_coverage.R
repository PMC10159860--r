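#' Describe a replicating circular genome for coverage simulation
#'
#' @param genome_length genome size in bp (must hold at least 50 bins).
#' @param ori_position,ter_position replication origin / terminus positions in
#'   bp; their circular separation must be 45-55% of the genome, as on real
#'   bidirectionally replicating bacterial chromosomes.
#' @param true_ptr peak-to-trough ratio (>= 1; 1 = not replicating).
#' @param read_depth mean reads per bin.
#' @param bin_size bin width in bp (default 10 kbp).
#' @return A list of class `genome_sim`.
#' @export
genome_sim <- function(genome_length, ori_position, ter_position,
                       true_ptr, read_depth = 200, bin_size = 10000) {
  n_bins <- floor(genome_length / bin_size)
  .assert(n_bins >= 50, "genome must span >= 50 bins (got %d)", n_bins)
  .assert(true_ptr >= 1, "true_ptr must be >= 1")
  .assert(read_depth > 0, "read_depth must be positive")
  .assert(ori_position >= 0 && ori_position < genome_length &&
            ter_position >= 0 && ter_position < genome_length,
          "ori/ter positions must lie within the genome")
  sep <- min(abs(ori_position - ter_position),
             genome_length - abs(ori_position - ter_position)) / genome_length
  .assert(sep >= 0.45 && sep <= 0.55,
          "circular ori-ter separation must be 45-55%% of the genome (got %.1f%%)",
          100 * sep)
  structure(list(genome_length = genome_length, ori_position = ori_position,
                 ter_position = ter_position, true_ptr = true_ptr,
                 read_depth = read_depth, bin_size = bin_size, n_bins = n_bins),
            class = "genome_sim")
}

#' A binned circular-genome coverage profile
#'
#' @param species_id,sample_id identifiers.
#' @param coverage non-negative coverage vector over circular genome bins
#'   (>= 20 bins).
#' @param bin_size bin width in bp.
#' @return A list of class `coverage_profile`.
#' @export
coverage_profile <- function(species_id, sample_id, coverage, bin_size = 10000) {
  .assert(length(coverage) >= 20, "coverage profile needs >= 20 bins")
  .assert(all(coverage >= 0), "coverage must be non-negative")
  structure(list(species_id = species_id, sample_id = sample_id,
                 coverage = as.numeric(coverage), bin_size = bin_size),
            class = "coverage_profile")
}

# expected (noise-free) per-bin coverage for a genome replicating at `ptr`:
# piecewise log-linear along both replication arms, maximum at ori, minimum
# at ter, normalized to mean `depth`
#' @keywords internal
#' @noRd
.expected_coverage <- function(n_bins, ori_bin, ter_bin, ptr, depth) {
  bins <- seq_len(n_bins)
  u <- .arm_position(bins, ori_bin, ter_bin, n_bins)
  shape <- 2^(-u * log2(ptr))
  depth * shape / mean(shape)
}

# normalized position along the replication arm: 0 at ori, 1 at ter
#' @keywords internal
#' @noRd
.arm_position <- function(bins, ori_bin, ter_bin, n_bins) {
  fwd_len <- (ter_bin - ori_bin) %% n_bins       # ori -> ter going "up"
  bwd_len <- n_bins - fwd_len
  steps_fwd <- (bins - ori_bin) %% n_bins
  on_fwd <- steps_fwd <= fwd_len
  u <- numeric(length(bins))
  u[on_fwd] <- steps_fwd[on_fwd] / fwd_len
  steps_bwd <- (ori_bin - bins) %% n_bins
  u[!on_fwd] <- steps_bwd[!on_fwd] / bwd_len
  u
}

#' Simulate binned coverage profiles from a replicating genome
#'
#' Expected bin coverage decays log-linearly with the normalized distance from
#' the replication origin along each arm, so that the ratio of the expected
#' coverage at ori to that at ter equals the true PTR exactly; observed counts
#' are Poisson around the expectation.
#'
#' @param gs a [genome_sim()].
#' @param n_samples number of samples to draw.
#' @param seed integer seed.
#' @param ptr_jitter_sd per-sample log-normal jitter of the true PTR
#'   (0 = every sample replicates at exactly `true_ptr`).
#' @param expected if `TRUE` return the noise-free expectation instead of
#'   Poisson counts ("infinite depth").
#' @param species_id species identifier stamped on the profiles.
#' @return A list with `profiles` (list of [coverage_profile]s), `truth`
#'   (per-sample true PTR), and `ori_bin` / `ter_bin` (1-based bin indices).
#' @export
generate_coverage <- function(gs, n_samples, seed, ptr_jitter_sd = 0,
                              expected = FALSE, species_id = "species_1") {
  .assert(inherits(gs, "genome_sim"), "`gs` must come from genome_sim()")
  n_bins <- gs$n_bins
  ori_bin <- floor(gs$ori_position / gs$bin_size) + 1L
  ter_bin <- floor(gs$ter_position / gs$bin_size) + 1L
  .with_seed(seed, {
    ptrs <- gs$true_ptr * exp(stats::rnorm(n_samples, 0, ptr_jitter_sd))
    ptrs <- pmax(ptrs, 1)
    profiles <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      lam <- .expected_coverage(n_bins, ori_bin, ter_bin, ptrs[s], gs$read_depth)
      cov <- if (expected) lam else stats::rpois(n_bins, lam)
      profiles[[s]] <- coverage_profile(species_id, sprintf("sample_%03d", s),
                                        cov, gs$bin_size)
    }
    list(profiles = profiles,
         truth = data.frame(sample_id = sprintf("sample_%03d", seq_len(n_samples)),
                            true_ptr = ptrs),
         ori_bin = ori_bin, ter_bin = ter_bin)
  })
}

#' Simulate a population of genomes with planted deletions in 1-kbp bins
#'
#' Background coverage is log-normal around the species mean depth; within
#' each planted region, samples are deleted independently with the planted
#' population fraction, and deleted cells get near-zero coverage.
#'
#' @param n_samples,n_bins matrix dimensions.
#' @param planted data.frame with columns `start`, `end` (1-based inclusive
#'   bin indices) and `fraction` (population deletion fraction in \[0, 1\]);
#'   regions must not overlap.
#' @param seed integer seed.
#' @param depth mean per-bin coverage of the species.
#' @param sdlog log-normal spread of the background coverage.
#' @return A list with `coverage` (samples x bins matrix), `deleted`
#'   (samples x regions logical truth) and `planted` (the region table).
#' @export
generate_sv_population <- function(n_samples, n_bins, planted, seed,
                                   depth = 50, sdlog = 0.3) {
  if (is.null(planted)) planted <- data.frame(start = integer(), end = integer(),
                                              fraction = numeric())
  .assert(all(c("start", "end", "fraction") %in% names(planted)),
          "`planted` needs columns start, end, fraction")
  .assert(all(planted$fraction >= 0 & planted$fraction <= 1),
          "planted fractions must lie in [0, 1]")
  .assert(all(planted$start >= 1 & planted$end <= n_bins & planted$start <= planted$end),
          "planted regions must lie within [1, n_bins]")
  if (nrow(planted) > 1) {
    o <- order(planted$start)
    p <- planted[o, ]
    .assert(all(p$start[-1] > p$end[-nrow(p)]), "planted regions overlap")
  }
  .with_seed(seed, {
    cov <- matrix(stats::rlnorm(n_samples * n_bins, log(depth), sdlog),
                  n_samples, n_bins,
                  dimnames = list(sprintf("sample_%03d", seq_len(n_samples)),
                                  sprintf("bin_%04d", seq_len(n_bins))))
    deleted <- matrix(FALSE, n_samples, nrow(planted))
    if (nrow(planted) > 0) {
      for (r in seq_len(nrow(planted))) {
        del <- stats::rbinom(n_samples, 1, planted$fraction[r]) == 1
        deleted[, r] <- del
        if (any(del)) {
          bins <- planted$start[r]:planted$end[r]
          cov[del, bins] <- stats::rpois(sum(del) * length(bins), 0.5)
        }
      }
    }
    list(coverage = cov, deleted = deleted, planted = planted)
  })
}
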