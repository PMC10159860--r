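#' Build a correlation network from SparCC output
#'
#' Edges are feature pairs with \eqn{|\rho| \ge} `rho_min` and pseudo-p
#' \eqn{\le} `p_max`; each edge is stored once (i < j). With
#' `cross_kingdom_only`, only virus-bacteria pairs are eligible — both as
#' edges and as the tested-pair universe used downstream by
#' [compare_networks()].
#'
#' @param rho SparCC correlation matrix (feature names required).
#' @param p matching pseudo-p matrix from [pseudo_pvalues()].
#' @param kingdoms named character vector mapping every feature id to its
#'   kingdom tag.
#' @param rho_min minimum |rho| for an edge.
#' @param p_max maximum pseudo-p for an edge.
#' @param cross_kingdom_only restrict to virus-bacteria pairs.
#' @param group optional group tag stored on the network.
#' @return A `correlation_network`: list with `edges` (data.frame `node1`,
#'   `node2`, `kingdom1`, `kingdom2`, `rho`, `p`), `n_pos`/`n_neg` edge
#'   counts, `tested_pairs` (size of the pair universe), `nodes`, and the
#'   filter settings.
#' @export
build_network <- function(rho, p, kingdoms, rho_min = 0.2, p_max = 0.05,
                          cross_kingdom_only = FALSE, group = NA_character_) {
  .assert(all(dim(rho) == dim(p)), "rho and p dimensions differ")
  ids <- colnames(rho)
  .assert(!is.null(ids), "rho must carry feature names")
  missing <- setdiff(ids, names(kingdoms))
  .assert(length(missing) == 0, "kingdom tag missing for: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  kg <- kingdoms[ids]
  D <- length(ids)
  ut <- which(upper.tri(matrix(0, D, D)), arr.ind = TRUE)
  if (cross_kingdom_only) {
    keep <- (kg[ut[, 1]] == "virus" & kg[ut[, 2]] == "bacteria") |
      (kg[ut[, 1]] == "bacteria" & kg[ut[, 2]] == "virus")
    ut <- ut[keep, , drop = FALSE]
  }
  rho_v <- rho[ut]
  p_v <- p[ut]
  is_edge <- !is.na(rho_v) & !is.na(p_v) & abs(rho_v) >= rho_min & p_v <= p_max
  edges <- data.frame(node1 = ids[ut[is_edge, 1]], node2 = ids[ut[is_edge, 2]],
                      kingdom1 = unname(kg[ut[is_edge, 1]]),
                      kingdom2 = unname(kg[ut[is_edge, 2]]),
                      rho = rho_v[is_edge], p = p_v[is_edge],
                      stringsAsFactors = FALSE)
  structure(list(nodes = data.frame(id = ids, kingdom = unname(kg),
                                    stringsAsFactors = FALSE),
                 edges = edges,
                 n_pos = sum(edges$rho > 0), n_neg = sum(edges$rho < 0),
                 tested_pairs = nrow(ut),
                 filters = list(rho_min = rho_min, p_max = p_max,
                                cross_kingdom_only = cross_kingdom_only),
                 group = group),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network [%s]: %d edges (%d+/%d-) over %d tested pairs\n",
              x$group, nrow(x$edges), x$n_pos, x$n_neg, x$tested_pairs))
  invisible(x)
}

#' Compare edge counts of two correlation networks
#'
#' Builds the 2x2 table groups x (significant edge, tested non-edge) over the
#' two networks' common tested-pair universe and applies the two-sided Fisher
#' exact test — the standard way to ask whether one group's trans-kingdom
#' network is sparser than the other's.
#'
#' @param netA,netB `correlation_network`s built over the same tested-pair
#'   universe (same nodes and filters; asserted).
#' @return A list with `table` (2x2 counts), `p` (Fisher), and
#'   `positive_ratio` (positive:negative edge ratio per network; `Inf` when a
#'   network has no negative edges).
#' @export
compare_networks <- function(netA, netB) {
  .assert(inherits(netA, "correlation_network") && inherits(netB, "correlation_network"),
          "inputs must be correlation_networks")
  .assert(identical(netA$nodes, netB$nodes) &&
            netA$tested_pairs == netB$tested_pairs &&
            identical(netA$filters$cross_kingdom_only, netB$filters$cross_kingdom_only),
          "networks were not built over the same tested-pair universe")
  a <- nrow(netA$edges); b <- nrow(netB$edges)
  tab <- matrix(c(a, netA$tested_pairs - a,
                  b, netB$tested_pairs - b), 2, 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("edge", "non_edge")))
  ratio <- c(A = netA$n_pos / max(netA$n_neg, 1e-12),
             B = netB$n_pos / max(netB$n_neg, 1e-12))
  list(table = tab, p = fisher_exact(tab), positive_ratio = ratio)
}

#' Trans-kingdom network construction for one sample group
#'
#' Convenience pipeline: joins a bacterial and a viral relative-abundance
#' table on shared samples, applies the prevalence/abundance filter per
#' kingdom, runs SparCC and its permutation pseudo-p-values on the combined
#' table, and builds the cross-kingdom network.
#'
#' @param bacteria,viruses relative-scale [feature_table]s over the same
#'   samples.
#' @param seed integer seed.
#' @param min_prev,min_abund filter thresholds (see [prevalence_filter()]).
#' @param rho_min,p_max edge thresholds (see [build_network()]).
#' @param n_boot permutations for [pseudo_pvalues()].
#' @param n_dirichlet Dirichlet resamples for [sparcc()].
#' @param group group tag stored on the network.
#' @return A `correlation_network` (cross-kingdom pairs only).
#' @export
trans_kingdom_network <- function(bacteria, viruses, seed,
                                  min_prev = 0.10, min_abund = 0.0001,
                                  rho_min = 0.2, p_max = 0.05,
                                  n_boot = 100, n_dirichlet = 20,
                                  group = NA_character_) {
  .assert(identical(rownames(bacteria), rownames(viruses)),
          "bacteria and virus tables must cover the same samples in order")
  bf <- prevalence_filter(bacteria, min_prev, min_abund)
  vf <- prevalence_filter(viruses, min_prev, min_abund)
  comb <- cbind(.ft_values(bf), .ft_values(vf))
  kingdoms <- stats::setNames(rep(c("bacteria", "virus"), c(ncol(bf), ncol(vf))),
                              colnames(comb))
  seeds <- .child_seeds(seed, 2)
  rho <- sparcc(comb, n_dirichlet = n_dirichlet, seed = seeds[1])
  p <- pseudo_pvalues(comb, rho, n_boot = n_boot, seed = seeds[2],
                      n_dirichlet = n_dirichlet)
  .log_stage("network", n_samples = nrow(comb), n_features = ncol(comb),
             seed = seed)
  build_network(rho, p, kingdoms, rho_min = rho_min, p_max = p_max,
                cross_kingdom_only = TRUE, group = group)
}

#' Write a network edge list as TSV
#' @param net a `correlation_network`.
#' @param path output path.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
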