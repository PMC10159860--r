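#' Quasi-Bayesian linear causal mediation for one triplet
#'
#' Fits the mediator model `M ~ T + X` and the outcome model `Y ~ T + M + X`
#' by least squares on rank-normalized variables, then propagates coefficient
#' uncertainty by drawing `n_sims` coefficient vectors from each model's
#' asymptotic normal distribution. Per draw, the average causal mediation
#' effect is ACME = a*b, the average direct effect ADE = c', and the total
#' effect a*b + c' (linear case, no treatment-mediator interaction). The
#' reported proportion mediated is the simulation median of ACME/total,
#' bounded to \[-5, 5\].
#'
#' @param treatment,mediator,outcome numeric vectors (rank-normalized
#'   internally; binary covariates are left as-is).
#' @param covariates data.frame of adjustment covariates (may have 0
#'   columns).
#' @param n_sims number of quasi-Bayesian draws (default 1000).
#' @param seed integer seed.
#' @param ids optional named list/vector with `treatment`, `mediator`,
#'   `outcome` identifiers for the result record.
#' @return A `mediation_result`: list with `acme`, `ade`, `total`,
#'   `prop_mediated`, `p_acme`, 95% percentile intervals, simulation
#'   standard errors, `z_acme` (|mean|/sd of the ACME draws), `n`, `n_sims`,
#'   `seed` and the ids.
#' @references Imai, Keele & Tingley (2010) A general approach to causal
#'   mediation analysis. Psychological Methods 15:309-334.
#' @export
mediate <- function(treatment, mediator, outcome, covariates = NULL,
                    n_sims = 1000, seed, ids = NULL) {
  .assert(n_sims >= 2, "n_sims must be >= 2")
  if (is.null(covariates)) covariates <- data.frame(row.names = seq_along(treatment))
  covariates <- as.data.frame(covariates)
  .assert(length(treatment) == length(mediator) &&
            length(treatment) == length(outcome) &&
            nrow(covariates) == length(treatment),
          "treatment/mediator/outcome/covariates lengths differ")
  cc <- stats::complete.cases(data.frame(t = treatment, m = mediator, y = outcome))
  if (ncol(covariates) > 0) cc <- cc & stats::complete.cases(covariates)
  treatment <- treatment[cc]; mediator <- mediator[cc]; outcome <- outcome[cc]
  covariates <- covariates[cc, , drop = FALSE]
  n <- length(treatment)
  n_reg <- 3 + ncol(covariates)
  .assert(n >= n_reg + 5, "too few complete cases (n = %d) for %d regressors", n, n_reg)

  rn <- function(x) if (length(unique(x)) > 2) rank_normal_transform(x) else x
  d <- data.frame(T = rn(treatment), M = rn(mediator), Y = rn(outcome))
  if (ncol(covariates) > 0) {
    for (nm in names(covariates)) d[[nm]] <- rn(covariates[[nm]])
  }
  xnames <- setdiff(names(d), c("T", "M", "Y"))
  f_m <- stats::reformulate(c("T", xnames), response = "M")
  f_y <- stats::reformulate(c("T", "M", xnames), response = "Y")
  m_mod <- stats::lm(f_m, data = d)
  y_mod <- stats::lm(f_y, data = d)
  .assert(m_mod$rank == length(stats::coef(m_mod)) &&
            y_mod$rank == length(stats::coef(y_mod)),
          "singular design in mediation models")

  draw_coef <- function(mod) {
    co <- stats::coef(mod)
    V <- stats::vcov(mod)
    L <- chol(V)
    sweep(matrix(stats::rnorm(n_sims * length(co)), n_sims) %*% L, 2, co, "+")
  }
  sims <- .with_seed(seed, {
    cm <- draw_coef(m_mod)
    cy <- draw_coef(y_mod)
    list(a = cm[, "T"], b = cy[, "M"], c = cy[, "T"])
  })
  acme_d <- sims$a * sims$b
  ade_d <- sims$c
  total_d <- acme_d + ade_d
  prop_d <- acme_d / total_d
  pm <- stats::median(prop_d)
  pm_out_of_range <- pm < -5 || pm > 5
  pm <- min(max(pm, -5), 5)
  two_sided_p <- function(x) {
    p <- 2 * min(mean(x <= 0), mean(x >= 0))
    min(max(p, 1 / n_sims), 1)
  }
  structure(list(
    treatment = if (!is.null(ids)) ids[["treatment"]] else "T",
    mediator = if (!is.null(ids)) ids[["mediator"]] else "M",
    outcome = if (!is.null(ids)) ids[["outcome"]] else "Y",
    acme = mean(acme_d), ade = mean(ade_d), total = mean(total_d),
    acme_ci = stats::quantile(acme_d, c(0.025, 0.975), names = FALSE),
    ade_ci = stats::quantile(ade_d, c(0.025, 0.975), names = FALSE),
    total_ci = stats::quantile(total_d, c(0.025, 0.975), names = FALSE),
    acme_se = stats::sd(acme_d), total_se = stats::sd(total_d),
    z_acme = abs(mean(acme_d)) / stats::sd(acme_d),
    prop_mediated = pm, prop_out_of_range = pm_out_of_range,
    p_acme = two_sided_p(acme_d), p_ade = two_sided_p(ade_d),
    n = n, n_sims = n_sims, seed = seed),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation %s -> %s -> %s (n = %d)\n", x$treatment, x$mediator,
              x$outcome, x$n))
  cat(sprintf("  ACME %.4f [%.4f, %.4f], p = %.4g\n", x$acme, x$acme_ci[1],
              x$acme_ci[2], x$p_acme))
  cat(sprintf("  ADE  %.4f; total %.4f; prop. mediated %.3f\n",
              x$ade, x$total, x$prop_mediated))
  invisible(x)
}

#' Triplet screen for mediation candidates
#'
#' Computes the three pairwise covariate-adjusted association scans —
#' microbial feature vs metabolite, metabolite vs phenotype, feature vs
#' phenotype — and returns exactly the (feature, metabolite, phenotype)
#' triplets whose three BH-adjusted p-values all fall below `p_gate`
#' (default 0.1). Only the surviving triplets are worth the cost of the
#' mediation simulation.
#'
#' @param features microbial [feature_table] or matrix.
#' @param metabolites metabolite [feature_table] or matrix (same samples).
#' @param phenotypes named numeric matrix/data.frame of outcomes.
#' @param covariates data.frame of adjustment covariates.
#' @param p_gate adjusted-p gate applied to all three associations.
#' @param adjust_bmi passed to [association_scan()] (FALSE for
#'   metabolic-trait outcomes where BMI is itself an outcome).
#' @return data.frame with `treatment`, `mediator`, `outcome` and the three
#'   gate p-values (`p_adj_tm`, `p_adj_my`, `p_adj_ty`).
#' @export
triplet_screen <- function(features, metabolites, phenotypes, covariates,
                           p_gate = 0.1, adjust_bmi = TRUE) {
  s_tm <- association_scan(features, .ft_values(metabolites), covariates,
                           adjust_bmi = adjust_bmi)
  s_my <- association_scan(metabolites, phenotypes, covariates,
                           adjust_bmi = adjust_bmi)
  s_ty <- association_scan(features, phenotypes, covariates,
                           adjust_bmi = adjust_bmi)
  .assert(nrow(s_tm) > 0 && nrow(s_my) > 0 && nrow(s_ty) > 0,
          "empty association tables")
  g_tm <- s_tm[s_tm$p_adj < p_gate, c("feature", "target", "p_adj")]
  g_my <- s_my[s_my$p_adj < p_gate, c("feature", "target", "p_adj")]
  g_ty <- s_ty[s_ty$p_adj < p_gate, c("feature", "target", "p_adj")]
  names(g_tm) <- c("treatment", "mediator", "p_adj_tm")
  names(g_my) <- c("mediator", "outcome", "p_adj_my")
  names(g_ty) <- c("treatment", "outcome", "p_adj_ty")
  tri <- merge(merge(g_tm, g_my, by = "mediator"), g_ty,
               by = c("treatment", "outcome"))
  tri <- tri[, c("treatment", "mediator", "outcome",
                 "p_adj_tm", "p_adj_my", "p_adj_ty")]
  rownames(tri) <- NULL
  tri[order(tri$treatment, tri$mediator, tri$outcome), , drop = FALSE]
}

#' Bidirectional mediation for one candidate triplet
#'
#' Direction 1 treats the metabolite as mediator of the microbial feature's
#' effect on the phenotype; direction 2 treats the phenotype as mediator and
#' the metabolite as outcome. Both results are always returned. The verdict
#' rule decides when a triplet is called direction 1:
#' \describe{
#'   \item{dominant (default)}{dir1 ACME significant at `alpha` AND its
#'     simulation z-statistic exceeds dir2's. In linear-Gaussian systems a
#'     reverse-wired chain still produces a nonzero forward ACME, so a pure
#'     significance threshold cannot certify direction; comparing the two
#'     directions can.}
#'   \item{acme1}{dir1 ACME significant at `alpha` (dir2 reported but not
#'     vetoing).}
#'   \item{exclusive}{dir1 significant AND dir2 not significant.}
#' }
#'
#' @param treatment microbial feature values.
#' @param metabolite candidate mediator values.
#' @param phenotype candidate outcome values.
#' @param covariates data.frame of adjustment covariates.
#' @param n_sims,seed simulation settings (see [mediate()]).
#' @param rule verdict rule (see above).
#' @param alpha significance level for the verdict (default 0.05).
#' @param ids optional identifiers (named list with `treatment`, `mediator`,
#'   `outcome`).
#' @return A list with `dir1`, `dir2` (both `mediation_result`s) and
#'   `verdict` (`"direction1"` or `"none"`).
#' @export
bidirectional <- function(treatment, metabolite, phenotype, covariates = NULL,
                          n_sims = 1000, seed,
                          rule = c("dominant", "acme1", "exclusive"),
                          alpha = 0.05, ids = NULL) {
  rule <- match.arg(rule)
  seeds <- .child_seeds(seed, 2)
  dir1 <- mediate(treatment, metabolite, phenotype, covariates,
                  n_sims = n_sims, seed = seeds[1], ids = ids)
  ids2 <- if (!is.null(ids))
    list(treatment = ids[["treatment"]], mediator = ids[["outcome"]],
         outcome = ids[["mediator"]]) else NULL
  dir2 <- mediate(treatment, phenotype, metabolite, covariates,
                  n_sims = n_sims, seed = seeds[2], ids = ids2)
  sig1 <- dir1$p_acme < alpha
  verdict <- switch(rule,
                    acme1 = sig1,
                    exclusive = sig1 && dir2$p_acme >= alpha,
                    dominant = sig1 && dir1$z_acme > dir2$z_acme)
  list(dir1 = dir1, dir2 = dir2,
       verdict = if (verdict) "direction1" else "none")
}

#' Screen-then-test mediation over a cohort
#'
#' Runs [triplet_screen()], then [bidirectional()] on every surviving
#' triplet (and only those). Returns all per-direction results plus the
#' direction-1 network edge list.
#'
#' @inheritParams triplet_screen
#' @inheritParams bidirectional
#' @param seed integer seed (one child seed per triplet).
#' @return A list with `triplets` (screen output), `results` (list of
#'   [bidirectional()] outputs), and `network` (see [mediation_network()]).
#' @export
run_mediation <- function(features, metabolites, phenotypes, covariates,
                          p_gate = 0.1, adjust_bmi = TRUE, n_sims = 1000,
                          rule = "dominant", alpha = 0.05, seed) {
  tri <- triplet_screen(features, metabolites, phenotypes, covariates,
                        p_gate = p_gate, adjust_bmi = adjust_bmi)
  fm <- .ft_values(features)
  mm <- .ft_values(metabolites)
  pm <- as.matrix(phenotypes)
  results <- list()
  if (nrow(tri) > 0) {
    seeds <- .child_seeds(seed, nrow(tri))
    for (i in seq_len(nrow(tri))) {
      results[[i]] <- bidirectional(
        fm[, tri$treatment[i]], mm[, tri$mediator[i]], pm[, tri$outcome[i]],
        covariates, n_sims = n_sims, seed = seeds[i], rule = rule,
        alpha = alpha,
        ids = list(treatment = tri$treatment[i], mediator = tri$mediator[i],
                   outcome = tri$outcome[i]))
    }
  }
  .log_stage("mediate", n_triplets = nrow(tri),
             n_direction1 = sum(vapply(results, function(r) r$verdict == "direction1",
                                       logical(1))))
  list(triplets = tri, results = results, network = mediation_network(results))
}

#' Direction-1 mediation network edge list
#'
#' Three-layer edge list (treatment -> mediator, mediator -> outcome) over
#' the triplets with verdict direction 1, annotated with ACME and proportion
#' mediated.
#'
#' @param results list of [bidirectional()] outputs.
#' @return data.frame with `from`, `to`, `layer`, `acme`, `prop_mediated`
#'   (zero rows when nothing is significant).
#' @export
mediation_network <- function(results) {
  keep <- Filter(function(r) identical(r$verdict, "direction1"), results)
  if (length(keep) == 0) {
    return(data.frame(from = character(), to = character(), layer = character(),
                      acme = numeric(), prop_mediated = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(keep, function(r) {
    d <- r$dir1
    data.frame(from = c(d$treatment, d$mediator),
               to = c(d$mediator, d$outcome),
               layer = c("treatment->mediator", "mediator->outcome"),
               acme = d$acme, prop_mediated = d$prop_mediated,
               stringsAsFactors = FALSE)
  }))
}
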