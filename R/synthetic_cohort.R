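#' Ground-truth configuration for synthetic cohorts
#'
#' Describes the effects planted into a cohort drawn by [generate_cohort()]:
#' case/control differential bacteria, medication-confounded bacteria, basis
#' correlations between features (the SparCC oracle), and linear-Gaussian
#' mediation paths microbe -> metabolite -> phenotype. Defaults mirror a
#' plausible clinical case/control cohort: modest numbers of truly shifted
#' species with mid-sized rank effects, a psychotropic-medication covariate
#' strongly imbalanced between groups, and a few planted mediation paths.
#' Effect sizes for differential features are expressed as Cliff's delta; they
#' are converted internally to mean shifts on the log-abundance scale via
#' \eqn{\Delta = \sqrt{2}\,\Phi^{-1}((\delta+1)/2)}.
#'
#' @param n_differential number of bacteria with a planted case/control shift.
#' @param differential_effect Cliff's delta magnitude of the planted shifts
#'   (signs alternate between features).
#' @param n_confounded number of bacteria driven by medication only.
#' @param confounded_effect Cliff's delta of the medication effect on the
#'   confounded features.
#' @param medication_rate_case,medication_rate_control probability of the
#'   medication flag in cases / controls (their imbalance is what makes the
#'   confounded features look differential).
#' @param basis_correlations optional data.frame with columns `feature1`,
#'   `feature2`, `rho`: planted correlations between log-basis abundances
#'   (feature ids as produced by the generator, e.g. `"bact_001"`,
#'   `"vir_003"`).
#' @param n_mediation number of planted mediation paths.
#' @param mediation_a,mediation_b,mediation_c path coefficients on the
#'   standardized latent scale: treatment -> mediator (`a`), mediator ->
#'   outcome (`b`) and the direct treatment -> outcome effect (`c`).
#' @param mediation_direction `"forward"` wires treatment -> metabolite ->
#'   phenotype; `"reverse"` wires treatment -> phenotype -> metabolite.
#' @param n_phenotypes number of phenotype scores in the metadata.
#' @param phenotype_age_effect standardized age effect added to every
#'   phenotype (mediation covariate adjustment has something to adjust).
#' @param bmi_case_mean,bmi_control_mean,bmi_sd BMI distribution (kg/m^2) by
#'   group; cases are severely underweight as in anorexia nervosa cohorts.
#' @param smoking_rate smoking prevalence (both groups).
#' @return A list of class `truth_config`.
#' @seealso [generate_cohort()]
#' @export
truth_config <- function(n_differential = 10,
                         differential_effect = 0.6,
                         n_confounded = 5,
                         confounded_effect = 0.8,
                         medication_rate_case = 0.65,
                         medication_rate_control = 0.05,
                         basis_correlations = NULL,
                         n_mediation = 3,
                         mediation_a = 0.5,
                         mediation_b = 0.4,
                         mediation_c = 0.3,
                         mediation_direction = c("forward", "reverse"),
                         n_phenotypes = 4,
                         phenotype_age_effect = 0.1,
                         bmi_case_mean = 16.5,
                         bmi_control_mean = 21.5,
                         bmi_sd = 2,
                         smoking_rate = 0.2) {
  mediation_direction <- match.arg(mediation_direction)
  .assert(all(c(n_differential, n_confounded, n_mediation, n_phenotypes) >= 0),
          "counts must be non-negative")
  .assert(all(is.finite(c(differential_effect, confounded_effect,
                          mediation_a, mediation_b, mediation_c))),
          "effect sizes must be finite")
  .assert(abs(differential_effect) < 1 && abs(confounded_effect) < 1,
          "Cliff's delta effects must lie in (-1, 1)")
  if (!is.null(basis_correlations)) {
    .assert(is.data.frame(basis_correlations) &&
              all(c("feature1", "feature2", "rho") %in% names(basis_correlations)),
            "basis_correlations needs columns feature1, feature2, rho")
    .assert(all(abs(basis_correlations$rho) <= 1), "|rho| must be <= 1")
  }
  structure(as.list(environment()), class = "truth_config")
}

#' Null configuration: a cohort with no planted effects
#' @inheritParams truth_config
#' @param ... passed on to [truth_config()].
#' @export
null_truth_config <- function(...) {
  truth_config(n_differential = 0, n_confounded = 0, n_mediation = 0, ...)
}

# delta (Cliff) -> mean shift for unit-variance normal groups
#' @keywords internal
#' @noRd
.cliff_to_shift <- function(delta) sqrt(2) * stats::qnorm((delta + 1) / 2)

#' Generate a synthetic case/control multi-omics cohort with known truth
#'
#' Draws bacterial and viral relative abundances as the closure of
#' exponentiated multivariate-normal log-basis abundances (so planted basis
#' correlations are exact on the latent scale), metabolite concentrations as
#' log-normal variables whose latent scale carries the planted mediation
#' paths, and phenotype scores as linear combinations of mediators, treatments
#' and covariates. Case/control differential features receive a mean shift on
#' the log scale calibrated to the requested Cliff's delta; confounded
#' features depend on the medication covariate only, which is itself
#' imbalanced between cases and controls.
#'
#' @param n_cases,n_controls group sizes (>= 3 each). Defaults mirror a
#'   77-case / 70-control clinical cohort.
#' @param n_bacteria,n_viruses,n_metabolites feature counts per kingdom.
#' @param truth a [truth_config()].
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return A list with elements `bacteria`, `viruses`, `metabolites`
#'   ([feature_table]s; `viruses`/`metabolites` may be `NULL` when their count
#'   is 0), `metadata` (a [sample_metadata]) and `truth` (a list recording
#'   every planted parameter).
#' @examples
#' coh <- generate_cohort(n_cases = 10, n_controls = 10, n_bacteria = 20,
#'                        n_viruses = 5, n_metabolites = 5,
#'                        truth = truth_config(n_differential = 2,
#'                                             n_confounded = 1,
#'                                             n_mediation = 1),
#'                        seed = 1)
#' dim(coh$bacteria)
#' @export
generate_cohort <- function(n_cases = 77, n_controls = 70,
                            n_bacteria = 200, n_viruses = 100,
                            n_metabolites = 50,
                            truth = truth_config(), seed) {
  .assert(inherits(truth, "truth_config"), "`truth` must come from truth_config()")
  .assert(n_cases >= 3 && n_controls >= 3, "need >= 3 samples per group")
  .assert(n_bacteria >= 1, "need at least one bacterial feature")
  .assert(truth$n_differential + truth$n_confounded <= n_bacteria,
          "more planted features (%d) than bacteria (%d)",
          truth$n_differential + truth$n_confounded, n_bacteria)
  n_treat_needed <- if (truth$n_mediation > 0) truth$n_mediation else 0
  .assert(truth$n_differential + truth$n_confounded + n_treat_needed <= n_bacteria,
          "not enough bacteria for planted mediation treatments")
  if (truth$n_mediation > 0) {
    .assert(n_metabolites >= truth$n_mediation, "not enough metabolites for mediation paths")
    .assert(truth$n_phenotypes >= truth$n_mediation, "not enough phenotypes for mediation paths")
  }
  n <- n_cases + n_controls

  .with_seed(seed, {
    sample_ids <- c(sprintf("case_%03d", seq_len(n_cases)),
                    sprintf("ctrl_%03d", seq_len(n_controls)))
    status <- rep(c(1, 0), c(n_cases, n_controls))
    subtype <- c(sample(c("AN-RS", "AN-BP"), n_cases, TRUE, prob = c(0.72, 0.28)),
                 rep("HC", n_controls))

    age <- round(stats::rnorm(n, 24, 4), 1)
    bmi <- round(ifelse(status == 1,
                        stats::rnorm(n, truth$bmi_case_mean, truth$bmi_sd),
                        stats::rnorm(n, truth$bmi_control_mean, truth$bmi_sd)), 1)
    smoking <- stats::rbinom(n, 1, truth$smoking_rate)
    medication <- stats::rbinom(n, 1, ifelse(status == 1,
                                             truth$medication_rate_case,
                                             truth$medication_rate_control))

    bact_ids <- sprintf("bact_%03d", seq_len(n_bacteria))
    vir_ids <- if (n_viruses > 0) sprintf("vir_%03d", seq_len(n_viruses)) else character()
    metab_ids <- if (n_metabolites > 0) sprintf("metab_%03d", seq_len(n_metabolites)) else character()
    micro_ids <- c(bact_ids, vir_ids)
    d_micro <- length(micro_ids)

    sigma <- diag(d_micro)
    dimnames(sigma) <- list(micro_ids, micro_ids)
    if (!is.null(truth$basis_correlations)) {
      bc <- truth$basis_correlations
      miss <- setdiff(c(bc$feature1, bc$feature2), micro_ids)
      .assert(length(miss) == 0, "basis correlation names unknown: %s",
              paste(miss, collapse = ", "))
      for (k in seq_len(nrow(bc))) {
        sigma[bc$feature1[k], bc$feature2[k]] <- bc$rho[k]
        sigma[bc$feature2[k], bc$feature1[k]] <- bc$rho[k]
      }
    }
    z <- .rmvnorm(n, sigma)                       # unit-variance log-basis noise
    mu <- stats::rnorm(d_micro, 0, 1)             # heterogeneous baselines
    logab <- sweep(z, 2, mu, "+")
    dimnames(logab) <- list(sample_ids, micro_ids)

    # planted case/control shifts
    diff_ids <- utils::head(bact_ids, truth$n_differential)
    diff_dir <- rep_len(c(1, -1), length(diff_ids))
    for (k in seq_along(diff_ids)) {
      logab[, diff_ids[k]] <- logab[, diff_ids[k]] +
        diff_dir[k] * .cliff_to_shift(truth$differential_effect) * status
    }
    # confounded features depend on medication only
    conf_ids <- bact_ids[seq_len(truth$n_confounded) + truth$n_differential]
    for (f in conf_ids) {
      logab[, f] <- logab[, f] + .cliff_to_shift(truth$confounded_effect) * medication
    }

    closure <- function(m) m / rowSums(m)
    bacteria <- feature_table(
      closure(exp(logab[, bact_ids, drop = FALSE])), "bacteria", "relative")
    viruses <- NULL
    if (n_viruses > 0) {
      viruses <- feature_table(
        closure(exp(logab[, vir_ids, drop = FALSE])), "virus", "relative")
    }

    # mediation wiring on the standardized latent scale
    treat_ids <- character(); med_ids <- character(); out_ids <- character()
    if (truth$n_mediation > 0) {
      treat_ids <- bact_ids[truth$n_differential + truth$n_confounded +
                              seq_len(truth$n_mediation)]
      med_ids <- metab_ids[seq_len(truth$n_mediation)]
      out_ids <- sprintf("pheno_%02d", seq_len(truth$n_mediation))
    }
    pheno_ids <- sprintf("pheno_%02d", seq_len(truth$n_phenotypes))
    age_z <- as.numeric(scale(age))

    metab_latent <- matrix(stats::rnorm(n * n_metabolites), n, n_metabolites,
                           dimnames = list(sample_ids, metab_ids))
    phenos <- matrix(NA_real_, n, truth$n_phenotypes,
                     dimnames = list(sample_ids, pheno_ids))
    for (j in seq_len(truth$n_phenotypes)) {
      g <- truth$phenotype_age_effect
      phenos[, j] <- g * age_z + sqrt(max(1 - g^2, 0.05)) * stats::rnorm(n)
    }
    if (truth$n_mediation > 0) {
      a <- truth$mediation_a; b <- truth$mediation_b; cc <- truth$mediation_c
      for (k in seq_len(truth$n_mediation)) {
        zt <- as.numeric(scale(logab[, treat_ids[k]]))
        if (truth$mediation_direction == "forward") {
          m_lat <- a * zt + sqrt(1 - a^2) * stats::rnorm(n)
          resid_var <- max(1 - b^2 - cc^2 - 2 * a * b * cc, 0.05)
          y <- b * m_lat + cc * zt +
            truth$phenotype_age_effect * age_z + sqrt(resid_var) * stats::rnorm(n)
          metab_latent[, med_ids[k]] <- m_lat
          phenos[, out_ids[k]] <- y
        } else {
          y <- a * zt + sqrt(1 - a^2) * stats::rnorm(n)
          resid_var <- max(1 - b^2 - cc^2 - 2 * a * b * cc, 0.05)
          m_lat <- b * y + cc * zt + sqrt(resid_var) * stats::rnorm(n)
          metab_latent[, med_ids[k]] <- m_lat
          phenos[, out_ids[k]] <- y
        }
      }
    }
    metabolites <- NULL
    if (n_metabolites > 0) {
      mu_m <- stats::rnorm(n_metabolites, 2, 0.5)
      conc <- exp(sweep(metab_latent, 2, mu_m, "+"))
      metabolites <- feature_table(conc, "metabolite", "concentration")
    }

    meta_df <- data.frame(sample_id = sample_ids, status = status,
                          subtype = subtype, age = age, bmi = bmi,
                          smoking = smoking, medication = medication,
                          stringsAsFactors = FALSE)
    meta_df <- cbind(meta_df, as.data.frame(phenos))
    metadata <- sample_metadata(meta_df,
                                covariates = c("age", "bmi", "smoking", "medication"),
                                phenotypes = pheno_ids)

    truth_out <- list(
      differential_features = data.frame(
        feature_id = diff_ids,
        direction = diff_dir[seq_along(diff_ids)],
        effect = rep(truth$differential_effect, length(diff_ids)),
        stringsAsFactors = FALSE),
      confounded_features = data.frame(
        feature_id = conf_ids,
        covariate = rep("medication", length(conf_ids)),
        stringsAsFactors = FALSE),
      basis_correlations = truth$basis_correlations,
      mediation_paths = if (truth$n_mediation > 0) data.frame(
        treatment = treat_ids, mediator = med_ids, outcome = out_ids,
        a = truth$mediation_a, b = truth$mediation_b, c_prime = truth$mediation_c,
        direction = truth$mediation_direction, stringsAsFactors = FALSE) else NULL,
      config = unclass(truth), seed = seed)

    .log_stage("simulate", n_samples = n, n_bacteria = n_bacteria,
               n_viruses = n_viruses, n_metabolites = n_metabolites, seed = seed)
    list(bacteria = bacteria, viruses = viruses, metabolites = metabolites,
         metadata = metadata, truth = truth_out)
  })
}

#' Write a generated cohort to a directory
#'
#' Emits the TSV dialect the loaders read (`bacteria.tsv`, `viruses.tsv`,
#' `metabolites.tsv`, `metadata.tsv`) plus the planted truth as a YAML
#' sidecar (`truth.yaml`).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(cohort$bacteria, file.path(dir, "bacteria.tsv"))
  if (!is.null(cohort$viruses))
    write_feature_table(cohort$viruses, file.path(dir, "viruses.tsv"))
  if (!is.null(cohort$metabolites))
    write_feature_table(cohort$metabolites, file.path(dir, "metabolites.tsv"))
  write_sample_metadata(cohort$metadata, file.path(dir, "metadata.tsv"))
  truth <- cohort$truth
  truth$basis_correlations <- if (is.null(truth$basis_correlations)) NULL else
    as.list(truth$basis_correlations)
  truth$differential_features <- as.list(truth$differential_features)
  truth$confounded_features <- as.list(truth$confounded_features)
  if (!is.null(truth$mediation_paths))
    truth$mediation_paths <- as.list(truth$mediation_paths)
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
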