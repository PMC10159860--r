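# allowed parameter keys per stage; seed listed separately where mandatory
.stage_schema <- list(
  simulate = list(keys = c("n_cases", "n_controls", "n_bacteria", "n_viruses",
                           "n_metabolites", "n_differential", "n_confounded",
                           "n_mediation"), stochastic = TRUE),
  differential = list(keys = c("table", "meta", "kingdom", "covariates",
                               "min_prevalence", "sig_threshold"),
                      stochastic = FALSE),
  ecology = list(keys = c("table", "meta", "kingdom", "metric", "n_perm"),
                 stochastic = TRUE),
  network = list(keys = c("bacteria", "virus", "meta", "group_col", "rho_min",
                          "p_max", "n_boot", "n_dirichlet", "min_prev",
                          "min_abund"), stochastic = TRUE),
  ptr = list(keys = c("coverage", "meta", "min_samples"), stochastic = FALSE),
  sv = list(keys = c("coverage", "meta", "min_unmasked"), stochastic = FALSE),
  mediate = list(keys = c("features", "metabolites", "meta", "targets",
                          "covariates", "gate", "sims", "rule", "adjust_bmi"),
                 stochastic = TRUE)
)

#' Validated run configuration for a pipeline stage
#'
#' @param stage one of `simulate`, `differential`, `ecology`, `network`,
#'   `ptr`, `sv`, `mediate`.
#' @param params named list of stage parameters; unknown keys are rejected.
#' @param out_dir output directory.
#' @param seed integer seed; mandatory for stochastic stages.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(stage, params = list(), out_dir, seed = NULL) {
  .assert(stage %in% names(.stage_schema), "unknown stage '%s' (known: %s)",
          stage, paste(names(.stage_schema), collapse = ", "))
  schema <- .stage_schema[[stage]]
  unknown <- setdiff(names(params), schema$keys)
  .assert(length(unknown) == 0, "unknown parameter(s) for stage '%s': %s",
          stage, paste(unknown, collapse = ", "))
  if (schema$stochastic) {
    .assert(!is.null(seed), "stage '%s' is stochastic: a seed is mandatory", stage)
  }
  structure(list(stage = stage, params = params, out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' @keywords internal
#' @noRd
.covariate_split <- function(x) {
  if (is.null(x)) c("age", "bmi", "smoking", "medication")
  else strsplit(x, ",")[[1]]
}

#' Run one pipeline stage
#'
#' Executes the stage described by a [run_config()]: outputs are written
#' atomically (into a temporary directory renamed on success; partial outputs
#' are removed on error) and a JSON manifest records the package version,
#' stage, parameters, seed, and MD5 checksums of all inputs and outputs.
#' Every stage is equally callable through the package's exported functions;
#' the runner only adds validation, atomicity and the manifest.
#'
#' @param config a [run_config()] (or arguments to build one).
#' @return Invisibly, the manifest list. Errors carry condition class
#'   `gutlink_validation_error` or `gutlink_data_error` for exit-code mapping
#'   in scripts.
#' @export
run_stage <- function(config) {
  .assert(inherits(config, "run_config"), "`config` must come from run_config()")
  p <- config$params
  out <- config$out_dir
  tmp <- paste0(out, ".tmp-", Sys.getpid())
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  inputs <- unlist(p[vapply(p, function(v) is.character(v) && length(v) == 1 &&
                              file.exists(v) && !dir.exists(v), logical(1))])
  getp <- function(key, default) if (!is.null(p[[key]])) p[[key]] else default

  switch(config$stage,
    simulate = {
      nb <- getp("n_bacteria", 200); nm <- getp("n_metabolites", 50)
      truth <- truth_config(
        n_differential = getp("n_differential", min(10, floor(nb / 4))),
        n_confounded = getp("n_confounded", min(5, floor(nb / 8))),
        n_mediation = getp("n_mediation", min(3, nm)))
      coh <- generate_cohort(n_cases = getp("n_cases", 77),
                             n_controls = getp("n_controls", 70),
                             n_bacteria = getp("n_bacteria", 200),
                             n_viruses = getp("n_viruses", 100),
                             n_metabolites = getp("n_metabolites", 50),
                             truth = truth, seed = config$seed)
      write_cohort(coh, tmp)
    },
    differential = {
      tab <- read_feature_table(p$table, kingdom = getp("kingdom", "bacteria"))
      covs <- .covariate_split(p$covariates)
      meta <- read_sample_metadata(p$meta, covariates = covs)
      res <- deconfound(tab, meta, covariates = covs,
                        min_prevalence = getp("min_prevalence", 0.10),
                        sig_threshold = getp("sig_threshold", 0.05))
      utils::write.table(res, file.path(tmp, "differential.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    ecology = {
      tab <- read_feature_table(p$table, kingdom = getp("kingdom", "bacteria"))
      meta <- read_sample_metadata(p$meta)
      meta_al <- .align_meta(tab, meta)
      v <- .ft_values(tab)
      div <- data.frame(sample_id = rownames(v),
                        shannon = apply(v, 1, shannon),
                        status = meta_al$status)
      utils::write.table(div, file.path(tmp, "alpha_diversity.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      d <- sample_distance(tab, metric = getp("metric", "canberra"))
      groups <- stats::setNames(ifelse(meta_al$status == 1, "case", "control"),
                                rownames(v))
      wb <- within_group_beta(d, groups)
      pm <- permanova(d, groups, n_perm = getp("n_perm", 999), seed = config$seed)
      utils::write.table(
        data.frame(metric = getp("metric", "canberra"),
                   median_within_case = wb$medians[["case"]],
                   median_within_control = wb$medians[["control"]],
                   p_within = wb$p, permanova_f = pm$f, permanova_p = pm$p),
        file.path(tmp, "beta_diversity.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    },
    network = {
      bact <- read_feature_table(p$bacteria, kingdom = "bacteria")
      vir <- read_feature_table(p$virus, kingdom = "virus")
      meta <- read_sample_metadata(p$meta)
      meta_al <- .align_meta(bact, meta)
      gcol <- getp("group_col", "status")
      groups <- meta_al[[gcol]]
      seeds <- .child_seeds(config$seed, length(unique(groups)))
      nets <- list()
      for (i in seq_along(unique(groups))) {
        gval <- unique(groups)[i]
        sel <- groups == gval
        nets[[as.character(gval)]] <- trans_kingdom_network(
          feature_table(.ft_values(bact)[sel, , drop = FALSE], "bacteria", "relative"),
          feature_table(.ft_values(vir)[sel, , drop = FALSE], "virus", "relative"),
          seed = seeds[i], rho_min = getp("rho_min", 0.2),
          p_max = getp("p_max", 0.05), n_boot = getp("n_boot", 100),
          n_dirichlet = getp("n_dirichlet", 20),
          min_prev = getp("min_prev", 0.10), min_abund = getp("min_abund", 0.0001),
          group = as.character(gval))
        write_network(nets[[as.character(gval)]],
                      file.path(tmp, sprintf("edges_%s.tsv", gval)))
      }
    },
    ptr = {
      files <- list.files(p$coverage, pattern = "\\.tsv$", full.names = TRUE)
      .assert(length(files) > 0, "no coverage TSVs in %s", p$coverage)
      inputs <- c(inputs, files)
      sets <- lapply(files, function(f)
        read_coverage_tsv(f, species_id = sub("\\.tsv$", "", basename(f))))
      names(sets) <- sub("\\.tsv$", "", basename(files))
      meta <- read_sample_metadata(p$meta)
      res <- cohort_ptr(sets, meta, min_samples = getp("min_samples", 20))
      utils::write.table(res$estimates, file.path(tmp, "ptr_estimates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$species_tests, file.path(tmp, "ptr_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    sv = {
      files <- list.files(p$coverage, pattern = "\\.tsv$", full.names = TRUE)
      .assert(length(files) > 0, "no coverage TSVs in %s", p$coverage)
      inputs <- c(inputs, files)
      meta <- read_sample_metadata(p$meta)
      profiles <- list()
      all_regions <- list()
      for (f in files) {
        sp <- sub("\\.tsv$", "", basename(f))
        profs <- read_coverage_tsv(f, species_id = sp, bin_size = 1000)
        covm <- t(vapply(profs, function(pr) pr$coverage,
                         numeric(length(profs[[1]]$coverage))))
        rownames(covm) <- vapply(profs, function(pr) pr$sample_id, "")
        colnames(covm) <- sprintf("bin_%04d", seq_len(ncol(covm)))
        prof <- classify_regions(call_deletions(covm), species_id = sp,
                                 min_unmasked = getp("min_unmasked", 10))
        if (!is.null(prof)) {
          profiles[[sp]] <- prof
          all_regions[[sp]] <- cbind(species = sp, prof$regions)
        }
      }
      profiles <- sv_prevalence_filter(profiles, cohort_size = nrow(meta))
      .assert(length(profiles) > 0, "no species retained after SV filtering")
      utils::write.table(do.call(rbind, all_regions),
                         file.path(tmp, "sv_regions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      dsv <- do.call(cbind, lapply(profiles, function(pr) pr$dsv_matrix))
      vsv <- do.call(cbind, lapply(profiles, function(pr) pr$vsv_matrix))
      if (!is.null(dsv) && ncol(dsv) > 0)
        utils::write.table(data.frame(sample_id = rownames(dsv), dsv,
                                      check.names = FALSE),
                           file.path(tmp, "dsv_matrix.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      if (!is.null(vsv) && ncol(vsv) > 0)
        utils::write.table(data.frame(sample_id = rownames(vsv), vsv,
                                      check.names = FALSE),
                           file.path(tmp, "vsv_matrix.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    },
    mediate = {
      feats <- read_feature_table(p$features, kingdom = "bacteria")
      metab <- read_feature_table(p$metabolites, kingdom = "metabolite",
                                  scale = "concentration")
      covs <- .covariate_split(p$covariates)
      targets <- strsplit(p$targets, ",")[[1]]
      meta <- read_sample_metadata(p$meta, covariates = covs, phenotypes = targets)
      meta_al <- .align_meta(feats, meta)
      res <- run_mediation(feats, metab,
                           as.matrix(meta_al[, targets, drop = FALSE]),
                           meta_al[, covs, drop = FALSE],
                           p_gate = getp("gate", 0.1),
                           adjust_bmi = getp("adjust_bmi", TRUE),
                           n_sims = getp("sims", 1000),
                           rule = getp("rule", "dominant"), seed = config$seed)
      utils::write.table(res$triplets, file.path(tmp, "triplets.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$network, file.path(tmp, "mediation_network.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  )

  produced <- list.files(tmp, recursive = TRUE)
  inputs <- as.character(inputs)
  manifest <- list(package = "gutlink",
                   version = as.character(utils::packageVersion("gutlink")),
                   stage = config$stage, params = p, seed = config$seed,
                   inputs = as.list(tools::md5sum(inputs)),
                   outputs = as.list(tools::md5sum(file.path(tmp, produced))))
  names(manifest$outputs) <- produced
  jsonlite::write_json(manifest, file.path(tmp, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(tmp, recursive = TRUE)) {
    file.rename(file.path(tmp, f), file.path(out, f))
  }
  invisible(manifest)
}
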