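# Orchestration of the discovery, validation and progression analyses:
# probe filtering -> bootstrap K selection -> deconvolution -> mixture
# association -> adjusted/unadjusted EWAS -> delta coefficients ->
# direction-stratified enrichment, with explicit per-stage seeds and plain
# TSV/JSON outputs so any stage can be rerun in isolation.

#' Build a pipeline configuration
#'
#' Collects every tunable of the discovery pipeline with its default. The
#' configuration round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param covariates Covariate names tested. Default `c("age")`.
#' @param k_grid Candidate numbers of cell types. Default `1:5`.
#' @param n_boot Bootstrap resamples for K selection. Default `100`.
#' @param top_variable Probes used for deconvolution. Default `10000`.
#' @param q_threshold FDR significance threshold. Default `0.01`.
#' @param permutations Permutations for the mixture-association test.
#'   Default `1000`.
#' @param exclude_flags Probe masks removed before analysis.
#' @param seeds Named list of per-stage integer seeds (`select_k`,
#'   `mixture`, `association`, `enrichment`).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(covariates = "age",
                            k_grid = 1:5,
                            n_boot = 100,
                            top_variable = 10000,
                            q_threshold = 0.01,
                            permutations = 1000,
                            exclude_flags = c("sex_chromosome",
                                              "cross_reactive",
                                              "snp_overlap"),
                            seeds = list(select_k = 11L, mixture = 12L,
                                         association = 13L,
                                         enrichment = 14L),
                            out_dir = NULL) {
  structure(list(covariates = covariates,
                 k_grid = as.integer(k_grid),
                 n_boot = as.integer(n_boot),
                 top_variable = as.integer(top_variable),
                 q_threshold = q_threshold,
                 permutations = as.integer(permutations),
                 exclude_flags = exclude_flags,
                 seeds = lapply(seeds, as.integer),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path Path to a YAML file written by [write_pipeline_config()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw[setdiff(names(raw), "out_dir")])
  cfg["out_dir"] <- list(raw$out_dir)
  cfg
}

.write_stage_tsv <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the discovery analysis
#'
#' Executes the full reference-free EWAS on one cohort: probe filtering,
#' bootstrap selection of K, deconvolution at the chosen K, the mixture
#' permutation test per covariate, adjusted and unadjusted moderated EWAS
#' per covariate with delta coefficients, and (when region sets are given)
#' direction-stratified enrichment for the first covariate. When
#' `config$out_dir` is set, every stage's table is written as TSV plus a
#' JSON run manifest.
#'
#' @param beta Beta matrix (probes x samples).
#' @param sheet Sample sheet aligned to the beta columns.
#' @param ann Probe annotation.
#' @param config A [pipeline_config()].
#' @param region_sets Optional list of [region_set()] objects.
#' @return A list with `k_selection`, `mixture`, `mixture_association`
#'   (per covariate), `ewas` (per covariate: `adjusted`, `unadjusted`,
#'   `delta`), `enrichment`, and `manifest`.
#' @export
run_discovery <- function(beta, sheet, ann, config = pipeline_config(),
                          region_sets = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  beta <- filter_probes(beta, ann, config$exclude_flags)
  beta <- drop_incomplete_probes(beta)
  message("discovery: ", nrow(beta), " probes x ", ncol(beta), " samples")

  ks <- select_k(beta, config$k_grid, n_boot = config$n_boot,
                 top_variable = config$top_variable,
                 seed = config$seeds$select_k)
  message("discovery: chosen K = ", ks$chosen_K)
  sub <- select_most_variable(beta, min(config$top_variable, nrow(beta)))
  mix <- fit_mixture(sub, ks$chosen_K, seed = config$seeds$mixture)

  assoc <- lapply(config$covariates, function(cv) {
    test_metadata_association(beta, sheet, cv, config$k_grid,
                              B = config$permutations,
                              top_variable = config$top_variable,
                              seed = config$seeds$association)
  })
  names(assoc) <- config$covariates

  M <- beta_to_mvalue(beta)
  ewas <- lapply(config$covariates, function(cv) {
    d_adj <- build_design(sheet, cv, mixture = mix)
    d_un <- build_design(sheet, cv, mixture = NULL)
    adj <- run_ewas(M, d_adj, cv, model_tag = "adjusted")
    un <- run_ewas(M, d_un, cv, model_tag = "unadjusted")
    list(adjusted = adj, unadjusted = un,
         delta = delta_coefficients(adj, un))
  })
  names(ewas) <- config$covariates

  enr <- NULL
  if (!is.null(region_sets)) {
    enr <- stratified_enrichment(ewas[[1]]$adjusted, rownames(beta), ann,
                                 region_sets,
                                 q_threshold = config$q_threshold)
  }

  n_sig <- vapply(ewas, function(e) {
    sum(e$adjusted$q_value < config$q_threshold)
  }, numeric(1))
  manifest <- list(
    n_probes = nrow(beta), n_samples = ncol(beta),
    chosen_K = ks$chosen_K,
    covariates = config$covariates,
    significant_adjusted = as.list(n_sig),
    q_threshold = config$q_threshold,
    seeds = config$seeds,
    stages = c("filter", "select_k", "fit_mixture",
               "mixture_association", "ewas", "delta",
               if (!is.null(enr)) "enrichment")
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_stage_tsv(data.frame(K = ks$k_grid,
                                deviance = ks$mean_bootstrap_deviance),
                     config$out_dir, "k_selection")
    .write_stage_tsv(data.frame(sample_id = rownames(mix$Omega),
                                mix$Omega),
                     config$out_dir, "omega")
    for (cv in config$covariates) {
      .write_stage_tsv(ewas[[cv]]$adjusted, config$out_dir,
                       paste0("ewas_", cv, "_adjusted"))
      .write_stage_tsv(ewas[[cv]]$unadjusted, config$out_dir,
                       paste0("ewas_", cv, "_unadjusted"))
      .write_stage_tsv(ewas[[cv]]$delta, config$out_dir,
                       paste0("delta_", cv))
    }
    if (!is.null(enr)) .write_stage_tsv(enr, config$out_dir, "enrichment")
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(k_selection = ks, mixture = mix, mixture_association = assoc,
       ewas = ewas, enrichment = enr, manifest = manifest)
}

#' Replicate discovery CpGs in an independent cohort
#'
#' Re-runs reference-free deconvolution on the validation cohort (its own
#' most-variable probes), then a cell-adjusted moderated EWAS restricted to
#' the discovery CpGs, reporting direction concordance with the discovery
#' coefficients, the count nominally significant at `p < 0.05`, and the
#' count passing the Bonferroni threshold `0.05 / n_discovery`.
#'
#' @param beta Validation beta matrix.
#' @param sheet Validation sample sheet.
#' @param discovery EWAS result table from the discovery cohort (supplies
#'   the CpG list and coefficient signs).
#' @param covariate Covariate name. Default `"age"`.
#' @param k_grid,n_boot,top_variable,seed Deconvolution settings.
#' @return A list with the per-CpG `table`, `concordance`,
#'   `n_nominal` (p < 0.05 and direction-consistent), `bonferroni_threshold`,
#'   `n_bonferroni`, and `n_shared`.
#' @export
run_validation <- function(beta, sheet, discovery, covariate = "age",
                           k_grid = 1:5, n_boot = 100, top_variable = 10000,
                           seed = 21L) {
  shared <- intersect(discovery$probe_id, rownames(beta))
  if (length(shared) == 0) stop("no shared discovery CpGs", call. = FALSE)
  missing_n <- length(setdiff(discovery$probe_id, shared))
  if (missing_n > 0) {
    message(missing_n, " discovery CpG(s) absent from validation cohort")
  }
  ks <- select_k(beta, k_grid, n_boot = n_boot,
                 top_variable = top_variable, seed = seed)
  sub <- select_most_variable(beta, min(top_variable, nrow(beta)))
  mix <- fit_mixture(sub, ks$chosen_K, seed = seed + 1L)
  M <- beta_to_mvalue(beta[shared, , drop = FALSE])
  design <- build_design(sheet, covariate, mixture = mix)
  res <- run_ewas(M, design, covariate, model_tag = "validation_adjusted")

  disc_coef <- discovery$coefficient[match(shared, discovery$probe_id)]
  concordant <- sign(res$coefficient) == sign(disc_coef)
  bonf <- 0.05 / length(discovery$probe_id)
  tab <- data.frame(probe_id = res$probe_id,
                    coefficient = res$coefficient,
                    p_value = res$p_value,
                    discovery_coefficient = disc_coef,
                    concordant = concordant,
                    stringsAsFactors = FALSE)
  list(table = tab,
       chosen_K = ks$chosen_K,
       concordance = mean(concordant),
       n_nominal = sum(res$p_value < 0.05 & concordant),
       bonferroni_threshold = bonf,
       n_bonferroni = sum(res$p_value < bonf),
       n_shared = length(shared))
}

#' Tumor-vs-normal progression contrast at query CpGs
#'
#' Fits age-adjusted moderated models of tumor-vs-normal status per CpG
#' across the combined cohorts, samples an annotation-matched background of
#' the same size as the query, and compares the two coefficient
#' distributions with a two-sample KS test. Larger query coefficients than
#' background indicate that the query CpGs are further deregulated in
#' tumors.
#'
#' @param normal,tumor Beta matrices over the same probes.
#' @param normal_sheet,tumor_sheet Sample sheets with `sample_id` and `age`.
#' @param query_cpgs Character vector of query probe ids.
#' @param ann Probe annotation (for background matching).
#' @param match_field Annotation column matched on. Default
#'   `"island_relation"`.
#' @param seed Integer seed for the background draw; changing it alters only
#'   the matched set, never the differential table.
#' @return A list with `table` (per-CpG status coefficients/p for query and
#'   background), `ks` (from [ks_compare()]), `query_fraction_sig` and
#'   `background_fraction_sig` at p < 0.05.
#' @export
run_progression <- function(normal, tumor, normal_sheet, tumor_sheet,
                            query_cpgs, ann,
                            match_field = "island_relation", seed = 31L) {
  if (!all(query_cpgs %in% rownames(normal)) ||
      !all(query_cpgs %in% rownames(tumor))) {
    stop("query CpGs missing from a cohort", call. = FALSE)
  }
  if (anyNA(normal_sheet$age) || anyNA(tumor_sheet$age)) {
    stop("age is required in both cohorts for adjustment", call. = FALSE)
  }
  combined <- cbind(normal, tumor[rownames(normal), , drop = FALSE])
  sheet <- data.frame(
    sample_id = c(normal_sheet$sample_id, tumor_sheet$sample_id),
    age = c(normal_sheet$age, tumor_sheet$age),
    tumor = rep(c(0, 1), c(ncol(normal), ncol(tumor))),
    stringsAsFactors = FALSE
  )
  M <- beta_to_mvalue(combined)
  design <- build_design(sheet, c("tumor", "age"))
  res <- run_ewas(M, design, "tumor", model_tag = "progression")

  background <- sample_matched_background(query_cpgs, rownames(combined),
                                          ann, match_field = match_field,
                                          seed = seed)
  q_res <- res[match(query_cpgs, res$probe_id), , drop = FALSE]
  b_res <- res[match(background, res$probe_id), , drop = FALSE]
  ks <- ks_compare(abs(q_res$coefficient), abs(b_res$coefficient))
  tab <- rbind(
    data.frame(q_res[, c("probe_id", "coefficient", "p_value")],
               set = "query", stringsAsFactors = FALSE),
    data.frame(b_res[, c("probe_id", "coefficient", "p_value")],
               set = "matched_background", stringsAsFactors = FALSE)
  )
  rownames(tab) <- NULL
  list(table = tab, ks = ks,
       query_fraction_sig = mean(q_res$p_value < 0.05),
       background_fraction_sig = mean(b_res$p_value < 0.05))
}
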