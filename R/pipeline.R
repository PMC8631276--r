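#' Pipeline configuration
#'
#' Central place for every tunable threshold of the end-to-end analysis.
#' Defaults are the published operating points of the workflow the
#' package implements: DML alpha 1e-5, DMR merge gap 200 bp, effect-size
#' filter |delta| >= 0.15, DEG thresholds FDR < 0.05 and |LFC| > 0.5,
#' BH-adjusted correlation p < 0.05, high-confidence overlap 0.8 and
#' eRNA-gene rho >= 0.7, eRNA activity of >= 3 reads in >= 1/3 of a
#' group.
#'
#' @param sim Optional [sim_config()]; when given the pipeline simulates
#'   its input cohort.
#' @param alpha_dml,max_gap,min_cpgs,min_delta DML/DMR thresholds.
#' @param deg_fdr,deg_lfc DEG thresholds.
#' @param rho_alpha Adjusted correlation-p threshold for linking.
#' @param hc_overlap,hc_rho High-confidence screening thresholds.
#' @param erna_min_reads,erna_frac eRNA activity criterion.
#' @param n_perm,null_per_cpg Permutation budget for [dml_test()].
#' @param seed Master seed; all stage randomness derives from it.
#' @param outdir Optional output directory for per-stage TSVs.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, alpha_dml = 1e-5, max_gap = 200,
                            min_cpgs = 1, min_delta = 0.15,
                            deg_fdr = 0.05, deg_lfc = 0.5,
                            rho_alpha = 0.05, hc_overlap = 0.8,
                            hc_rho = 0.7, erna_min_reads = 3,
                            erna_frac = 1 / 3, n_perm = 1000,
                            null_per_cpg = 2, seed = 1, outdir = NULL) {
  cfg <- as.list(environment())
  checks <- list(
    alpha_dml = alpha_dml > 0 && alpha_dml < 1,
    max_gap = max_gap > 0,
    min_delta = min_delta >= 0 && min_delta <= 1,
    deg_fdr = deg_fdr > 0 && deg_fdr < 1,
    rho_alpha = rho_alpha > 0 && rho_alpha < 1,
    hc_overlap = hc_overlap > 0 && hc_overlap <= 1,
    hc_rho = hc_rho >= 0 && hc_rho <= 1,
    erna_frac = erna_frac > 0 && erna_frac <= 1
  )
  bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
  if (length(bad) > 0) {
    stop_dmrlink(paste0("pipeline_config thresholds out of range: ",
                        paste(bad, collapse = ", ")),
                 "dmrlink_configuration_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the integrative pipeline end to end
#'
#' Executes, in order: cohort simulation (or ingestion), stratified
#' combined-BWS DML testing, DMR merging and summarisation, effect-size
#' filtering, regulatory classification, DMR-DEG linking with
#' high-confidence screening, and a link summary table. Optionally
#' replicates the links in a second cohort and runs clinical
#' associations for linked genes.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional cohort list (as from [generate_cohort()] or
#'   [read_cohort()]); required when `config$sim` is NULL.
#' @param replication Optional list with `manifest`, `meth`,
#'   `expression`, `design` for replication, or `"simulate"` to derive a
#'   second synthetic cohort (new noise, same planted truth) plus a
#'   sparse array manifest from the simulation config.
#' @param clinical Logical: run survival/stage association for
#'   high-confidence linked genes using the cohort's clinical table.
#' @return A list bundle with every stage's result plus the echoed
#'   configuration.
#' @export
run_pipeline <- function(config, cohort = NULL, replication = NULL,
                         clinical = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    if (is.null(config$sim)) {
      stop_dmrlink("either a cohort or config$sim is required",
                   "dmrlink_configuration_error")
    }
    cohort <- generate_cohort(config$sim)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_dmrlink(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)),
                   "dmrlink_stage_error")
    })
  }
  dml <- stage("dml_test", dml_test(
    cohort$methylation, cohort$design, n_perm = config$n_perm,
    null_per_cpg = config$null_per_cpg, alpha = config$alpha_dml,
    seed = config$seed))
  dml_pos <- dml$cpg |>
    dplyr::filter(.data$is_dml) |>
    dplyr::select("chrom", "pos")
  all_pos <- dml$cpg |> dplyr::select("chrom", "pos")
  dmrs <- stage("dmr_calling", merge_dml_to_dmrs(
    dml_pos, all_pos, max_gap = config$max_gap,
    min_cpgs = config$min_cpgs))
  dmrs <- stage("dmr_summary", summarize_dmrs(
    dmrs, dml, cohort$methylation, cohort$design,
    seed = config$seed + 1L))
  reg <- stage("regulatory", classify_regulatory(
    dmrs, cohort$states, cohort$gene_model))
  de <- stage("differential_expression", differential_expression(
    filter_expressed_genes(cohort$expression), cohort$design,
    lfc_threshold = config$deg_lfc, fdr_threshold = config$deg_fdr))
  links <- stage("linking", link_dmr_deg(
    reg, cohort$gene_model, cohort$methylation, cohort$design,
    cohort$expression, de, cohort$states, erna = cohort$erna,
    min_delta = config$min_delta, rho_alpha = config$rho_alpha,
    hc_overlap = config$hc_overlap, hc_rho = config$hc_rho))

  rep_records <- NULL
  if (identical(replication, "simulate")) {
    replication <- stage("replication_sim",
                         simulate_replication_cohort(config, cohort))
  }
  if (is.list(replication)) {
    probe_map <- stage("probe_mapping", map_dmr_to_probes(
      links |> dplyr::distinct(.data$dmr_id, .data$chrom, .data$start,
                               .data$end),
      replication$manifest))
    rep_records <- stage("replication", replicate_links(
      links, probe_map, replication$meth, replication$expression,
      replication$design))
  }
  summary <- summarize_links(links, rep_records)

  clin <- NULL
  if (isTRUE(clinical) && nrow(links) > 0 &&
        !is.null(cohort$clinical)) {
    clin <- stage("clinical", clinical_associations(cohort, links))
  }
  bundle <- list(cohort = cohort, dml = dml, dmrs = dmrs,
                 regulatory = reg, de = de, links = links,
                 replication = rep_records, summary = summary,
                 clinical = clin, config = config)
  if (!is.null(config$outdir)) write_pipeline_outputs(bundle)
  bundle
}

# second synthetic cohort with the same planted truth (layout is a
# deterministic function of the planted counts) but fresh noise, plus a
# sparse probe manifest emulating array coverage
simulate_replication_cohort <- function(config, cohort,
                                        coverage = 0.35) {
  sim2 <- cohort$config
  sim2$seed <- config$seed + 1000L
  rep_cohort <- generate_cohort(sim2)
  manifest <- with_local_seed(config$seed + 2000L, {
    keep <- stats::runif(nrow(rep_cohort$methylation)) < coverage
    tibble::tibble(
      probe_id = sprintf("cg%07d", which(keep)),
      chrom = rep_cohort$methylation$chrom[keep],
      pos = rep_cohort$methylation$pos[keep])
  })
  meth <- dplyr::bind_cols(
    tibble::tibble(probe_id = manifest$probe_id),
    rep_cohort$methylation[match(manifest$pos, rep_cohort$methylation$pos),
                           rep_cohort$design$sample_id])
  list(manifest = manifest, meth = meth,
       expression = rep_cohort$expression, design = rep_cohort$design,
       cohort = rep_cohort)
}

# survival and stage association for linked genes, using per-patient
# tumor expression and DMR methylation
clinical_associations <- function(cohort, links) {
  cl <- cohort$clinical
  design <- cohort$design
  pats <- cl$patient_id
  tum_ids <- design$sample_id[design$condition == "tumor"][
    match(pats, design$patient_id[design$condition == "tumor"])]
  expr_m <- as_matrix_by_sample(cohort$expression, design)
  rownames(expr_m) <- cohort$expression$gene_id
  hc <- links[links$high_confidence, ]
  if (nrow(hc) == 0) hc <- links
  genes <- unique(hc$gene_id)
  purrr::map(genes, function(g) {
    v <- log2(expr_m[g, tum_ids] + 0.01)
    cox <- tryCatch(
      cox_univariate(v, cl$os_time, cl$os_event, min_events = 5),
      error = function(e) NULL)
    oc <- tryCatch(
      optimal_cutoff(v, cl$os_time, cl$os_event, min_n = 15),
      error = function(e) NULL)
    st <- tryCatch(stage_association(v, cl$stage),
                   error = function(e) NULL)
    tibble::tibble(
      gene_id = g,
      hr = if (is.null(cox)) NA_real_ else cox$hr,
      p_cox = if (is.null(cox)) NA_real_ else cox$p,
      cutoff = if (is.null(oc)) NA_real_ else oc$cutoff,
      p_logrank = if (is.null(oc)) NA_real_ else oc$p_min,
      f_stage = if (is.null(st)) NA_real_ else st$statistic,
      p_stage = if (is.null(st)) NA_real_ else st$p)
  }) |> dplyr::bind_rows()
}

write_pipeline_outputs <- function(bundle) {
  dir <- bundle$config$outdir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(bundle$dml$cpg, file.path(dir, "dml.tsv"))
  write_dmr_bed(bundle$dmrs, file.path(dir, "dmrs.tsv"))
  readr::write_tsv(bundle$de, file.path(dir, "differential_expression.tsv"))
  readr::write_tsv(bundle$links, file.path(dir, "links.tsv"))
  readr::write_tsv(format_replication_summary(bundle$summary),
                   file.path(dir, "link_summary.tsv"))
  if (!is.null(bundle$replication)) {
    readr::write_tsv(bundle$replication, file.path(dir, "replication.tsv"))
  }
  if (!is.null(bundle$clinical)) {
    readr::write_tsv(bundle$clinical, file.path(dir, "clinical.tsv"))
  }
  cfg <- bundle$config
  cfg$sim <- NULL
  log_lines <- c(
    paste0("dmrlink ", as.character(utils::packageVersion("dmrlink"))),
    paste0("R ", R.version.string),
    vapply(names(cfg), function(nm) {
      paste0(nm, " = ", paste(format(cfg[[nm]]), collapse = " "))
    }, character(1)))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
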