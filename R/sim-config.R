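#' Configuration for the synthetic HCC-like cohort generator
#'
#' Bundles and validates all knobs of [generate_cohort()]. Defaults mirror
#' the discovery-cohort structure the package targets: 33 patients with
#' paired tumor/adjacent samples spread over three age strata, planted
#' hyper- and hypomethylated DMRs with a beta-scale effect of 0.3, and
#' methylation-expression links with target Spearman magnitude 0.7.
#'
#' @param n_patients Number of patients (each contributes a tumor and an
#'   adjacent sample). At least 6, so every age stratum holds >= 2.
#' @param n_cpgs Total number of simulated CpGs (planted DMR CpGs
#'   included).
#' @param n_genes Total number of genes in the gene model.
#' @param n_planted_hyper_dmrs,n_planted_hypo_dmrs Planted DMR counts.
#' @param delta_effect Beta-scale tumor-minus-adjacent methylation
#'   difference planted in DMRs; in \[0, 1). Zero plants a truth manifest
#'   with no realized effect.
#' @param rho_target Intended magnitude of the Spearman correlation
#'   between planted DMR methylation and target-gene expression.
#' @param frac_positive_links Fraction of planted links with non-classical
#'   positive methylation-expression sign.
#' @param erna_mean_active,erna_mean_inactive Expected eRNA read counts
#'   for active and inactive intergenic regions.
#' @param lfc_target Approximate |log2 fold change| planted for linked
#'   genes.
#' @param sigma_logit Logit-scale noise standard deviation of methylation
#'   values around their per-CpG baseline.
#' @param cpgs_per_dmr CpGs per planted DMR (>= 3).
#' @param n_background_erna Inactive intergenic eRNA regions added as
#'   background.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return A validated list of class `sim_config`.
#' @examples
#' sim_config(n_patients = 10, n_cpgs = 500, n_genes = 40, seed = 7)
#' @export
sim_config <- function(n_patients = 33,
                       n_cpgs = 5000,
                       n_genes = 120,
                       n_planted_hyper_dmrs = 5,
                       n_planted_hypo_dmrs = 5,
                       delta_effect = 0.3,
                       rho_target = 0.7,
                       frac_positive_links = 0.2,
                       erna_mean_active = 20,
                       erna_mean_inactive = 0.5,
                       lfc_target = 2,
                       sigma_logit = 0.35,
                       cpgs_per_dmr = 8,
                       n_background_erna = 20,
                       seed = 1) {
  cfg <- list(
    n_patients = n_patients, n_cpgs = n_cpgs, n_genes = n_genes,
    n_planted_hyper_dmrs = n_planted_hyper_dmrs,
    n_planted_hypo_dmrs = n_planted_hypo_dmrs,
    delta_effect = delta_effect, rho_target = rho_target,
    frac_positive_links = frac_positive_links,
    erna_mean_active = erna_mean_active,
    erna_mean_inactive = erna_mean_inactive,
    lfc_target = lfc_target, sigma_logit = sigma_logit,
    cpgs_per_dmr = cpgs_per_dmr,
    n_background_erna = n_background_erna,
    seed = seed
  )
  bad <- function(field, why) {
    stop_dmrlink(paste0("invalid sim_config field '", field, "': ", why),
                 "dmrlink_configuration_error")
  }
  if (!is.numeric(n_patients) || n_patients < 6) {
    bad("n_patients", "need at least 6 patients (2 per age stratum)")
  }
  if (delta_effect < 0 || delta_effect >= 1) {
    bad("delta_effect", "must lie in [0, 1)")
  }
  if (rho_target <= 0 || rho_target > 1) bad("rho_target", "must lie in (0, 1]")
  if (frac_positive_links < 0 || frac_positive_links > 1) {
    bad("frac_positive_links", "must lie in [0, 1]")
  }
  if (cpgs_per_dmr < 3) bad("cpgs_per_dmr", "each planted DMR needs >= 3 CpGs")
  n_planted <- n_planted_hyper_dmrs + n_planted_hypo_dmrs
  counts <- c(n_cpgs = n_cpgs, n_genes = n_genes,
              erna_mean_active = erna_mean_active)
  for (nm in names(counts)) {
    if (counts[[nm]] <= 0) bad(nm, "must be positive")
  }
  if (n_planted_hyper_dmrs < 0 || n_planted_hypo_dmrs < 0) {
    bad("n_planted_hyper_dmrs", "planted counts must be non-negative")
  }
  if (n_cpgs < n_planted * cpgs_per_dmr + 10) {
    bad("n_cpgs", "too few CpGs to host the planted DMRs plus background")
  }
  if (n_genes < n_planted + 3) {
    bad("n_genes", "too few genes to host planted links plus background")
  }
  if (!is.numeric(seed) || length(seed) != 1) bad("seed", "must be one integer")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d patients, %d CpGs, %d genes\n",
              x$n_patients, x$n_cpgs, x$n_genes))
  cat(sprintf("  planted DMRs: %d hyper + %d hypo, delta = %g, rho = %g\n",
              x$n_planted_hyper_dmrs, x$n_planted_hypo_dmrs,
              x$delta_effect, x$rho_target))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
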