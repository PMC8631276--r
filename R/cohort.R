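#' Generate a synthetic paired tumor/adjacent cohort with planted truth
#'
#' Simulates a self-contained HCC-like multi-omic cohort: paired
#' beta-valued methylation with age structure, planted hyper- and
#' hypomethylated DMRs, gene expression correlated (either sign) with
#' planted DMR methylation, eRNA counts correlated with intergenic
#' enhancer methylation, chromatin-state interval maps overlapping the
#' planted regulatory DMRs, and survival/stage outcomes driven by one
#' planted gene. A truth manifest records every planted DMR and link so
#' recovery can be scored.
#'
#' Methylation is simulated on the logit scale (logit-normal noise around
#' per-CpG baselines) so values stay in (0, 1) with tunable variance.
#' Planted DMRs occupy dedicated, widely separated loci ("cassettes") on a
#' single synthetic chromosome; the cassette layout is a deterministic
#' function of the planted counts, so two cohorts generated from configs
#' that differ only in `seed` share the same planted coordinates and genes
#' (useful for simulating an independent replication cohort).
#'
#' @param config A [sim_config()] object.
#' @return An object of class `synthetic_cohort`: a list with `design`,
#'   `methylation`, `expression`, `erna`, `gene_model`, `states`,
#'   `clinical`, `truth`, and `config`. All genomic coordinates are
#'   0-based half-open.
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 8, n_cpgs = 200,
#'                                      n_genes = 20, seed = 3))
#' cohort$truth
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_dmrlink("config must be created by sim_config()",
                 "dmrlink_configuration_error")
  }
  with_local_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  chrom <- "chr1"
  n <- cfg$n_patients
  design <- simulate_design(n)
  layout <- cohort_layout(cfg)
  n2 <- 2 * n
  tumor_idx <- which(design$condition == "tumor")
  adj_idx <- which(design$condition == "adjacent")

  # --- methylation ----------------------------------------------------
  cpg_pos <- sort(c(layout$planted_cpgs$pos, layout$bg_cpg_pos))
  n_cpg <- length(cpg_pos)
  mu_adj <- numeric(n_cpg)
  mu_tum <- numeric(n_cpg)
  bg <- !(cpg_pos %in% layout$planted_cpgs$pos)
  mu_bg <- 0.05 + 0.9 * stats::rbeta(sum(bg), 2.5, 1)
  mu_adj[bg] <- mu_bg
  mu_tum[bg] <- mu_bg
  pl <- match(layout$planted_cpgs$pos, cpg_pos)
  mu_adj[pl] <- layout$planted_cpgs$mu_adj
  mu_tum[pl] <- layout$planted_cpgs$mu_tum
  # mild global age trend (hypomethylation with age), applied equally to
  # both tissues of a patient so the tumor/adjacent contrast stays null
  # outside planted DMRs and within-stratum label permutation stays valid
  age_eff <- -0.01 * (design$age - 60)
  M <- matrix(0, n_cpg, n2)
  for (j in seq_len(n2)) {
    mu <- if (design$condition[j] == "tumor") mu_tum else mu_adj
    M[, j] <- stats::plogis(stats::qlogis(pmin(pmax(mu, 0.02), 0.98)) +
                              age_eff[j] +
                              stats::rnorm(n_cpg, 0, cfg$sigma_logit))
  }
  colnames(M) <- design$sample_id
  methylation <- dplyr::bind_cols(
    tibble::tibble(chrom = chrom, pos = cpg_pos),
    tibble::as_tibble(M)
  )

  # --- expression -----------------------------------------------------
  expr_log2 <- matrix(stats::rnorm(cfg$n_genes * n2, 0, 0.4),
                      cfg$n_genes, n2)
  base_expr <- stats::runif(cfg$n_genes, 2, 8)
  expr_log2 <- expr_log2 + base_expr
  rownames(expr_log2) <- layout$genes$gene_id

  erna_rows <- list()
  truth <- layout$truth
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    rows <- which(cpg_pos >= tr$start & cpg_pos < tr$end)
    m_s <- colMeans(M[rows, , drop = FALSE])
    z <- if (stats::sd(m_s) > 0) as.vector(scale(m_s)) else rep(0, n2)
    dz <- mean(z[tumor_idx]) - mean(z[adj_idx])
    gi <- match(tr$gene_id, layout$genes$gene_id)
    if (tr$kind == "intergenic_enhancer") {
      rho_me <- 0.8
      a <- tr$sign_me_erna * rho_me * z +
        sqrt(1 - rho_me^2) * stats::rnorm(n2)
      a_std <- if (stats::sd(a) > 0) as.vector(scale(a)) else a
      counts <- stats::rpois(n2, exp(log(cfg$erna_mean_active) + 0.5 * a_std))
      erna_rows[[length(erna_rows) + 1]] <- c(
        list(region_id = tr$erna_id, chrom = chrom,
             start = tr$start - 50L, end = tr$end + 50L),
        as.list(stats::setNames(counts, design$sample_id))
      )
      rho_eg <- min(0.97, cfg$rho_target + 0.15)
      e <- rho_eg * a_std + sqrt(1 - rho_eg^2) * stats::rnorm(n2)
    } else {
      rho_g <- min(0.98, 2 * sin(pi * min(cfg$rho_target, 0.95) / 6) + 0.08)
      e <- tr$sign * rho_g * z + sqrt(1 - rho_g^2) * stats::rnorm(n2)
    }
    de <- mean(e[tumor_idx]) - mean(e[adj_idx])
    k <- if (abs(de) > 1e-8 && cfg$delta_effect > 0) {
      cfg$lfc_target / abs(de)
    } else {
      1
    }
    expr_log2[gi, ] <- base_expr[gi] + k * e
  }
  tpm <- 2^expr_log2
  tpm[layout$genes$silent, ] <- 0
  expression <- dplyr::bind_cols(
    tibble::tibble(gene_id = layout$genes$gene_id),
    tibble::as_tibble(stats::setNames(as.data.frame(tpm), design$sample_id))
  )

  # --- background eRNA regions ---------------------------------------
  for (b in seq_len(cfg$n_background_erna)) {
    st <- layout$bg_zone_start + (b - 1) * 30000
    counts <- stats::rpois(n2, cfg$erna_mean_inactive)
    erna_rows[[length(erna_rows) + 1]] <- c(
      list(region_id = sprintf("erna_bg_%03d", b), chrom = chrom,
           start = st, end = st + 500),
      as.list(stats::setNames(counts, design$sample_id))
    )
  }
  erna <- dplyr::bind_rows(lapply(erna_rows, tibble::as_tibble))

  # --- clinical -------------------------------------------------------
  clinical <- simulate_clinical(design, expression, truth, tumor_idx)

  structure(
    list(design = design, methylation = methylation,
         expression = expression, erna = erna,
         gene_model = layout$gene_model, states = layout$states,
         clinical = clinical, truth = truth, config = cfg,
         chrom_len = layout$chrom_len),
    class = "synthetic_cohort"
  )
}

simulate_design <- function(n) {
  n_young <- max(2, round(n * 10 / 33))
  n_old <- max(2, round(n * 10 / 33))
  n_med <- n - n_young - n_old
  ages <- c(sample(40:54, n_young, replace = TRUE),
            sample(55:65, n_med, replace = TRUE),
            sample(66:80, n_old, replace = TRUE))
  patient_id <- sprintf("P%03d", seq_len(n))
  tibble::tibble(
    sample_id = c(paste0(patient_id, "_T"), paste0(patient_id, "_A")),
    patient_id = rep(patient_id, 2),
    condition = rep(c("tumor", "adjacent"), each = n),
    age = rep(ages, 2),
    age_group = assign_age_group(rep(ages, 2))
  ) |>
    dplyr::arrange(.data$patient_id, dplyr::desc(.data$condition == "tumor"))
}

# deterministic genomic layout: planted cassettes, genes, states, truth
cohort_layout <- function(cfg) {
  chrom <- "chr1"
  k <- cfg$cpgs_per_dmr
  n_planted <- cfg$n_planted_hyper_dmrs + cfg$n_planted_hypo_dmrs
  dirs <- rep(c("hyper", "hypo"),
              c(cfg$n_planted_hyper_dmrs, cfg$n_planted_hypo_dmrs))
  kinds <- rep(c("promoter", "genic_enhancer", "intergenic_enhancer"),
               length.out = max(n_planted, 1))[seq_len(n_planted)]
  n_pos <- round(cfg$frac_positive_links * n_planted)
  signs <- rep(-1, n_planted)
  if (n_pos > 0) signs[seq(n_planted, by = -1, length.out = n_pos)] <- 1

  planted_cpgs <- list()
  truth_rows <- list()
  gene_rows <- list()
  exon_rows <- list()
  state_rows <- list()
  state_samples <- tibble::tibble(
    sample_id = sprintf("chip_%02d", 1:8),
    is_tumor = c(TRUE, TRUE, rep(FALSE, 6))
  )
  for (j in seq_len(n_planted)) {
    o <- as.integer(1e6 + (j - 1) * 1.5e6)
    g <- o + 600000L
    gene_id <- sprintf("GENE_PL%03d", j)
    gene_rows[[j]] <- tibble::tibble(
      gene_id = gene_id, gene_name = gene_id,
      transcript_id = paste0(gene_id, ".1"),
      chrom = chrom, strand = "+", start = g, end = g + 20000L,
      silent = FALSE
    )
    exon_rows[[j]] <- tibble::tibble(
      transcript_id = paste0(gene_id, ".1"),
      start = c(g, g + 19000L), end = c(g + 200L, g + 20000L)
    )
    anchor <- switch(kinds[j],
      promoter = g - 800L,
      genic_enhancer = g + 5000L,
      intergenic_enhancer = o + 150000L
    )
    pos <- anchor + 60L * (0:(k - 1))
    dmr_start <- pos[1]
    dmr_end <- pos[k] + 1L
    base <- if (dirs[j] == "hyper") 0.35 else 0.80
    delta <- if (dirs[j] == "hyper") cfg$delta_effect else -cfg$delta_effect
    planted_cpgs[[j]] <- tibble::tibble(
      pos = pos, mu_adj = base, mu_tum = pmin(pmax(base + delta, 0.02), 0.98)
    )
    is_intergenic <- kinds[j] == "intergenic_enhancer"
    truth_rows[[j]] <- tibble::tibble(
      dmr_id = sprintf("planted_%03d", j), chrom = chrom,
      start = dmr_start, end = dmr_end,
      direction = dirs[j], kind = kinds[j], gene_id = gene_id,
      sign = signs[j],
      sign_me_erna = if (is_intergenic) signs[j] else NA_real_,
      erna_id = if (is_intergenic) sprintf("erna_pl_%03d", j) else NA_character_
    )
    # chromatin-state elements sitting inside the planted DMR; hyper DMRs
    # are painted active in non-tumor samples (repressed in tumor), hypo
    # DMRs active in tumor samples (activated in tumor)
    if (kinds[j] != "intergenic_enhancer") {
      label <- if (kinds[j] == "promoter") "activePromoter" else "activeEnhancer"
      cre <- if (kinds[j] == "promoter") "promoterLikeCRE" else "enhancerLikeCRE"
      el_start <- dmr_start + 40L
      el_end <- dmr_end - 40L
      samples_on <- if (dirs[j] == "hyper") {
        c("chip_03", "chip_04", "chip_05")
      } else {
        c("chip_01", "chip_02", "chip_03")
      }
      for (sid in samples_on) {
        state_rows[[length(state_rows) + 1]] <- tibble::tibble(
          sample_id = sid, chrom = chrom,
          start = el_start, end = el_end, state = label
        )
      }
      state_rows[[length(state_rows) + 1]] <- tibble::tibble(
        sample_id = "chip_06", chrom = chrom,
        start = el_start, end = el_end, state = cre
      )
    } else {
      state_rows[[length(state_rows) + 1]] <- tibble::tibble(
        sample_id = "chip_01", chrom = chrom,
        start = dmr_start, end = dmr_end, state = "activeEnhancer"
      )
    }
  }

  # background genes and CpGs in a separate gene-rich zone
  bg_zone_start <- as.integer(1e6 + max(n_planted, 1) * 1.5e6 + 5e5)
  n_bg_genes <- cfg$n_genes - n_planted
  n_silent <- min(2, max(0, n_bg_genes - 1))
  for (b in seq_len(n_bg_genes)) {
    s <- as.integer(bg_zone_start + 2e5 + (b - 1) * 120000)
    strand <- if (b %% 2 == 0) "-" else "+"
    gene_id <- sprintf("GENE_BG%03d", b)
    gene_rows[[n_planted + b]] <- tibble::tibble(
      gene_id = gene_id, gene_name = gene_id,
      transcript_id = paste0(gene_id, ".1"),
      chrom = chrom, strand = strand, start = s, end = s + 20000L,
      silent = b > n_bg_genes - n_silent
    )
    exon_rows[[n_planted + b]] <- tibble::tibble(
      transcript_id = paste0(gene_id, ".1"),
      start = c(s, s + 19000L), end = c(s + 200L, s + 20000L)
    )
  }
  genes <- dplyr::bind_rows(gene_rows)
  exons <- dplyr::bind_rows(exon_rows)
  n_bg_cpg <- cfg$n_cpgs - n_planted * k
  zone_len <- as.integer(max(2e6, n_bg_genes * 120000 + 6e5))
  bg_cpg_pos <- bg_zone_start +
    sort(sample.int(zone_len, n_bg_cpg, replace = FALSE))
  planted_cpgs <- if (n_planted > 0) {
    dplyr::bind_rows(planted_cpgs)
  } else {
    tibble::tibble(pos = integer(), mu_adj = double(), mu_tum = double())
  }
  states <- if (length(state_rows) > 0) {
    dplyr::bind_rows(state_rows) |>
      dplyr::left_join(state_samples, by = "sample_id") |>
      dplyr::select("sample_id", "is_tumor", "chrom", "start", "end", "state")
  } else {
    tibble::tibble(sample_id = character(), is_tumor = logical(),
                   chrom = character(), start = integer(),
                   end = integer(), state = character())
  }
  # scatter a few background state intervals
  states <- dplyr::bind_rows(states, tibble::tibble(
    sample_id = c("chip_07", "chip_08"),
    is_tumor = FALSE,
    chrom = chrom,
    start = bg_zone_start + c(100000L, 300000L),
    end = bg_zone_start + c(100000L, 300000L) + 800L,
    state = c("other", "enhancerLikeCRE")
  ))
  gm <- new_gene_model(
    transcripts = genes |>
      dplyr::select("transcript_id", "gene_id", "gene_name", "chrom",
                    "strand", "start", "end"),
    exons = exons
  )
  list(
    planted_cpgs = planted_cpgs,
    bg_cpg_pos = bg_cpg_pos,
    genes = genes,
    gene_model = gm,
    states = states,
    truth = if (n_planted > 0) dplyr::bind_rows(truth_rows) else empty_truth(),
    bg_zone_start = bg_zone_start,
    chrom_len = bg_zone_start + zone_len + 1e5
  )
}

empty_truth <- function() {
  tibble::tibble(
    dmr_id = character(), chrom = character(), start = integer(),
    end = integer(), direction = character(), kind = character(),
    gene_id = character(), sign = double(), sign_me_erna = double(),
    erna_id = character()
  )
}

simulate_clinical <- function(design, expression, truth, tumor_idx) {
  pats <- unique(design$patient_id)
  n <- length(pats)
  ages <- design$age[match(pats, design$patient_id)]
  lp <- rep(0, n)
  if (nrow(truth) > 0) {
    g <- truth$gene_id[1]
    tum_samples <- design$sample_id[design$condition == "tumor"]
    tum_samples <- tum_samples[match(pats, design$patient_id[design$condition == "tumor"])]
    v <- log2(as.numeric(expression[expression$gene_id == g, tum_samples]) + 0.01)
    if (stats::sd(v) > 0) lp <- 0.8 * as.vector(scale(v))
  }
  os_raw <- stats::rexp(n) / (0.15 * exp(lp))
  os_cens <- stats::runif(n, 2, 10)
  pfs_raw <- stats::rexp(n) / (0.25 * exp(lp))
  pfs_cens <- stats::runif(n, 1, 8)
  stage_score <- lp + stats::rnorm(n, 0, 0.7)
  stage <- cut(stage_score,
               breaks = stats::quantile(stage_score, c(0, 0.4, 0.7, 0.9, 1)),
               labels = c("I", "II", "III", "IV"), include.lowest = TRUE)
  tibble::tibble(
    patient_id = pats, age = ages,
    os_time = round(pmin(os_raw, os_cens), 4),
    os_event = as.integer(os_raw <= os_cens),
    pfs_time = round(pmin(pfs_raw, pfs_cens), 4),
    pfs_event = as.integer(pfs_raw <= pfs_cens),
    stage = as.character(stage)
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic paired tumor/adjacent cohort\n")
  cat(sprintf("  %d patients (%d samples), %d CpGs, %d genes, %d eRNA regions\n",
              nrow(x$clinical), nrow(x$design), nrow(x$methylation),
              nrow(x$expression), nrow(x$erna)))
  cat(sprintf("  planted DMRs: %d (truth manifest)\n", nrow(x$truth)))
  invisible(x)
}
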