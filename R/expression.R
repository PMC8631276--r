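#' Drop non-expressed and low-expressed genes
#'
#' Removes genes whose TPM falls below `min_tpm` in strictly more than
#' half of the samples.
#'
#' @param expression Tibble with `gene_id` plus one numeric TPM column
#'   per sample.
#' @param min_tpm Expression floor (default 0.01 TPM).
#' @return The filtered expression tibble.
#' @export
filter_expressed_genes <- function(expression, min_tpm = 0.01) {
  vals <- as.matrix(expression[, setdiff(names(expression), "gene_id"),
                               drop = FALSE])
  if (ncol(vals) < 2) {
    stop_dmrlink("expression needs at least 2 sample columns",
                 "dmrlink_validation_error")
  }
  n_low <- rowSums(vals < min_tpm)
  expression[n_low <= ncol(vals) / 2, ]
}

#' Paired differential expression (rank-based fallback)
#'
#' A simple paired differential-expression engine for TPM matrices when
#' no external DE table is available: the log2 fold change is
#' `log2((mean tumor TPM + eps) / (mean adjacent TPM + eps))` and the
#' p-value a paired Wilcoxon signed-rank test across patients, adjusted
#' with Benjamini-Hochberg. Alternatively pass `external` to ingest a DE
#' table verbatim (columns `gene_id`, `lfc`, `fdr`).
#'
#' @param expression TPM tibble (`gene_id` + sample columns).
#' @param design Paired design tibble (see [dml_test()]).
#' @param external Optional externally computed DE tibble; returned with
#'   the DEG flag applied and otherwise untouched.
#' @param lfc_threshold,fdr_threshold DEG calling thresholds
#'   (`|lfc| > 0.5`, `fdr < 0.05`).
#' @param eps Pseudo-TPM added to group means before the ratio.
#' @return A tibble `gene_id`, `lfc`, `p`, `fdr`, `mean_tpm_tumor`,
#'   `mean_tpm_adjacent`, `is_deg`.
#' @export
differential_expression <- function(expression, design, external = NULL,
                                    lfc_threshold = 0.5,
                                    fdr_threshold = 0.05, eps = 0.01) {
  if (!is.null(external)) {
    stopifnot(all(c("gene_id", "lfc", "fdr") %in% names(external)))
    return(dplyr::mutate(
      external,
      is_deg = .data$fdr < fdr_threshold & abs(.data$lfc) > lfc_threshold))
  }
  check_design(design)
  pats <- unique(design$patient_id)
  t_ids <- design$sample_id[design$condition == "tumor"][
    match(pats, design$patient_id[design$condition == "tumor"])]
  a_ids <- design$sample_id[design$condition == "adjacent"][
    match(pats, design$patient_id[design$condition == "adjacent"])]
  Tm <- as.matrix(expression[, t_ids, drop = FALSE])
  Am <- as.matrix(expression[, a_ids, drop = FALSE])
  mt <- rowMeans(Tm)
  ma <- rowMeans(Am)
  lfc <- log2((mt + eps) / (ma + eps))
  p <- vapply(seq_len(nrow(Tm)), function(i) {
    d <- Tm[i, ] - Am[i, ]
    if (all(d == 0)) return(1)
    suppressWarnings(stats::wilcox.test(Tm[i, ], Am[i, ],
                                        paired = TRUE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1
  fdr <- stats::p.adjust(p, method = "BH")
  tibble::tibble(
    gene_id = expression$gene_id, lfc = lfc, p = p, fdr = fdr,
    mean_tpm_tumor = mt, mean_tpm_adjacent = ma,
    is_deg = fdr < fdr_threshold & abs(lfc) > lfc_threshold
  )
}

#' Flag intergenic regions with active eRNA expression
#'
#' A region shows active enhancer RNA expression when at least one third
#' (ceiling) of the tumor samples or of the adjacent samples have a read
#' count of `min_reads` or more.
#'
#' @param counts Tibble of eRNA read counts (`region_id` + sample
#'   columns) or a numeric matrix.
#' @param design Design tibble mapping sample columns to conditions.
#' @param min_reads Read-count threshold (default 3).
#' @param frac Fraction of a group that must reach `min_reads`
#'   (default 1/3, applied with ceiling).
#' @return Logical vector, one entry per region.
#' @export
is_active_enhancer <- function(counts, design, min_reads = 3, frac = 1 / 3) {
  m <- if (is.matrix(counts)) counts else
    as.matrix(counts[, design$sample_id, drop = FALSE])
  if (any(m < 0) || any(m != round(m))) {
    stop_dmrlink("eRNA counts must be non-negative integers",
                 "dmrlink_validation_error")
  }
  t_col <- design$condition == "tumor"
  need_t <- ceiling(sum(t_col) * frac)
  need_a <- ceiling(sum(!t_col) * frac)
  hit <- m >= min_reads
  rowSums(hit[, t_col, drop = FALSE]) >= need_t |
    rowSums(hit[, !t_col, drop = FALSE]) >= need_a
}
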