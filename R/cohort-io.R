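#' Write a synthetic cohort as plain-text fixture files
#'
#' Emits the cohort as the pipeline's on-disk interchange formats:
#' tab-separated matrices (`methylation.tsv`, `expression.tsv`,
#' `erna.tsv`), the gene model as 1-based GTF (`gene_model.gtf`),
#' regulatory states as BED6+1 (`states.bed`, 0-based half-open), plus
#' `design.tsv`, `clinical.tsv` and the planted-truth manifest
#' `truth.tsv`. Files round-trip losslessly through [read_cohort()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, mode = 2) != 0) {
    stop_dmrlink(paste0("cannot write to directory: ", dir),
                 "dmrlink_io_error")
  }
  p <- function(f) file.path(dir, f)
  readr::write_tsv(cohort$methylation, p("methylation.tsv"))
  readr::write_tsv(cohort$expression, p("expression.tsv"))
  readr::write_tsv(cohort$erna, p("erna.tsv"))
  readr::write_tsv(cohort$design, p("design.tsv"))
  readr::write_tsv(cohort$clinical, p("clinical.tsv"))
  readr::write_tsv(cohort$truth, p("truth.tsv"))
  write_gtf(cohort$gene_model, p("gene_model.gtf"))
  write_state_bed(cohort$states, p("states.bed"))
  invisible(dir)
}

#' Read a cohort back from fixture files
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `synthetic_cohort`-shaped list (without the `config`).
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  design <- readr::read_tsv(p("design.tsv"), show_col_types = FALSE)
  design$age_group <- factor(design$age_group,
                             levels = c("young", "medium", "old"))
  structure(
    list(
      design = design,
      methylation = readr::read_tsv(p("methylation.tsv"),
                                    show_col_types = FALSE),
      expression = readr::read_tsv(p("expression.tsv"),
                                   show_col_types = FALSE),
      erna = readr::read_tsv(p("erna.tsv"), show_col_types = FALSE),
      clinical = readr::read_tsv(p("clinical.tsv"), show_col_types = FALSE),
      truth = readr::read_tsv(p("truth.tsv"), show_col_types = FALSE,
                              col_types = readr::cols(
                                erna_id = readr::col_character())),
      gene_model = read_gtf(p("gene_model.gtf")),
      states = read_state_bed(p("states.bed"))
    ),
    class = "synthetic_cohort"
  )
}
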