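#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_abline
#'   geom_hline labs facet_wrap theme_minimal position_dodge geom_jitter
NULL

#' Plot per-CpG combined-test statistics along the genome
#'
#' Manhattan-style view of the combined BWS `T` statistic with DML
#' highlighted.
#'
#' @param object A `dml_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dml_result <- function(object, ...) {
  ggplot(object$cpg, aes(x = .data$pos, y = .data$T,
                         colour = .data$is_dml)) +
    geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (bp)", y = "combined BWS T",
         colour = "DML") +
    theme_minimal()
}

#' Bar plot of genomic-region enrichment of DML
#'
#' @param enrichment Output of [region_enrichment()].
#' @return A ggplot object.
#' @export
plot_region_enrichment <- function(enrichment) {
  ggplot(enrichment,
         aes(x = factor(.data$location, levels = location_levels),
             y = .data$fold, fill = .data$direction)) +
    geom_col(position = position_dodge()) +
    geom_hline(yintercept = 1, linetype = 2) +
    labs(x = NULL, y = "fold enrichment vs all CpGs",
         fill = "direction") +
    theme_minimal()
}

#' Tumor versus non-tumor regulatory activity scores
#'
#' Scatter of per-DMR activity scores (counts of ChIP-seq samples with an
#' active overlap) in tumor versus non-tumor samples; points above the
#' diagonal are activated in tumor, below repressed.
#'
#' @param calls Output of [classify_regulatory()].
#' @param element `"promoter"` or `"enhancer"` scores.
#' @return A ggplot object.
#' @export
plot_activity <- function(calls, element = c("promoter", "enhancer")) {
  element <- match.arg(element)
  xcol <- paste0(element, "_score_nontumor")
  ycol <- paste0(element, "_score_tumor")
  keep <- calls[[paste0(element, "_like")]]
  ggplot(calls[keep, ],
         aes(x = .data[[xcol]], y = .data[[ycol]],
             colour = .data$direction)) +
    geom_jitter(width = 0.15, height = 0.15, alpha = 0.7) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "non-tumor activity score", y = "tumor activity score",
         title = paste0(element, "-like DMRs")) +
    theme_minimal()
}

#' Link counts by class and category
#'
#' Bar chart of HyperDown/HypoUp/HyperUp/HypoDown counts per link type.
#'
#' @param links Output of [link_dmr_deg()].
#' @return A ggplot object.
#' @export
plot_link_classes <- function(links) {
  ggplot(links, aes(x = factor(.data$class, levels = link_classes),
                    fill = .data$link_type)) +
    ggplot2::geom_bar(position = position_dodge()) +
    labs(x = NULL, y = "DMR-DEG links", fill = "category") +
    theme_minimal()
}
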