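#' Map DMRs to methylation-array probes
#'
#' Finds the array probes whose CpG coordinate falls inside each DMR
#' (`[start, end)`, half-open). Links whose DMR captures no probe cannot
#' be evaluated on the array platform and become type I replication
#' failures downstream.
#'
#' @param dmrs DMR tibble (`dmr_id`, `chrom`, `start`, `end`).
#' @param manifest Probe manifest tibble: `probe_id`, `chrom`, `pos`
#'   (0-based), optionally a `build` attribute/column.
#' @param build,manifest_build Optional genome-build tags; if both given
#'   and unequal the function refuses to map.
#' @return A tibble `dmr_id`, `probe_id`, `pos` (one row per probe in a
#'   DMR).
#' @export
map_dmr_to_probes <- function(dmrs, manifest, build = NULL,
                              manifest_build = NULL) {
  if (!is.null(build) && !is.null(manifest_build) &&
        !identical(build, manifest_build)) {
    stop_dmrlink(paste0("coordinate systems differ (", build, " vs ",
                        manifest_build, "); lift over before mapping"),
                 "dmrlink_coordinate_system_error")
  }
  if (anyDuplicated(manifest$probe_id)) {
    stop_dmrlink("manifest probe ids must be unique",
                 "dmrlink_validation_error")
  }
  probes <- tibble::tibble(chrom = manifest$chrom, start = manifest$pos,
                           end = manifest$pos + 1L)
  hits <- find_interval_overlaps(
    dmrs |> dplyr::select("chrom", "start", "end"), probes)
  tibble::tibble(
    dmr_id = dmrs$dmr_id[hits$q_idx],
    probe_id = manifest$probe_id[hits$s_idx],
    pos = manifest$pos[hits$s_idx]
  )
}

#' Replicate discovered links in an independent cohort
#'
#' For each discovery link: if the DMR contains no array probe, or the
#' target gene is not expressed in the replication cohort, the outcome is
#' a type I failure (the platform cannot test it). Otherwise probe
#' methylation is averaged within the DMR per sample and three criteria
#' are evaluated: differential methylation (two-sided rank-sum tumor vs
#' normal, p < `alpha`), differential expression (rank-sum, p <
#' `alpha`), and a significant methylation-expression Spearman
#' correlation with the same sign as in discovery. All three pass:
#' `replicated`; otherwise `type_II_failure`.
#'
#' @param links Discovery link tibble ([link_dmr_deg()]); `rho` carries
#'   the discovery correlation sign.
#' @param probe_map Output of [map_dmr_to_probes()].
#' @param meth Array methylation tibble: `probe_id` + sample columns
#'   (beta values).
#' @param expression Replication expression tibble: `gene_id` + sample
#'   columns.
#' @param design Replication design tibble with `sample_id` and
#'   `condition` (`tumor`/`adjacent`); pairing is not required.
#' @param alpha Per-criterion significance threshold (default 0.05).
#' @param adjust Multiple-testing adjustment across links for the three
#'   criterion p-value families: `"none"` (default, per-link verdicts) or
#'   `"BH"`.
#' @param min_tpm Expression floor used to declare a gene expressed.
#' @return A `replication_result` tibble: one row per link with
#'   `n_probes`, criterion statistics and `outcome` in
#'   `{replicated, type_I_failure, type_II_failure}`.
#' @export
replicate_links <- function(links, probe_map, meth, expression, design,
                            alpha = 0.05, adjust = c("none", "BH"),
                            min_tpm = 0.01) {
  adjust <- match.arg(adjust)
  if (!all(design$condition %in% c("tumor", "adjacent"))) {
    stop_dmrlink("replication design condition must be tumor/adjacent",
                 "dmrlink_design_error")
  }
  t_ids <- design$sample_id[design$condition == "tumor"]
  a_ids <- design$sample_id[design$condition == "adjacent"]
  expressed <- filter_expressed_genes(expression, min_tpm)$gene_id
  meth_m <- as.matrix(meth[, design$sample_id, drop = FALSE])
  rownames(meth_m) <- meth$probe_id
  expr_m <- as.matrix(expression[, design$sample_id, drop = FALSE])
  rownames(expr_m) <- expression$gene_id
  t_col <- design$condition == "tumor"

  rows <- purrr::pmap(
    list(links$dmr_id, links$gene_id, links$rho),
    function(did, gid, rho_disc) {
      probes <- probe_map$probe_id[probe_map$dmr_id == did]
      base <- tibble::tibble(
        dmr_id = did, gene_id = gid, n_probes = length(probes),
        p_meth = NA_real_, p_expr = NA_real_,
        rho = NA_real_, p_rho = NA_real_)
      if (length(probes) == 0 || !gid %in% expressed ||
            !gid %in% rownames(expr_m)) {
        base$outcome <- "type_I_failure"
        return(base)
      }
      mv <- colMeans(meth_m[probes, , drop = FALSE])
      ev <- expr_m[gid, ]
      base$p_meth <- suppressWarnings(
        stats::wilcox.test(mv[t_col], mv[!t_col])$p.value)
      base$p_expr <- suppressWarnings(
        stats::wilcox.test(ev[t_col], ev[!t_col])$p.value)
      ct <- spearman_cor(mv, ev)
      base$rho <- ct$rho
      base$p_rho <- ct$p
      base$outcome <- NA_character_
      base
    }) |> dplyr::bind_rows()

  testable <- is.na(rows$outcome)
  adj <- function(p) {
    out <- p
    out[testable] <- if (adjust == "BH") {
      stats::p.adjust(p[testable], "BH")
    } else {
      p[testable]
    }
    out
  }
  p_meth <- adj(rows$p_meth)
  p_expr <- adj(rows$p_expr)
  p_rho <- adj(rows$p_rho)
  ok <- testable &
    !is.na(p_meth) & p_meth < alpha &
    !is.na(p_expr) & p_expr < alpha &
    !is.na(p_rho) & p_rho < alpha &
    !is.na(rows$rho) & sign(rows$rho) == sign(links$rho)
  rows$outcome[testable] <- ifelse(ok[testable], "replicated",
                                   "type_II_failure")
  rows$class <- links$class
  rows$link_type <- links$link_type
  rows
}

#' Raw and platform-adjusted replication rates
#'
#' `rate_raw = replicated / discovery * 100`;
#' `rate_adjusted = replicated / (discovery - type_I) * 100`, i.e. the
#' rate among links the array platform could actually test. Rates are
#' rounded to 2 decimals; a zero denominator yields `NA` (rendered "/"
#' in formatted summaries).
#'
#' @param discovery,type_I,type_II,replicated Integer count vectors
#'   satisfying `discovery = type_I + type_II + replicated`.
#' @return A tibble with `rate_raw` and `rate_adjusted`.
#' @examples
#' replication_rates(171, 76, 32, 63)
#' @export
replication_rates <- function(discovery, type_I, type_II, replicated) {
  if (any(discovery != type_I + type_II + replicated)) {
    stop_dmrlink("counts are inconsistent: discovery must equal type_I + type_II + replicated",
                 "dmrlink_accounting_error")
  }
  raw <- ifelse(discovery > 0, round(replicated / discovery * 100, 2),
                NA_real_)
  den <- discovery - type_I
  adj <- ifelse(den > 0, round(replicated / den * 100, 2), NA_real_)
  tibble::tibble(rate_raw = raw, rate_adjusted = adj)
}

link_classes <- c("HyperDown", "HypoUp", "HyperUp", "HypoDown")
link_categories <- c("promoter", "genic_enhancer", "intergenic_enhancer")

#' Summarise links and replication outcomes by category and class
#'
#' Builds the per-(link type x class) accounting table: discovery
#' counts, type I / type II failure and replicated counts (when
#' replication records are supplied), raw and adjusted replication rates,
#' plus a total row per category. Also reports per category the fraction
#' of negatively correlated classes (HyperDown + HypoUp) among
#' discovered links.
#'
#' @param links Discovery link tibble with `link_type` and `class`.
#' @param records Optional [replicate_links()] output aligned with
#'   `links`.
#' @return A `replication_summary` tibble.
#' @export
summarize_links <- function(links, records = NULL) {
  grid <- tidyr::expand_grid(category = link_categories,
                             class = c(link_classes, "Total"))
  count_in <- function(tbl, cat, cls) {
    if (is.null(tbl)) return(NA_integer_)
    sub <- tbl[tbl$link_type == cat, ]
    if (cls != "Total") sub <- sub[sub$class == cls, ]
    nrow(sub)
  }
  out <- grid |>
    dplyr::mutate(
      discovery = purrr::map2_int(.data$category, .data$class,
                                  ~ count_in(links, .x, .y)))
  if (!is.null(records)) {
    cnt <- function(outc) {
      purrr::map2_int(grid$category, grid$class, function(cat, cls) {
        sub <- records[records$link_type == cat &
                         records$outcome == outc, ]
        if (cls != "Total") sub <- sub[sub$class == cls, ]
        nrow(sub)
      })
    }
    out$type_I <- cnt("type_I_failure")
    out$type_II <- cnt("type_II_failure")
    out$replicated <- cnt("replicated")
    out <- dplyr::bind_cols(
      out, replication_rates(out$discovery, out$type_I, out$type_II,
                             out$replicated))
  }
  neg <- out |>
    dplyr::filter(.data$class %in% c("HyperDown", "HypoUp")) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n_neg = sum(.data$discovery), .groups = "drop")
  tot <- out |>
    dplyr::filter(.data$class == "Total") |>
    dplyr::select("category", n_total = "discovery")
  frac <- dplyr::left_join(neg, tot, by = "category") |>
    dplyr::mutate(negative_fraction = ifelse(
      .data$n_total > 0, round(.data$n_neg / .data$n_total * 100, 2),
      NA_real_))
  out <- out |>
    dplyr::left_join(frac |> dplyr::select("category", "negative_fraction"),
                     by = "category") |>
    dplyr::mutate(negative_fraction = ifelse(.data$class == "Total",
                                             .data$negative_fraction,
                                             NA_real_))
  class(out) <- c("replication_summary", class(out))
  out
}

#' Format a replication summary for display
#'
#' Renders undefined rates as "/" the way published accounting tables
#' do.
#'
#' @param summary A [summarize_links()] tibble.
#' @return A character-formatted tibble.
#' @export
format_replication_summary <- function(summary) {
  fmt <- function(x) ifelse(is.na(x), "/", sprintf("%.2f", x))
  out <- tibble::as_tibble(summary)
  for (cc in intersect(c("rate_raw", "rate_adjusted"), names(out))) {
    out[[cc]] <- fmt(out[[cc]])
  }
  out
}
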