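#' Candidate target genes of a set of DMRs
#'
#' Distance-window candidate search, by link type: `promoter` keeps genes
#' whose TSS lies within 2 kb of the DMR start or end (distance 0 if the
#' TSS falls inside the DMR); `genic_enhancer` keeps genes whose interval
#' is separated from the DMR by less than 100 kb; `intergenic_enhancer`
#' keeps genes whose TSS lies within +/- 0.5 Mb of the DMR.
#'
#' The reported distance is signed: 0 when the TSS is inside the DMR,
#' otherwise TSS minus the nearest DMR boundary, with the sign flipped
#' for minus-strand genes so that the sign is consistent in transcription
#' coordinates. When a gene has several transcripts the one with the
#' smallest |distance| is kept.
#'
#' @param dmrs DMR tibble (`dmr_id`, `chrom`, `start`, `end`).
#' @param gene_model A `gene_model`.
#' @param link_type One of `"promoter"`, `"genic_enhancer"`,
#'   `"intergenic_enhancer"`.
#' @param promoter_window,genic_max_gap,intergenic_window Window sizes in
#'   bp for the three link types.
#' @return A tibble `dmr_id`, `gene_id`, `gene_name`, `transcript_id`,
#'   `distance`.
#' @export
candidate_genes <- function(dmrs, gene_model,
                            link_type = c("promoter", "genic_enhancer",
                                          "intergenic_enhancer"),
                            promoter_window = 2000,
                            genic_max_gap = 100000,
                            intergenic_window = 500000) {
  link_type <- match.arg(link_type)
  tx <- gene_model$transcripts
  tss <- transcript_tss(tx)
  rows <- purrr::pmap(
    list(dmrs$dmr_id, dmrs$chrom, dmrs$start, dmrs$end),
    function(id, ch, st, en) {
      on_chr <- tx$chrom == ch
      if (!any(on_chr)) return(NULL)
      t <- tss[on_chr]
      d0 <- ifelse(t >= st & t < en, 0L,
                   ifelse(t < st, t - st, t - en))
      dist <- ifelse(tx$strand[on_chr] == "-", -d0, d0)
      keep <- switch(link_type,
        promoter = abs(d0) <= promoter_window,
        genic_enhancer = pmax(0, tx$start[on_chr] - en,
                              st - tx$end[on_chr]) < genic_max_gap,
        intergenic_enhancer = abs(d0) <= intergenic_window
      )
      if (!any(keep)) return(NULL)
      tibble::tibble(
        dmr_id = id,
        gene_id = tx$gene_id[on_chr][keep],
        gene_name = tx$gene_name[on_chr][keep],
        transcript_id = tx$transcript_id[on_chr][keep],
        distance = dist[keep]
      )
    })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(dmr_id = character(), gene_id = character(),
                          gene_name = character(),
                          transcript_id = character(),
                          distance = integer()))
  }
  out |>
    dplyr::group_by(.data$dmr_id, .data$gene_id) |>
    dplyr::slice_min(abs(.data$distance), n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Classify a DMR-gene link by joint sign
#'
#' Joint sign classes of (methylation change, expression change):
#' hypermethylated + downregulated is `HyperDown`, hypomethylated +
#' upregulated `HypoUp` (the two classical, negatively correlated
#' classes), and `HyperUp` / `HypoDown` the non-classical positive
#' classes.
#'
#' @param delta Beta-scale methylation difference (tumor - adjacent);
#'   non-zero.
#' @param lfc log2 fold change of the gene; non-zero.
#' @return Character vector of class labels.
#' @examples
#' classify_link(c(0.3, -0.16), c(-3.36, 4.18))
#' @export
classify_link <- function(delta, lfc) {
  if (any(delta == 0) || any(lfc == 0)) {
    stop_dmrlink("links with zero delta or zero LFC are unclassifiable",
                 "dmrlink_value_error")
  }
  ifelse(delta > 0,
         ifelse(lfc < 0, "HyperDown", "HyperUp"),
         ifelse(lfc > 0, "HypoUp", "HypoDown"))
}

# Spearman correlation with p-value; returns NAs on constant input
spearman_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Methylation-eRNA-gene triple correlation
#'
#' The three Spearman correlations that an intergenic enhancer-like link
#' must pass simultaneously: DMR methylation vs eRNA counts (`rho_me`),
#' eRNA vs gene expression (`rho_eg`), and DMR methylation vs gene
#' expression (`rho_mg`).
#'
#' @param meth,erna,expr Numeric per-sample vectors (same sample order).
#' @param alpha Per-correlation significance threshold applied to the
#'   supplied p-values (raw here; the linker applies BH across candidate
#'   pairs before thresholding).
#' @return A list with the three correlations, their p-values, and
#'   `pass` (all three significant).
#' @export
triple_correlation <- function(meth, erna, expr, alpha = 0.05) {
  me <- spearman_cor(meth, erna)
  eg <- spearman_cor(erna, expr)
  mg <- spearman_cor(meth, expr)
  ps <- c(me$p, eg$p, mg$p)
  list(rho_me = me$rho, rho_eg = eg$rho, rho_mg = mg$rho,
       p_me = me$p, p_eg = eg$p, p_mg = mg$p,
       pass = !anyNA(ps) && all(ps < alpha))
}

# per-sample mean methylation of each DMR (rows follow dmrs)
dmr_methylation <- function(dmrs, methylation, design) {
  M <- as_matrix_by_sample(methylation, design)
  key <- paste(methylation$chrom, methylation$pos)
  out <- matrix(NA_real_, nrow(dmrs), ncol(M),
                dimnames = list(dmrs$dmr_id, design$sample_id))
  for (i in seq_len(nrow(dmrs))) {
    idx <- match(paste(dmrs$chrom[i], dmrs$cpgs[[i]]), key)
    if (anyNA(idx)) {
      stop_dmrlink("DMR member CpG missing from the methylation matrix",
                   "dmrlink_data_error")
    }
    out[i, ] <- colMeans(M[idx, , drop = FALSE])
  }
  out
}

#' Link promoter- and enhancer-like DMRs to differentially expressed genes
#'
#' The integrative linking step. Input DMRs must carry effect summaries
#' (from [summarize_dmrs()]) and regulatory flags (from
#' [classify_regulatory()]); only DMRs with `|delta| >= min_delta` are
#' considered. Three link routes are evaluated:
#'
#' * promoter: promoter-like DMRs vs genes with a TSS within 2 kb;
#'   Spearman correlation of DMR methylation and gene TPM across all
#'   samples, BH-adjusted across candidate pairs of this route; a link is
#'   kept when the gene is a DEG and `rho_padj < rho_alpha`.
#' * genic enhancer: enhancer-like, non-intergenic DMRs vs genes closer
#'   than 100 kb; same correlation screen.
#' * intergenic enhancer: intergenic DMRs whose eRNA region shows active
#'   expression ([is_active_enhancer()]) vs genes within +/- 0.5 Mb;
#'   requires the methylation-eRNA-gene triple correlation
#'   ([triple_correlation()]), each family BH-adjusted across candidate
#'   pairs.
#'
#' Genes linked through a promoter are excluded from both enhancer
#' routes. Each link is classified by [classify_link()] and screened for
#' high confidence ([screen_high_confidence()]).
#'
#' @param dmrs Summarised and regulatory-classified DMR tibble.
#' @param gene_model A `gene_model`.
#' @param methylation,design Methylation matrix and paired design.
#' @param expression TPM tibble; filtered through
#'   [filter_expressed_genes()] internally.
#' @param de_table Differential-expression tibble with `gene_id`, `lfc`,
#'   `fdr`, `is_deg` (see [differential_expression()]).
#' @param states Regulatory-state tibble (for high-confidence screening).
#' @param erna eRNA count tibble (`region_id`, `chrom`, `start`, `end`,
#'   sample columns); required for the intergenic route.
#' @param min_delta Effect-size filter (default 0.15).
#' @param rho_alpha Significance threshold on BH-adjusted correlation
#'   p-values (default 0.05).
#' @param triple_adjust `"BH"` (default) adjusts each triple-correlation
#'   family across candidate pairs; `"none"` uses raw p-values.
#' @param hc_overlap,hc_rho,hc_denominator High-confidence screening
#'   parameters, see [screen_high_confidence()].
#' @return A tibble of links: identification, `link_type`, `distance`,
#'   effect sizes, correlations with adjusted p-values, `class`, and
#'   `high_confidence`.
#' @export
link_dmr_deg <- function(dmrs, gene_model, methylation, design, expression,
                         de_table, states, erna = NULL,
                         min_delta = 0.15, rho_alpha = 0.05,
                         triple_adjust = c("BH", "none"),
                         hc_overlap = 0.8, hc_rho = 0.7,
                         hc_denominator = c("element", "dmr")) {
  triple_adjust <- match.arg(triple_adjust)
  hc_denominator <- match.arg(hc_denominator)
  needed <- c("delta", "direction", "promoter_like", "enhancer_like",
              "location", "cpgs")
  missing <- setdiff(needed, names(dmrs))
  if (length(missing) > 0) {
    stop_dmrlink(paste0("dmrs must be summarised and classified first; ",
                        "missing: ", paste(missing, collapse = ", ")),
                 "dmrlink_validation_error")
  }
  d <- filter_effect_size(dmrs, min_delta)
  expression <- filter_expressed_genes(expression)
  de_table <- de_table[de_table$gene_id %in% expression$gene_id, ]
  if (nrow(d) == 0) return(empty_links())
  meth_by_dmr <- dmr_methylation(d, methylation, design)
  expr_m <- as_matrix_by_sample(expression, design)
  rownames(expr_m) <- expression$gene_id

  corr_route <- function(sub, type) {
    if (nrow(sub) == 0) return(NULL)
    cand <- candidate_genes(sub, gene_model, type) |>
      dplyr::inner_join(de_table, by = "gene_id")
    if (nrow(cand) == 0) return(NULL)
    cors <- purrr::map2(cand$dmr_id, cand$gene_id, function(did, gid) {
      spearman_cor(meth_by_dmr[did, ], expr_m[gid, ])
    })
    cand$rho <- purrr::map_dbl(cors, "rho")
    cand$rho_p <- purrr::map_dbl(cors, "p")
    bad <- is.na(cand$rho)
    if (any(bad)) {
      rlang::warn(paste0(sum(bad), " ", type,
                         " candidate pair(s) with constant values; ",
                         "correlation undefined, link rejected"))
    }
    cand$rho_padj <- stats::p.adjust(cand$rho_p, method = "BH")
    cand |>
      dplyr::filter(!is.na(.data$rho), .data$is_deg,
                    .data$rho_padj < rho_alpha) |>
      dplyr::mutate(link_type = type)
  }

  prom <- corr_route(d[d$promoter_like, ], "promoter")
  genic <- corr_route(d[d$enhancer_like & d$location != "intergenic", ],
                      "genic_enhancer")
  promoter_genes <- if (is.null(prom)) character() else prom$gene_id
  if (!is.null(genic)) {
    genic <- genic[!genic$gene_id %in% promoter_genes, ]
  }

  inter <- NULL
  d_int <- d[d$location == "intergenic", ]
  if (!is.null(erna) && nrow(d_int) > 0) {
    active <- is_active_enhancer(erna, design)
    hits <- find_interval_overlaps(d_int, erna)
    hits <- hits[active[hits$s_idx], , drop = FALSE]
    if (nrow(hits) > 0) {
      erna_m <- as_matrix_by_sample(erna, design)
      d_act <- d_int[unique(hits$q_idx), ]
      region_of <- stats::setNames(
        erna$region_id[hits$s_idx[match(unique(hits$q_idx), hits$q_idx)]],
        d_int$dmr_id[unique(hits$q_idx)])
      cand <- candidate_genes(d_act, gene_model, "intergenic_enhancer") |>
        dplyr::inner_join(de_table, by = "gene_id") |>
        dplyr::filter(!.data$gene_id %in% promoter_genes)
      if (nrow(cand) > 0) {
        trips <- purrr::map2(cand$dmr_id, cand$gene_id, function(did, gid) {
          rid <- region_of[[did]]
          triple_correlation(meth_by_dmr[did, ],
                             erna_m[match(rid, erna$region_id), ],
                             expr_m[gid, ])
        })
        for (f in c("rho_me", "rho_eg", "rho_mg", "p_me", "p_eg", "p_mg")) {
          cand[[f]] <- purrr::map_dbl(trips, f)
        }
        adj <- function(p) {
          if (triple_adjust == "BH") stats::p.adjust(p, "BH") else p
        }
        cand$p_me_adj <- adj(cand$p_me)
        cand$p_eg_adj <- adj(cand$p_eg)
        cand$p_mg_adj <- adj(cand$p_mg)
        inter <- cand |>
          dplyr::filter(.data$is_deg,
                        !is.na(.data$rho_me), !is.na(.data$rho_eg),
                        !is.na(.data$rho_mg),
                        .data$p_me_adj < rho_alpha,
                        .data$p_eg_adj < rho_alpha,
                        .data$p_mg_adj < rho_alpha) |>
          dplyr::mutate(link_type = "intergenic_enhancer",
                        rho = .data$rho_mg, rho_p = .data$p_mg,
                        rho_padj = .data$p_mg_adj)
      }
    }
  }

  links <- dplyr::bind_rows(prom, genic, inter)
  if (nrow(links) == 0) return(empty_links())
  links <- links |>
    dplyr::left_join(
      d |> dplyr::select("dmr_id", "chrom", "start", "end", "delta",
                         "direction"),
      by = "dmr_id") |>
    dplyr::mutate(class = classify_link(.data$delta, .data$lfc))
  links$high_confidence <- screen_high_confidence(
    links, gene_model, states,
    hc_overlap = hc_overlap, hc_rho = hc_rho,
    denominator = hc_denominator)
  cols <- c("dmr_id", "chrom", "start", "end", "delta", "direction",
            "link_type", "gene_id", "gene_name", "distance", "lfc", "fdr",
            "rho", "rho_p", "rho_padj", "rho_me", "rho_eg", "rho_mg",
            "class", "high_confidence")
  for (cc in setdiff(cols, names(links))) links[[cc]] <- NA_real_
  links[, cols]
}

empty_links <- function() {
  tibble::tibble(
    dmr_id = character(), chrom = character(), start = integer(),
    end = integer(), delta = double(), direction = character(),
    link_type = character(), gene_id = character(), gene_name = character(),
    distance = double(), lfc = double(), fdr = double(), rho = double(),
    rho_p = double(), rho_padj = double(), rho_me = double(),
    rho_eg = double(), rho_mg = double(), class = character(),
    high_confidence = logical()
  )
}

#' High-confidence screening of DMR-DEG links
#'
#' Promoter and genic-enhancer links pass when the DMR covers at least
#' `hc_overlap` (default 80%) of a regulatory element: a promoter region
#' of the gene model, or an active-promoter / active-enhancer state
#' interval from any ChIP-seq sample. With `denominator = "element"`
#' (default) the fraction is overlap width over element width; `"dmr"`
#' divides by the DMR width instead. Intergenic enhancer links pass when
#' the eRNA-gene Spearman correlation `rho_eg >= hc_rho` (default 0.7).
#'
#' @param links Link tibble from [link_dmr_deg()] (needs `dmr_id`,
#'   `chrom`, `start`, `end`, `link_type`, `rho_eg`).
#' @param gene_model,states Sources of regulatory elements.
#' @param hc_overlap Minimum covered fraction.
#' @param hc_rho Minimum eRNA-gene correlation for intergenic links.
#' @param denominator `"element"` or `"dmr"`.
#' @return Logical vector along `links`.
#' @export
screen_high_confidence <- function(links, gene_model, states,
                                   hc_overlap = 0.8, hc_rho = 0.7,
                                   denominator = c("element", "dmr")) {
  denominator <- match.arg(denominator)
  if (nrow(links) == 0) return(logical(0))
  elements <- dplyr::bind_rows(
    promoter_regions(gene_model) |>
      dplyr::select("chrom", "start", "end"),
    states |>
      dplyr::filter(.data$state %in% c(promoter_state_labels,
                                       enhancer_state_labels)) |>
      dplyr::select("chrom", "start", "end")
  )
  q <- links |> dplyr::select("chrom", "start", "end")
  hits <- find_interval_overlaps(q, elements)
  covered <- rep(FALSE, nrow(links))
  if (nrow(hits) > 0) {
    denom <- if (denominator == "element") {
      elements$end[hits$s_idx] - elements$start[hits$s_idx]
    } else {
      links$end[hits$q_idx] - links$start[hits$q_idx]
    }
    frac <- hits$overlap_width / denom
    ok <- tapply(frac, factor(hits$q_idx, levels = seq_len(nrow(links))),
                 max)
    covered <- !is.na(ok) & as.numeric(ok) >= hc_overlap
  }
  ifelse(links$link_type == "intergenic_enhancer",
         !is.na(links$rho_eg) & links$rho_eg >= hc_rho,
         covered)
}
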