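#' Recognised chromatin-state labels
#'
#' Vocabulary for regulatory-state interval maps: `activeTSS`,
#' `activePromoter` and `promoterLikeCRE` mark active-promoter evidence
#' (H3K4me3 with H3K27ac or DNase); `activeEnhancer` and
#' `enhancerLikeCRE` mark active-enhancer evidence (H3K4me1/H3K27ac or
#' H3K27ac/DNase); `other` is inert.
#'
#' @export
regulatory_state_labels <- c("activeTSS", "activePromoter",
                             "promoterLikeCRE", "activeEnhancer",
                             "enhancerLikeCRE", "other")

promoter_state_labels <- c("activeTSS", "activePromoter", "promoterLikeCRE")
enhancer_state_labels <- c("activeEnhancer", "enhancerLikeCRE")

location_levels <- c("promoter", "utr5", "utr3", "exon", "intron",
                     "intergenic")

#' Annotate intervals with genomic-location labels
#'
#' Labels each interval with every genomic region class it overlaps by at
#' least 1 bp — promoter (−1,500/+500 bp around a TSS, strand-aware),
#' 5'UTR, 3'UTR, exon, intron — plus a single `location` chosen by the
#' priority promoter > 5'UTR > 3'UTR > exon > intron > intergenic.
#' Intervals overlapping nothing genic are `intergenic`.
#'
#' @param intervals A tibble with `chrom`, `start`, `end` (0-based
#'   half-open). A point CpG at position p is the interval `[p, p + 1)`.
#' @param gene_model A [new_gene_model()] object.
#' @return `intervals` with a list-column `location_set` and a character
#'   column `location` (the unique priority label).
#' @examples
#' gm <- new_gene_model(
#'   tibble::tibble(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
#'                  strand = "+", start = 10000, end = 12000),
#'   tibble::tibble(transcript_id = "t1", start = c(10000, 11500),
#'                  end = c(10200, 12000)))
#' annotate_location(tibble::tibble(chrom = "chr1", start = 8600,
#'                                  end = 8601), gm)$location
#' @export
annotate_location <- function(intervals, gene_model) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  known <- unique(gene_model$transcripts$chrom)
  unknown <- setdiff(unique(intervals$chrom), known)
  if (length(unknown) > 0) {
    rlang::warn(paste0("chromosomes absent from gene model: ",
                       paste(unknown, collapse = ", "),
                       "; labelled intergenic"))
  }
  cats <- list(
    promoter = promoter_regions(gene_model),
    utr5 = dplyr::left_join(
      gene_model$utr5,
      gene_model$transcripts |> dplyr::select("transcript_id", "chrom"),
      by = "transcript_id"),
    utr3 = dplyr::left_join(
      gene_model$utr3,
      gene_model$transcripts |> dplyr::select("transcript_id", "chrom"),
      by = "transcript_id"),
    exon = dplyr::left_join(
      gene_model$exons,
      gene_model$transcripts |> dplyr::select("transcript_id", "chrom"),
      by = "transcript_id"),
    intron = intron_regions(gene_model)
  )
  n <- nrow(intervals)
  hit_mat <- vapply(cats, function(s) {
    if (is.null(s) || nrow(s) == 0) return(rep(FALSE, n))
    overlaps_any(intervals, s)
  }, logical(n))
  if (n == 1) hit_mat <- matrix(hit_mat, nrow = 1,
                                dimnames = list(NULL, names(cats)))
  location_set <- lapply(seq_len(n), function(i) {
    labs <- names(cats)[hit_mat[i, ]]
    if (length(labs) == 0) "intergenic" else labs
  })
  unique_label <- vapply(location_set, function(labs) {
    location_levels[min(match(labs, location_levels))]
  }, character(1))
  intervals$location_set <- location_set
  intervals$location <- unique_label
  intervals
}

#' Genomic-region enrichment of DML relative to all CpGs
#'
#' For each unique location label, the fold enrichment is the fraction of
#' DML carrying that label divided by the fraction of all profiled CpGs
#' carrying it. If the `dml` table has a `direction` column
#' (hyper/hypo), folds are reported per direction.
#'
#' @param dml Tibble of DML positions (`chrom`, `pos`, optional
#'   `direction`).
#' @param all_cpgs Tibble of all profiled CpG positions (`chrom`, `pos`);
#'   `dml` must be a subset.
#' @param gene_model A `gene_model` object.
#' @return A tibble with `direction`, `location`, `n_dml`, `frac_dml`,
#'   `frac_background`, `fold`. Regions absent from the background get
#'   `fold = NA`.
#' @export
region_enrichment <- function(dml, all_cpgs, gene_model) {
  if (!all(dml$pos %in% all_cpgs$pos)) {
    stop_dmrlink("dml positions must be a subset of all_cpgs",
                 "dmrlink_validation_error")
  }
  bg <- annotate_location(
    tibble::tibble(chrom = all_cpgs$chrom, start = all_cpgs$pos,
                   end = all_cpgs$pos + 1L),
    gene_model)
  bg_tab <- table(factor(bg$location, levels = location_levels))
  bg_frac <- as.numeric(bg_tab) / nrow(bg)
  key <- paste(all_cpgs$chrom, all_cpgs$pos)
  dml$location <- bg$location[match(paste(dml$chrom, dml$pos), key)]
  if (!"direction" %in% names(dml)) dml$direction <- "all"
  dml |>
    dplyr::count(.data$direction,
                 location = factor(.data$location,
                                   levels = location_levels),
                 .drop = FALSE, name = "n_dml") |>
    dplyr::group_by(.data$direction) |>
    dplyr::mutate(frac_dml = .data$n_dml / sum(.data$n_dml)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      location = as.character(.data$location),
      frac_background = bg_frac[match(.data$location, location_levels)],
      fold = ifelse(.data$frac_background > 0,
                    .data$frac_dml / .data$frac_background, NA_real_)
    )
}

#' Classify DMRs as promoter- or enhancer-like from chromatin-state maps
#'
#' A DMR is promoter-like if it overlaps (>= 1 bp) an active-promoter
#' state interval in any ChIP-seq sample or carries a promoter location
#' annotation; enhancer-like if it overlaps an active-enhancer state
#' interval in any sample. Activity scores count the ChIP-seq samples
#' with such an overlap, split into tumor and non-tumor sample classes,
#' and activation in tumor is called per element class by comparing the
#' two counts ([call_activation()]).
#'
#' @param dmrs Tibble of DMR intervals with `dmr_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param states Tibble of state intervals: `sample_id`, `is_tumor`,
#'   `chrom`, `start`, `end`, `state` (labels from
#'   [regulatory_state_labels]).
#' @param gene_model A `gene_model` for the promoter location fallback.
#' @return A tibble with flags `promoter_like`/`enhancer_like`, scores
#'   `promoter_score_tumor`, `promoter_score_nontumor`,
#'   `enhancer_score_tumor`, `enhancer_score_nontumor`, and activation
#'   calls `activation_promoter`, `activation_enhancer`.
#' @export
classify_regulatory <- function(dmrs, states, gene_model) {
  if (nrow(states) == 0) {
    stop_dmrlink("at least one regulatory state map is required",
                 "dmrlink_validation_error")
  }
  bad <- setdiff(unique(states$state), regulatory_state_labels)
  if (length(bad) > 0) {
    stop_dmrlink(paste0("unknown regulatory state label(s): ",
                        paste(bad, collapse = ", ")),
                 "dmrlink_validation_error")
  }
  loc <- annotate_location(
    dmrs |> dplyr::select("chrom", "start", "end"), gene_model)
  hits <- find_interval_overlaps(dmrs, states)
  score <- function(labels, tumor_class) {
    if (nrow(hits) == 0) return(integer(nrow(dmrs)))
    h <- hits |>
      dplyr::filter(states$state[.data$s_idx] %in% labels,
                    states$is_tumor[.data$s_idx] == tumor_class)
    counts <- tapply(states$sample_id[h$s_idx], factor(h$q_idx,
                     levels = seq_len(nrow(dmrs))),
                     function(x) length(unique(x)))
    out <- as.integer(counts)
    out[is.na(out)] <- 0L
    out
  }
  p_t <- score(promoter_state_labels, TRUE)
  p_n <- score(promoter_state_labels, FALSE)
  e_t <- score(enhancer_state_labels, TRUE)
  e_n <- score(enhancer_state_labels, FALSE)
  has_promoter_loc <- vapply(loc$location_set,
                             function(s) "promoter" %in% s, logical(1))
  dmrs |>
    dplyr::mutate(
      location = loc$location,
      promoter_score_tumor = p_t,
      promoter_score_nontumor = p_n,
      enhancer_score_tumor = e_t,
      enhancer_score_nontumor = e_n,
      promoter_like = (p_t + p_n) > 0 | has_promoter_loc,
      enhancer_like = (e_t + e_n) > 0,
      activation_promoter = call_activation(p_t, p_n),
      activation_enhancer = call_activation(e_t, e_n)
    )
}

#' Call tumor activation from activity scores
#'
#' An element is `activated` in tumor when its tumor-sample activity
#' score exceeds its non-tumor score, `repressed` when smaller, and
#' `unchanged` on ties (ties are excluded from activated/repressed
#' numerators but retained in denominators when summarising).
#'
#' @param tumor_score,nontumor_score Integer vectors of per-class sample
#'   counts.
#' @return A character vector in `{activated, repressed, unchanged}`.
#' @examples
#' call_activation(c(2, 0, 1), c(0, 3, 1))
#' @export
call_activation <- function(tumor_score, nontumor_score) {
  ifelse(tumor_score > nontumor_score, "activated",
         ifelse(tumor_score < nontumor_score, "repressed", "unchanged"))
}

#' Read a BED6+1 regulatory-state file
#'
#' Columns: chrom, start, end, sample_id, score (1 = tumor sample, 0 =
#' non-tumor), strand, state label. BED coordinates are 0-based half-open
#' and used as-is.
#'
#' @param path Path to the BED file.
#' @return A states tibble as consumed by [classify_regulatory()].
#' @export
read_state_bed <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "start", "end", "sample_id",
                                "score", "strand", "state"),
                  col_types = "ciicicc", progress = FALSE) |>
    dplyr::transmute(sample_id = .data$sample_id,
                     is_tumor = .data$score == 1L,
                     chrom = .data$chrom, start = .data$start,
                     end = .data$end, state = .data$state)
}

#' Write a regulatory-state table as BED6+1
#'
#' @param states States tibble (`sample_id`, `is_tumor`, `chrom`,
#'   `start`, `end`, `state`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state_bed <- function(states, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%s",
                   states$chrom, states$start, states$end,
                   states$sample_id, as.integer(states$is_tumor),
                   states$state)
  writeLines(lines, path)
  invisible(path)
}
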