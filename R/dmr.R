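#' Merge differentially methylated loci into regions
#'
#' Two-step DMR construction: (1) consecutive DML on the same chromosome
#' with pairwise distance < `max_gap` bp form pre-DMRs; (2) every
#' profiled CpG lying between the first and last DML of a pre-DMR is
#' added as a member. Regions with fewer than `min_cpgs` members are
#' dropped. The region end is the last member CpG + 1 (half-open), making
#' BED export unambiguous.
#'
#' @param dml Tibble of DML positions: `chrom`, `pos`, sorted ascending
#'   within chromosome. Must be a subset of `all_cpgs`.
#' @param all_cpgs Tibble of all profiled CpG positions (`chrom`, `pos`),
#'   sorted ascending within chromosome.
#' @param max_gap Distance threshold in bp; neighbouring DML closer than
#'   this merge (default 200).
#' @param min_cpgs Minimum member count for a region to be kept. The
#'   default 1 retains single-CpG regions.
#' @return A tibble with `dmr_id`, `chrom`, `start`, `end`, `n_cpgs` and a
#'   list-column `cpgs` of member CpG positions.
#' @examples
#' dml <- tibble::tibble(chrom = "chr1", pos = c(100, 250, 600, 790))
#' all <- tibble::tibble(chrom = "chr1",
#'                       pos = c(100, 180, 250, 430, 600, 790))
#' merge_dml_to_dmrs(dml, all)
#' @export
merge_dml_to_dmrs <- function(dml, all_cpgs, max_gap = 200, min_cpgs = 1) {
  for (tbl in list(dml, all_cpgs)) {
    split(tbl$pos, tbl$chrom) |>
      lapply(assert_sorted, what = "CpG positions within a chromosome")
  }
  if (!all(paste(dml$chrom, dml$pos) %in%
             paste(all_cpgs$chrom, all_cpgs$pos))) {
    stop_dmrlink("every DML must be present among all_cpgs",
                 "dmrlink_validation_error")
  }
  out <- list()
  for (ch in unique(dml$chrom)) {
    d <- dml$pos[dml$chrom == ch]
    a <- all_cpgs$pos[all_cpgs$chrom == ch]
    if (length(d) == 0) next
    grp <- cumsum(c(1, diff(d) >= max_gap))
    for (g in unique(grp)) {
      members_dml <- d[grp == g]
      members <- a[a >= members_dml[1] & a <= members_dml[length(members_dml)]]
      if (length(members) < min_cpgs) next
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch, start = members[1], end = members[length(members)] + 1L,
        n_cpgs = length(members), cpgs = list(members)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(dmr_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_cpgs = integer(), cpgs = list()))
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(dmr_id = sprintf("dmr_%05d", dplyr::row_number()),
                  .before = 1)
}

#' Summarise DMRs: mean T, empirical p, group methylation and direction
#'
#' For each region: `mean_T` is the arithmetic mean of the member CpGs'
#' combined-test T statistics; its empirical p-value is estimated against
#' a null of means of equally many draws from the pooled CpG-level
#' permutation null; group-level methylation is the arithmetic average of
#' all member CpGs across the tumor (resp. adjacent) samples;
#' `delta = methy_tumor - methy_adjacent` and `direction` is `hyper` when
#' `delta > 0`, otherwise `hypo`.
#'
#' @param dmrs Output of [merge_dml_to_dmrs()].
#' @param dml_result A `dml_result` from [dml_test()] covering all member
#'   CpGs.
#' @param methylation,design As in [dml_test()].
#' @param n_null Monte Carlo draws per distinct member count for the
#'   mean-T null.
#' @param seed Optional local seed for the mean-T null resampling.
#' @return `dmrs` with columns `mean_T`, `p_empirical`, `methy_tumor`,
#'   `methy_adjacent`, `delta`, `direction`.
#' @export
summarize_dmrs <- function(dmrs, dml_result, methylation, design,
                           n_null = 2000, seed = NULL) {
  if (nrow(dmrs) == 0) {
    return(dplyr::mutate(dmrs, mean_T = double(), p_empirical = double(),
                         methy_tumor = double(), methy_adjacent = double(),
                         delta = double(), direction = character()))
  }
  check_design(design)
  key <- paste(dml_result$cpg$chrom, dml_result$cpg$pos)
  M <- as_matrix_by_sample(methylation, design)
  mkey <- paste(methylation$chrom, methylation$pos)
  t_col <- design$condition == "tumor"
  pool <- dml_result$null_T
  sizes <- sort(unique(dmrs$n_cpgs))
  null_means <- with_local_seed(seed, stats::setNames(lapply(sizes, function(m) {
    if (m == 1) sort.int(pool)
    else sort.int(colMeans(matrix(sample(pool, m * n_null, replace = TRUE),
                                  m, n_null)))
  }), sizes))
  res <- purrr::pmap(list(dmrs$chrom, dmrs$cpgs, dmrs$n_cpgs),
                     function(ch, cpgs, m) {
    idxT <- match(paste(ch, cpgs), key)
    if (anyNA(idxT)) {
      stop_dmrlink("DMR member CpG missing from the test results",
                   "dmrlink_data_error")
    }
    mean_t <- mean(dml_result$cpg$T[idxT])
    nm <- null_means[[as.character(m)]]
    p <- (1 + length(nm) - findInterval(mean_t - 1e-12, nm)) /
      (1 + length(nm))
    idxM <- match(paste(ch, cpgs), mkey)
    if (anyNA(idxM)) {
      stop_dmrlink("DMR member CpG missing from the methylation matrix",
                   "dmrlink_data_error")
    }
    sub <- M[idxM, , drop = FALSE]
    mt <- mean(sub[, t_col])
    ma <- mean(sub[, !t_col])
    tibble::tibble(mean_T = mean_t, p_empirical = p,
                   methy_tumor = mt, methy_adjacent = ma)
  }) |> dplyr::bind_rows()
  dmrs |>
    dplyr::bind_cols(res) |>
    dplyr::mutate(delta = .data$methy_tumor - .data$methy_adjacent,
                  direction = ifelse(.data$delta > 0, "hyper", "hypo"))
}

#' Keep DMRs with a minimum absolute methylation difference
#'
#' Retains regions with `|delta| >= min_delta` (inclusive). The default
#' 0.15 focuses downstream linking on regions with a substantial
#' beta-scale effect.
#'
#' @param dmrs Tibble with a `delta` column.
#' @param min_delta Effect-size threshold on the beta scale.
#' @return The filtered tibble.
#' @export
filter_effect_size <- function(dmrs, min_delta = 0.15) {
  if (nrow(dmrs) > 0 && !"delta" %in% names(dmrs)) {
    stop_dmrlink("dmrs must carry a populated 'delta' column",
                 "dmrlink_validation_error")
  }
  dplyr::filter(dmrs, abs(.data$delta) >= min_delta)
}

#' Export DMRs as a BED-style TSV
#'
#' Writes chrom, start, end, name, mean_T, direction plus delta, group
#' methylation means and empirical p.
#'
#' @param dmrs Summarised DMR tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  dmrs |>
    dplyr::select("chrom", "start", "end", name = "dmr_id", score = "mean_T",
                  "direction", "delta", "methy_tumor", "methy_adjacent",
                  "p_empirical") |>
    readr::write_tsv(path)
  invisible(path)
}
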