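#' Bundled reference accounting tables
#'
#' Two small plain-text tables ship with the package as worked-example
#' inputs for the accounting arithmetic:
#'
#' * `hcc_replication_counts()` — per-(category x class) link counts of a
#'   611-link high-confidence DMR-DEG discovery set from a 33-patient
#'   paired HCC WGBS cohort, with its independent 450k-array replication
#'   outcomes (type I failure: no probe in the DMR; type II failure:
#'   probes present but differential signal or correlation not
#'   confirmed; replicated).
#' * `hcc_enhancer_annotation()` — counts of intergenic DMRs with active
#'   eRNA expression and their overlap with ChIP-seq-annotated active
#'   enhancers, used to compute annotation percentages.
#'
#' @return A tibble.
#' @examples
#' counts <- hcc_replication_counts()
#' with(subset(aggregate(cbind(discovery, type_I, type_II, replicated)
#'                         ~ category, counts, sum),
#'             category == "promoter"),
#'      replication_rates(discovery, type_I, type_II, replicated))
#' @export
hcc_replication_counts <- function() {
  readr::read_tsv(system.file("extdata", "hcc_replication_counts.tsv",
                              package = "dmrlink"),
                  show_col_types = FALSE)
}

#' @rdname hcc_replication_counts
#' @export
hcc_enhancer_annotation <- function() {
  readr::read_tsv(system.file("extdata",
                              "hcc_enhancer_annotation_counts.tsv",
                              package = "dmrlink"),
                  show_col_types = FALSE)
}

#' Category replication summary from a plain count table
#'
#' Convenience wrapper turning a (category, class, discovery, type_I,
#' type_II, replicated) count table into the per-class and per-category
#' accounting table with raw and adjusted replication rates and
#' negative-correlation fractions, exactly as [summarize_links()] builds
#' from pipeline output.
#'
#' @param counts A tibble like [hcc_replication_counts()].
#' @return A `replication_summary` tibble.
#' @export
summarize_link_counts <- function(counts) {
  needed <- c("category", "class", "discovery", "type_I", "type_II",
              "replicated")
  missing <- setdiff(needed, names(counts))
  if (length(missing) > 0) {
    stop_dmrlink(paste0("count table missing columns: ",
                        paste(missing, collapse = ", ")),
                 "dmrlink_validation_error")
  }
  grid <- tidyr::expand_grid(category = link_categories,
                             class = c(link_classes, "Total"))
  cnt <- function(col) {
    purrr::map2_int(grid$category, grid$class, function(cat, cls) {
      sub <- counts[counts$category == cat, ]
      if (cls != "Total") sub <- sub[sub$class == cls, ]
      as.integer(sum(sub[[col]]))
    })
  }
  out <- grid
  out$discovery <- cnt("discovery")
  out$type_I <- cnt("type_I")
  out$type_II <- cnt("type_II")
  out$replicated <- cnt("replicated")
  out <- dplyr::bind_cols(
    out, replication_rates(out$discovery, out$type_I, out$type_II,
                           out$replicated))
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
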