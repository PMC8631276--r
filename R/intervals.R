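# Interval overlap helpers built on IRanges. All package coordinates are
# 0-based half-open; IRanges is 1-based inclusive, so [start, end) maps to
# IRanges(start + 1, end).

as_iranges <- function(tbl) {
  IRanges::IRanges(start = tbl$start + 1L, end = tbl$end)
}

#' Overlaps between two interval tables
#'
#' Any-overlap (>= 1 bp) join between two tibbles carrying `chrom`,
#' `start`, `end` (0-based half-open), chromosome-aware.
#'
#' @param query,subject Interval tibbles.
#' @return A tibble with `q_idx`, `s_idx` (row indices into query and
#'   subject) and `overlap_width` in bp.
#' @keywords internal
find_interval_overlaps <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble::tibble(q_idx = integer(), s_idx = integer(),
                          overlap_width = integer()))
  }
  out <- list()
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    hits <- IRanges::findOverlaps(as_iranges(query[qi, ]),
                                  as_iranges(subject[si, ]),
                                  minoverlap = 1L)
    if (length(hits) == 0) next
    qh <- qi[S4Vectors::queryHits(hits)]
    sh <- si[S4Vectors::subjectHits(hits)]
    w <- pmin(query$end[qh], subject$end[sh]) -
      pmax(query$start[qh], subject$start[sh])
    out[[length(out) + 1]] <- tibble::tibble(q_idx = qh, s_idx = sh,
                                             overlap_width = as.integer(w))
  }
  if (length(out) == 0) {
    return(tibble::tibble(q_idx = integer(), s_idx = integer(),
                          overlap_width = integer()))
  }
  dplyr::bind_rows(out)
}

overlaps_any <- function(query, subject) {
  hits <- find_interval_overlaps(query, subject)
  seq_len(nrow(query)) %in% hits$q_idx
}
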