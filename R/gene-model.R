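#' Gene model container
#'
#' A light container for transcript structures: a `transcripts` tibble
#' (`transcript_id`, `gene_id`, `gene_name`, `chrom`, `strand`, `start`,
#' `end`) and an `exons` tibble (`transcript_id`, `start`, `end`). All
#' coordinates are 0-based half-open; conversion to/from 1-based GTF
#' happens only in [read_gtf()] / [write_gtf()]. Optional `utr5`/`utr3`
#' tibbles with the same interval columns refine location annotation.
#'
#' @param transcripts,exons,utr5,utr3 Tibbles as described above.
#' @return An object of class `gene_model`.
#' @export
new_gene_model <- function(transcripts, exons,
                           utr5 = NULL, utr3 = NULL) {
  needed <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  missing <- setdiff(needed, names(transcripts))
  if (length(missing) > 0) {
    stop_dmrlink(paste0("gene model transcripts missing columns: ",
                        paste(missing, collapse = ", ")),
                 "dmrlink_validation_error")
  }
  if (!all(transcripts$strand %in% c("+", "-"))) {
    stop_dmrlink("transcript strand must be '+' or '-'",
                 "dmrlink_validation_error")
  }
  if (!"gene_name" %in% names(transcripts)) {
    transcripts$gene_name <- transcripts$gene_id
  }
  bad <- dplyr::anti_join(exons, transcripts, by = "transcript_id")
  if (nrow(bad) > 0) {
    stop_dmrlink("exons reference unknown transcripts",
                 "dmrlink_validation_error")
  }
  empty_iv <- tibble::tibble(transcript_id = character(),
                             start = integer(), end = integer())
  structure(
    list(transcripts = tibble::as_tibble(transcripts),
         exons = tibble::as_tibble(exons),
         utr5 = utr5 %||% empty_iv, utr3 = utr3 %||% empty_iv),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("Gene model: %d transcripts (%d genes), %d exons\n",
              nrow(x$transcripts), dplyr::n_distinct(x$transcripts$gene_id),
              nrow(x$exons)))
  invisible(x)
}

# 0-based TSS position of each transcript
transcript_tss <- function(transcripts) {
  ifelse(transcripts$strand == "+", transcripts$start, transcripts$end - 1)
}

#' Promoter intervals of a gene model
#'
#' The promoter of a transcript spans 1,500 bp upstream to 500 bp
#' downstream of its TSS: `[TSS - 1500, TSS + 500)` on the plus strand and
#' `[TSS - 500, TSS + 1500)` on the minus strand (0-based half-open).
#'
#' @param gene_model A [new_gene_model()] object.
#' @param upstream,downstream Window sizes in bp relative to transcription
#'   direction.
#' @return A tibble with `transcript_id`, `gene_id`, `gene_name`, `chrom`,
#'   `strand`, `tss`, `start`, `end`.
#' @export
promoter_regions <- function(gene_model, upstream = 1500, downstream = 500) {
  tx <- gene_model$transcripts
  tss <- transcript_tss(tx)
  plus <- tx$strand == "+"
  tibble::tibble(
    transcript_id = tx$transcript_id,
    gene_id = tx$gene_id,
    gene_name = tx$gene_name,
    chrom = tx$chrom,
    strand = tx$strand,
    tss = tss,
    start = pmax(0, ifelse(plus, tss - upstream, tss - downstream)),
    end = ifelse(plus, tss + downstream, tss + upstream)
  )
}

# intron intervals: transcript span minus exons (assumes exons sorted and
# non-overlapping within a transcript)
intron_regions <- function(gene_model) {
  ex <- gene_model$exons |>
    dplyr::arrange(.data$transcript_id, .data$start)
  by_tx <- split(ex, ex$transcript_id)
  rows <- lapply(by_tx, function(e) {
    if (nrow(e) < 2) return(NULL)
    tibble::tibble(transcript_id = e$transcript_id[1],
                   start = e$end[-nrow(e)], end = e$start[-1])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(transcript_id = character(), chrom = character(),
                          start = integer(), end = integer()))
  }
  out |>
    dplyr::left_join(
      gene_model$transcripts |> dplyr::select("transcript_id", "chrom"),
      by = "transcript_id") |>
    dplyr::filter(.data$end > .data$start)
}

#' Read a gene model from a GTF file
#'
#' Parses `transcript` and `exon` features of a 9-column GTF (1-based
#' inclusive coordinates) into a [new_gene_model()] with 0-based half-open
#' coordinates.
#'
#' @param path Path to a GTF file.
#' @return A `gene_model` object.
#' @export
read_gtf <- function(path) {
  g <- readr::read_tsv(path, comment = "#",
                       col_names = c("chrom", "source", "feature", "start",
                                     "end", "score", "strand", "frame",
                                     "attributes"),
                       col_types = "cccddcccc", progress = FALSE)
  attr_field <- function(x, key) {
    pat <- paste0(key, ' "([^"]*)"')
    m <- regexpr(pat, x)
    out <- rep(NA_character_, length(x))
    ok <- m != -1L
    out[ok] <- sub(pat, "\\1", regmatches(x, m))
    out
  }
  g$transcript_id <- attr_field(g$attributes, "transcript_id")
  g$gene_id <- attr_field(g$attributes, "gene_id")
  g$gene_name <- attr_field(g$attributes, "gene_name")
  tx <- g |>
    dplyr::filter(.data$feature == "transcript") |>
    dplyr::transmute(
      transcript_id = .data$transcript_id, gene_id = .data$gene_id,
      gene_name = dplyr::coalesce(.data$gene_name, .data$gene_id),
      chrom = .data$chrom, strand = .data$strand,
      start = as.integer(.data$start) - 1L, end = as.integer(.data$end)
    )
  ex <- g |>
    dplyr::filter(.data$feature == "exon") |>
    dplyr::transmute(transcript_id = .data$transcript_id,
                     start = as.integer(.data$start) - 1L,
                     end = as.integer(.data$end))
  new_gene_model(tx, ex)
}

#' Write a gene model to GTF
#'
#' @param gene_model A `gene_model` object (0-based half-open internally).
#' @param path Output path; coordinates are converted to 1-based
#'   inclusive.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gene_model, path) {
  tx <- gene_model$transcripts
  attr_str <- function(gid, tid, gname) {
    sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
            gid, tid, gname)
  }
  tx_lines <- sprintf("%s\tdmrlink\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                      tx$chrom, tx$start + 1L, tx$end, tx$strand,
                      attr_str(tx$gene_id, tx$transcript_id, tx$gene_name))
  ex <- gene_model$exons |>
    dplyr::left_join(tx |> dplyr::select("transcript_id", "gene_id",
                                         "gene_name", "chrom", "strand"),
                     by = "transcript_id")
  ex_lines <- sprintf("%s\tdmrlink\texon\t%d\t%d\t.\t%s\t.\t%s",
                      ex$chrom, ex$start + 1L, ex$end, ex$strand,
                      attr_str(ex$gene_id, ex$transcript_id, ex$gene_name))
  writeLines(c(tx_lines, ex_lines), path)
  invisible(path)
}
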