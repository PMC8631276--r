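#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider unnest
#' @importFrom purrr map map_dbl map2 pmap imap list_rbind
NULL

# internal: stop with a classed condition so callers/tests can be specific
stop_dmrlink <- function(msg, class) {
  rlang::abort(msg, class = c(class, "dmrlink_error"))
}

assert_sorted <- function(x, what) {
  if (is.unsorted(x)) {
    stop_dmrlink(paste0(what, " must be sorted in ascending order"),
                 "dmrlink_validation_error")
  }
  invisible(x)
}

# sample-matrix helpers: wide tibbles carry sample values in columns named
# by sample_id; everything else is annotation
sample_cols <- function(tbl, design) {
  ids <- design$sample_id
  missing <- setdiff(ids, names(tbl))
  if (length(missing) > 0) {
    stop_dmrlink(paste0("samples absent from table: ",
                        paste(missing, collapse = ", ")),
                 "dmrlink_data_error")
  }
  ids
}

as_matrix_by_sample <- function(tbl, design) {
  ids <- sample_cols(tbl, design)
  m <- as.matrix(tbl[, ids, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

check_design <- function(design) {
  needed <- c("sample_id", "patient_id", "condition")
  missing <- setdiff(needed, names(design))
  if (length(missing) > 0) {
    stop_dmrlink(paste0("design is missing columns: ",
                        paste(missing, collapse = ", ")),
                 "dmrlink_design_error")
  }
  if (!all(design$condition %in% c("tumor", "adjacent"))) {
    stop_dmrlink("design$condition must be 'tumor' or 'adjacent'",
                 "dmrlink_design_error")
  }
  tum <- design$patient_id[design$condition == "tumor"]
  adj <- design$patient_id[design$condition == "adjacent"]
  if (!setequal(tum, adj) || anyDuplicated(tum) || anyDuplicated(adj)) {
    stop_dmrlink("design must pair exactly one tumor and one adjacent sample per patient",
                 "dmrlink_design_error")
  }
  invisible(design)
}
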