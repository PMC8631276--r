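#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a BWS statistic
#'
#' @param x A `bws_test` object.
#' @param ... Unused.
#' @return A one-row tibble with `B`, `B_X`, `B_Y`, `n`, `m`.
#' @export
tidy.bws_test <- function(x, ...) {
  tibble::tibble(B = x$B, B_X = x$B_X, B_Y = x$B_Y, n = x$n, m = x$m)
}

#' Tidy per-CpG differential methylation results
#'
#' @param x A `dml_result`.
#' @param ... Unused.
#' @return The per-CpG results tibble.
#' @export
tidy.dml_result <- function(x, ...) {
  x$cpg
}

#' One-row summary of a differential methylation run
#'
#' @param x A `dml_result`.
#' @param ... Unused.
#' @return A tibble with CpG/DML counts and calibration parameters.
#' @export
glance.dml_result <- function(x, ...) {
  tibble::tibble(
    n_cpgs = nrow(x$cpg),
    n_dml = sum(x$cpg$is_dml),
    alpha = x$alpha,
    null_pool = length(x$null_T),
    n_perm = x$n_perm,
    scheme = x$scheme
  )
}
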