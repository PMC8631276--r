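#' Age-stratified combined BWS test for differential methylation
#'
#' Tests every CpG for differential methylation between tumor and adjacent
#' samples while adjusting for age. Patients are divided into three age
#' strata (see [assign_age_group()]); within each stratum a one-sided BWS
#' permutation test ([bws_one_sided()]) yields `p_left` and `p_right`,
#' which are combined across strata into `T_left`, `T_right` and
#' `T = max(T_left, T_right)` ([combined_bws()]). An empirical null of `T`
#' is built by re-testing label permutations and pooled across CpGs so the
#' achievable p-value resolution is `1/(n_cpgs * null_per_cpg + 1)` rather
#' than `1/(n_perm + 1)`. CpGs with `p_empirical < alpha` are flagged as
#' differentially methylated loci (DML).
#'
#' @param methylation A tibble with columns `chrom`, `pos` (0-based CpG
#'   coordinate) and one numeric column per sample (beta values in
#'   \[0, 1\]).
#' @param design A tibble with columns `sample_id`, `patient_id`,
#'   `condition` (`"tumor"`/`"adjacent"`) and either `age` or `age_group`.
#' @param n_perm Permutations per stratum per CpG when exhaustive
#'   enumeration is infeasible.
#' @param null_per_cpg Null draws of `T` contributed by each CpG to the
#'   pooled empirical null.
#' @param alpha Significance threshold on the empirical p-value. The
#'   default `1e-5` matches genome-scale use; reduce the threshold or
#'   raise `null_per_cpg` for small simulated cohorts.
#' @param seed Optional integer seed (applied locally).
#' @param scheme Label permutation scheme: `"stratum"` permutes
#'   tumor/adjacent labels freely within each age stratum (default);
#'   `"paired"` swaps labels within patients.
#' @param max_exhaustive Per-stratum arrangement count below which the
#'   permutation distribution is enumerated exhaustively.
#' @return An object of class `dml_result` with elements `cpg` (tibble of
#'   per-CpG results: `chrom`, `pos`, `T_left`, `T_right`, `T`,
#'   `p_empirical`, `is_dml`), `null_T` (pooled null draws), and the call
#'   parameters. Has [generics::tidy()] and [generics::glance()] methods.
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 8, n_cpgs = 40,
#'                                      n_genes = 10, seed = 1))
#' res <- dml_test(cohort$methylation, cohort$design,
#'                 n_perm = 200, alpha = 0.05, seed = 1)
#' head(tidy(res))
#' @export
dml_test <- function(methylation, design, n_perm = 1000, null_per_cpg = 2,
                     alpha = 1e-5, seed = NULL,
                     scheme = c("stratum", "paired"),
                     max_exhaustive = 10000) {
  scheme <- match.arg(scheme)
  check_design(design)
  if (n_perm < 100) {
    stop_dmrlink("n_perm must be at least 100", "dmrlink_parameter_error")
  }
  if (!"age_group" %in% names(design)) {
    if (!"age" %in% names(design)) {
      stop_dmrlink("design needs an 'age' or 'age_group' column",
                   "dmrlink_design_error")
    }
    design$age_group <- assign_age_group(design$age)
  }
  M <- as_matrix_by_sample(methylation, design)
  n_cpg <- nrow(M)
  res <- with_local_seed(seed, dml_test_impl(
    M, design, n_perm, null_per_cpg, scheme, max_exhaustive))
  pool <- length(res$null_T)
  if (1 / (pool + 1) > alpha) {
    stop_dmrlink(paste0(
      "empirical-null resolution 1/", pool + 1,
      " is coarser than alpha = ", alpha,
      "; increase null_per_cpg (or the number of CpGs) or raise alpha"),
      "dmrlink_calibration_resolution_error")
  }
  null_sorted <- sort.int(res$null_T)
  t_obs <- pmax(res$T_left, res$T_right)
  n_ge <- pool - findInterval(t_obs - 1e-12, null_sorted)
  p_emp <- (1 + n_ge) / (1 + pool)
  cpg <- tibble::tibble(
    chrom = methylation$chrom,
    pos = methylation$pos,
    T_left = res$T_left,
    T_right = res$T_right,
    T = t_obs,
    p_empirical = p_emp,
    is_dml = p_emp < alpha
  )
  structure(
    list(cpg = cpg, null_T = res$null_T, design = design,
         alpha = alpha, n_perm = n_perm, null_per_cpg = null_per_cpg,
         scheme = scheme),
    class = "dml_result"
  )
}

dml_test_impl <- function(M, design, n_perm, null_per_cpg, scheme,
                          max_exhaustive) {
  strata <- build_strata(design, scheme, n_perm, max_exhaustive)
  n_cpg <- nrow(M)
  n_str <- length(strata)
  k <- null_per_cpg
  T_left <- numeric(n_cpg)
  T_right <- numeric(n_cpg)
  null_T <- numeric(n_cpg * k)
  for (i in seq_len(n_cpg)) {
    tl <- 0
    tr <- 0
    ntl <- numeric(k)
    ntr <- numeric(k)
    for (st in strata) {
      v <- M[i, st$cols]
      dd <- stratum_directional(v, st)
      pv <- perm_pvalues(dd$D, dd$d_obs, st$arr$exhaustive)
      tl <- tl - 2 * log10(pv$p_left)
      tr <- tr - 2 * log10(pv$p_right)
      # null draws of T: each draw relabels the stratum with a fresh
      # random arrangement and scores it against the same permutation
      # reference sample with the same estimator as the observed
      # labeling, so observed and null p-values are identically
      # distributed under the null by construction
      for (q in seq_len(k)) {
        d_null <- null_directional(dd, st)
        pv_n <- perm_pvalues(dd$D, d_null, st$arr$exhaustive)
        ntl[q] <- ntl[q] - 2 * log10(pv_n$p_left)
        ntr[q] <- ntr[q] - 2 * log10(pv_n$p_right)
      }
    }
    T_left[i] <- tl
    T_right[i] <- tr
    null_T[(i - 1) * k + seq_len(k)] <- pmax(ntl, ntr)
  }
  list(T_left = T_left, T_right = T_right, null_T = null_T)
}

# per-stratum bookkeeping: column indices into the sample matrix (tumor
# columns first) and a precomputed arrangement set shared by all CpGs
build_strata <- function(design, scheme, n_perm, max_exhaustive) {
  groups <- split(seq_len(nrow(design)), design$age_group, drop = TRUE)
  lapply(groups, function(idx) {
    d <- design[idx, ]
    pats <- sort(unique(d$patient_id))
    if (length(pats) < 2) {
      stop_dmrlink("each age stratum needs at least 2 patients",
                   "dmrlink_design_error")
    }
    tum <- idx[d$condition == "tumor"]
    adj <- idx[d$condition == "adjacent"]
    t_col <- tum[match(pats, design$patient_id[tum])]
    a_col <- adj[match(pats, design$patient_id[adj])]
    n <- length(pats)
    arr <- if (scheme == "stratum") {
      bws_arrangements(2 * n, n, n_perm, max_exhaustive)
    } else {
      paired_arrangements(n, n_perm, max_exhaustive)
    }
    list(cols = c(t_col, a_col), n = n, m = n, N = 2 * n,
         scheme = scheme, arr = arr)
  })
}

# arrangements for the paired scheme: each arrangement swaps the
# tumor/adjacent labels of a subset of patients; indices address the
# pooled vector c(tumor values, adjacent values) in patient order
paired_arrangements <- function(n, n_perm, max_exhaustive = 10000) {
  total <- 2^n
  exhaustive <- total <= max_exhaustive
  swap <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  } else {
    matrix(sample(c(FALSE, TRUE), n_perm * n, replace = TRUE), n_perm, n)
  }
  base <- matrix(rep(seq_len(n), each = nrow(swap)), nrow(swap), n)
  idx_x <- base + n * swap
  idx_y <- base + n * (!swap)
  ix <- seq_len(n)
  list(idx_x = idx_x, idx_y = idx_y, n = n, m = n, N = 2 * n,
       n_arrangements = nrow(swap), exhaustive = exhaustive,
       wx_inv = 1 / ((ix / (n + 1)) * (1 - ix / (n + 1)) * (n * 2 * n / n)),
       wy_inv = 1 / ((ix / (n + 1)) * (1 - ix / (n + 1)) * (n * 2 * n / n)),
       ex = 2 * ix, ey = 2 * ix, paired = TRUE)
}

# directional statistic for all arrangements of one stratum at one CpG
stratum_directional <- function(v, st) {
  arr <- st$arr
  if (is.null(arr$paired)) {
    r <- rank(v)
    ord <- order(v)
    s <- r[ord]
    pos_obs <- which(ord <= st$n)
    list(D = bws_directional(s, arr),
         d_obs = bws_directional_one(s, pos_obs, st$n, st$m, st$N),
         s = s)
  } else {
    r <- rank(v)
    rx <- row_sort(matrix(r[arr$idx_x], arr$n_arrangements, arr$n))
    ry <- row_sort(matrix(r[arr$idx_y], arr$n_arrangements, arr$m))
    dx <- rx - rep(arr$ex, each = arr$n_arrangements)
    dy <- ry - rep(arr$ey, each = arr$n_arrangements)
    bx <- as.vector((dx * abs(dx)) %*% arr$wx_inv) / arr$n
    by <- as.vector((dy * abs(dy)) %*% arr$wy_inv) / arr$m
    d_obs <- bws_directional_one(sort.int(r), sort_positions(r, st$n),
                                 st$n, st$m, st$N)
    list(D = (by - bx) / 2, d_obs = d_obs, r = r)
  }
}

# directional statistic of one fresh random relabelling of a stratum
null_directional <- function(dd, st) {
  if (is.null(st$arr$paired)) {
    pos <- sort.int(sample.int(st$N, st$n))
    bws_directional_one(dd$s, pos, st$n, st$m, st$N)
  } else {
    swap <- sample(c(TRUE, FALSE), st$n, replace = TRUE)
    idx <- seq_len(st$n) + st$n * swap
    r <- dd$r
    rx <- sort.int(r[idx])
    ry <- sort.int(r[setdiff(seq_len(st$N), idx)])
    bx <- bws_component(rx, st$n, st$m, st$N, signed = TRUE)
    by <- bws_component(ry, st$m, st$n, st$N, signed = TRUE)
    (by - bx) / 2
  }
}

row_sort <- function(x) {
  t(apply(x, 1, sort.int))
}

# positions (in sorted pooled order) occupied by the first n entries
sort_positions <- function(r, n) {
  ord <- order(r)
  which(ord <= n)
}

#' @export
print.dml_result <- function(x, ...) {
  cat("Stratified combined-BWS differential methylation test\n")
  cat(sprintf("  %d CpGs, %d flagged as DML at alpha = %g\n",
              nrow(x$cpg), sum(x$cpg$is_dml), x$alpha))
  cat(sprintf("  pooled null size %d, scheme '%s', n_perm %d\n",
              length(x$null_T), x$scheme, x$n_perm))
  invisible(x)
}
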