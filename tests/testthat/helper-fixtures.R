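# Shared fixtures, built in code and cached for the duration of a test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small cohort for unit-level checks
small_cohort <- function(seed = 5) {
  cached(paste0("small_", seed), generate_cohort(
    sim_config(n_patients = 12, n_cpgs = 400, n_genes = 25, seed = seed)))
}

# discovery-scale cohort under the study conditions: 30 pairs, delta 0.3,
# rho 0.7, 5 + 5 planted DMRs across promoter/genic/intergenic kinds
study_cohort <- function() {
  cached("study", generate_cohort(sim_config(n_patients = 30, seed = 42)))
}

# null cohort (no planted effects) for calibration checks
null_cohort <- function() {
  cached("null", generate_cohort(
    sim_config(n_patients = 30, n_cpgs = 5000, n_genes = 120,
               n_planted_hyper_dmrs = 0, n_planted_hypo_dmrs = 0,
               seed = 101)))
}

null_dml_result <- function() {
  cached("null_dml", dml_test(null_cohort()$methylation,
                              null_cohort()$design,
                              n_perm = 300, null_per_cpg = 2,
                              alpha = 0.05, seed = 7))
}

# full pipeline stages on the study cohort, shared by recovery tests
study_pipeline <- function() {
  cached("study_pipe", {
    co <- study_cohort()
    res <- dml_test(co$methylation, co$design, n_perm = 500,
                    null_per_cpg = 2, alpha = 1e-3, seed = 1)
    dml_pos <- res$cpg[res$cpg$is_dml, c("chrom", "pos")]
    dmrs <- summarize_dmrs(
      merge_dml_to_dmrs(dml_pos, res$cpg[, c("chrom", "pos")]),
      res, co$methylation, co$design, seed = 2)
    reg <- classify_regulatory(dmrs, co$states, co$gene_model)
    de <- differential_expression(filter_expressed_genes(co$expression),
                                  co$design)
    links <- link_dmr_deg(reg, co$gene_model, co$methylation, co$design,
                          co$expression, de, co$states, erna = co$erna)
    list(cohort = co, dml = res, dmrs = dmrs, reg = reg, de = de,
         links = links)
  })
}

# expected class of each planted link from the truth manifest
truth_classes <- function(truth) {
  ifelse(truth$direction == "hyper",
         ifelse(truth$sign < 0, "HyperDown", "HyperUp"),
         ifelse(truth$sign < 0, "HypoUp", "HypoDown"))
}

# --- independent oracles -------------------------------------------------

# direct-formula BWS components, written independently of the package
# engine (plain loops over the definition)
oracle_bws_component <- function(sorted_ranks, n, other, N, signed) {
  acc <- 0
  for (i in seq_len(n)) {
    d <- sorted_ranks[i] - (N / n) * i
    w <- (i / (n + 1)) * (1 - i / (n + 1)) * (other * N / n)
    acc <- acc + (if (signed) d * abs(d) else d^2) / w
  }
  acc / n
}

oracle_bws_B <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  bx <- oracle_bws_component(sort(r[seq_len(n)]), n, m, N, signed = FALSE)
  by <- oracle_bws_component(sort(r[n + seq_len(m)]), m, n, N,
                             signed = FALSE)
  (bx + by) / 2
}

oracle_bws_D <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  bx <- oracle_bws_component(sort(r[seq_len(n)]), n, m, N, signed = TRUE)
  by <- oracle_bws_component(sort(r[n + seq_len(m)]), m, n, N,
                             signed = TRUE)
  (by - bx) / 2
}

# exhaustive enumeration of one-sided permutation p-values
oracle_exhaustive_pvalues <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  combs <- utils::combn(N, n)
  d <- apply(combs, 2, function(ix) oracle_bws_D(pooled[ix], pooled[-ix]))
  d_obs <- oracle_bws_D(x, y)
  tol <- 1e-9 * (1 + abs(d_obs))
  list(p_left = mean(d <= d_obs + tol), p_right = mean(d >= d_obs - tol))
}

# O(n^2) DMR merge oracle: pre-DMRs are connected components of the full
# pairwise "distance < gap" graph (valid for sorted positions)
oracle_merge <- function(dml, all, gap = 200, min_cpgs = 1) {
  if (length(dml) == 0) return(list())
  adj <- abs(outer(dml, dml, "-")) < gap
  repeat {
    nxt <- ((adj %*% adj) > 0) | adj
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp_id <- apply(adj, 1, function(r) min(which(r)))
  out <- lapply(unique(comp_id), function(cid) {
    g <- dml[comp_id == cid]
    members <- all[all >= min(g) & all <= max(g)]
    if (length(members) < min_cpgs) NULL else members
  })
  Filter(Negate(is.null), out)
}

# hand-style log-rank oracle: observed minus expected events in group 1
# over hypergeometric variances across distinct event times
oracle_logrank <- function(group, time, event) {
  g <- as.integer(factor(group)) - 1L
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d_tot <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o_minus_e <- o_minus_e + d1 - d_tot * n1 / n_tot
    if (n_tot > 1) {
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
    }
  }
  if (v == 0) return(0)
  o_minus_e^2 / v
}
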