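test_that("low-expression filter drops genes below the floor in a sample majority", {
  n <- 66
  ids <- sprintf("s%02d", seq_len(n))
  mk <- function(n_low) {
    vals <- c(rep(0.001, n_low), rep(5, n - n_low))
    tibble::as_tibble(stats::setNames(as.list(vals), ids)) |>
      dplyr::mutate(gene_id = paste0("g", n_low), .before = 1)
  }
  expr <- dplyr::bind_rows(mk(34), mk(33), mk(66), mk(0))
  kept <- filter_expressed_genes(expr)
  expect_equal(kept$gene_id, c("g33", "g0"))  # 34/66 and 66/66 excluded
})

test_that("paired DE fallback: identity gives no DEGs, planted effect is found", {
  co <- small_cohort()
  # duplicate adjacent columns as tumor -> all LFC 0
  dup <- co$expression
  t_ids <- co$design$sample_id[co$design$condition == "tumor"]
  a_ids <- co$design$sample_id[co$design$condition == "adjacent"]
  dup[, t_ids] <- dup[, a_ids]
  de0 <- differential_expression(dup, co$design)
  expect_true(all(de0$lfc == 0))
  expect_false(any(de0$is_deg))
  # planted links carry an LFC of about the configured target
  de <- differential_expression(filter_expressed_genes(co$expression),
                                co$design)
  planted <- de[de$gene_id %in% co$truth$gene_id, ]
  expect_gte(mean(abs(planted$lfc) > 0.5), 0.8)
})

test_that("external DE tables pass through with the DEG flag applied", {
  ext <- tibble::tibble(gene_id = c("a", "b", "c"),
                        lfc = c(2, 0.3, -1),
                        fdr = c(0.01, 0.01, 0.2))
  de <- differential_expression(NULL, NULL, external = ext)
  expect_equal(de$is_deg, c(TRUE, FALSE, FALSE))
  expect_equal(de$lfc, ext$lfc)
})

test_that("candidate windows and signed distances follow the conventions", {
  gm <- new_gene_model(
    tibble::tibble(
      transcript_id = c("tA", "tB", "tC"),
      gene_id = c("A", "B", "C"), gene_name = c("A", "B", "C"),
      chrom = "chr1", strand = c("+", "+", "-"),
      start = c(7500, 8100, 2000), end = c(9500, 9800, 3700)),
    tibble::tibble(transcript_id = c("tA", "tB", "tC"),
                   start = c(7500, 8100, 2000),
                   end = c(9500, 9800, 3700)))
  dmr <- tibble::tibble(dmr_id = "d", chrom = "chr1",
                        start = 5000, end = 6000)
  cand <- candidate_genes(dmr, gm, "promoter")
  # A: + strand TSS 7500, right of the DMR -> distance 7500 - 6000 = 1500
  expect_equal(cand$distance[cand$gene_id == "A"], 1500)
  # B: TSS 8100, 2100 bp from both boundaries -> excluded
  expect_false("B" %in% cand$gene_id)
  # C: - strand TSS 3699, 1301 bp left of start, sign flipped
  expect_equal(cand$distance[cand$gene_id == "C"], 1301)
  inside <- candidate_genes(
    tibble::tibble(dmr_id = "d2", chrom = "chr1",
                   start = 7000, end = 8000), gm, "promoter")
  expect_equal(inside$distance[inside$gene_id == "A"], 0)
  genic <- candidate_genes(
    tibble::tibble(dmr_id = "d3", chrom = "chr1",
                   start = 105000, end = 105500), gm, "genic_enhancer")
  expect_true("A" %in% genic$gene_id)  # gap 95,500 < 100 kb
  far <- candidate_genes(
    tibble::tibble(dmr_id = "d4", chrom = "chr1",
                   start = 109900, end = 110000), gm, "genic_enhancer")
  expect_false("A" %in% far$gene_id)   # gap 100,400 >= 100 kb
  inter <- candidate_genes(
    tibble::tibble(dmr_id = "d5", chrom = "chr1",
                   start = 500000, end = 500100), gm,
    "intergenic_enhancer")
  expect_true(all(c("A", "B", "C") %in% inter$gene_id))  # within 0.5 Mb
})

test_that("eRNA activity needs >= 3 reads in a third of either group", {
  n <- 33
  design <- tibble::tibble(
    sample_id = c(sprintf("t%02d", 1:n), sprintf("a%02d", 1:n)),
    patient_id = rep(sprintf("p%02d", 1:n), 2),
    condition = rep(c("tumor", "adjacent"), each = n))
  mk_counts <- function(n_t_hit, n_a_hit) {
    vals <- c(rep(3, n_t_hit), rep(0, n - n_t_hit),
              rep(3, n_a_hit), rep(0, n - n_a_hit))
    tibble::as_tibble(stats::setNames(as.list(vals), design$sample_id))
  }
  counts <- dplyr::bind_rows(mk_counts(11, 0), mk_counts(10, 10),
                             mk_counts(0, 0))
  expect_equal(is_active_enhancer(counts, design),
               c(TRUE, FALSE, FALSE))
  expect_error(is_active_enhancer(mk_counts(1, 1) - 5, design),
               class = "dmrlink_validation_error")
})

test_that("joint sign classification is total and exclusive", {
  expect_equal(classify_link(c(0.3, -0.16, 0.2, -0.19),
                             c(-3.36, 4.18, 1.2, -2.68)),
               c("HyperDown", "HypoUp", "HyperUp", "HypoDown"))
  set.seed(2)
  d <- runif(50, -1, 1); l <- runif(50, -4, 4)
  keep <- d != 0 & l != 0
  cls <- classify_link(d[keep], l[keep])
  expect_true(all(cls %in% c("HyperDown", "HypoUp", "HyperUp", "HypoDown")))
  expect_error(classify_link(0, 1), class = "dmrlink_value_error")
})

test_that("triple correlation passes only when all three tests do", {
  set.seed(8)
  m <- rnorm(40)
  e <- -0.9 * m + 0.3 * rnorm(40)
  g <- 0.9 * e + 0.3 * rnorm(40)
  tri <- triple_correlation(m, e, g)
  expect_true(tri$pass)
  expect_lt(tri$rho_me, 0)
  expect_gt(tri$rho_eg, 0)
  # identical eRNA and gene vectors give rho_eg = 1
  expect_equal(triple_correlation(m, e, e)$rho_eg, 1)
  # an unrelated gene breaks one leg
  tri2 <- triple_correlation(m, e, rnorm(40))
  expect_false(tri2$pass)
})

test_that("high-confidence screening applies the 80% coverage and rho rules", {
  gm <- new_gene_model(
    tibble::tibble(transcript_id = "t", gene_id = "G", gene_name = "G",
                   chrom = "chr9", strand = "+",
                   start = 900000, end = 920000),
    tibble::tibble(transcript_id = "t", start = 900000, end = 920000))
  states <- tibble::tibble(
    sample_id = "s1", is_tumor = TRUE, chrom = "chr1",
    start = c(1000, 5000), end = c(2000, 6000),
    state = "activePromoter")
  links <- tibble::tibble(
    dmr_id = c("d85", "d50", "i1", "i2"),
    chrom = "chr1",
    start = c(1000, 1500, 7000, 8000),
    end = c(1850, 2000, 7100, 8100),
    link_type = c("promoter", "promoter", "intergenic_enhancer",
                  "intergenic_enhancer"),
    rho_eg = c(NA, NA, 0.72, 0.69))
  hc <- screen_high_confidence(links, gm, states)
  expect_equal(hc, c(TRUE, FALSE, TRUE, FALSE))
  # denominator switch: 850/850 of the DMR covered -> d85 still passes
  hc2 <- screen_high_confidence(links, gm, states, denominator = "dmr")
  expect_true(hc2[1])
})

test_that("planted links are recovered with correct class and no promoter/enhancer double-linking", {
  pipe <- study_pipeline()
  links <- pipe$links
  truth <- pipe$cohort$truth
  expected <- truth_classes(truth)
  hit <- purrr::map2_lgl(truth$gene_id, expected, function(g, cls) {
    any(links$gene_id == g & links$class == cls)
  })
  expect_gte(mean(hit), 0.8)
  # exclusivity: no gene appears both as promoter- and enhancer-type target
  by_gene <- split(links$link_type, links$gene_id)
  expect_false(any(vapply(by_gene, function(tt) {
    "promoter" %in% tt && any(tt != "promoter")
  }, logical(1))))
  # false links on null genes stay below 5% of null genes
  null_genes <- setdiff(pipe$de$gene_id, truth$gene_id)
  false_rate <- mean(null_genes %in% links$gene_id)
  expect_lte(false_rate, 0.05)
  # high-confidence links are a subset of all links
  expect_true(all(which(links$high_confidence) %in% seq_len(nrow(links))))
})
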