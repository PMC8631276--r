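# compact gene model: one + strand and one - strand gene
toy_model <- function() {
  new_gene_model(
    tibble::tibble(
      transcript_id = c("t1", "t2"),
      gene_id = c("g1", "g2"),
      gene_name = c("g1", "g2"),
      chrom = "chr1",
      strand = c("+", "-"),
      start = c(10000, 40000),
      end = c(12000, 42000)),
    tibble::tibble(
      transcript_id = c("t1", "t1", "t2", "t2"),
      start = c(10000, 11500, 40000, 41800),
      end = c(10200, 12000, 40200, 42000)))
}

test_that("location annotation follows the promoter window and priority rule", {
  gm <- toy_model()
  # + strand TSS 10000 -> promoter [8500, 10500)
  got <- annotate_location(
    tibble::tibble(chrom = "chr1", start = c(8600, 8499, 500, 10100),
                   end = c(8601, 8500, 501, 10101)), gm)
  expect_equal(got$location,
               c("promoter", "intergenic", "intergenic", "promoter"))
  # interval spanning promoter and first exon: both labels, promoter wins
  span <- annotate_location(
    tibble::tibble(chrom = "chr1", start = 9900, end = 10150), gm)
  expect_setequal(span$location_set[[1]], c("promoter", "exon"))
  expect_equal(span$location, "promoter")
  # intron between the two exons of t1
  intr <- annotate_location(
    tibble::tibble(chrom = "chr1", start = 10800, end = 10801), gm)
  expect_equal(intr$location, "intron")
})

test_that("minus-strand promoters mirror plus-strand promoters about the TSS", {
  gm <- toy_model()
  pr <- promoter_regions(gm)
  plus <- pr[pr$strand == "+", ]
  minus <- pr[pr$strand == "-", ]
  expect_equal(plus$tss - plus$start, 1500)
  expect_equal(plus$end - plus$tss, 500)
  expect_equal(minus$tss - minus$start, 500)
  expect_equal(minus$end - minus$tss, 1500)
  expect_equal(plus$end - plus$start, minus$end - minus$start)
})

test_that("unknown chromosomes warn and fall back to intergenic", {
  gm <- toy_model()
  expect_warning(
    got <- annotate_location(
      tibble::tibble(chrom = "chrZ", start = 1, end = 2), gm),
    "absent")
  expect_equal(got$location, "intergenic")
})

test_that("region enrichment: identity, concentration, and conservation", {
  gm <- toy_model()
  set.seed(21)
  all_cpgs <- tibble::tibble(chrom = "chr1",
                             pos = sort(sample.int(60000, 400)))
  # DML distributed identically to the background -> every fold is 1
  enr <- region_enrichment(all_cpgs, all_cpgs, gm)
  expect_true(all(abs(enr$fold[!is.na(enr$fold)] - 1) < 1e-12))
  # all DML in promoters -> fold = 1 / background fraction
  prom <- promoter_regions(gm)[1, ]
  in_prom <- all_cpgs[all_cpgs$pos >= prom$start & all_cpgs$pos < prom$end, ]
  enr2 <- region_enrichment(in_prom, all_cpgs, gm)
  bg_frac <- enr2$frac_background[enr2$location == "promoter"][1]
  expect_equal(enr2$fold[enr2$location == "promoter"], 1 / bg_frac)
  # folds weighted by background fractions average to 1
  dml <- all_cpgs[sample.int(400, 120), ]
  enr3 <- region_enrichment(dml, all_cpgs, gm)
  ok <- !is.na(enr3$fold)
  expect_equal(sum(enr3$fold[ok] * enr3$frac_background[ok]), 1)
})

test_that("unique location labels partition all CpGs", {
  co <- small_cohort()
  ann <- annotate_location(
    tibble::tibble(chrom = co$methylation$chrom,
                   start = co$methylation$pos,
                   end = co$methylation$pos + 1L),
    co$gene_model)
  expect_true(all(ann$location %in%
                    c("promoter", "utr5", "utr3", "exon", "intron",
                      "intergenic")))
  expect_equal(length(ann$location), nrow(co$methylation))
})

test_that("regulatory classification counts samples per class", {
  gm <- toy_model()
  dmrs <- tibble::tibble(dmr_id = c("d1", "d2"), chrom = "chr1",
                         start = c(20000, 30000), end = c(20500, 30500))
  states <- tibble::tibble(
    sample_id = c("hcc1", "enc1", "tis1", "tis2", "tis3"),
    is_tumor = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    chrom = "chr1",
    start = c(20100, 20200, 30100, 30100, 30100),
    end = c(20400, 20450, 30400, 30400, 30400),
    state = c("activeTSS", "promoterLikeCRE", "activeEnhancer",
              "activeEnhancer", "activeEnhancer"))
  calls <- classify_regulatory(dmrs, states, gm)
  # d1: activeTSS in one tumor sample + promoter-like cRE in one non-tumor
  expect_true(calls$promoter_like[1])
  expect_equal(calls$promoter_score_tumor[1], 1)
  expect_equal(calls$promoter_score_nontumor[1], 1)
  expect_equal(calls$activation_promoter[1], "unchanged")
  # d2: activeEnhancer in 3 of 5 samples, all non-tumor
  expect_true(calls$enhancer_like[2])
  expect_equal(calls$enhancer_score_tumor[2] +
                 calls$enhancer_score_nontumor[2], 3)
  expect_equal(calls$activation_enhancer[2], "repressed")
  # no overlap, no promoter location -> both flags false
  far <- classify_regulatory(
    tibble::tibble(dmr_id = "d3", chrom = "chr1",
                   start = 55000, end = 55100), states, gm)
  expect_false(far$promoter_like)
  expect_false(far$enhancer_like)
  expect_equal(far$promoter_score_tumor + far$promoter_score_nontumor, 0)
})

test_that("activity scores never exceed the per-class map counts", {
  co <- small_cohort()
  res <- classify_regulatory(
    tibble::tibble(dmr_id = co$truth$dmr_id, chrom = co$truth$chrom,
                   start = co$truth$start, end = co$truth$end),
    co$states, co$gene_model)
  n_tumor_maps <- length(unique(co$states$sample_id[co$states$is_tumor]))
  n_nt_maps <- length(unique(co$states$sample_id[!co$states$is_tumor]))
  expect_true(all(res$promoter_score_tumor <= n_tumor_maps))
  expect_true(all(res$enhancer_score_tumor <= n_tumor_maps))
  expect_true(all(res$promoter_score_nontumor <= n_nt_maps))
  expect_true(all(res$enhancer_score_nontumor <= n_nt_maps))
})

test_that("unknown state labels are rejected by name", {
  gm <- toy_model()
  dmrs <- tibble::tibble(dmr_id = "d1", chrom = "chr1",
                         start = 100, end = 200)
  states <- tibble::tibble(sample_id = "s", is_tumor = FALSE,
                           chrom = "chr1", start = 100, end = 200,
                           state = "superEnhancer")
  expect_error(classify_regulatory(dmrs, states, gm), "superEnhancer",
               class = "dmrlink_validation_error")
  expect_error(classify_regulatory(dmrs, states[0, ], gm),
               class = "dmrlink_validation_error")
})

test_that("activation calls follow the score comparison with ties unchanged", {
  expect_equal(call_activation(c(2, 0, 1), c(0, 3, 1)),
               c("activated", "repressed", "unchanged"))
})
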