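test_that("two-step merge reproduces the worked example", {
  dml <- tibble::tibble(chrom = "chr1", pos = c(100, 250, 600, 790))
  all <- tibble::tibble(chrom = "chr1",
                        pos = c(100, 180, 250, 430, 600, 790))
  dmrs <- merge_dml_to_dmrs(dml, all)
  expect_equal(nrow(dmrs), 2)
  expect_equal(dmrs$cpgs[[1]], c(100, 180, 250))
  expect_equal(dmrs$cpgs[[2]], c(600, 790))
  expect_equal(dmrs$start, c(100, 600))
  expect_equal(dmrs$end, c(251, 791))  # last member + 1, half-open
})

test_that("degenerate merges: single DML, empty set, min_cpgs filter", {
  one <- merge_dml_to_dmrs(tibble::tibble(chrom = "chr1", pos = 50),
                           tibble::tibble(chrom = "chr1", pos = 50))
  expect_equal(nrow(one), 1)
  expect_equal(one$n_cpgs, 1)
  empty <- merge_dml_to_dmrs(
    tibble::tibble(chrom = character(), pos = integer()),
    tibble::tibble(chrom = "chr1", pos = c(1, 2)))
  expect_equal(nrow(empty), 0)
  dropped <- merge_dml_to_dmrs(tibble::tibble(chrom = "chr1", pos = 50),
                               tibble::tibble(chrom = "chr1", pos = 50),
                               min_cpgs = 2)
  expect_equal(nrow(dropped), 0)
})

test_that("merge input validation", {
  expect_error(merge_dml_to_dmrs(
    tibble::tibble(chrom = "chr1", pos = c(200, 100)),
    tibble::tibble(chrom = "chr1", pos = c(100, 200))),
    class = "dmrlink_validation_error")
  expect_error(merge_dml_to_dmrs(
    tibble::tibble(chrom = "chr1", pos = 100),
    tibble::tibble(chrom = "chr1", pos = 200)),
    class = "dmrlink_validation_error")
})

test_that("merge agrees with a brute-force oracle on fuzzed inputs", {
  set.seed(99)
  for (i in seq_len(1000)) {
    all_pos <- sort(sample.int(3000, sample(3:25, 1)))
    dml_pos <- sort(sample(all_pos, sample(seq_len(length(all_pos)), 1)))
    got <- merge_dml_to_dmrs(
      tibble::tibble(chrom = "chrF", pos = dml_pos),
      tibble::tibble(chrom = "chrF", pos = all_pos))
    want <- oracle_merge(dml_pos, all_pos)
    expect_equal(length(got$cpgs), length(want))
    expect_equal(unname(got$cpgs), unname(want))
  }
})

test_that("every DML lands in exactly one DMR; non-DML members lie between DML", {
  set.seed(7)
  for (i in 1:50) {
    all_pos <- sort(sample.int(5000, 40))
    dml_pos <- sort(sample(all_pos, 15))
    dmrs <- merge_dml_to_dmrs(tibble::tibble(chrom = "c", pos = dml_pos),
                              tibble::tibble(chrom = "c", pos = all_pos))
    members <- unlist(dmrs$cpgs)
    expect_true(all(dml_pos %in% members))
    expect_equal(sum(members %in% dml_pos), length(dml_pos))
    extra <- setdiff(members, dml_pos)
    for (e in extra) {
      inside <- purrr::map_lgl(dmrs$cpgs, function(cp) {
        d <- intersect(cp, dml_pos)
        e > min(d) && e < max(d)
      })
      expect_true(any(inside))
    }
  }
})

test_that("DMR summaries compute group methylation, delta and direction", {
  # two CpGs, 4 patients: tumor mean 0.2, adjacent mean 0.5 -> hypo
  design <- tibble::tibble(
    sample_id = c(paste0("P", 1:4, "_T"), paste0("P", 1:4, "_A")),
    patient_id = rep(paste0("P", 1:4), 2),
    condition = rep(c("tumor", "adjacent"), each = 4),
    age = rep(c(50, 52, 60, 70), 2))
  meth <- dplyr::bind_cols(
    tibble::tibble(chrom = "chr1", pos = c(100, 160)),
    tibble::as_tibble(matrix(rep(c(rep(0.2, 4), rep(0.5, 4)), times = 2),
                             nrow = 2, byrow = TRUE,
                             dimnames = list(NULL, design$sample_id))))
  dmrs <- merge_dml_to_dmrs(tibble::tibble(chrom = "chr1", pos = c(100, 160)),
                            tibble::tibble(chrom = "chr1", pos = c(100, 160)))
  fake_dml <- structure(list(
    cpg = tibble::tibble(chrom = "chr1", pos = c(100, 160),
                         T = c(4, 4)),
    null_T = runif(500, 0, 8)), class = "dml_result")
  out <- summarize_dmrs(dmrs, fake_dml, meth, design, seed = 1)
  expect_equal(out$methy_tumor, 0.2)
  expect_equal(out$methy_adjacent, 0.5)
  expect_equal(out$delta, -0.3)
  expect_equal(out$direction, "hypo")
  expect_equal(out$mean_T, 4)  # all member T equal t -> mean_T = t
  expect_error(summarize_dmrs(dplyr::mutate(dmrs, chrom = "chrX"),
                              fake_dml, meth, design, seed = 1),
               class = "dmrlink_data_error")
})

test_that("effect-size filter is inclusive at the threshold", {
  dmrs <- tibble::tibble(dmr_id = c("a", "b", "c"),
                         delta = c(0.15, -0.149, 0.30))
  kept <- filter_effect_size(dmrs)
  expect_equal(kept$dmr_id, c("a", "c"))
  expect_equal(nrow(filter_effect_size(dmrs[0, ])), 0)
})
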