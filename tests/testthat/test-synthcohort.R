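test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_patients = 4), "n_patients",
               class = "dmrlink_configuration_error")
  expect_error(sim_config(delta_effect = 1.2), "delta_effect",
               class = "dmrlink_configuration_error")
  expect_error(sim_config(cpgs_per_dmr = 2), "cpgs_per_dmr",
               class = "dmrlink_configuration_error")
  expect_error(sim_config(n_cpgs = 10), "n_cpgs",
               class = "dmrlink_configuration_error")
})

test_that("cohort invariants: beta range, pairing, planted CpG counts", {
  co <- small_cohort()
  m <- as.matrix(co$methylation[, co$design$sample_id])
  expect_true(all(m > 0 & m < 1))
  expect_true(all(table(co$design$patient_id) == 2))
  expect_true(all(table(co$design$age_group) >= 4))
  for (i in seq_len(nrow(co$truth))) {
    n_in <- sum(co$methylation$pos >= co$truth$start[i] &
                  co$methylation$pos < co$truth$end[i])
    expect_gte(n_in, 3)
  }
  expect_true(all(co$truth$start >= min(co$methylation$pos)))
  expect_true(all(co$truth$end <= max(co$methylation$pos) + 1))
})

test_that("same config and seed give byte-identical fixture files", {
  co1 <- generate_cohort(sim_config(n_patients = 8, n_cpgs = 200,
                                    n_genes = 20, seed = 31))
  co2 <- generate_cohort(sim_config(n_patients = 8, n_cpgs = 200,
                                    n_genes = 20, seed = 31))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co1, d1)
  write_cohort(co2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("zero planted effect leaves no realized group difference", {
  cfg <- sim_config(n_patients = 30, n_cpgs = 300, n_genes = 20,
                    delta_effect = 0, seed = 13)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$truth), 10)  # manifest still present
  m <- as.matrix(co$methylation[, co$design$sample_id])
  t_col <- co$design$condition == "tumor"
  delta <- rowMeans(m[, t_col]) - rowMeans(m[, !t_col])
  expect_lt(abs(mean(delta)), 0.02)
})

test_that("planted link signs are realized in the expression data", {
  co <- study_cohort()
  m <- as.matrix(co$methylation[, co$design$sample_id])
  e <- as.matrix(co$expression[, co$design$sample_id])
  sign_ok <- vapply(seq_len(nrow(co$truth)), function(i) {
    tr <- co$truth[i, ]
    rows <- which(co$methylation$pos >= tr$start &
                    co$methylation$pos < tr$end)
    mv <- colMeans(m[rows, , drop = FALSE])
    gv <- e[match(tr$gene_id, co$expression$gene_id), ]
    rho <- suppressWarnings(cor(mv, gv, method = "spearman"))
    sign(rho) == tr$sign && abs(rho) >= 0.5
  }, logical(1))
  expect_gte(mean(sign_ok), 0.95)
})

test_that("fixture files round-trip losslessly through the readers", {
  co <- small_cohort()
  d <- withr::local_tempdir()
  write_cohort(co, d)
  co2 <- read_cohort(d)
  for (f in c("methylation", "expression", "erna", "clinical", "design")) {
    expect_equal(as.data.frame(co[[f]]), as.data.frame(co2[[f]]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_equal(as.data.frame(co$truth), as.data.frame(co2$truth),
               ignore_attr = TRUE)
  expect_equal(co$gene_model$transcripts$start,
               as.numeric(co2$gene_model$transcripts$start))
  expect_equal(co$gene_model$exons$end,
               as.numeric(co2$gene_model$exons$end))
})

test_that("GTF is written 1-based inclusive and BED 0-based half-open", {
  co <- small_cohort()
  d <- withr::local_tempdir()
  write_cohort(co, d)
  gtf <- read.delim(file.path(d, "gene_model.gtf"), header = FALSE)
  tx <- gtf[gtf$V3 == "transcript", ]
  i <- match(paste0(co$gene_model$transcripts$gene_id[1], "\""),
             sub('.*gene_id "', "", tx$V9))
  expect_equal(tx$V4[1], co$gene_model$transcripts$start[1] + 1)
  expect_equal(tx$V5[1], co$gene_model$transcripts$end[1])
  bed <- read.delim(file.path(d, "states.bed"), header = FALSE)
  expect_equal(bed$V2[1], co$states$start[1])
  expect_equal(bed$V3[1], co$states$end[1])
})

test_that("generate_cohort rejects a bare list config", {
  expect_error(generate_cohort(list(n_patients = 10)),
               class = "dmrlink_configuration_error")
})
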