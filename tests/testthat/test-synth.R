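test_that("one seed gives one bundle, bit-reproducibly", {
  b1 <- simulate_bundle(small_sim_config(seed = 7L))
  b2 <- simulate_bundle(small_sim_config(seed = 7L))
  expect_identical(b1$expression$values, b2$expression$values)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$peaks, b2$peaks)
  expect_identical(b1$tracks, b2$tracks)
  b3 <- simulate_bundle(small_sim_config(seed = 8L))
  expect_false(identical(b1$expression$values, b3$expression$values))
})

test_that("simulated bundles survive the strict format validators on disk", {
  b <- simulate_bundle(small_sim_config(seed = 3L))
  d <- withr::local_tempdir()
  write_bundle(b, d)
  back <- read_expression(file.path(d, "expression.tsv"),
                          file.path(d, "sample_sheet.tsv"))
  expect_equal(back$values, b$expression$values, tolerance = 1e-9)
  ann <- read_annotation(file.path(d, "annotation.bed"))
  expect_identical(nrow(ann), 400L)
  pk <- read_peaks(file.path(d, "peaks_H3K27ac_TzR.narrowPeak"), "H3K27ac")
  expect_identical(pk$start, b$peaks$H3K27ac$TzR$start)
  tr <- read_bedgraph(file.path(d, "track_H3K4me1_TzS.bedGraph"))
  expect_s3_class(tr, "SignalTrack")
})

test_that("planted sets are mutually disjoint and inconsistent counts error", {
  b <- simulate_bundle(small_sim_config(seed = 2L))
  tg <- b$truth$genes
  flags <- tg[, c("concordant", "invivo_only", "invitro_only", "shortterm",
                  "background_peaks")]
  expect_true(all(rowSums(flags) <= 1))
  expect_identical(sum(tg$concordant), 10L)
  expect_true(all(!is.na(tg$direction[tg$concordant])))
  expect_error(sim_config(n_genes = 50L, n_concordant = 30L,
                          n_invivo_only = 30L), "exceed")
})

test_that("baselines make the expression gate realistic, not the bottleneck", {
  b <- simulate_bundle(sim_config(seed = 1L))
  cfg <- de_config()
  tum <- subset_dataset(b$expression, "tumor")
  pass <- gate_expression(tum, cfg, "TzR", "TzS")
  expect_gt(mean(pass), 0.95)
  # lincRNA baselines sit lower than mRNA baselines so the 0.25 gate matters
  med_linc <- median(b$expression$values[b$expression$biotype == "lincRNA", 1])
  med_mrna <- median(b$expression$values[b$expression$biotype == "mRNA", 1])
  expect_lt(med_linc, med_mrna)
})

test_that("with no planted effects the DE calls stay at the noise floor", {
  cfg <- sim_config(n_concordant = 0L, n_invivo_only = 0L,
                    n_invitro_only = 0L, n_shortterm = 0L,
                    n_background_peak_genes = 30L, seed = 1L)
  b <- simulate_bundle(cfg)
  tum <- call_de(subset_dataset(b$expression, "tumor"), de_config(),
                 "TzR", "TzS")
  cl <- call_de(subset_dataset(b$expression, "cellline"),
                de_config(use_paired_test = TRUE), "TzR", "TzS")
  expect_lt(mean(tum$is_differential), 0.05)
  expect_lt(mean(cl$is_differential), 0.05)
})

test_that("shifted peaks sit only near planted concordant genes", {
  b <- simulate_bundle(small_sim_config(seed = 5L))
  tp <- b$truth$peaks
  tg <- b$truth$genes
  shifted <- tp[tp$shift > 1, ]
  expect_true(all(shifted$target_gene %in% tg$gene_id[tg$concordant]))
  unshifted_targets <- tp$target_gene[tp$shift == 1 & !is.na(tp$target_gene)]
  expect_true(all(unshifted_targets %in% tg$gene_id[tg$background_peaks]))
  # planted peaks stay inside the 150-kb window of their target's TSS
  ann <- b$annotation
  tss <- ann$tss[match(tp$target_gene, ann$gene_id)]
  mid <- floor((tp$start + tp$end) / 2)
  local <- !is.na(tp$target_gene)
  expect_true(all(abs(mid[local] - tss[local]) <= 150000))
})

test_that("truth_report computes confusion summaries that conserve counts", {
  tg <- data.frame(gene_id = sprintf("g%d", 1:20),
                   biotype = rep(c("mRNA", "lincRNA"), 10),
                   concordant = c(rep(TRUE, 5), rep(FALSE, 15)),
                   stringsAsFactors = FALSE)
  perfect <- signature_set(tg$gene_id[1:5], rep("up", 5), tg$biotype[1:5],
                           "integrated")
  r <- truth_report(tg, perfect)
  expect_equal(r$sensitivity[r$scope == "overall"], 1)
  expect_equal(r$fdr[r$scope == "overall"], 0)

  none <- signature_set(character(), character(), character(), "integrated")
  r0 <- truth_report(tg, none)
  expect_equal(r0$sensitivity[r0$scope == "overall"], 0)
  expect_equal(r0$specificity[r0$scope == "overall"], 1)

  set.seed(6)
  some <- signature_set(sample(tg$gene_id, 8), rep("up", 8), rep("mRNA", 8),
                        "integrated")
  rs <- truth_report(tg, some)
  ov <- rs[rs$scope == "overall", ]
  expect_identical(ov$tp + ov$fp + ov$fn + ov$tn, nrow(tg))
})
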