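test_that("track normalization divides by the length-weighted mean", {
  t1 <- signal_track(data.frame(chrom = "chr1", start = 0, end = 100, value = 4))
  expect_equal(normalize_track(t1)$value, 1)

  t2 <- signal_track(data.frame(chrom = "chr1", start = c(0, 20),
                                end = c(10, 30), value = c(1, 3)))
  expect_equal(normalize_track(t2)$value, c(0.5, 1.5))

  set.seed(2)
  s <- cumsum(sample(10:100, 30))
  tr <- signal_track(data.frame(chrom = "chr1", start = s, end = s + 9,
                                value = runif(30, 0.1, 5)))
  nt <- normalize_track(tr)
  w <- nt$end - nt$start
  expect_equal(sum(nt$value * w) / sum(w), 1, tolerance = 1e-12)

  zero <- signal_track(data.frame(chrom = "chr1", start = 0, end = 10, value = 0))
  expect_error(normalize_track(zero), "all-zero")
})

test_that("the significance filter is strict at the -log10 p threshold", {
  p <- rand_peaks(3)
  p$neg_log10_p <- c(12, 9, 8.9)
  cfg <- enhancer_config(p_threshold_neglog10 = 9)
  kept <- filter_peaks(p, cfg)
  expect_identical(kept$neg_log10_p, 12)
  expect_identical(nrow(filter_peaks(p[0, ], cfg)), 0L)
  all_pos <- filter_peaks(p, enhancer_config(p_threshold_neglog10 = 0))
  expect_identical(nrow(all_pos), 3L)
})

test_that("peak assignment uses the midpoint and an inclusive 150-kb window", {
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = c("chr1", "chr2"),
                    tss = c(500000L, 500000L), biotype = "mRNA",
                    strand = "+", stringsAsFactors = FALSE)
  pk <- data.frame(chrom = "chr1", start = c(640000L, 640002L, 100L),
                   end = c(660000L, 660002L, 200L),
                   name = c("in", "out", "far"), mark = "H3K27ac",
                   neg_log10_p = 20, signal_A = 1, signal_B = 1,
                   stringsAsFactors = FALSE)
  cfg <- enhancer_config()
  asg <- assign_peaks(pk, ann, c("gA", "gB"), cfg)
  # midpoint 650000 is exactly 150000 away: assigned; 650002 is not
  expect_identical(asg$name, "in")
  expect_identical(asg$gene_id, "gA")
  expect_identical(asg$tss_distance, 150000)
  # nothing on gB's chromosome
  expect_false("gB" %in% asg$gene_id)
  expect_error(assign_peaks(pk, ann, "missing_gene", cfg), "missing_gene")
})

test_that("peak assignment matches the brute-force all-pairs scan", {
  set.seed(19)
  cfg <- enhancer_config(window_bp = 120000)
  for (i in 1:25) {
    pk <- rand_peaks(sample(5:40, 1))
    ann <- rand_annotation(sample(2:10, 1))
    asg <- assign_peaks(pk, ann, ann$gene_id, cfg)
    oracle <- bf_assign(pk, ann, ann$gene_id, cfg$window_bp)
    got <- paste(asg$gene_id, asg$name)
    want <- paste(oracle$gene_id, pk$name[oracle$peak])
    expect_setequal(got, want)
  }
})

test_that("log2 ratios are antisymmetric in the two conditions", {
  cfg0 <- enhancer_config(signal_pseudocount = 0)
  expect_equal(peak_log2_ratio(4, 1, cfg0), 2)
  expect_equal(peak_log2_ratio(3, 3, cfg0), 0)
  set.seed(4)
  a <- runif(50); b <- runif(50)
  cfg <- enhancer_config()
  expect_equal(peak_log2_ratio(a, b, cfg), -peak_log2_ratio(b, a, cfg))
})

test_that("per-peak mean signal is length-weighted with uncovered bases at zero", {
  tr <- signal_track(data.frame(chrom = "chr1", start = c(0, 100),
                                end = c(50, 200), value = c(2, 4)))
  pk <- data.frame(chrom = c("chr1", "chr1", "chr9"), start = c(0L, 40L, 0L),
                   end = c(100L, 120L, 10L), name = c("p1", "p2", "p3"),
                   mark = "H3K4me1", neg_log10_p = 20,
                   signal_A = NA_real_, signal_B = NA_real_,
                   stringsAsFactors = FALSE)
  s <- peak_mean_signal(pk, tr)
  expect_equal(s[1], (50 * 2) / 100)            # half covered at 2
  expect_equal(s[2], (10 * 2 + 20 * 4) / 80)    # two partial overlaps
  expect_equal(s[3], 0)                         # no coverage on that chrom
})

test_that("per-gene summaries take the median of assigned same-mark peaks", {
  cfg <- enhancer_config(signal_pseudocount = 0)
  mk <- function(gene, mark, sa, sb) {
    data.frame(chrom = "chr1", start = seq_along(sa) * 100L,
               end = seq_along(sa) * 100L + 50L,
               name = sprintf("%s_%d", gene, seq_along(sa)), mark = mark,
               neg_log10_p = 20, signal_A = sa, signal_B = sb,
               gene_id = gene, tss_distance = 0,
               stringsAsFactors = FALSE)
  }
  asg <- rbind(mk("gA", "H3K27ac", c(2, 4, 8), c(1, 1, 1)),
               mk("gA", "H3K4me1", c(2, 8), c(1, 1)),
               mk("gB", "H3K27ac", 16, 1))
  res <- summarize_enhancers(asg, cfg)
  s <- res$summary
  expect_equal(s$median_log2_ratio[s$gene_id == "gA" & s$mark == "H3K27ac"], 2)
  expect_equal(s$median_log2_ratio[s$gene_id == "gA" & s$mark == "H3K4me1"], 2)
  expect_equal(s$median_log2_ratio[s$gene_id == "gB"], 4)
  expect_identical(s$n_peaks[s$gene_id == "gA" & s$mark == "H3K27ac"], 3L)
  # a gene with no peaks is omitted with a notice, never NaN
  expect_message(summarize_enhancers(asg, cfg, gene_ids = c("gA", "gB", "gC")),
                 "gC")
})

test_that("rescaling both condition tracks leaves all ratios unchanged", {
  set.seed(8)
  s <- cumsum(sample(200:1000, 40))
  mkt <- function(scale) {
    signal_track(data.frame(chrom = "chr1", start = s, end = s + 150,
                            value = runif(40, 0.5, 6) * scale))
  }
  trA <- mkt(1); trB <- mkt(1)
  pk <- rand_peaks(15, chroms = "chr1", max_pos = max(s))
  cfg <- enhancer_config()
  r1 <- peak_log2_ratio(peak_mean_signal(pk, normalize_track(trA)),
                        peak_mean_signal(pk, normalize_track(trB)), cfg)
  scale_both <- function(tr, f) { tr$value <- tr$value * f; tr }
  r2 <- peak_log2_ratio(
    peak_mean_signal(pk, normalize_track(scale_both(trA, 37))),
    peak_mean_signal(pk, normalize_track(scale_both(trB, 37))), cfg)
  expect_equal(r1, r2, tolerance = 1e-12)
})
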