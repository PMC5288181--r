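test_that("expression gate requires one uniformly expressed group", {
  cfg <- de_config()
  v <- rbind(g1 = c(1.2, 1.0, 3.0, 0.1, 0.2),
             g2 = c(0.9, 5.0, 5.0, 0.9, 5.0),
             g3 = c(0.1, 0.1, 0.1, 0.25, 0.25))
  colnames(v) <- sprintf("S%d", 1:5)
  mat <- tiny_matrix(v, c("mRNA", "mRNA", "lincRNA"),
                     c("TzS", "TzS", "TzS", "TzR", "TzR"))
  g <- gate_expression(mat, cfg, "TzR", "TzS")
  expect_true(g[["g1"]])    # all TzS >= 1.0
  expect_false(g[["g2"]])   # no group uniformly >= 1.0
  expect_true(g[["g3"]])    # lincRNA boundary: all TzR >= 0.25, inclusive
  expect_error(gate_expression(mat, cfg, "TzR", "mock"), "condition")
})

test_that("raising either gate threshold never adds a gated-in gene", {
  set.seed(11)
  v <- matrix(runif(300, 0, 3), 50, 6)
  rownames(v) <- sprintf("g%d", 1:50)
  mat <- tiny_matrix(v, sample(c("mRNA", "lincRNA"), 50, replace = TRUE),
                     rep(c("TzS", "TzR"), each = 3))
  base <- gate_expression(mat, de_config(), "TzR", "TzS")
  for (cfg in list(de_config(fpkm_min_mrna = 1.5),
                   de_config(fpkm_min_lincrna = 0.6),
                   de_config(fpkm_min_mrna = 2, fpkm_min_lincrna = 1))) {
    expect_true(all(gate_expression(mat, cfg, "TzR", "TzS") <= base))
  }
})

test_that("fold-change boundary at 2.0 is inclusive and tumor mode needs no p", {
  v <- rbind(gA = c(4, 4, 2, 2), gB = c(2, 2, 4, 4), gC = c(3, 3, 3, 3))
  colnames(v) <- sprintf("S%d", 1:4)
  mat <- tiny_matrix(v, rep("mRNA", 3), c("TzR", "TzR", "TzS", "TzS"))
  calls <- call_de(mat, de_config(pseudocount = 0), "TzR", "TzS")
  expect_equal(calls$fold_change, c(2, 0.5, 1))
  expect_identical(calls$direction, c("up", "down", "none"))
  expect_identical(calls$is_differential, c(TRUE, TRUE, FALSE))
  expect_true(all(is.na(calls$p_value)))
  # differential implies gated
  expect_true(all(!calls$is_differential | calls$passes_gate))
})

test_that("paired mode matches stats::t.test and gates on p < alpha", {
  set.seed(42)
  n_genes <- 60
  log2_num <- matrix(rnorm(n_genes * 4, 3, 1), n_genes)
  log2_den <- matrix(rnorm(n_genes * 4, 3, 1), n_genes)
  mat <- paired_matrix(log2_num, log2_den)
  calls <- call_de(mat, de_config(use_paired_test = TRUE, pseudocount = 0),
                   "TzR", "TzS")
  expected <- vapply(seq_len(n_genes), function(i) {
    stats::t.test(log2_num[i, ], log2_den[i, ], paired = TRUE)$p.value
  }, numeric(1))
  expect_equal(calls$p_value, expected, tolerance = 1e-12)
  # identical paired values: t = 0, p = 1, never differential
  same <- paired_matrix(matrix(c(2, 3, 4), 1), matrix(c(2, 3, 4), 1))
  c2 <- call_de(same, de_config(use_paired_test = TRUE, pseudocount = 0),
                "TzR", "TzS")
  expect_identical(c2$p_value, 1)
  expect_false(c2$is_differential)
  # closed-form check: paired log2 differences 1.0, 1.1, 0.9
  d3 <- paired_matrix(matrix(c(2.0, 3.1, 1.9), 1), matrix(c(1, 2, 1), 1))
  c3 <- call_de(d3, de_config(use_paired_test = TRUE, pseudocount = 0),
                "TzR", "TzS")
  expect_equal(c3$p_value,
               stats::t.test(c(1.0, 1.1, 0.9))$p.value, tolerance = 1e-10)
})

test_that("paired mode demands pairing metadata and at least two pairs", {
  v <- matrix(2, 2, 2, dimnames = list(c("g1", "g2"), c("A", "B")))
  sheet <- data.frame(sample = c("A", "B"), dataset = "cellline",
                      condition = c("TzR", "TzS"), pair_id = c("P1", "P1"))
  m1 <- expression_matrix(v, c("mRNA", "mRNA"), sheet)
  expect_error(call_de(m1, de_config(use_paired_test = TRUE), "TzR", "TzS"),
               "2 pairs")
  m2 <- tiny_matrix(matrix(2, 1, 4), "mRNA", c("TzR", "TzR", "TzS", "TzS"),
                    dataset = "cellline")
  expect_error(call_de(m2, de_config(use_paired_test = TRUE), "TzR", "TzS"),
               "pairing ids")
})

test_that("swapping conditions inverts fold changes, flips direction, keeps p", {
  set.seed(5)
  mat <- paired_matrix(matrix(rnorm(120, 4, 1.5), 30),
                       matrix(rnorm(120, 4, 1.5), 30))
  cfg <- de_config(use_paired_test = TRUE, pseudocount = 0)
  fwd <- call_de(mat, cfg, "TzR", "TzS")
  rev <- call_de(mat, cfg, "TzS", "TzR")
  expect_equal(rev$fold_change, 1 / fwd$fold_change, tolerance = 1e-12)
  expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)
  flipped <- c(up = "down", down = "up", none = "none")
  expect_identical(rev$direction, unname(flipped[fwd$direction]))
})

test_that("tightening the fold-change cutoff never adds a differential gene", {
  set.seed(9)
  mat <- tiny_matrix(matrix(2^rnorm(500 * 5, 3, 1.2), 500),
                     rep("mRNA", 500), c(rep("TzR", 2), rep("TzS", 3)))
  base <- call_de(mat, de_config(), "TzR", "TzS")$is_differential
  for (fc in c(2.5, 3, 4)) {
    tighter <- call_de(mat, de_config(fc_up = fc), "TzR", "TzS")$is_differential
    expect_true(all(tighter <= base))
  }
})

test_that("Benjamini-Hochberg option only ever shrinks the differential set", {
  set.seed(13)
  mat <- paired_matrix(matrix(rnorm(200 * 3, 4, 1.5), 200),
                       matrix(rnorm(200 * 3, 4, 1.5), 200))
  raw <- call_de(mat, de_config(use_paired_test = TRUE), "TzR", "TzS")
  adj <- call_de(mat, de_config(use_paired_test = TRUE,
                                adjust_method = "BH"), "TzR", "TzS")
  expect_true(all(adj$is_differential <= raw$is_differential))
  expect_equal(adj$p_value, raw$p_value)  # reported p stays unadjusted
})

test_that("heatmap rows are z-scored log2 expression with sd = 0 rows zeroed", {
  v <- rbind(g1 = c(1, 3, 7), g2 = c(5, 5, 5), g3 = c(15, 3, 0))
  colnames(v) <- c("A", "B", "C")
  mat <- tiny_matrix(v, rep("mRNA", 3), c("TzR", "TzS", "TzS"))
  calls <- data.frame(gene_id = c("g1", "g2", "g3"),
                      is_differential = TRUE)
  z <- heatmap_matrix(mat, calls, pseudocount = 1)
  expect_equal(z["g1", ], c(A = -1, B = 0, C = 1))
  expect_equal(unname(z["g2", ]), c(0, 0, 0))
  # every row has mean 0 and sd 1, or is all-zero
  for (i in seq_len(nrow(z))) {
    if (all(z[i, ] == 0)) succeed() else {
      expect_equal(mean(z[i, ]), 0, tolerance = 1e-12)
      expect_equal(sd(z[i, ]), 1, tolerance = 1e-12)
    }
  }
  expect_identical(rownames(z), c("g1", "g2", "g3"))
})

test_that("2^-ddCt relative quantification follows the closed form", {
  expect_identical(ddct_fold_change(25, 20, 25, 20), 1)
  expect_identical(ddct_fold_change(24, 20, 25, 20), 2)
  expect_identical(ddct_fold_change(26, 20, 25, 20), 0.5)
  expect_error(ddct_fold_change(NA, 20, 25, 20), "finite")
})
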