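# Fixtures built in code and independent brute-force oracles.

# small two-condition expression matrix; values indexed [gene, sample]
tiny_matrix <- function(values, biotype, condition, dataset = "tumor",
                        pair_id = NA_character_) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  }
  sheet <- data.frame(sample = colnames(values), dataset = dataset,
                      condition = condition, pair_id = pair_id,
                      stringsAsFactors = FALSE)
  expression_matrix(values, biotype, sheet)
}

# paired two-condition cell-line style matrix from log2 values (pseudocount
# 0 makes log2(FPKM) recover them exactly)
paired_matrix <- function(log2_num, log2_den, biotype = NULL) {
  log2_num <- as.matrix(log2_num); log2_den <- as.matrix(log2_den)
  n <- ncol(log2_num)
  v <- cbind(2^log2_num, 2^log2_den)
  colnames(v) <- c(sprintf("R%d", seq_len(n)), sprintf("S%d", seq_len(n)))
  if (is.null(rownames(v))) rownames(v) <- sprintf("g%d", seq_len(nrow(v)))
  if (is.null(biotype)) biotype <- rep("mRNA", nrow(v))
  sheet <- data.frame(sample = colnames(v), dataset = "cellline",
                      condition = rep(c("TzR", "TzS"), each = n),
                      pair_id = rep(sprintf("P%d", seq_len(n)), 2),
                      stringsAsFactors = FALSE)
  expression_matrix(v, biotype, sheet)
}

rand_signature <- function(n, universe, provenance = "tumor") {
  ids <- sample(sprintf("g%03d", seq_len(universe)), n)
  signature_set(ids, sample(c("up", "down"), n, replace = TRUE),
                sample(c("mRNA", "lincRNA"), n, replace = TRUE), provenance)
}

# exact-integer two-tailed hypergeometric enumerator: all binomial
# coefficients for a universe <= 40 are exact in doubles (< 2^53), so table
# probabilities are compared as exact integer numerators over a common
# denominator; the point-probability rule with the stated 1e-7 relative tie
# tolerance defines the two tails
bf_fisher_p <- function(universe_n, n_a, n_b, n_overlap) {
  k <- max(0, n_a + n_b - universe_n):min(n_a, n_b)
  num <- choose(n_a, k) * choose(universe_n - n_a, n_b - k)
  num_obs <- num[match(n_overlap, k)]
  sum(num[num <= num_obs * (1 + 1e-7)]) / choose(universe_n, n_b)
}

# all-pairs window assignment oracle
bf_assign <- function(peaks, annotation, gene_ids, window_bp) {
  out <- list()
  for (g in gene_ids) {
    a <- annotation[annotation$gene_id == g, ]
    for (i in seq_len(nrow(peaks))) {
      mid <- floor((peaks$start[i] + peaks$end[i]) / 2)
      if (peaks$chrom[i] == a$chrom && abs(mid - a$tss) <= window_bp) {
        out[[length(out) + 1L]] <- data.frame(gene_id = g, peak = i)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(), peak = integer()))
  }
  do.call(rbind, out)
}

rand_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6) {
  start <- sample.int(max_pos, n)
  width <- sample(50:5000, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + width, name = sprintf("p%d", seq_len(n)),
             mark = "H3K27ac", neg_log10_p = runif(n, 0, 30),
             signal_A = runif(n), signal_B = runif(n),
             stringsAsFactors = FALSE)
}

rand_annotation <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6) {
  data.frame(gene_id = sprintf("g%d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             tss = sample.int(max_pos, n),
             biotype = sample(c("mRNA", "lincRNA"), n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# compact simulation config for tests that only need structure, not power
small_sim_config <- function(seed = 1L, ...) {
  sim_config(n_genes = 400L, n_concordant = 10L, n_invivo_only = 15L,
             n_invitro_only = 15L, n_shortterm = 10L,
             n_background_peak_genes = 10L, n_background_peaks = 40L,
             n_lowsig_peaks = 40L, seed = seed, ...)
}
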