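# Synthetic-data generator with planted ground truth. Emulates the study
# design end to end: an 11-responder vs 2-non-responder tumor cohort
# (fold-change-only regime), paired sensitive/resistant cell-line
# replicates, a mock vs 48-h-treated short-term contrast, and per-mark
# (H3K4me1, H3K27ac) enhancer peak sets whose signal is shifted in the
# resistant condition near planted signature genes.

CHIP_MARKS <- c("H3K4me1", "H3K27ac")
CHIP_CONDITIONS <- c("TzR", "TzS")

#' Simulation configuration
#'
#' Defaults mirror the study conditions: 11 responders vs 2 non-responders,
#' 3 paired cell-line replicates, planted |log2FC| = 2 with lognormal noise
#' (sigma 0.2 on the log2 scale), and a 2x resistant-condition ChIP signal
#' shift at peaks near planted concordant genes.
#'
#' @param n_genes number of genes.
#' @param frac_lincrna fraction of genes labelled lincRNA; lincRNA baselines
#'   are drawn lower than mRNA baselines so the 0.25-FPKM gate is exercised.
#' @param n_responders,n_nonresponders tumor cohort sizes (TzS / TzR).
#' @param n_cellline_pairs paired sensitive/resistant cell-line replicates;
#'   also used for the mock vs treated short-term contrast.
#' @param n_concordant genes planted differential in the same direction in
#'   both the tumor and cell-line datasets (the recoverable signature).
#' @param n_invivo_only,n_invitro_only genes planted differential in only
#'   one dataset.
#' @param n_shortterm genes perturbed only in the 48-h-treated samples of
#'   the short-term dataset. All planted sets are mutually disjoint.
#' @param planted_log2fc magnitude of the planted log2 fold change.
#' @param baseline_log2_fpkm_mean,baseline_log2_fpkm_sd mRNA baseline
#'   log2 FPKM distribution.
#' @param lincrna_baseline_shift added to the baseline mean for lincRNAs
#'   (negative: lower expression).
#' @param noise_sigma per-sample lognormal noise, sd on the log2 scale.
#' @param pair_sd sd of the per-pair batch offset shared by both members of
#'   a cell-line pair (what the paired t-test gains over an unpaired one).
#' @param gene_spacing bp between consecutive TSSs on the single synthetic
#'   chromosome.
#' @param chrom synthetic chromosome name.
#' @param peaks_per_gene ChIP peaks planted per mark within +/-120 kb of
#'   each peak-bearing gene's TSS (inside the 150-kb window).
#' @param n_background_peak_genes unplanted genes that also receive local
#'   peaks (no signal shift) — the enhancer-analysis background.
#' @param n_background_peaks additional unshifted peaks per mark placed
#'   uniformly along the chromosome.
#' @param n_lowsig_peaks peaks per mark below the significance threshold
#'   (-log10 p < 9), exercising the peak filter.
#' @param peak_signal_shift multiplicative resistant-condition signal shift
#'   at peaks near planted concordant genes.
#' @param peak_noise_sigma sd (log2 scale) of the per-peak signal ratio
#'   noise; split evenly (sd / sqrt(2)) between the two condition tracks.
#' @param seed RNG seed; one seed, one bundle, bit-reproducibly.
#' @return A list of class \code{SimConfig}.
#' @export
sim_config <- function(n_genes = 2000L, frac_lincrna = 0.15,
                       n_responders = 11L, n_nonresponders = 2L,
                       n_cellline_pairs = 3L,
                       n_concordant = 30L, n_invivo_only = 40L,
                       n_invitro_only = 40L, n_shortterm = 30L,
                       planted_log2fc = 2,
                       baseline_log2_fpkm_mean = 5,
                       baseline_log2_fpkm_sd = 2,
                       lincrna_baseline_shift = -3,
                       noise_sigma = 0.2, pair_sd = 0.3,
                       gene_spacing = 160000L, chrom = "chrS",
                       peaks_per_gene = 6L, n_background_peak_genes = 30L,
                       n_background_peaks = 150L, n_lowsig_peaks = 150L,
                       peak_signal_shift = 2, peak_noise_sigma = 0.1,
                       seed = 1L) {
  cfg <- as.list(environment())
  n_planted <- n_concordant + n_invivo_only + n_invitro_only + n_shortterm
  if (n_planted + n_background_peak_genes > n_genes) {
    stop("planted set counts exceed the number of genes")
  }
  sep <- ceiling(800000 / gene_spacing)
  if (n_concordant + n_background_peak_genes > length(seq(1L, n_genes, by = sep))) {
    stop("too many peak-bearing genes for the chromosome layout")
  }
  stopifnot(noise_sigma > 0, n_cellline_pairs >= 2, n_responders >= 1,
            n_nonresponders >= 1, peaks_per_gene >= 1)
  cfg$chrom_length <- 200000 + as.numeric(n_genes) * gene_spacing
  structure(cfg, class = "SimConfig")
}

# log2-normal expression matrix for one dataset
sim_expr <- function(baseline, effect, active, sample_names, col_offsets,
                     sigma) {
  n <- length(baseline)
  x <- matrix(baseline, n, length(sample_names)) +
    outer(effect, active) +
    matrix(col_offsets, n, length(sample_names), byrow = TRUE) +
    matrix(stats::rnorm(n * length(sample_names), 0, sigma), n)
  colnames(x) <- sample_names
  2^x
}

#' Simulate a complete input bundle with planted truth
#'
#' Generates, from one seed, every input the pipeline consumes: a combined
#' expression matrix over the three datasets (tumor, cellline, shortterm)
#' with sample sheet, a TSS annotation, per-mark per-condition narrowPeak
#' sets and bedGraph signal tracks, and a ground-truth table of the planted
#' gene sets and peak shifts.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return A list of class \code{SimBundle}: \code{expression}
#'   (ExpressionMatrix, all three datasets), \code{annotation},
#'   \code{peaks[[mark]][[condition]]}, \code{tracks[[mark]][[condition]]},
#'   \code{truth} (list with \code{genes} and \code{peaks} data.frames) and
#'   \code{config}.
#' @export
simulate_bundle <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n))

  biotype <- rep("mRNA", n)
  n_linc <- round(cfg$frac_lincrna * n)
  if (n_linc > 0) biotype[sample.int(n, n_linc)] <- "lincRNA"

  # peak-bearing genes sit on a sparse grid (>= 800 kb apart) so 150-kb
  # windows never share local peaks
  sep <- ceiling(800000 / cfg$gene_spacing)
  candidates <- seq(1L, n, by = sep)
  pick <- sample(candidates, cfg$n_concordant + cfg$n_background_peak_genes)
  idx_conc <- sort(pick[seq_len(cfg$n_concordant)])
  idx_bgpk <- sort(pick[cfg$n_concordant + seq_len(cfg$n_background_peak_genes)])

  rest <- setdiff(seq_len(n), c(idx_conc, idx_bgpk))
  others <- sample(rest, cfg$n_invivo_only + cfg$n_invitro_only + cfg$n_shortterm)
  idx_vivo <- sort(others[seq_len(cfg$n_invivo_only)])
  idx_vitro <- sort(others[cfg$n_invivo_only + seq_len(cfg$n_invitro_only)])
  idx_st <- sort(others[cfg$n_invivo_only + cfg$n_invitro_only +
                          seq_len(cfg$n_shortterm)])

  direction <- rep(NA_character_, n)
  planted <- c(idx_conc, idx_vivo, idx_vitro, idx_st)
  direction[planted] <- sample(c("up", "down"), length(planted), replace = TRUE)
  eff <- ifelse(is.na(direction), 0,
                ifelse(direction == "up", cfg$planted_log2fc,
                       -cfg$planted_log2fc))

  baseline <- stats::rnorm(n, cfg$baseline_log2_fpkm_mean +
                             cfg$lincrna_baseline_shift * (biotype == "lincRNA"),
                           cfg$baseline_log2_fpkm_sd)

  # tumor cohort: fold-change-only regime, no pairing
  tum_names <- c(sprintf("TUM_TzS_%02d", seq_len(cfg$n_responders)),
                 sprintf("TUM_TzR_%02d", seq_len(cfg$n_nonresponders)))
  tum_cond <- c(rep("TzS", cfg$n_responders), rep("TzR", cfg$n_nonresponders))
  eff_tumor <- eff * (seq_len(n) %in% c(idx_conc, idx_vivo))
  tum_vals <- sim_expr(baseline, eff_tumor, as.numeric(tum_cond == "TzR"),
                       tum_names, rep(0, length(tum_names)), cfg$noise_sigma)

  # isogenic cell-line pairs with a shared per-pair batch offset
  np <- cfg$n_cellline_pairs
  cl_names <- c(sprintf("CL_TzS_P%d", seq_len(np)),
                sprintf("CL_TzR_P%d", seq_len(np)))
  cl_cond <- rep(c("TzS", "TzR"), each = np)
  cl_pair <- rep(sprintf("P%d", seq_len(np)), 2)
  cl_batch <- stats::rnorm(np, 0, cfg$pair_sd)[rep(seq_len(np), 2)]
  eff_cl <- eff * (seq_len(n) %in% c(idx_conc, idx_vitro))
  cl_vals <- sim_expr(baseline, eff_cl, as.numeric(cl_cond == "TzR"),
                      cl_names, cl_batch, cfg$noise_sigma)

  # short-term contrast: sensitive cells, mock vs 48-h trastuzumab;
  # short-term genes are perturbed only in the treated samples
  st_names <- c(sprintf("ST_mock_Q%d", seq_len(np)),
                sprintf("ST_treated_Q%d", seq_len(np)))
  st_cond <- rep(c("mock", "treated"), each = np)
  st_pair <- rep(sprintf("Q%d", seq_len(np)), 2)
  st_batch <- stats::rnorm(np, 0, cfg$pair_sd)[rep(seq_len(np), 2)]
  eff_st <- eff * (seq_len(n) %in% idx_st)
  st_vals <- sim_expr(baseline, eff_st, as.numeric(st_cond == "treated"),
                      st_names, st_batch, cfg$noise_sigma)

  values <- cbind(tum_vals, cl_vals, st_vals)
  rownames(values) <- gene_ids
  sheet <- data.frame(
    sample = c(tum_names, cl_names, st_names),
    dataset = c(rep("tumor", length(tum_names)),
                rep("cellline", length(cl_names)),
                rep("shortterm", length(st_names))),
    condition = c(tum_cond, cl_cond, st_cond),
    pair_id = c(rep(NA_character_, length(tum_names)), cl_pair, st_pair),
    stringsAsFactors = FALSE)
  expr <- expression_matrix(values, biotype, sheet)

  tss <- 100000 + (seq_len(n) - 1) * as.numeric(cfg$gene_spacing)
  annotation <- data.frame(gene_id = gene_ids, chrom = cfg$chrom, tss = tss,
                           biotype = biotype,
                           strand = sample(c("+", "-"), n, replace = TRUE),
                           stringsAsFactors = FALSE)

  peak_gene_idx <- c(idx_conc, idx_bgpk)
  peaks <- list(); tracks <- list(); truth_peaks <- list()
  for (mark in CHIP_MARKS) {
    pg <- sim_mark_peaks(cfg, mark, peak_gene_idx, gene_ids, tss, idx_conc)
    peaks[[mark]] <- pg$peak_files
    tracks[[mark]] <- pg$tracks
    truth_peaks[[mark]] <- pg$truth
  }
  truth_peaks <- do.call(rbind, truth_peaks)
  rownames(truth_peaks) <- NULL

  truth_genes <- data.frame(
    gene_id = gene_ids, biotype = biotype,
    concordant = seq_len(n) %in% idx_conc,
    invivo_only = seq_len(n) %in% idx_vivo,
    invitro_only = seq_len(n) %in% idx_vitro,
    shortterm = seq_len(n) %in% idx_st,
    background_peaks = seq_len(n) %in% idx_bgpk,
    direction = direction, stringsAsFactors = FALSE)

  structure(list(expression = expr, annotation = annotation, peaks = peaks,
                 tracks = tracks,
                 truth = list(genes = truth_genes, peaks = truth_peaks),
                 config = cfg),
            class = "SimBundle")
}

# peaks and tracks for one histone mark
sim_mark_peaks <- function(cfg, mark, peak_gene_idx, gene_ids, tss, idx_conc) {
  k <- cfg$peaks_per_gene
  slot_w <- 240000 / k
  glist <- lapply(peak_gene_idx, function(g) {
    mids <- tss[g] - 120000 + (seq_len(k) - 1) * slot_w +
      round(stats::runif(k, 0.125 * slot_w, 0.875 * slot_w))
    half <- round(stats::runif(k, 300, 700))
    data.frame(start = mids - half, end = mids + half,
               target_gene = gene_ids[g],
               shift = if (g %in% idx_conc) cfg$peak_signal_shift else 1,
               stringsAsFactors = FALSE)
  })
  real <- do.call(rbind, glist)

  # unshifted background peaks, rejection-sampled to avoid any overlap
  bg <- matrix(0, 0, 2)
  for (i in seq_len(cfg$n_background_peaks)) {
    for (try in 1:100) {
      half <- round(stats::runif(1, 300, 700))
      mid <- round(stats::runif(1, half, cfg$chrom_length - half))
      s <- mid - half; e <- mid + half
      clash <- any(real$start < e & real$end > s) ||
        (nrow(bg) > 0 && any(bg[, 1] < e & bg[, 2] > s))
      if (!clash) { bg <- rbind(bg, c(s, e)); break }
    }
  }
  if (nrow(bg) > 0) {
    real <- rbind(real, data.frame(start = bg[, 1], end = bg[, 2],
                                   target_gene = NA_character_, shift = 1,
                                   stringsAsFactors = FALSE))
  }
  real <- real[order(real$start), , drop = FALSE]
  rownames(real) <- NULL
  nreal <- nrow(real)
  name <- sprintf("%s_peak_%04d", mark, seq_len(nreal))
  height <- stats::runif(nreal, 5, 15)

  # below-threshold peaks exercising the significance filter; kept out of
  # the tracks (they are discarded upstream of any signal computation)
  ls_half <- round(stats::runif(cfg$n_lowsig_peaks, 300, 700))
  ls_mid <- round(stats::runif(cfg$n_lowsig_peaks, ls_half,
                               cfg$chrom_length - ls_half))
  lowsig <- data.frame(start = ls_mid - ls_half, end = ls_mid + ls_half,
                       name = sprintf("%s_lowsig_%04d", mark,
                                      seq_len(cfg$n_lowsig_peaks)),
                       stringsAsFactors = FALSE)

  peak_files <- list(); trks <- list()
  tile_start <- seq(0, cfg$chrom_length - 5000, by = 20000)
  for (cond in CHIP_CONDITIONS) {
    pf <- data.frame(chrom = cfg$chrom,
                     start = as.integer(c(real$start, lowsig$start)),
                     end = as.integer(c(real$end, lowsig$end)),
                     name = c(name, lowsig$name), mark = mark,
                     neg_log10_p = c(stats::runif(nreal, 12, 60),
                                     stats::runif(cfg$n_lowsig_peaks, 1, 8.5)),
                     signal_A = NA_real_, signal_B = NA_real_,
                     stringsAsFactors = FALSE)
    pf <- pf[order(pf$start, pf$end), , drop = FALSE]
    rownames(pf) <- NULL
    peak_files[[cond]] <- pf

    shift <- if (cond == "TzR") real$shift else rep(1, nreal)
    value <- height * shift *
      2^stats::rnorm(nreal, 0, cfg$peak_noise_sigma / sqrt(2))
    keep_tile <- !vapply(tile_start, function(s) {
      any(real$start < s + 5000 & real$end > s)
    }, logical(1))
    ts <- tile_start[keep_tile]
    tiles <- data.frame(chrom = cfg$chrom, start = ts, end = ts + 5000,
                        value = 2^stats::rnorm(length(ts), 0, 0.05),
                        stringsAsFactors = FALSE)
    pk <- data.frame(chrom = cfg$chrom, start = real$start, end = real$end,
                     value = value, stringsAsFactors = FALSE)
    trks[[cond]] <- signal_track(rbind(tiles, pk))
  }
  truth <- data.frame(mark = mark, chrom = cfg$chrom,
                      start = as.integer(real$start),
                      end = as.integer(real$end), name = name,
                      target_gene = real$target_gene, shift = real$shift,
                      stringsAsFactors = FALSE)
  list(peak_files = peak_files, tracks = trks, truth = truth)
}

#' Write a simulated bundle to a directory
#'
#' Writes every component in the exact text formats the readers consume:
#' \code{expression.tsv} + \code{sample_sheet.tsv}, \code{annotation.bed},
#' \code{peaks_<mark>_<condition>.narrowPeak},
#' \code{track_<mark>_<condition>.bedGraph}, \code{truth_genes.tsv} and
#' \code{truth_peaks.tsv}. Identical seeds give byte-identical directories.
#'
#' @param bundle a \code{\link{simulate_bundle}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "SimBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(bundle$expression, file.path(dir, "expression.tsv"),
                   file.path(dir, "sample_sheet.tsv"))
  write_annotation(bundle$annotation, file.path(dir, "annotation.bed"))
  for (mark in names(bundle$peaks)) {
    for (cond in names(bundle$peaks[[mark]])) {
      write_peaks(bundle$peaks[[mark]][[cond]],
                  file.path(dir, sprintf("peaks_%s_%s.narrowPeak", mark, cond)))
      write_bedgraph(bundle$tracks[[mark]][[cond]],
                     file.path(dir, sprintf("track_%s_%s.bedGraph", mark, cond)))
    }
  }
  write_tsv(bundle$truth$genes, file.path(dir, "truth_genes.tsv"))
  write_tsv(bundle$truth$peaks, file.path(dir, "truth_peaks.tsv"))
  invisible(dir)
}

#' Confusion summary of a called signature against planted truth
#'
#' Compares the gene ids of a called signature with the planted concordant
#' set, overall and per biotype.
#'
#' @param truth_genes the \code{truth$genes} data.frame of a bundle (or a
#'   data.frame with columns \code{gene_id, biotype, concordant}).
#' @param called a \code{\link{signature_set}}.
#' @return data.frame with rows \code{overall}, \code{mRNA}, \code{lincRNA}
#'   and columns \code{tp, fp, fn, tn, sensitivity, specificity, fdr}.
#' @export
truth_report <- function(truth_genes, called) {
  one <- function(tg) {
    pos <- tg$gene_id[tg$concordant]
    neg <- tg$gene_id[!tg$concordant]
    hit <- intersect(called$gene_id, tg$gene_id)
    tp <- length(intersect(hit, pos)); fp <- length(intersect(hit, neg))
    fn <- length(pos) - tp; tn <- length(neg) - fp
    data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
               sensitivity = if (length(pos)) tp / length(pos) else NA_real_,
               specificity = if (length(neg)) tn / length(neg) else NA_real_,
               fdr = if (tp + fp > 0) fp / (tp + fp) else 0)
  }
  out <- rbind(one(truth_genes),
               one(truth_genes[truth_genes$biotype == "mRNA", ]),
               one(truth_genes[truth_genes$biotype == "lincRNA", ]))
  cbind(data.frame(scope = c("overall", "mRNA", "lincRNA"),
                   stringsAsFactors = FALSE), out)
}
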