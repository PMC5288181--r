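# Expression gating and differential-expression calling in the study's two
# modes: tumor cohorts (fold-change-only, the 11-responder vs 2-non-responder
# regime) and isogenic cell lines (fold change + paired t-test on log2 FPKM).

#' Differential-expression configuration
#'
#' @param fpkm_min_mrna expression gate for mRNAs: a gene is "expressed" in a
#'   condition when every sample of that condition has FPKM at or above this
#'   value. Default 1.0.
#' @param fpkm_min_lincrna the same gate for lincRNAs, which are expressed at
#'   lower absolute levels. Default 0.25.
#' @param fc_up fold-change cutoff for up-calls (inclusive). Default 2.0.
#' @param fc_down fold-change cutoff for down-calls (inclusive). Defaults to
#'   \code{1 / fc_up}.
#' @param alpha p-value cutoff for the paired-test mode (strict \code{<}).
#'   Default 0.05.
#' @param use_paired_test compute a two-sided paired t-test on
#'   \code{log2(FPKM + pseudocount)} and require \code{p < alpha} in addition
#'   to the fold-change rule. Requires pairing ids.
#' @param pseudocount small value added to condition means before the ratio
#'   and inside every log2 transform, guarding one-sided zeros. Default 0.01;
#'   zero is accepted for exact-arithmetic checks.
#' @param adjust_method multiple-testing correction applied to the paired-test
#'   p-values before comparison with \code{alpha}; \code{"none"} (the
#'   per-gene rule, default) or any \code{\link[stats]{p.adjust}} method such
#'   as \code{"BH"}.
#' @return A list of class \code{DEConfig}.
#' @export
de_config <- function(fpkm_min_mrna = 1.0, fpkm_min_lincrna = 0.25,
                      fc_up = 2.0, fc_down = 1 / fc_up, alpha = 0.05,
                      use_paired_test = FALSE, pseudocount = 0.01,
                      adjust_method = "none") {
  stopifnot(fpkm_min_mrna >= 0, fpkm_min_lincrna >= 0,
            fc_up > 1, fc_down > 0, fc_down < 1,
            alpha > 0, alpha < 1, pseudocount >= 0)
  structure(list(fpkm_min_mrna = fpkm_min_mrna,
                 fpkm_min_lincrna = fpkm_min_lincrna,
                 fc_up = fc_up, fc_down = fc_down, alpha = alpha,
                 use_paired_test = use_paired_test,
                 pseudocount = pseudocount,
                 adjust_method = adjust_method),
            class = "DEConfig")
}

biotype_threshold <- function(biotype, cfg) {
  ifelse(biotype == "lincRNA", cfg$fpkm_min_lincrna, cfg$fpkm_min_mrna)
}

condition_columns <- function(mat, condition) {
  sel <- mat$samples$sample[mat$samples$condition == condition]
  if (length(sel) == 0L) stop("unknown or empty condition label: ", condition)
  sel
}

#' Biotype-aware expression gate
#'
#' A gene passes when every sample of condition A is at or above its biotype
#' threshold, or every sample of condition B is — i.e. the gene is uniformly
#' expressed in at least one of the two groups being compared.
#'
#' @param mat an \code{\link{expression_matrix}}.
#' @param cfg a \code{\link{de_config}}.
#' @param condition_a,condition_b the two condition labels.
#' @return Named logical vector over genes.
#' @export
gate_expression <- function(mat, cfg, condition_a, condition_b) {
  stopifnot(inherits(mat, "ExpressionMatrix"), inherits(cfg, "DEConfig"))
  a <- mat$values[, condition_columns(mat, condition_a), drop = FALSE]
  b <- mat$values[, condition_columns(mat, condition_b), drop = FALSE]
  thr <- biotype_threshold(mat$biotype, cfg)
  pass <- (rowSums(a >= thr) == ncol(a)) | (rowSums(b >= thr) == ncol(b))
  names(pass) <- rownames(mat$values)
  pass
}

paired_t_pvalues <- function(log2_num, log2_den) {
  # closed-form two-sided paired t on the per-pair log2 differences; the
  # all-equal-pairs degenerate case is defined as t = 0, p = 1
  d <- log2_num - log2_den
  n <- ncol(d)
  if (n < 2L) stop("paired t-test needs at least 2 pairs")
  md <- rowMeans(d)
  sdd <- sqrt(rowSums((d - md)^2) / (n - 1L))
  p <- rep(NA_real_, nrow(d))
  zero_sd <- sdd == 0
  p[zero_sd & md == 0] <- 1
  p[zero_sd & md != 0] <- 0
  ok <- !zero_sd
  tstat <- md[ok] / (sdd[ok] / sqrt(n))
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 1L)
  p
}

#' Call differentially expressed genes between two conditions
#'
#' Condition means are computed on the FPKM scale and the fold change is
#' \code{(mean_num + pc) / (mean_den + pc)}. A gene is differential when it
#' passes the expression gate and the fold change is at or beyond
#' \code{fc_up} / \code{fc_down}; in paired mode a two-sided paired t-test on
#' \code{log2(FPKM + pc)} must additionally give \code{p < alpha}.
#'
#' @param mat an \code{\link{expression_matrix}} (typically one dataset, see
#'   \code{\link{subset_dataset}}).
#' @param cfg a \code{\link{de_config}}.
#' @param numerator_condition condition in the numerator of the fold change
#'   (the resistant condition in the study design).
#' @param denominator_condition condition in the denominator.
#' @return data.frame with one row per gene: \code{gene_id, biotype,
#'   passes_gate, mean_num, mean_den, fold_change, log2fc, p_value,
#'   is_differential, direction}.
#' @export
call_de <- function(mat, cfg, numerator_condition, denominator_condition) {
  stopifnot(inherits(mat, "ExpressionMatrix"), inherits(cfg, "DEConfig"))
  num_cols <- condition_columns(mat, numerator_condition)
  den_cols <- condition_columns(mat, denominator_condition)
  v <- mat$values
  pc <- cfg$pseudocount
  mean_num <- rowMeans(v[, num_cols, drop = FALSE])
  mean_den <- rowMeans(v[, den_cols, drop = FALSE])
  fc <- (mean_num + pc) / (mean_den + pc)
  gate <- gate_expression(mat, cfg, numerator_condition, denominator_condition)

  p <- rep(NA_real_, nrow(v))
  if (isTRUE(cfg$use_paired_test)) {
    sh <- mat$samples
    pairs_num <- sh[sh$condition == numerator_condition, , drop = FALSE]
    pairs_den <- sh[sh$condition == denominator_condition, , drop = FALSE]
    if (anyNA(pairs_num$pair_id) || anyNA(pairs_den$pair_id)) {
      stop("paired test requested but pairing ids are missing")
    }
    pairs_den <- pairs_den[match(pairs_num$pair_id, pairs_den$pair_id), ,
                           drop = FALSE]
    if (anyNA(pairs_den$sample)) stop("pairing ids do not match 1:1 across conditions")
    if (nrow(pairs_num) < 2L) stop("paired test needs at least 2 pairs")
    p <- paired_t_pvalues(log2(v[, pairs_num$sample, drop = FALSE] + pc),
                          log2(v[, pairs_den$sample, drop = FALSE] + pc))
  }
  p_crit <- p
  if (isTRUE(cfg$use_paired_test) && cfg$adjust_method != "none") {
    p_crit <- stats::p.adjust(p, method = cfg$adjust_method)
  }

  fc_hit <- fc >= cfg$fc_up | fc <= cfg$fc_down
  de <- gate & fc_hit
  if (isTRUE(cfg$use_paired_test)) de <- de & p_crit < cfg$alpha
  direction <- ifelse(!de, "none", ifelse(fc >= cfg$fc_up, "up", "down"))

  data.frame(gene_id = rownames(v), biotype = unname(mat$biotype),
             passes_gate = unname(gate), mean_num = unname(mean_num),
             mean_den = unname(mean_den), fold_change = unname(fc),
             log2fc = unname(log2(fc)), p_value = unname(p),
             is_differential = unname(de), direction = direction,
             stringsAsFactors = FALSE)
}

#' Row-standardized log-expression matrix for heatmap display
#'
#' Restricts to differential genes and z-scores each gene's
#' \code{log2(FPKM + pc)} profile across samples (sample standard deviation,
#' n - 1 denominator). Constant rows map to all zeros.
#'
#' @param mat an \code{\link{expression_matrix}}.
#' @param de_calls result of \code{\link{call_de}} on \code{mat}.
#' @param pseudocount added inside the log2; default 0.01.
#' @return Numeric matrix, differential genes x samples.
#' @export
heatmap_matrix <- function(mat, de_calls, pseudocount = 0.01) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  keep <- de_calls$gene_id[de_calls$is_differential]
  x <- log2(mat$values[keep, , drop = FALSE] + pseudocount)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  z <- (x - mu) / sdv
  z[sdv == 0, ] <- 0
  z
}

#' Relative expression by the 2^-ddCt method
#'
#' qPCR relative quantification against a reference gene (GAPDH in the
#' study): \code{ddCt = (Ct_target,test - Ct_ref,test) -
#' (Ct_target,ctrl - Ct_ref,ctrl)} and the fold change is \code{2^-ddCt}.
#'
#' @param ct_target_test,ct_ref_test Ct of target and reference gene in the
#'   test sample.
#' @param ct_target_ctrl,ct_ref_ctrl Ct of target and reference gene in the
#'   control sample.
#' @return Relative expression (fold change over control).
#' @export
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(is.finite(ct_target_test), is.finite(ct_ref_test),
            is.finite(ct_target_ctrl), is.finite(ct_ref_ctrl))
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Write a DE-call table to TSV
#'
#' @param de_calls result of \code{\link{call_de}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_de_calls <- function(de_calls, path) {
  out <- de_calls[, c("gene_id", "biotype", "mean_num", "mean_den",
                      "fold_change", "log2fc", "p_value", "is_differential",
                      "direction")]
  names(out)[3:4] <- c("mean_a", "mean_b")
  write_tsv(out, path)
  invisible(path)
}
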