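# Enhancer-level ChIP analysis: keep high-confidence peaks, normalize the
# condition signal tracks to whole-track mean 1, assign peaks to genes
# within a fixed window of the TSS, and summarize per-gene log2 condition
# ratios by their median.

#' Enhancer analysis configuration
#'
#' @param p_threshold_neglog10 minimum -log10(p): peaks are kept when their
#'   enrichment score is strictly above this, i.e. p strictly below the
#'   corresponding cutoff. Default 9 (p < 1e-9).
#' @param window_bp maximum TSS-to-peak-midpoint distance in bp (inclusive).
#'   Default 150000.
#' @param signal_pseudocount added to both condition signals before the
#'   ratio, guarding zero-coverage peaks. Default 0.5.
#' @return A list of class \code{EnhancerConfig}.
#' @export
enhancer_config <- function(p_threshold_neglog10 = 9, window_bp = 150000L,
                            signal_pseudocount = 0.5) {
  stopifnot(window_bp > 0, signal_pseudocount >= 0, p_threshold_neglog10 >= 0)
  structure(list(p_threshold_neglog10 = p_threshold_neglog10,
                 window_bp = as.numeric(window_bp),
                 signal_pseudocount = signal_pseudocount),
            class = "EnhancerConfig")
}

#' Normalize a signal track to length-weighted mean 1
#'
#' Divides every interval value by the length-weighted mean signal over all
#' covered bases, mirroring normalization of coverage tracks to the mean
#' whole-genome signal.
#'
#' @param track a \code{\link{signal_track}}.
#' @return The normalized \code{SignalTrack}.
#' @export
normalize_track <- function(track) {
  stopifnot(inherits(track, "SignalTrack"))
  if (nrow(track) == 0L) stop("cannot normalize an empty track")
  w <- track$end - track$start
  m <- sum(track$value * w) / sum(w)
  if (m == 0) stop("cannot normalize an all-zero track")
  track$value <- track$value / m
  track
}

#' Filter peaks by enrichment significance
#'
#' Keeps peaks whose \code{neg_log10_p} is strictly greater than the
#' configured threshold (p strictly below the cutoff).
#'
#' @param peaks a peak data.frame (see \code{\link{read_peaks}}).
#' @param cfg an \code{\link{enhancer_config}}.
#' @return The filtered peak data.frame.
#' @export
filter_peaks <- function(peaks, cfg) {
  out <- peaks[peaks$neg_log10_p > cfg$p_threshold_neglog10, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length-weighted mean track signal over each peak interval
#'
#' Bases of the peak not covered by the track contribute 0; the denominator
#' is the full peak length.
#'
#' @param peaks a peak data.frame.
#' @param track a \code{\link{signal_track}} (normalize first if comparing
#'   conditions).
#' @return Numeric vector of per-peak mean signals.
#' @export
peak_mean_signal <- function(peaks, track) {
  out <- numeric(nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == chr)
    tr <- track[track$chrom == chr, , drop = FALSE]
    if (nrow(tr) == 0L) next
    for (i in pi) {
      s <- peaks$start[i]; e <- peaks$end[i]
      j <- which(tr$end > s & tr$start < e)
      if (length(j) == 0L) next
      ov <- pmin(tr$end[j], e) - pmax(tr$start[j], s)
      out[i] <- sum(tr$value[j] * ov) / (e - s)
    }
  }
  out
}

#' Attach per-condition signals to peaks from two tracks
#'
#' @param peaks a peak data.frame.
#' @param track_resistant,track_sensitive \code{\link{signal_track}} objects
#'   for the resistant (A) and sensitive (B) conditions.
#' @param normalize normalize each track to length-weighted mean 1 first
#'   (default TRUE).
#' @return \code{peaks} with \code{signal_A} and \code{signal_B} filled.
#' @export
attach_peak_signals <- function(peaks, track_resistant, track_sensitive,
                                normalize = TRUE) {
  if (normalize) {
    track_resistant <- normalize_track(track_resistant)
    track_sensitive <- normalize_track(track_sensitive)
  }
  peaks$signal_A <- peak_mean_signal(peaks, track_resistant)
  peaks$signal_B <- peak_mean_signal(peaks, track_sensitive)
  peaks
}

#' Assign peaks to genes within a TSS window
#'
#' A peak is assigned to a gene when both lie on the same chromosome and the
#' absolute distance between the peak midpoint (\code{floor((start+end)/2)})
#' and the gene's TSS is at most \code{window_bp} (inclusive). A peak may be
#' assigned to several genes.
#'
#' @param peaks a peak data.frame.
#' @param annotation TSS annotation (see \code{\link{read_annotation}}).
#' @param gene_ids genes of interest; must all be present in the annotation.
#' @param cfg an \code{\link{enhancer_config}}.
#' @return Long data.frame: one row per (gene, peak) assignment, columns of
#'   \code{peaks} plus \code{gene_id} and \code{tss_distance}.
#' @export
assign_peaks <- function(peaks, annotation, gene_ids, cfg) {
  missing_ids <- setdiff(gene_ids, annotation$gene_id)
  if (length(missing_ids) > 0L) {
    stop("gene id(s) absent from annotation: ",
         paste(missing_ids, collapse = ", "))
  }
  ann <- annotation[match(gene_ids, annotation$gene_id), , drop = FALSE]
  mid <- floor((peaks$start + peaks$end) / 2)
  res <- vector("list", length(gene_ids))
  for (g in seq_along(gene_ids)) {
    hit <- which(peaks$chrom == ann$chrom[g] &
                   abs(mid - ann$tss[g]) <= cfg$window_bp)
    if (length(hit) > 0L) {
      block <- peaks[hit, , drop = FALSE]
      block$gene_id <- gene_ids[g]
      block$tss_distance <- abs(mid[hit] - ann$tss[g])
      res[[g]] <- block
    }
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    out <- peaks[0, , drop = FALSE]
    out$gene_id <- character()
    out$tss_distance <- numeric()
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-peak log2 ratio of resistant over sensitive signal
#'
#' @param signal_a,signal_b signals in the resistant (A) and sensitive (B)
#'   conditions.
#' @param cfg an \code{\link{enhancer_config}} supplying the pseudocount.
#' @return \code{log2((signal_a + pc) / (signal_b + pc))}.
#' @export
peak_log2_ratio <- function(signal_a, signal_b, cfg) {
  pc <- cfg$signal_pseudocount
  log2((signal_a + pc) / (signal_b + pc))
}

#' Summarize per-gene enhancer signal changes
#'
#' For each gene x mark combination with at least one assigned peak, collects
#' the per-peak log2 ratios and their median (middle order statistic; mean of
#' the two middle values for even counts). Genes with no assigned peaks of a
#' mark are omitted from the summary (with a message), never NaN-propagated.
#'
#' @param assigned long assignment table from \code{\link{assign_peaks}} with
#'   signals attached (\code{\link{attach_peak_signals}}).
#' @param cfg an \code{\link{enhancer_config}}.
#' @param gene_ids optional; genes expected in the summary, used only to
#'   report which were omitted for lack of peaks.
#' @return List with \code{summary} (data.frame \code{gene_id, mark, n_peaks,
#'   median_log2_ratio}) and \code{peaks} (long per-peak table with
#'   \code{log2_ratio}, the data behind a per-gene dot plot).
#' @export
summarize_enhancers <- function(assigned, cfg, gene_ids = NULL) {
  assigned$log2_ratio <- peak_log2_ratio(assigned$signal_A,
                                         assigned$signal_B, cfg)
  key <- interaction(assigned$gene_id, assigned$mark, drop = TRUE)
  if (nrow(assigned) == 0L) {
    summ <- data.frame(gene_id = character(), mark = character(),
                       n_peaks = integer(), median_log2_ratio = double(),
                       stringsAsFactors = FALSE)
  } else {
    pieces <- split(assigned, key)
    summ <- do.call(rbind, lapply(pieces, function(d) {
      data.frame(gene_id = d$gene_id[1], mark = d$mark[1],
                 n_peaks = nrow(d),
                 median_log2_ratio = stats::median(d$log2_ratio),
                 stringsAsFactors = FALSE)
    }))
    summ <- summ[order(summ$gene_id, summ$mark), , drop = FALSE]
    rownames(summ) <- NULL
  }
  if (!is.null(gene_ids)) {
    dropped <- setdiff(gene_ids, unique(summ$gene_id))
    if (length(dropped) > 0L) {
      message("omitting ", length(dropped),
              " gene(s) with no assigned peaks: ",
              paste(utils::head(dropped, 5), collapse = ", "),
              if (length(dropped) > 5) ", ..." else "")
    }
  }
  cols <- c("gene_id", "mark", "chrom", "start", "end", "name",
            "neg_log10_p", "signal_A", "signal_B", "tss_distance",
            "log2_ratio")
  list(summary = summ, peaks = assigned[, intersect(cols, names(assigned)),
                                        drop = FALSE])
}

#' Dot plot of per-peak enhancer log2 ratios by gene
#'
#' Recreates the per-gene dot-plot view of enhancer remodeling: one point per
#' peak within the TSS window, with a bar at the per-gene median.
#'
#' @param peaks_long long per-peak table from \code{\link{summarize_enhancers}}
#'   (one mark).
#' @return A ggplot object.
#' @export
plot_enhancer_ratios <- function(peaks_long) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  med <- stats::aggregate(log2_ratio ~ gene_id, peaks_long, stats::median)
  ggplot2::ggplot(peaks_long,
                  ggplot2::aes(x = .data[["gene_id"]],
                               y = .data[["log2_ratio"]])) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6, size = 1) +
    ggplot2::geom_crossbar(data = med,
                           ggplot2::aes(ymin = .data[["log2_ratio"]],
                                        ymax = .data[["log2_ratio"]]),
                           color = "red", width = 0.5, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "log2 ChIP signal ratio (resistant / sensitive)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
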