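# Orchestrates the four-stage analysis: tumor DE -> cell-line DE ->
# short-term subtraction -> concordant intersection + Fisher enrichment ->
# enhancer summary. Stage order matters: acute drug-response genes are
# subtracted from the cell-line list BEFORE intersecting with the in-vivo
# list, so the signature reflects stable resistance rather than short-term
# drug response.

#' Pipeline configuration
#'
#' Collects input paths and per-stage configurations. Path defaults follow
#' the file layout of \code{\link{write_bundle}}.
#'
#' @param input_dir directory holding the inputs.
#' @param out_dir run directory for all outputs (created if needed).
#' @param expression,sample_sheet,annotation input paths.
#' @param peaks,tracks nested named lists \code{[[mark]][[condition]]} of
#'   narrowPeak / bedGraph paths; NULL for the bundle layout defaults.
#' @param tumor_cfg,cellline_cfg,shortterm_cfg \code{\link{de_config}}s per
#'   dataset; tumor mode is fold-change-only, the two cell-line modes add
#'   the paired t-test.
#' @param enhancer_cfg an \code{\link{enhancer_config}}.
#' @param fisher_universe \code{"both_gated"} (genes passing the expression
#'   gate in both the tumor and cell-line datasets; default) or
#'   \code{"all"} (every gene in the matrix).
#' @param conditions named list with character pairs
#'   \code{c(numerator, denominator)} per dataset.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic; randomness lives only in simulation).
#' @return A list of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            expression = file.path(input_dir, "expression.tsv"),
                            sample_sheet = file.path(input_dir, "sample_sheet.tsv"),
                            annotation = file.path(input_dir, "annotation.bed"),
                            peaks = NULL, tracks = NULL,
                            tumor_cfg = de_config(use_paired_test = FALSE),
                            cellline_cfg = de_config(use_paired_test = TRUE),
                            shortterm_cfg = de_config(use_paired_test = TRUE),
                            enhancer_cfg = enhancer_config(),
                            fisher_universe = c("both_gated", "all"),
                            conditions = list(tumor = c("TzR", "TzS"),
                                              cellline = c("TzR", "TzS"),
                                              shortterm = c("treated", "mock")),
                            seed = NA_integer_) {
  fisher_universe <- match.arg(fisher_universe)
  if (is.null(peaks)) {
    peaks <- lapply(stats::setNames(CHIP_MARKS, CHIP_MARKS), function(mark) {
      lapply(stats::setNames(CHIP_CONDITIONS, CHIP_CONDITIONS), function(cond) {
        file.path(input_dir, sprintf("peaks_%s_%s.narrowPeak", mark, cond))
      })
    })
  }
  if (is.null(tracks)) {
    tracks <- lapply(stats::setNames(CHIP_MARKS, CHIP_MARKS), function(mark) {
      lapply(stats::setNames(CHIP_CONDITIONS, CHIP_CONDITIONS), function(cond) {
        file.path(input_dir, sprintf("track_%s_%s.bedGraph", mark, cond))
      })
    })
  }
  inputs <- c(expression, sample_sheet, annotation,
              unlist(peaks), unlist(tracks))
  missing_files <- inputs[!file.exists(inputs)]
  if (length(missing_files) > 0L) {
    stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  }
  structure(list(expression = expression, sample_sheet = sample_sheet,
                 annotation = annotation, peaks = peaks, tracks = tracks,
                 out_dir = out_dir, tumor_cfg = tumor_cfg,
                 cellline_cfg = cellline_cfg, shortterm_cfg = shortterm_cfg,
                 enhancer_cfg = enhancer_cfg,
                 fisher_universe = fisher_universe,
                 conditions = conditions, seed = seed),
            class = "PipelineConfig")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full integrative analysis
#'
#' Executes, in order: tumor DE (fold-change-only), cell-line DE (paired
#' t-test), short-term DE (paired t-test), subtraction of short-term
#' drug-response genes from the cell-line list, concordant-direction
#' intersection with the in-vivo list, Fisher exact overlap enrichment
#' (pooled and per biotype), and the enhancer log2-ratio summary for the
#' integrated signature genes. Writes all outputs plus a manifest to the run
#' directory; identical inputs and config give byte-identical outputs.
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @return Invisibly, a list with every intermediate object (DE tables,
#'   signature sets, Fisher results, enhancer summaries, manifest).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  message("reading inputs")
  expr <- stage("read_expression",
                read_expression(cfg$expression, cfg$sample_sheet))
  ann <- stage("read_annotation", read_annotation(cfg$annotation))

  message("stage 1/5: tumor differential expression (fold-change rule)")
  tum <- stage("tumor_de", {
    m <- subset_dataset(expr, "tumor")
    call_de(m, cfg$tumor_cfg, cfg$conditions$tumor[1], cfg$conditions$tumor[2])
  })
  write_de_calls(tum, file.path(cfg$out_dir, "tumor_de.tsv"))

  message("stage 2/5: cell-line differential expression (paired t-test)")
  cl <- stage("cellline_de", {
    m <- subset_dataset(expr, "cellline")
    call_de(m, cfg$cellline_cfg, cfg$conditions$cellline[1],
            cfg$conditions$cellline[2])
  })
  write_de_calls(cl, file.path(cfg$out_dir, "cellline_de.tsv"))

  message("stage 3/5: short-term (48-h) response differential expression")
  st <- stage("shortterm_de", {
    m <- subset_dataset(expr, "shortterm")
    call_de(m, cfg$shortterm_cfg, cfg$conditions$shortterm[1],
            cfg$conditions$shortterm[2])
  })
  write_de_calls(st, file.path(cfg$out_dir, "shortterm_de.tsv"))

  message("stage 4/5: subtraction, concordant intersection, Fisher test")
  sig_tumor <- de_signature(tum, "tumor")
  sig_cl <- de_signature(cl, "cellline")
  sig_st <- de_signature(st, "shortterm")
  sig_cl_stable <- subtract_signature(sig_cl, sig_st)
  write_signature(sig_cl_stable,
                  file.path(cfg$out_dir, "post_subtraction_signature.tsv"))
  integrated <- intersect_concordant(sig_tumor, sig_cl_stable)

  out_sig <- as.data.frame(integrated)
  out_sig$log2fc_invivo <- tum$log2fc[match(out_sig$gene_id, tum$gene_id)]
  out_sig$log2fc_invitro <- cl$log2fc[match(out_sig$gene_id, cl$gene_id)]
  write_tsv(out_sig, file.path(cfg$out_dir, "integrated_signature.tsv"))

  fish <- fisher_by_biotype(tum, cl, sig_tumor, sig_cl_stable, integrated,
                            cfg$fisher_universe)
  jsonlite::write_json(fish, file.path(cfg$out_dir, "fisher.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  message("stage 5/5: enhancer signal ratios around signature TSSs")
  enh <- stage("enhancer", {
    genes <- intersect(integrated$gene_id, ann$gene_id)
    run_enhancer_stage(cfg$peaks, cfg$tracks, ann, genes, cfg$enhancer_cfg)
  })
  write_tsv(enh$summary, file.path(cfg$out_dir, "enhancer_summary.tsv"))
  write_tsv(enh$peaks, file.path(cfg$out_dir, "enhancer_peaks.tsv"))

  manifest <- list(
    package = "tzrsig",
    version = as.character(utils::packageVersion("tzrsig")),
    seed = cfg$seed,
    fisher_universe = cfg$fisher_universe,
    conditions = cfg$conditions,
    config = list(tumor = unclass(cfg$tumor_cfg),
                  cellline = unclass(cfg$cellline_cfg),
                  shortterm = unclass(cfg$shortterm_cfg),
                  enhancer = unclass(cfg$enhancer_cfg)),
    inputs = {
      files <- c(cfg$expression, cfg$sample_sheet, cfg$annotation,
                 unlist(cfg$peaks), unlist(cfg$tracks))
      md5 <- tools::md5sum(files)
      names(md5) <- basename(files)
      as.list(md5[order(names(md5))])
    },
    counts = list(
      tumor_de = sum(tum$is_differential),
      cellline_de = sum(cl$is_differential),
      shortterm_de = sum(st$is_differential),
      post_subtraction = nrow(sig_cl_stable),
      integrated = nrow(integrated),
      integrated_mrna = sum(integrated$biotype == "mRNA"),
      integrated_lincrna = sum(integrated$biotype == "lincRNA")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("integrated signature: %d mRNAs, %d lincRNAs (Fisher p = %.3g)",
                  manifest$counts$integrated_mrna,
                  manifest$counts$integrated_lincrna,
                  fish$pooled$p_two_tailed))
  invisible(list(tumor_de = tum, cellline_de = cl, shortterm_de = st,
                 sig_tumor = sig_tumor, sig_cellline = sig_cl,
                 sig_shortterm = sig_st, sig_post_subtraction = sig_cl_stable,
                 integrated = integrated, fisher = fish, enhancer = enh,
                 manifest = manifest))
}

# Fisher enrichment of the in-vivo vs stable cell-line overlap, pooled and
# per biotype. Universe: genes gated in both datasets (the gate defines
# which genes could have been called at all).
fisher_by_biotype <- function(tum, cl, sig_tumor, sig_cl_stable, integrated,
                              universe_policy) {
  gated_both <- if (universe_policy == "both_gated") {
    tum$gene_id[tum$passes_gate & cl$passes_gate[match(tum$gene_id, cl$gene_id)]]
  } else {
    tum$gene_id
  }
  biotype <- tum$biotype[match(gated_both, tum$gene_id)]
  one <- function(ids) {
    u <- length(ids)
    na <- sum(sig_tumor$gene_id %in% ids)
    nb <- sum(sig_cl_stable$gene_id %in% ids)
    nov <- sum(integrated$gene_id %in% ids)
    fr <- fisher_overlap(u, na, nb, nov)
    fisher_summary(fr, u, na, nb, nov)
  }
  list(pooled = one(gated_both),
       mRNA = one(gated_both[biotype == "mRNA"]),
       lincRNA = one(gated_both[biotype == "lincRNA"]))
}

#' Run the enhancer stage from peak and track files
#'
#' Reads per-condition narrowPeak files for each mark, filters each at the
#' significance threshold, takes the union of the two conditions' filtered
#' peaks, attaches normalized per-condition signals from the bedGraph
#' tracks, assigns peaks within the TSS window of the requested genes and
#' summarizes per-gene median log2 ratios.
#'
#' @param peak_paths,track_paths nested lists \code{[[mark]][[condition]]}
#'   of file paths; conditions are \code{TzR} (resistant, numerator) and
#'   \code{TzS} (sensitive, denominator).
#' @param annotation TSS annotation data.frame.
#' @param gene_ids genes to summarize.
#' @param cfg an \code{\link{enhancer_config}}.
#' @return As \code{\link{summarize_enhancers}}: list with \code{summary}
#'   and long \code{peaks}, all marks combined.
#' @export
run_enhancer_stage <- function(peak_paths, track_paths, annotation, gene_ids,
                               cfg) {
  summaries <- list(); longs <- list()
  for (mark in names(peak_paths)) {
    pA <- filter_peaks(read_peaks(peak_paths[[mark]][["TzR"]], mark), cfg)
    pB <- filter_peaks(read_peaks(peak_paths[[mark]][["TzS"]], mark), cfg)
    both <- rbind(pA, pB)
    both <- both[!duplicated(both[, c("chrom", "start", "end")]), ,
                 drop = FALSE]
    both <- attach_peak_signals(both,
                                read_bedgraph(track_paths[[mark]][["TzR"]]),
                                read_bedgraph(track_paths[[mark]][["TzS"]]))
    assigned <- assign_peaks(both, annotation, gene_ids, cfg)
    res <- summarize_enhancers(assigned, cfg, gene_ids)
    summaries[[mark]] <- res$summary
    longs[[mark]] <- res$peaks
  }
  summ <- do.call(rbind, summaries)
  long <- do.call(rbind, longs)
  rownames(summ) <- NULL
  rownames(long) <- NULL
  list(summary = summ, peaks = long)
}
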