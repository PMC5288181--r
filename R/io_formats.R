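# Readers/writers for every external format the pipeline touches, with
# strict validation. All genomic intervals are 0-based half-open (BED
# convention); a TSS is a single 0-based base.

VALID_BIOTYPES <- c("mRNA", "lincRNA")
VALID_DATASETS <- c("tumor", "cellline", "shortterm")

#' Construct a validated expression matrix
#'
#' Bundles a genes x samples FPKM matrix with per-gene biotype labels and a
#' sample sheet assigning each sample a dataset tag, a condition label and an
#' optional pairing id.
#'
#' @param values numeric matrix of non-negative FPKM values, genes in rows
#'   (rownames = gene ids), samples in columns (colnames = sample names).
#' @param biotype character vector, one of \code{"mRNA"} or \code{"lincRNA"}
#'   per gene, parallel to the rows of \code{values}.
#' @param sample_sheet data.frame with columns \code{sample},
#'   \code{dataset} (one of tumor/cellline/shortterm), \code{condition} and
#'   optionally \code{pair_id} (NA when unpaired). Every column of
#'   \code{values} must appear in \code{sample}.
#'
#' @return An object of class \code{ExpressionMatrix}: a list with elements
#'   \code{values}, \code{biotype} (named by gene id) and \code{samples}.
#' @export
expression_matrix <- function(values, biotype, sample_sheet) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- rownames(values)
  if (is.null(gene_ids)) stop("expression values must have gene ids as rownames")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0L) {
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  }
  if (anyNA(values)) stop("FPKM values must not contain NA")
  if (any(values < 0)) {
    bad <- gene_ids[which(rowSums(values < 0) > 0)[1]]
    stop("negative FPKM value (first offending gene: ", bad, ")")
  }
  biotype <- as.character(biotype)
  if (length(biotype) != nrow(values)) {
    stop("biotype must have one entry per gene")
  }
  unknown <- setdiff(unique(biotype), VALID_BIOTYPES)
  if (length(unknown) > 0L) {
    stop("unknown biotype(s): ", paste(unknown, collapse = ", "),
         " (expected mRNA or lincRNA)")
  }
  names(biotype) <- gene_ids
  sample_sheet <- as.data.frame(sample_sheet, stringsAsFactors = FALSE)
  needed <- c("sample", "dataset", "condition")
  missing_cols <- setdiff(needed, names(sample_sheet))
  if (length(missing_cols) > 0L) {
    stop("sample sheet missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"pair_id" %in% names(sample_sheet)) sample_sheet$pair_id <- NA_character_
  sample_sheet$pair_id <- as.character(sample_sheet$pair_id)
  sample_sheet$pair_id[sample_sheet$pair_id %in% c("", "NA")] <- NA_character_
  if (anyDuplicated(sample_sheet$sample)) stop("duplicate sample in sample sheet")
  bad_ds <- setdiff(unique(sample_sheet$dataset), VALID_DATASETS)
  if (length(bad_ds) > 0L) {
    stop("unknown dataset tag(s): ", paste(bad_ds, collapse = ", "))
  }
  absent <- setdiff(sample_sheet$sample, colnames(values))
  if (length(absent) > 0L) {
    stop("sample(s) in sheet missing from expression table: ",
         paste(absent, collapse = ", "))
  }
  extra <- setdiff(colnames(values), sample_sheet$sample)
  if (length(extra) > 0L) {
    stop("sample(s) in expression table missing from sheet: ",
         paste(extra, collapse = ", "))
  }
  # within a dataset, pairing is all-or-none and 1:1 across the two conditions
  for (ds in unique(sample_sheet$dataset)) {
    sh <- sample_sheet[sample_sheet$dataset == ds, , drop = FALSE]
    has_pair <- !is.na(sh$pair_id)
    if (any(has_pair) && !all(has_pair)) {
      stop("dataset '", ds, "': pairing ids must be present for all samples or none")
    }
    if (all(has_pair) && nrow(sh) > 0L) {
      conds <- unique(sh$condition)
      if (length(conds) == 2L) {
        p1 <- sort(sh$pair_id[sh$condition == conds[1]])
        p2 <- sort(sh$pair_id[sh$condition == conds[2]])
        if (length(p1) != length(p2) || anyDuplicated(p1) || anyDuplicated(p2) ||
            !identical(p1, p2)) {
          stop("dataset '", ds, "': pairing ids must match 1:1 across conditions")
        }
      }
    }
  }
  # order columns as in the sheet for a canonical layout
  values <- values[, sample_sheet$sample, drop = FALSE]
  structure(list(values = values, biotype = biotype, samples = sample_sheet),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  cat("  biotypes:", paste(sprintf("%s=%d", names(table(x$biotype)),
                                   table(x$biotype)), collapse = ", "), "\n")
  ds <- unique(x$samples$dataset)
  for (d in ds) {
    sh <- x$samples[x$samples$dataset == d, ]
    cat("  dataset", d, ":",
        paste(sprintf("%s=%d", names(table(sh$condition)), table(sh$condition)),
              collapse = ", "),
        if (all(!is.na(sh$pair_id))) "(paired)" else "", "\n")
  }
  invisible(x)
}

#' Subset an expression matrix to one dataset
#'
#' @param mat an \code{ExpressionMatrix}.
#' @param dataset dataset tag to keep (tumor, cellline or shortterm).
#' @return An \code{ExpressionMatrix} restricted to the samples of that
#'   dataset.
#' @export
subset_dataset <- function(mat, dataset) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  sh <- mat$samples[mat$samples$dataset == dataset, , drop = FALSE]
  if (nrow(sh) == 0L) stop("no samples with dataset tag '", dataset, "'")
  expression_matrix(mat$values[, sh$sample, drop = FALSE], mat$biotype, sh)
}

#' Read an FPKM expression table and its sample sheet
#'
#' The expression table is TSV with a header: columns \code{gene_id},
#' \code{biotype}, then one column per sample. The sample sheet is TSV with
#' columns \code{sample}, \code{dataset}, \code{condition}, \code{pair_id}.
#'
#' @param path path to the expression TSV.
#' @param sample_sheet_path path to the sample sheet TSV.
#' @return An \code{\link{expression_matrix}} object.
#' @export
read_expression <- function(path, sample_sheet_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 3L || !identical(names(tab)[1:2], c("gene_id", "biotype"))) {
    stop("expression table must start with columns gene_id, biotype")
  }
  dup <- unique(tab$gene_id[duplicated(tab$gene_id)])
  if (length(dup) > 0L) {
    stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric FPKM values in ", path)
  rownames(vals) <- tab$gene_id
  sheet <- utils::read.delim(sample_sheet_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  expression_matrix(vals, tab$biotype, sheet)
}

#' Write an expression matrix and sample sheet to TSV
#'
#' @param mat an \code{ExpressionMatrix}.
#' @param path output path for the expression TSV.
#' @param sample_sheet_path optional output path for the sample sheet TSV.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(mat, path, sample_sheet_path = NULL) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  out <- data.frame(gene_id = rownames(mat$values),
                    biotype = unname(mat$biotype),
                    mat$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
  if (!is.null(sample_sheet_path)) {
    sh <- mat$samples
    sh$pair_id[is.na(sh$pair_id)] <- "NA"
    write_tsv(sh, sample_sheet_path)
  }
  invisible(path)
}

#' Read a TSS annotation table
#'
#' BED-like TSV without header: \code{chrom, tss_start (0-based),
#' tss_end (= tss_start + 1), gene_id, biotype, strand}.
#'
#' @param path path to the annotation file.
#' @return data.frame with columns \code{gene_id, chrom, tss, biotype,
#'   strand}; \code{tss} is the 0-based TSS position.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "tss_start", "tss_end",
                                         "gene_id", "biotype", "strand"))
  ann <- data.frame(gene_id = tab$gene_id, chrom = tab$chrom,
                    tss = as.integer(tab$tss_start),
                    biotype = tab$biotype, strand = tab$strand,
                    stringsAsFactors = FALSE)
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
  if (length(dup) > 0L) stop("duplicate gene id(s) in annotation: ",
                             paste(dup, collapse = ", "))
  if (any(ann$tss < 0)) stop("TSS positions must be >= 0")
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be + or -")
  unknown <- setdiff(unique(ann$biotype), VALID_BIOTYPES)
  if (length(unknown) > 0L) stop("unknown biotype(s) in annotation: ",
                                 paste(unknown, collapse = ", "))
  invisible(ann)
}

#' Write a TSS annotation table
#'
#' @param ann annotation data.frame as returned by
#'   \code{\link{read_annotation}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(ann, path) {
  validate_annotation(ann)
  out <- data.frame(ann$chrom, ann$tss, ann$tss + 1L, ann$gene_id,
                    ann$biotype, ann$strand)
  write_tsv(out, path, col.names = FALSE)
  invisible(path)
}

#' Read ChIP-seq peaks from an ENCODE narrowPeak file
#'
#' narrowPeak is BED6+4: chrom, start, end, name, score, strand, signalValue,
#' pValue (as -log10), qValue, summit offset. Column 8 is taken as
#' \code{neg_log10_p}. The histone-mark label is not part of the format and
#' is supplied by the caller.
#'
#' @param path path to a narrowPeak file.
#' @param mark histone mark label for every peak in this file, one of
#'   \code{"H3K4me1"} or \code{"H3K27ac"}.
#' @return data.frame with columns \code{chrom, start, end, name, mark,
#'   neg_log10_p, signal_A, signal_B} (the last two NA until filled from
#'   signal tracks). Coordinates are 0-based half-open, preserved verbatim.
#' @export
read_peaks <- function(path, mark) {
  mark <- match.arg(mark, c("H3K4me1", "H3K27ac"))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), mark = character(),
                      neg_log10_p = double(), signal_A = double(),
                      signal_B = double(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10L)) {
    bad <- which(nf != 10L)[1]
    stop("malformed narrowPeak line ", bad, " in ", path,
         ": expected 10 tab-separated fields, got ", nf[bad])
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  p <- suppressWarnings(as.numeric(m[, 8]))
  if (anyNA(start) || anyNA(end)) stop("non-numeric coordinates in ", path)
  if (anyNA(p)) {
    stop("non-numeric -log10(p) score at line ", which(is.na(p))[1], " in ", path)
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop("invalid interval (start >= end) at line ", bad, " in ", path)
  }
  if (any(p < 0)) stop("negative -log10(p) score in ", path)
  data.frame(chrom = m[, 1], start = start, end = end, name = m[, 4],
             mark = mark, neg_log10_p = p,
             signal_A = NA_real_, signal_B = NA_real_,
             stringsAsFactors = FALSE)
}

#' Write peaks to an ENCODE narrowPeak file
#'
#' @param peaks a peak data.frame as returned by \code{\link{read_peaks}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  out <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                    0L, ".", 0, format_num(peaks$neg_log10_p), -1, -1)
  write_tsv(out, path, col.names = FALSE)
  invisible(path)
}

#' Read a signal track from a bedGraph file
#'
#' 4-column bedGraph: chrom, start, end, value; 0-based half-open intervals.
#' Intervals are sorted internally per chromosome; overlapping input
#' intervals are an error.
#'
#' @param path path to a bedGraph file.
#' @return data.frame of class \code{SignalTrack} with columns
#'   \code{chrom, start, end, value}, sorted by (chrom, start),
#'   non-overlapping within each chromosome.
#' @export
read_bedgraph <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "value"))
  signal_track(tab)
}

#' Construct a validated signal track
#'
#' @param df data.frame with columns \code{chrom, start, end, value}.
#' @return The sorted, validated track (class \code{SignalTrack}).
#' @export
signal_track <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$value <- as.numeric(df$value)
  if (any(!is.finite(df$value))) stop("signal track values must be finite")
  if (any(df$start >= df$end)) stop("signal track interval with start >= end")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (chr in unique(df$chrom)) {
    d <- df[df$chrom == chr, , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("overlapping intervals in signal track on ", chr)
    }
  }
  class(df) <- c("SignalTrack", "data.frame")
  df
}

#' Write a signal track to bedGraph
#'
#' @param track a \code{SignalTrack}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  out <- data.frame(track$chrom, track$start, track$end,
                    format_num(track$value))
  write_tsv(out, path, col.names = FALSE)
  invisible(path)
}

#' Write a gene signature to TSV
#'
#' @param sig a \code{\link{signature_set}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_signature <- function(sig, path) {
  write_tsv(as.data.frame(sig), path)
  invisible(path)
}

#' Read a gene signature from TSV
#'
#' @param path a TSV with columns \code{gene_id, biotype, direction} (extra
#'   columns such as per-dataset log2 fold changes are carried through).
#' @param provenance provenance tag for the resulting set.
#' @return A \code{\link{signature_set}}.
#' @export
read_signature <- function(path, provenance = "integrated") {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  signature_set(tab$gene_id, tab$direction, tab$biotype, provenance)
}

# deterministic TSV writer: fixed number formatting, no quoting, LF endings
write_tsv <- function(df, path, col.names = TRUE) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], format_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names, na = "NA", eol = "\n")
}

# fixed significant-digit rendering so identical values give identical bytes
format_num <- function(x) {
  out <- formatC(x, digits = 10, format = "g")
  out[is.na(x)] <- NA_character_
  trimws(out)
}
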