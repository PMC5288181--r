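# Set-level integration: subtract short-term drug-response genes, intersect
# the in-vivo and in-vitro differential sets requiring concordant direction,
# and test the overlap with a two-tailed Fisher exact test.

#' Construct a directed gene signature set
#'
#' @param gene_ids character vector of unique gene ids.
#' @param direction per-gene direction in the resistant condition,
#'   \code{"up"} or \code{"down"}.
#' @param biotype per-gene biotype, \code{"mRNA"} or \code{"lincRNA"}.
#' @param provenance one of \code{"tumor"}, \code{"cellline"},
#'   \code{"shortterm"}, \code{"integrated"}.
#' @return data.frame of class \code{SignatureSet} with columns
#'   \code{gene_id, biotype, direction} and a \code{provenance} attribute.
#' @export
signature_set <- function(gene_ids, direction, biotype,
                          provenance = c("tumor", "cellline", "shortterm",
                                         "integrated")) {
  provenance <- match.arg(provenance)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in signature set")
  direction <- as.character(direction)
  biotype <- as.character(biotype)
  stopifnot(length(direction) == length(gene_ids),
            length(biotype) == length(gene_ids))
  if (!all(direction %in% c("up", "down"))) {
    stop("signature directions must be 'up' or 'down'")
  }
  df <- data.frame(gene_id = gene_ids, biotype = biotype,
                   direction = direction, stringsAsFactors = FALSE)
  df <- df[order(df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("SignatureSet", "data.frame")
  df
}

#' Extract the differential genes of a DE-call table as a signature set
#'
#' @param de_calls result of \code{\link{call_de}}.
#' @param provenance provenance tag for the set.
#' @return A \code{\link{signature_set}} of the \code{is_differential} genes.
#' @export
de_signature <- function(de_calls, provenance) {
  d <- de_calls[de_calls$is_differential, , drop = FALSE]
  signature_set(d$gene_id, d$direction, d$biotype, provenance)
}

#' Subtract one signature from another by gene id
#'
#' Removes from \code{resistance_set} every gene present in
#' \code{short_term_set}, regardless of direction; the study uses this to
#' discard acute (48-h) drug-response genes so the signature reflects stable
#' resistance. Directions of surviving genes are preserved.
#'
#' @param resistance_set,short_term_set \code{\link{signature_set}} objects.
#' @return A \code{SignatureSet} with the provenance of
#'   \code{resistance_set}.
#' @export
subtract_signature <- function(resistance_set, short_term_set) {
  keep <- !(resistance_set$gene_id %in% short_term_set$gene_id)
  out <- resistance_set[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(resistance_set, "provenance")
  class(out) <- c("SignatureSet", "data.frame")
  out
}

#' Intersect two signatures requiring concordant direction
#'
#' A gene is kept only when present in both sets with the same direction of
#' change (sign of the log2 fold change; magnitudes are not compared).
#'
#' @param in_vivo,in_vitro \code{\link{signature_set}} objects.
#' @return A \code{SignatureSet} with provenance \code{"integrated"}.
#' @export
intersect_concordant <- function(in_vivo, in_vitro) {
  idx <- match(in_vivo$gene_id, in_vitro$gene_id)
  hit <- !is.na(idx) & in_vivo$direction == in_vitro$direction[idx]
  out <- in_vivo[hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- "integrated"
  class(out) <- c("SignatureSet", "data.frame")
  out
}

#' Two-tailed Fisher exact test for gene-set overlap
#'
#' Exact hypergeometric test of the 2x2 table (in both sets / A only /
#' B only / neither) over a stated gene universe. The two-tailed p-value
#' follows the point-probability rule: the sum of probabilities of all
#' tables with the same margins whose probability does not exceed that of
#' the observed table (relative tie tolerance 1e-7). No normal
#' approximation is used.
#'
#' @param universe_n number of genes in the universe.
#' @param n_a,n_b sizes of the two sets.
#' @param n_overlap observed overlap.
#' @return List of class \code{FisherResult}: \code{table} (2x2 integer
#'   matrix), \code{p_two_tailed}, \code{odds_ratio} (sample odds ratio,
#'   \code{Inf} allowed).
#' @export
fisher_overlap <- function(universe_n, n_a, n_b, n_overlap) {
  universe_n <- as.integer(universe_n); n_a <- as.integer(n_a)
  n_b <- as.integer(n_b); n_overlap <- as.integer(n_overlap)
  if (n_a > universe_n || n_b > universe_n) {
    stop("set sizes cannot exceed the universe")
  }
  if (n_overlap > min(n_a, n_b) || n_overlap < max(0L, n_a + n_b - universe_n)) {
    stop("inconsistent overlap count for the given margins")
  }
  k <- max(0L, n_a + n_b - universe_n):min(n_a, n_b)
  pk <- stats::dhyper(k, n_a, universe_n - n_a, n_b)
  p_obs <- pk[match(n_overlap, k)]
  p <- min(1, sum(pk[pk <= p_obs * (1 + 1e-7)]))
  tab <- matrix(c(n_overlap, n_a - n_overlap,
                  n_b - n_overlap, universe_n - n_a - n_b + n_overlap),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("in_A", "not_A"), c("in_B", "not_B")))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(list(table = tab, p_two_tailed = p, odds_ratio = or),
            class = "FisherResult")
}

#' @export
print.FisherResult <- function(x, ...) {
  cat("Fisher exact overlap test (two-tailed)\n")
  print(x$table)
  cat(sprintf("p = %.4g, odds ratio = %.4g\n", x$p_two_tailed, x$odds_ratio))
  invisible(x)
}

#' Summarize a Fisher overlap result as a flat list for JSON output
#'
#' @param fr a \code{FisherResult}.
#' @param universe_n,n_a,n_b,n_overlap the counts that produced it.
#' @return Named list \code{universe, n_a, n_b, overlap, p_two_tailed,
#'   odds_ratio}.
#' @export
fisher_summary <- function(fr, universe_n, n_a, n_b, n_overlap) {
  list(universe = universe_n, n_a = n_a, n_b = n_b, overlap = n_overlap,
       p_two_tailed = fr$p_two_tailed, odds_ratio = fr$odds_ratio)
}
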