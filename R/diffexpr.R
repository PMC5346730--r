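#' FPKM from raw fragment counts
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' \eqn{10^9 \cdot c / (L \cdot N)} for count \eqn{c}, transcript length
#' \eqn{L} (bp) and library size \eqn{N} (mapped fragments). Vectorized.
#'
#' @param count Nonnegative fragment counts.
#' @param length_bp Transcript lengths in base pairs (>= 1).
#' @param total_mapped Library sizes (>= 1).
#' @return FPKM values, same length as the longest argument.
#' @export
compute_fpkm <- function(count, length_bp, total_mapped) {
  if (any(count < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(length_bp < 1)) stop("length_bp must be >= 1", call. = FALSE)
  if (any(total_mapped < 1)) stop("total_mapped must be >= 1", call. = FALSE)
  1e9 * count / (length_bp * total_mapped)
}

#' Select one representative transcript per protein-coding gene
#'
#' Keeps, for each protein-coding gene, the isoform with the highest mean
#' abundance across the two conditions; non-protein-coding genes are dropped.
#' Ties are broken by transcript id so the choice is deterministic, and the
#' operation is idempotent.
#'
#' @param tx Transcript table: `transcript_id`, `gene_id`, `biotype`,
#'   `length_bp`, `expr_a`, `expr_b`.
#' @return The same columns, one row per retained gene.
#' @export
select_representative_transcripts <- function(tx) {
  stopifnot(nrow(tx) >= 1)
  pc <- tx[tx$biotype == "protein_coding", , drop = FALSE]
  if (nrow(pc) == 0) return(pc)
  mean_expr <- (pc$expr_a + pc$expr_b) / 2
  ord <- order(pc$gene_id, -mean_expr, pc$transcript_id)
  pc <- pc[ord, , drop = FALSE]
  out <- pc[!duplicated(pc$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Log2 fold-change with pseudocount
#'
#' `log2((b + pseudocount) / (a + pseudocount))`; antisymmetric under
#' swapping the two conditions. The pseudocount bounds fold-changes for
#' dropout genes.
#'
#' @param expr_a,expr_b Nonnegative abundances (FPKM).
#' @param pseudocount Positive abundance added to both conditions.
#' @export
compute_log2_fold_change <- function(expr_a, expr_b, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
  if (any(expr_a < 0) || any(expr_b < 0))
    stop("abundances must be nonnegative", call. = FALSE)
  log2((expr_b + pseudocount) / (expr_a + pseudocount))
}

#' Build the gene-level differential-expression table
#'
#' Representative-transcript selection followed by log2 fold-change.
#'
#' @param tx Transcript table (see [select_representative_transcripts()]).
#' @param pseudocount Passed to [compute_log2_fold_change()].
#' @return data.frame: `gene_id`, `transcript_id`, `expr_a`, `expr_b`,
#'   `log2fc`.
#' @export
gene_de_table <- function(tx, pseudocount = 1) {
  rep_tx <- select_representative_transcripts(tx)
  data.frame(
    gene_id = rep_tx$gene_id,
    transcript_id = rep_tx$transcript_id,
    expr_a = rep_tx$expr_a,
    expr_b = rep_tx$expr_b,
    log2fc = compute_log2_fold_change(rep_tx$expr_a, rep_tx$expr_b,
                                      pseudocount),
    row.names = NULL
  )
}

#' Remove low-expression and abnormal-signal genes
#'
#' Drops genes whose abundance is below `min_expr` in both conditions, and
#' genes with |log2 fold-change| above `max_abs_log2fc` (abnormal signals of
#' the kind flagged on a volcano plot).
#'
#' @param de Gene-level table from [gene_de_table()].
#' @param min_expr Minimum abundance (FPKM) required in at least one
#'   condition.
#' @param max_abs_log2fc Maximum tolerated |log2fc|.
#' @return Filtered table; the number of removed genes is reported via
#'   `message()`.
#' @export
filter_outliers <- function(de, min_expr = 0.1, max_abs_log2fc = 10) {
  stopifnot(min_expr >= 0, max_abs_log2fc >= 0)
  low <- de$expr_a < min_expr & de$expr_b < min_expr
  extreme <- abs(de$log2fc) > max_abs_log2fc
  drop <- low | extreme
  if (any(drop))
    message(sum(drop), " gene(s) removed (", sum(low), " low-expression, ",
            sum(extreme), " extreme fold-change)")
  out <- de[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top fraction of genes by absolute log2 fold-change
#'
#' Returns the `k = max(1, floor(q * n))` gene ids with largest |log2fc|.
#' Boundary ties are broken by lexicographic gene id, so the selection is
#' deterministic.
#'
#' @param de Gene-level table with `gene_id` and `log2fc`.
#' @param q Fraction in (0, 1); the analysis default is 0.10.
#' @return Character vector of selected gene ids.
#' @export
top_fraction <- function(de, q = 0.1) {
  if (nrow(de) == 0) stop("empty gene table", call. = FALSE)
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  k <- max(1L, floor(q * nrow(de)))
  ord <- order(-abs(de$log2fc), de$gene_id)
  de$gene_id[ord[seq_len(k)]]
}
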