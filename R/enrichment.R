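#' Intersect the differential-expression and cohort gene universes
#'
#' The enrichment analysis is only meaningful on genes observed in both data
#' sets (the two-condition profile and the cohort matrix); all module sizes
#' and top-gene counts downstream are taken on this common universe.
#'
#' @param de_genes,cohort_genes Nonempty character vectors of gene ids.
#' @return Sorted character vector of the intersection.
#' @export
intersect_gene_universe <- function(de_genes, cohort_genes) {
  stopifnot(length(de_genes) > 0, length(cohort_genes) > 0)
  common <- sort(intersect(de_genes, cohort_genes))
  if (length(common) == 0)
    stop("empty intersection between DE and cohort gene universes",
         call. = FALSE)
  common
}

#' Exact upper-tail binomial probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim Binomial(n, q)}, by direct summation of
#' the tail terms in log space (summed in ascending magnitude for
#' stability). Monotone nonincreasing in `k` for fixed `n`, `q`.
#'
#' @param n Number of trials.
#' @param k Observed count, 0 <= k <= n.
#' @param q Success probability in (0, 1).
#' @return Probability in (0, 1].
#' @export
binomial_tail <- function(n, k, q) {
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  if (k == 0) return(1)
  i <- k:n
  terms <- exp(lchoose(n, i) + i * log(q) + (n - i) * log1p(-q))
  min(sum(sort(terms)), 1)
}

#' Score modules for over-representation of top differentially expressed genes
#'
#' If resistance-related genes were unrelated to the co-expression
#' structure, the top-fraction DE genes would fall uniformly across modules.
#' Each module is therefore tested for containing more than the background
#' fraction `q` of top genes with an upper-tail binomial test; the module
#' score is \eqn{-\ln p}, and the module-tumor correlation is carried along
#' as a companion coordinate. A module is flagged enriched when `p < alpha`
#' and its observed top-gene fraction exceeds `q`. Module 0 (unassigned) is
#' reported but never flagged.
#'
#' @param partition Named integer vector gene -> module, restricted to the
#'   common gene universe.
#' @param top_genes Character vector of top-DE gene ids (must be a subset of
#'   `names(partition)`).
#' @param trait_cor Optional long module-trait table from
#'   [module_trait_cor()]; its `tumor` rows populate `tumor_r`.
#' @param q Background fraction (the same top fraction used upstream).
#' @param alpha Significance level.
#' @return data.frame sorted by decreasing score: `module`, `n`, `k`,
#'   `frac`, `p_binom`, `score`, `tumor_r`, `enriched`.
#' @export
score_modules <- function(partition, top_genes, trait_cor = NULL,
                          q = 0.1, alpha = 0.05) {
  if (!all(top_genes %in% names(partition)))
    stop("top genes outside the module gene universe", call. = FALSE)
  if (q <= 0 || q >= 1 || alpha <= 0 || alpha >= 1)
    stop("q and alpha must be in (0, 1)", call. = FALSE)
  mods <- sort(unique(partition))
  top_mod <- partition[top_genes]
  out <- data.frame(module = mods,
                    n = as.integer(tabulate(match(partition, mods),
                                            length(mods))),
                    k = as.integer(tabulate(match(top_mod, mods),
                                            length(mods))))
  out$frac <- out$k / out$n
  out$p_binom <- mapply(binomial_tail, out$n, out$k, MoreArgs = list(q = q))
  out$score <- -log(out$p_binom)
  out$tumor_r <- NA_real_
  if (!is.null(trait_cor) && "tumor" %in% trait_cor$trait) {
    tum <- trait_cor[trait_cor$trait == "tumor", ]
    out$tumor_r <- tum$r[match(paste0("ME", out$module), tum$module)]
  }
  out$enriched <- out$module != 0L & out$p_binom < alpha & out$frac > q
  out <- out[order(-out$score, out$module), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prioritize candidate genes from enriched modules
#'
#' Candidates are the top-DE genes falling inside enriched modules, ordered
#' by (module score descending, |log2fc| descending, gene id ascending).
#'
#' @param enrichment Table from [score_modules()].
#' @param partition Named integer vector gene -> module (same universe).
#' @param de Gene-level DE table with `gene_id` and `log2fc`.
#' @param top_genes Character vector of top-DE gene ids.
#' @return data.frame: `rank`, `gene_id`, `module`, `module_score`,
#'   `abs_log2fc`. Empty (with a message) when no module is enriched.
#' @export
prioritize_genes <- function(enrichment, partition, de, top_genes) {
  enr <- enrichment[enrichment$enriched, , drop = FALSE]
  empty <- data.frame(rank = integer(), gene_id = character(),
                      module = integer(), module_score = numeric(),
                      abs_log2fc = numeric())
  if (nrow(enr) == 0) {
    message("no enriched modules; no candidates")
    return(empty)
  }
  cand <- top_genes[partition[top_genes] %in% enr$module]
  if (length(cand) == 0) {
    message("no candidates")
    return(empty)
  }
  mod <- partition[cand]
  score <- enr$score[match(mod, enr$module)]
  lfc <- abs(de$log2fc[match(cand, de$gene_id)])
  ord <- order(-score, -lfc, cand)
  data.frame(rank = seq_along(cand), gene_id = cand[ord],
             module = as.integer(mod[ord]), module_score = score[ord],
             abs_log2fc = lfc[ord], row.names = NULL)
}
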