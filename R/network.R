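#' Drop constant genes before correlation
#' @noRd
drop_constant_genes <- function(expr) {
  v <- apply(expr, 1, stats::var)
  const <- v == 0 | is.na(v)
  if (any(const)) {
    warning(sum(const), " constant gene(s) dropped before correlation",
            call. = FALSE)
    expr <- expr[!const, , drop = FALSE]
  }
  expr
}

#' Soft-threshold adjacency matrix
#'
#' Correlation-based weighted network adjacency. Unsigned:
#' \eqn{a_{ij} = |cor(x_i, x_j)|^\beta}; signed:
#' \eqn{a_{ij} = ((1 + cor)/2)^\beta}. The diagonal is 1.
#'
#' @param expr Genes x samples matrix (>= 3 samples).
#' @param power Soft-threshold power \eqn{\beta \ge 1}.
#' @param signed Use the signed transform.
#' @return Symmetric gene x gene matrix with entries in \[0, 1\].
#' @export
adjacency_matrix <- function(expr, power = 6, signed = FALSE) {
  if (ncol(expr) < 3) stop("need at least 3 samples", call. = FALSE)
  if (power < 1) stop("power must be >= 1", call. = FALSE)
  cc <- stats::cor(t(expr))
  a <- if (signed) ((1 + cc) / 2)^power else abs(cc)^power
  diag(a) <- 1
  a
}

#' Pick the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, builds the adjacency, computes connectivities
#' \eqn{k_i = \sum_{j \ne i} a_{ij}}, bins log10(k) against log10(frequency)
#' and fits a line. The scale-free fit index is the signed R-squared
#' (negated when the slope is positive, as a rising connectivity
#' distribution is not scale-free). Returns the smallest power whose fit
#' reaches `r2_target`; if none does, the power with the maximal fit is
#' returned with a warning.
#'
#' @param expr Genes x samples matrix.
#' @param candidate_powers Ascending positive integers to try.
#' @param r2_target Required signed R-squared (default 0.8).
#' @param signed Signed network (default unsigned).
#' @param n_breaks Number of connectivity bins.
#' @return Integer power with attribute `"fit"`: a data.frame of
#'   `power`, `r2`, `slope`, `mean_k`.
#' @export
pick_soft_threshold <- function(expr, candidate_powers = 1:20,
                                r2_target = 0.8, signed = FALSE,
                                n_breaks = 10) {
  stopifnot(length(candidate_powers) >= 1, all(diff(candidate_powers) > 0))
  if (ncol(expr) < 3 || nrow(expr) < 10)
    stop("need >= 3 samples and >= 10 genes", call. = FALSE)
  expr <- drop_constant_genes(expr)
  cc <- stats::cor(t(expr))
  base <- if (signed) (1 + cc) / 2 else abs(cc)
  diag(base) <- 0  # connectivity excludes the self-edge
  fit <- data.frame(power = candidate_powers, r2 = NA_real_,
                    slope = NA_real_, mean_k = NA_real_)
  for (i in seq_along(candidate_powers)) {
    k <- rowSums(base^candidate_powers[i])
    fit$mean_k[i] <- mean(k)
    sf <- scale_free_fit(k, n_breaks)
    fit$r2[i] <- sf["r2"]; fit$slope[i] <- sf["slope"]
  }
  ok <- which(fit$r2 >= r2_target)
  if (length(ok) > 0) {
    power <- candidate_powers[ok[1]]
  } else {
    power <- candidate_powers[which.max(fit$r2)]
    warning("no candidate power reached the scale-free fit target (",
            r2_target, "); returning the best fit (power = ", power, ")",
            call. = FALSE)
  }
  structure(as.integer(power), fit = fit)
}

#' Signed scale-free fit index of a connectivity vector
#' @noRd
scale_free_fit <- function(k, n_breaks = 10) {
  k <- k[k > 0]
  cuts <- cut(k, n_breaks)
  freq <- tapply(k, cuts, length)
  centers <- tapply(k, cuts, mean)
  keep <- !is.na(freq) & freq > 0
  x <- log10(centers[keep]); y <- log10(freq[keep])
  if (length(x) < 3 || stats::var(x) == 0)
    return(c(r2 = 0, slope = 0))
  fm <- stats::lm(y ~ x)
  slope <- stats::coef(fm)[[2]]
  r2 <- summary(fm)$r.squared
  c(r2 = -sign(slope) * r2, slope = slope)
}

#' Topological overlap matrix
#'
#' Similarity combining direct adjacency with shared-neighbor weight:
#' \deqn{TOM_{ij} = \frac{\ell_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}. The clustering dissimilarity is
#' `1 - TOM`.
#'
#' @param a Symmetric adjacency with unit diagonal and entries in \[0, 1\].
#' @return Symmetric TOM with unit diagonal, entries in \[0, 1\].
#' @export
topological_overlap <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-10))
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(a < 0) || any(a > 1 + 1e-12) || any(abs(diag(a) - 1) > 1e-12))
    stop("adjacency entries must be in [0, 1] with unit diagonal",
         call. = FALSE)
  # l_ij = sum_u a_iu a_uj - a_ii a_ij - a_ij a_jj = (A %*% A)_ij - 2 a_ij
  l <- a %*% a - 2 * a
  k <- rowSums(a) - 1
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  tom
}

#' Cluster genes into modules from the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, cut at a fixed
#' height. Clusters smaller than `min_module_size` are pooled into module 0
#' (the unassigned bucket, "ME0"); remaining modules are renumbered 1..k by
#' decreasing size (size ties broken by the original cut order), so the
#' labeling is deterministic.
#'
#' @param diss_tom Square symmetric dissimilarity with zero diagonal.
#' @param min_module_size Minimum genes per retained module (default 20).
#' @param cut_height Tree cut height on the dissimilarity scale. Unrelated
#'   genes merge at TOM dissimilarities close to 1 while coherent modules
#'   complete their merges well below it, so the default 0.9 (the static-cut
#'   convention) separates modules from the unassigned background across the
#'   usual soft-threshold range.
#' @return Named integer vector gene -> module (0 = unassigned) with
#'   attribute `"n_modules"`.
#' @export
cluster_modules <- function(diss_tom, min_module_size = 20,
                            cut_height = 0.9) {
  stopifnot(nrow(diss_tom) == ncol(diss_tom))
  if (cut_height <= 0 || cut_height > 1)
    stop("cut_height must be in (0, 1]", call. = FALSE)
  off <- diss_tom[upper.tri(diss_tom)]
  if (length(unique(round(off, 12))) == 1L)
    warning("degenerate dissimilarity (all pairs identical); ",
            "a single module results", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(diss_tom), method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- integer(length(raw))
  if (length(keep) > 0) {
    keep <- keep[order(-sizes[as.character(keep)], keep)]
    for (i in seq_along(keep)) labels[raw == keep[i]] <- i
  }
  names(labels) <- rownames(diss_tom)
  structure(labels, n_modules = length(keep))
}

#' Module eigengenes
#'
#' For each module the member genes are standardized (zero mean, unit
#' variance across samples) and the first principal component across samples
#' is taken as the module eigengene: a unit-norm sample profile summarizing
#' the module. Its sign is fixed so that its correlation with the module's
#' mean expression profile is nonnegative. The fraction of standardized
#' variance explained is recorded.
#'
#' @param expr Genes x samples matrix.
#' @param partition Named integer vector from [cluster_modules()]. Module 0
#'   (unassigned) also receives an eigengene when it has >= 2 genes, for
#'   reporting parity with assigned modules.
#' @return List: `me` (modules x samples matrix, rownames `ME<label>`) and
#'   `var_explained` (named numeric).
#' @export
module_eigengenes <- function(expr, partition) {
  stopifnot(all(names(partition) %in% rownames(expr)))
  mods <- sort(unique(partition))
  me <- matrix(NA_real_, nrow = length(mods), ncol = ncol(expr),
               dimnames = list(paste0("ME", mods), colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    genes <- names(partition)[partition == mods[i]]
    x <- expr[genes, , drop = FALSE]
    v <- apply(x, 1, stats::var)
    if (any(v == 0)) {
      warning("module ", mods[i], ": ", sum(v == 0),
              " zero-variance gene(s) dropped", call. = FALSE)
      x <- x[v > 0, , drop = FALSE]
    }
    if (nrow(x) < 2) stop("module ", mods[i], " has fewer than 2 usable genes",
                          call. = FALSE)
    xs <- t(scale(t(x)))  # standardize each gene across samples
    sv <- svd(t(xs), nu = 1, nv = 0)
    e <- sv$u[, 1]
    if (stats::cor(e, colMeans(xs)) < 0) e <- -e
    me[i, ] <- e
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(me = me, var_explained = ve)
}

#' Correlate module eigengenes with clinical traits
#'
#' Pearson correlation between each eigengene and each 0/1 trait over
#' pairwise-complete samples, with the two-sided p-value from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom.
#' Modules with `p >= alpha` against a trait are flagged not significant,
#' mirroring the "not sig" annotation of module-trait heatmaps.
#'
#' @param me Modules x samples eigengene matrix (from [module_eigengenes()]).
#' @param traits data.frame with `sample_id` and binary trait columns
#'   (NA allowed; excluded pairwise).
#' @param alpha Significance level for the flag (default 0.05).
#' @return Long data.frame: `module`, `trait`, `r`, `n`, `p`, `significant`.
#' @export
module_trait_cor <- function(me, traits, alpha = 0.05) {
  stopifnot("sample_id" %in% names(traits))
  traits <- traits[match(colnames(me), traits$sample_id), , drop = FALSE]
  trait_names <- setdiff(names(traits), "sample_id")
  out <- expand.grid(module = rownames(me), trait = trait_names,
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$n <- NA_integer_; out$p <- NA_real_
  for (i in seq_len(nrow(out))) {
    e <- me[out$module[i], ]
    tr <- traits[[out$trait[i]]]
    ok <- !is.na(tr) & !is.na(e)
    n <- sum(ok)
    if (n < 3) {
      warning("fewer than 3 complete samples for ", out$trait[i],
              call. = FALSE)
      next
    }
    if (stats::var(tr[ok]) == 0) {
      warning("trait '", out$trait[i], "' is constant; correlation undefined",
              call. = FALSE)
      next
    }
    r <- stats::cor(e[ok], tr[ok])
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    out$r[i] <- r; out$n[i] <- n
    out$p[i] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  out$significant <- !is.na(out$p) & out$p < alpha
  out
}
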