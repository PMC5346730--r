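#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic study generator.
#' The generator emulates the two data sources the prioritization pipeline
#' consumes: a patient cohort expression matrix with clinical traits and
#' survival follow-up, and a two-condition (parental vs. resistant)
#' transcript-level expression profile.
#'
#' The cohort follows a latent-factor model: genes in module \eqn{m} are
#' \eqn{x_{gs} = \lambda F_m(s) + \sigma \epsilon_{gs}} with \eqn{F_m} a
#' standard-normal factor per module, mean-shifted in trait-positive samples
#' for the traits listed in `trait_effects`; background genes are pure noise.
#'
#' @param n_genes Total number of genes.
#' @param n_samples Number of cohort samples.
#' @param module_sizes Integer vector of planted module sizes; their sum must
#'   not exceed `n_genes`. Remaining genes are unstructured background.
#' @param loading Factor loading \eqn{\lambda} in (0, 1].
#' @param noise_sd Noise standard deviation \eqn{\sigma \ge 0}; also the
#'   standard deviation of per-gene log2 fold-change noise in the
#'   differential-expression profile.
#' @param trait_effects Named list mapping a trait name (one of
#'   `"tumor"`, `"ER"`, `"PR"`, `"HER2"`) to `c(module, shift)`: the factor of
#'   that module is shifted by `shift` in trait-positive samples.
#' @param trait_prevalence Named numeric vector of Bernoulli trait
#'   probabilities.
#' @param her2_missing_rate Fraction of samples whose recorded HER2 status is
#'   missing (IHC/FISH calls are frequently unavailable in clinical tables).
#' @param de_module Index of the module from which planted differentially
#'   expressed (DE) genes are preferentially drawn.
#' @param n_de_genes Number of planted DE genes.
#' @param de_module_frac Fraction of planted DE genes drawn from `de_module`
#'   (capped at the module size; the remainder come from background genes).
#' @param de_log2fc Absolute log2 fold-change planted on DE genes.
#' @param target_log2fc_boost Multiplier applied to `de_log2fc` for the one
#'   designated target gene (the analysis' "KLK10 analog"), emulating a
#'   dominant resistance driver.
#' @param n_isoforms_range Length-2 integer vector, min and max isoforms per
#'   gene.
#' @param noncoding_frac Fraction of background genes given a non-coding
#'   biotype (exercises representative-transcript filtering).
#' @param dropout_rate Fraction of minor isoforms with zero abundance in
#'   condition A.
#' @param target_log_hr True log hazard ratio of the high-expression group of
#'   the target gene (per median-split group indicator).
#' @param censor_rate Fraction of subjects censored, in \[0, 1).
#' @param baseline_hazard Baseline hazard in events per day.
#' @param seed Integer seed; fully determines all generator output.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 500L,
                       n_samples = 444L,
                       module_sizes = rep(60L, 5L),
                       loading = 0.8,
                       noise_sd = 0.3,
                       trait_effects = list(
                         tumor = c(module = 1, shift = 1.5),
                         ER    = c(module = 2, shift = 1.0),
                         PR    = c(module = 2, shift = 0.8),
                         HER2  = c(module = 3, shift = 0.8)
                       ),
                       trait_prevalence = c(tumor = 0.5, ER = 0.6,
                                            PR = 0.5, HER2 = 0.3),
                       her2_missing_rate = 0.05,
                       de_module = 1L,
                       n_de_genes = 50L,
                       de_module_frac = 0.8,
                       de_log2fc = 2,
                       target_log2fc_boost = 1.5,
                       n_isoforms_range = c(1L, 4L),
                       noncoding_frac = 0.05,
                       dropout_rate = 0.01,
                       target_log_hr = log(1.2),
                       censor_rate = 0.3,
                       baseline_hazard = 1 / 1000,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    module_sizes = as.integer(module_sizes), loading = loading,
    noise_sd = noise_sd, trait_effects = trait_effects,
    trait_prevalence = trait_prevalence,
    her2_missing_rate = her2_missing_rate,
    de_module = as.integer(de_module), n_de_genes = as.integer(n_de_genes),
    de_module_frac = de_module_frac, de_log2fc = de_log2fc,
    target_log2fc_boost = target_log2fc_boost,
    n_isoforms_range = as.integer(n_isoforms_range),
    noncoding_frac = noncoding_frac, dropout_rate = dropout_rate,
    target_log_hr = target_log_hr, censor_rate = censor_rate,
    baseline_hazard = baseline_hazard, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1L, cfg$n_samples >= 2L)
  if (any(cfg$module_sizes < 1L))
    stop("module_sizes must all be >= 1", call. = FALSE)
  if (sum(cfg$module_sizes) > cfg$n_genes)
    stop("sum(module_sizes) exceeds n_genes", call. = FALSE)
  if (cfg$loading <= 0 || cfg$loading > 1)
    stop("loading must be in (0, 1]", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$de_module < 1L || cfg$de_module > length(cfg$module_sizes))
    stop("de_module is not a valid module index", call. = FALSE)
  n_background <- cfg$n_genes - sum(cfg$module_sizes)
  if (cfg$n_de_genes > cfg$module_sizes[cfg$de_module] + n_background)
    stop("n_de_genes exceeds de_module size plus background genes",
         call. = FALSE)
  if (length(cfg$n_isoforms_range) != 2L ||
      cfg$n_isoforms_range[1] < 1L ||
      cfg$n_isoforms_range[1] > cfg$n_isoforms_range[2])
    stop("n_isoforms_range must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  if (cfg$baseline_hazard <= 0)
    stop("baseline_hazard must be positive", call. = FALSE)
  for (tr in names(cfg$trait_effects)) {
    eff <- cfg$trait_effects[[tr]]
    if (!tr %in% names(cfg$trait_prevalence))
      stop("trait_effects names a trait with no prevalence: ", tr,
           call. = FALSE)
    if (eff[1] < 1 || eff[1] > length(cfg$module_sizes))
      stop("trait_effects for '", tr, "' points at a missing module",
           call. = FALSE)
  }
  invisible(cfg)
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))
sample_ids <- function(n) sprintf("s%04d", seq_len(n))

#' Generate a module-structured cohort expression matrix
#'
#' Draws a genes-by-samples expression matrix from the latent-factor model in
#' [sim_config()], together with binary clinical traits (tumor/normal, ER,
#' PR, HER2; HER2 may be recorded as `NA`) and the generating ground truth.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{expr}{numeric matrix, genes x samples, with dimnames.}
#'     \item{traits}{data.frame: `sample_id`, `tumor`, `ER`, `PR`, `HER2`
#'       (0/1, `HER2` may be `NA`).}
#'     \item{factors}{numeric matrix, modules x samples: the latent factors.}
#'     \item{truth}{list: `modules` (named integer vector, 0 = background),
#'       `biotype` (named character vector).}
#'   }
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_g <- config$n_genes; n_s <- config$n_samples
  n_mod <- length(config$module_sizes)
  gid <- gene_ids(n_g); sid <- sample_ids(n_s)

  # true (complete) trait values; HER2 masking happens at the end
  traits_true <- sapply(names(config$trait_prevalence), function(tr) {
    stats::rbinom(n_s, 1L, config$trait_prevalence[[tr]])
  })
  rownames(traits_true) <- sid

  factors <- matrix(stats::rnorm(n_mod * n_s), nrow = n_mod,
                    dimnames = list(paste0("F", seq_len(n_mod)), sid))
  for (tr in names(config$trait_effects)) {
    eff <- config$trait_effects[[tr]]
    factors[eff[1], ] <- factors[eff[1], ] + eff[2] * traits_true[, tr]
  }

  modules <- rep(0L, n_g)
  modules[seq_len(sum(config$module_sizes))] <-
    rep(seq_len(n_mod), config$module_sizes)
  names(modules) <- gid

  expr <- matrix(stats::rnorm(n_g * n_s, sd = config$noise_sd), nrow = n_g,
                 dimnames = list(gid, sid))
  assigned <- modules > 0L
  expr[assigned, ] <- expr[assigned, ] +
    config$loading * factors[modules[assigned], , drop = FALSE]

  # biotypes: planted-module genes are protein coding; a slice of the
  # background is non-coding to exercise the representative-transcript filter
  biotype <- rep("protein_coding", n_g)
  bg <- which(!assigned)
  n_nc <- floor(config$noncoding_frac * length(bg))
  if (n_nc > 0) {
    nc <- sample(bg, n_nc)
    biotype[nc] <- sample(c("lincRNA", "processed_pseudogene", "antisense"),
                          n_nc, replace = TRUE)
  }
  names(biotype) <- gid

  traits <- data.frame(sample_id = sid, traits_true,
                       row.names = NULL, check.names = FALSE)
  if (config$her2_missing_rate > 0 && "HER2" %in% names(traits)) {
    miss <- stats::runif(n_s) < config$her2_missing_rate
    traits$HER2[miss] <- NA_integer_
  }

  list(expr = expr, traits = traits, factors = factors,
       truth = list(modules = modules, biotype = biotype))
}

#' Generate a two-condition transcript-level expression profile
#'
#' Each gene receives 1 to `max(n_isoforms_range)` isoforms with distinct
#' lengths. Planted DE genes -- drawn preferentially from the `de_module` of
#' the cohort -- carry a log2 fold-change of \eqn{\pm}`de_log2fc` on their
#' dominant isoform between condition A (parental) and condition B
#' (resistant); every gene additionally receives multiplicative log2-scale
#' noise with standard deviation `noise_sd`. One planted DE gene inside
#' `de_module` is designated the target gene and gets a boosted fold-change.
#'
#' @param cohort A cohort list from [generate_cohort()].
#' @param config A [sim_config()].
#' @return A list with `transcripts` (data.frame: `transcript_id`, `gene_id`,
#'   `biotype`, `length_bp`, `expr_a`, `expr_b`) and `truth` (list:
#'   `de_genes`, `target_gene`, `de_log2fc` named vector of planted signed
#'   effects).
#' @export
generate_de_profile <- function(cohort, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  modules <- cohort$truth$modules
  biotype <- cohort$truth$biotype
  gid <- names(modules)

  mod_genes <- gid[modules == config$de_module]
  bg_genes <- gid[modules == 0L & biotype == "protein_coding"]
  n_from_mod <- min(round(config$de_module_frac * config$n_de_genes),
                    length(mod_genes))
  n_from_bg <- config$n_de_genes - n_from_mod
  if (n_from_bg > length(bg_genes))
    stop("n_de_genes exceeds available de_module plus background genes",
         call. = FALSE)
  de_genes <- c(sample(mod_genes, n_from_mod),
                if (n_from_bg > 0) sample(bg_genes, n_from_bg))
  target_gene <- de_genes[1L]  # first draw is inside de_module by design

  sign_g <- stats::setNames(sample(c(-1, 1), length(de_genes), replace = TRUE),
                            de_genes)
  sign_g[target_gene] <- 1
  planted <- stats::setNames(rep(0, length(gid)), gid)
  planted[de_genes] <- sign_g * config$de_log2fc
  planted[target_gene] <- config$de_log2fc * config$target_log2fc_boost

  n_iso <- sample(seq(config$n_isoforms_range[1], config$n_isoforms_range[2]),
                  length(gid), replace = TRUE)
  rows <- vector("list", length(gid))
  for (i in seq_along(gid)) {
    g <- gid[i]; k <- n_iso[i]
    len <- sample(seq(200L, 10000L), k)
    base <- stats::rlnorm(1, meanlog = 3, sdlog = 1)
    abun <- base * c(1, if (k > 1) stats::runif(k - 1, 0.05, 0.6))
    lfc <- stats::rnorm(k, 0, config$noise_sd)
    lfc[1] <- lfc[1] + planted[g]  # planted effect on the dominant isoform
    expr_a <- abun
    expr_b <- abun * 2^lfc
    if (k > 1 && planted[g] == 0 && stats::runif(1) < config$dropout_rate) {
      expr_a[k] <- 0  # designated dropout on a minor isoform
    }
    rows[[i]] <- data.frame(
      transcript_id = sprintf("%s.t%d", g, seq_len(k)),
      gene_id = g, biotype = biotype[g], length_bp = len,
      expr_a = expr_a, expr_b = expr_b, row.names = NULL
    )
  }
  transcripts <- do.call(rbind, rows)
  rownames(transcripts) <- NULL
  list(transcripts = transcripts,
       truth = list(de_genes = de_genes, target_gene = target_gene,
                    de_log2fc = planted[de_genes]))
}

#' Generate proportional-hazards survival data tied to a target gene
#'
#' Samples are split at the cohort median of the target gene's expression;
#' the high group's hazard is multiplied by `exp(target_log_hr)`. Event times
#' are exponential; independent exponential censoring is calibrated so each
#' subject is censored with probability `censor_rate`.
#'
#' @param cohort A cohort list from [generate_cohort()].
#' @param target_gene Gene id present in the cohort matrix.
#' @param config A [sim_config()].
#' @return data.frame: `sample_id`, `time_days`, `event` (1 = death observed).
#' @export
generate_survival <- function(cohort, target_gene, config) {
  validate_sim_config(config)
  if (!target_gene %in% rownames(cohort$expr))
    stop("target_gene not present in cohort", call. = FALSE)
  set.seed(config$seed + 2L)
  x <- cohort$expr[target_gene, ]
  high <- x >= stats::median(x)
  rate <- config$baseline_hazard * exp(config$target_log_hr * high)
  t_event <- stats::rexp(length(x), rate)
  if (config$censor_rate > 0) {
    # per-subject censoring hazard proportional to the event hazard, so
    # P(censored) = censor_rate exactly for every subject
    rate_c <- rate * config$censor_rate / (1 - config$censor_rate)
    t_cens <- stats::rexp(length(x), rate_c)
  } else {
    t_cens <- rep(Inf, length(x))
  }
  data.frame(sample_id = colnames(cohort$expr),
             time_days = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             row.names = NULL)
}

#' Simulate a complete study
#'
#' Runs [generate_cohort()], [generate_de_profile()] and
#' [generate_survival()] under one configuration and collects the ground
#' truth.
#'
#' @param config A [sim_config()].
#' @return List with `cohort`, `transcripts`, `survival` and `truth` (module
#'   labels, biotypes, DE gene set, target gene, planted effects, true log
#'   hazard ratio).
#' @export
simulate_study <- function(config = sim_config()) {
  cohort <- generate_cohort(config)
  de <- generate_de_profile(cohort, config)
  surv <- generate_survival(cohort, de$truth$target_gene, config)
  truth <- c(cohort$truth, de$truth, list(target_log_hr = config$target_log_hr))
  list(cohort = cohort, transcripts = de$transcripts, survival = surv,
       truth = truth)
}

#' Write a simulated study to plain-text files
#'
#' Writes the cohort matrix, trait table, survival table and transcript table
#' as TSV, and the ground truth as JSON, into `outdir`.
#'
#' @param sim Output of [simulate_study()].
#' @param outdir Directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expr = file.path(outdir, "cohort_expr.tsv"),
    traits = file.path(outdir, "traits.tsv"),
    survival = file.path(outdir, "survival.tsv"),
    transcripts = file.path(outdir, "transcripts.tsv"),
    truth = file.path(outdir, "ground_truth.json")
  )
  write_matrix_tsv(sim$cohort$expr, paths["expr"], id_col = "gene_id")
  write_tsv(sim$cohort$traits, paths["traits"])
  write_tsv(sim$survival, paths["survival"])
  write_tsv(sim$transcripts, paths["transcripts"])
  truth <- sim$truth
  truth$modules <- as.list(truth$modules)
  truth$biotype <- as.list(truth$biotype)
  truth$de_log2fc <- as.list(truth$de_log2fc)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
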