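#' Default pipeline configuration
#'
#' Nested list of every pipeline setting with its default. Exactly one of
#' the `simulation` block (synthetic study) or the `inputs` block (paths to
#' cohort/trait/survival/transcript TSVs) must be present in a resolved
#' configuration; the default carries the simulation block.
#'
#' @return Named list (see [validate_config()] for the schema).
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    q = 0.1,
    alpha = 0.05,
    pseudocount = 1,
    min_expr = 0.1,
    max_abs_log2fc = 10,
    simulation = unclass(sim_config()),
    inputs = NULL,
    network = list(
      # fixed conventional unsigned power for cohorts with > 40 samples;
      # supply a vector (e.g. 1:20) to enable the scale-free scan instead
      candidate_powers = 6L,
      r2_target = 0.8,
      signed = FALSE,
      min_module_size = 20,
      cut_height = 0.9
    ),
    survival = list(
      continuous = FALSE,
      n_candidates = 5L
    ),
    outdir = NULL
  )
}

#' Validate and resolve a pipeline configuration
#'
#' Accepts a YAML file path, a YAML string, or a list; unknown keys are
#' rejected (typo safety), fractions are range-checked and defaults are
#' filled in. The resolved configuration is echoed into the run report.
#'
#' @param config Path, YAML text, or list. `NULL` resolves to the defaults.
#' @return Resolved list of class `"pipeline_config"`.
#' @export
validate_config <- function(config = NULL) {
  if (is.null(config)) config <- list()
  if (is.character(config) && length(config) == 1) {
    config <- if (file.exists(config)) yaml::read_yaml(config) else
      yaml::yaml.load(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a list, path or YAML text",
                             call. = FALSE)
  def <- default_pipeline_config()
  check_keys <- function(x, ref, where) {
    unknown <- setdiff(names(x), names(ref))
    if (length(unknown) > 0)
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  check_keys(config, def, "top level")
  for (blk in c("simulation", "network", "survival"))
    if (!is.null(config[[blk]]))
      check_keys(config[[blk]], def[[blk]], blk)
  if (!is.null(config$inputs))
    check_keys(config$inputs,
               list(expr = NULL, traits = NULL, survival = NULL,
                    transcripts = NULL), "inputs")

  has_sim <- !is.null(config$simulation)
  has_inputs <- !is.null(config$inputs)
  if (has_sim && has_inputs)
    stop("config must contain either 'inputs' or 'simulation', not both",
         call. = FALSE)

  merge <- function(d, x) { d[names(x)] <- x; d }
  cfg <- merge(def, config)
  cfg$network <- merge(def$network, if (is.null(config$network)) list()
                       else config$network)
  cfg$survival <- merge(def$survival, if (is.null(config$survival)) list()
                        else config$survival)
  if (has_inputs) {
    cfg$simulation <- NULL
  } else {
    sim <- merge(unclass(sim_config()),
                 if (has_sim) config$simulation else list())
    if (!has_sim || is.null(config$simulation$seed)) sim$seed <- cfg$seed
    cfg$simulation <- do.call(sim_config, sim)
  }
  for (f in c("q", "alpha")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop("config field '", f, "' must be a fraction in (0, 1)",
           call. = FALSE)
  }
  if (cfg$pseudocount <= 0)
    stop("config field 'pseudocount' must be positive", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

read_pipeline_inputs <- function(paths) {
  for (f in c("expr", "traits", "survival", "transcripts"))
    if (is.null(paths[[f]]) || !file.exists(paths[[f]]))
      stop("input file for '", f, "' is missing", call. = FALSE)
  list(
    cohort = list(expr = read_matrix_tsv(paths$expr),
                  traits = read_tsv(paths$traits),
                  truth = NULL),
    transcripts = read_tsv(paths$transcripts),
    survival = read_tsv(paths$survival),
    truth = NULL
  )
}

#' Run the full target-prioritization pipeline
#'
#' Stages: (1) simulate or ingest the study data; (2) gene-level
#' differential expression with representative-transcript selection, outlier
#' filtering and top-fraction selection; (3) restrict to the common gene
#' universe and detect co-expression modules (soft threshold, TOM,
#' average-linkage clustering), with eigengenes and module-trait
#' correlations; (4) binomial enrichment scoring of modules against the top
#' DE genes and candidate prioritization; (5) survival validation of the
#' leading candidates. Identical configuration and seed give identical
#' outputs.
#'
#' @param config Anything accepted by [validate_config()].
#' @return A `"run_report"` list: per-stage counts, chosen power, module
#'   partition, eigengenes, module-trait table, enrichment table, candidate
#'   ranking, survival validation, the resolved config and (for simulated
#'   runs) the ground truth. When `config$outdir` is set, every intermediate
#'   table is also written there as TSV.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- validate_config(config)

  # stage 1: data
  if (!is.null(cfg$simulation)) {
    sim <- simulate_study(cfg$simulation)
    data <- sim
  } else {
    data <- read_pipeline_inputs(cfg$inputs)
  }
  expr <- data$cohort$expr

  # stage 2: differential expression
  de_all <- gene_de_table(data$transcripts, pseudocount = cfg$pseudocount)
  de <- suppressMessages(
    filter_outliers(de_all, cfg$min_expr, cfg$max_abs_log2fc)
  )

  # stage 3: common universe + co-expression network
  universe <- intersect_gene_universe(de$gene_id, rownames(expr))
  de_u <- de[de$gene_id %in% universe, , drop = FALSE]
  top <- top_fraction(de_u, cfg$q)
  de_u$top_flag <- de_u$gene_id %in% top
  expr_u <- expr[universe, , drop = FALSE]

  net <- cfg$network
  power <- pick_soft_threshold(expr_u, net$candidate_powers, net$r2_target,
                               net$signed)
  a <- adjacency_matrix(expr_u, power, net$signed)
  tom <- topological_overlap(a)
  partition <- cluster_modules(1 - tom, net$min_module_size, net$cut_height)
  eig <- module_eigengenes(expr_u, partition)
  trait_cor <- module_trait_cor(eig$me, data$cohort$traits, cfg$alpha)

  # stage 4: enrichment + prioritization
  enrichment <- score_modules(partition, top, trait_cor, cfg$q, cfg$alpha)
  ranking <- suppressMessages(
    prioritize_genes(enrichment, partition, de_u, top)
  )

  # stage 5: survival validation of the leading candidates
  n_val <- min(cfg$survival$n_candidates, nrow(ranking))
  surv_val <- validate_candidates(ranking[seq_len(n_val), , drop = FALSE],
                                  expr, data$survival,
                                  continuous = cfg$survival$continuous)

  report <- structure(list(
    seed = cfg$seed,
    counts = c(transcripts = nrow(data$transcripts),
               genes_de = nrow(de_all), genes_filtered = nrow(de),
               universe = length(universe), top_genes = length(top),
               candidates = nrow(ranking), validated = nrow(surv_val)),
    power = as.integer(power),
    power_fit = attr(power, "fit"),
    n_modules = attr(partition, "n_modules"),
    partition = partition,
    eigengenes = eig,
    trait_cor = trait_cor,
    de = de_u,
    enrichment = enrichment,
    ranking = ranking,
    survival_validation = surv_val,
    config = cfg,
    truth = data$truth
  ), class = "run_report")

  if (!is.null(cfg$outdir)) write_report(report, cfg$outdir)
  report
}

#' Write every pipeline intermediate as TSV
#' @param report A `"run_report"`.
#' @param outdir Directory (created if missing).
#' @return Invisibly, the output directory.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$de, file.path(outdir, "de_genes.tsv"))
  write_tsv(data.frame(gene_id = names(report$partition),
                       module = as.integer(report$partition)),
            file.path(outdir, "modules.tsv"))
  write_matrix_tsv(report$eigengenes$me, file.path(outdir, "eigengenes.tsv"),
                   id_col = "module")
  write_tsv(report$trait_cor, file.path(outdir, "module_trait.tsv"))
  write_tsv(report$enrichment, file.path(outdir, "enrichment.tsv"))
  write_tsv(report$ranking, file.path(outdir, "ranking.tsv"))
  write_tsv(report$survival_validation,
            file.path(outdir, "survival_validation.tsv"))
  invisible(outdir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Target-prioritization run (seed ", x$seed, ")\n", sep = "")
  cat("  stage counts: ",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n",
      sep = "")
  cat("  soft-threshold power: ", x$power, "; modules: ", x$n_modules,
      "\n", sep = "")
  enr <- x$enrichment[x$enrichment$enriched, , drop = FALSE]
  if (nrow(enr) > 0) {
    cat("  enriched modules:\n")
    for (i in seq_len(nrow(enr)))
      cat(sprintf("    ME%d: n=%d, k=%d, -ln(p)=%.1f, tumor r=%.2f\n",
                  enr$module[i], enr$n[i], enr$k[i], enr$score[i],
                  ifelse(is.na(enr$tumor_r[i]), NA, enr$tumor_r[i])))
  } else cat("  no enriched modules; no candidates\n")
  if (nrow(x$ranking) > 0) {
    top <- utils::head(x$ranking, 3)
    cat("  top candidates: ",
        paste(sprintf("%s (ME%d)", top$gene_id, top$module),
              collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$survival_validation) > 0) {
    sv <- x$survival_validation[1, ]
    cat(sprintf(
      "  lead candidate %s: HR %.3f (95%% CI %.3f-%.3f), %+.1f%% hazard, log-rank p %.4g\n",
      sv$gene_id, sv$hr, sv$ci_low, sv$ci_high, sv$percent_risk,
      sv$logrank_p))
  }
  invisible(x)
}
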