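#' Pipeline configuration
#'
#' Collects input paths, threshold/policy overrides, the model list and
#' run parameters for [run_pipeline()]. Also constructible from a YAML
#' file whose keys mirror the argument names (threshold and policy
#' overrides as nested maps).
#'
#' @param vcf,manifest,kinship,domains Input file paths (`kinship` and
#'   `domains` optional).
#' @param out_dir Output directory.
#' @param models Model names from [model_registry()] to run.
#' @param gene_sets Optional path(s) to gene-set files or a directory;
#'   `NULL` skips enrichment; `"builtin"` uses [als_gene_tiers()].
#' @param qc Named list of [qc_thresholds()] overrides.
#' @param policy Named list of [cluster_policy()] overrides.
#' @param n_permutations Permutations for the QQ/inflation stage (0
#'   skips it).
#' @param qq_models Models to calibrate (default: first of `models`).
#' @param alpha Study-wide significance level.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(vcf, manifest, kinship = NULL, domains = NULL,
                            out_dir = "rarecollapse_out",
                            models = c("ptv_missense",
                                       "ptv_missense_domain",
                                       "synonymous"),
                            gene_sets = NULL,
                            qc = list(), policy = list(),
                            n_permutations = 0,
                            qq_models = NULL,
                            alpha = 4.9e-7, seed = 1L) {
  for (field in c("vcf", "manifest")) {
    path <- get(field)
    if (is.null(path) || !is.character(path)) {
      abort(sprintf("pipeline config field `%s` is required", field))
    }
  }
  structure(
    list(vcf = vcf, manifest = manifest, kinship = kinship,
         domains = domains, out_dir = out_dir, models = models,
         gene_sets = gene_sets, qc = qc, policy = policy,
         n_permutations = n_permutations,
         qq_models = qq_models %||% models[1],
         alpha = alpha, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path Path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full collapsing analysis
#'
#' Stages in fixed order: read inputs, sample QC + relatedness pruning,
#' cluster pruning, variant/genotype QC, coverage harmonization,
#' qualifying-variant selection per model, collapsing + stratification +
#' exact CMH per model, optional permutation QQ/inflation, optional
#' gene-set enrichment. Every stage writes its TSV outputs under
#' `out_dir` and the run closes with a JSON manifest (config echo, input
#' hashes, seed, per-stage counts). Identical inputs, config and seed
#' reproduce identical result files.
#'
#' @param config A [pipeline_config()] (or a path to a YAML config).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  for (field in c("vcf", "manifest", "kinship", "domains")) {
    path <- config[[field]]
    if (!is.null(path) && !file.exists(path)) {
      abort(sprintf("pipeline config `%s`: file '%s' does not exist",
                    field, path))
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  counts <- list()

  cohort <- stage("read", read_cohort(config$vcf, config$manifest,
                                      config$kinship, config$domains))
  counts$n_variants_input <- nrow(cohort$variants)
  counts$n_samples_input <- nrow(cohort$samples)

  th <- do.call(qc_thresholds, config$qc)
  pol <- do.call(cluster_policy, config$policy)

  sqc <- stage("sample_qc",
               filter_samples(cohort$samples, cohort$kinship, th))
  readr::write_tsv(sqc$log, out("sample_exclusions.tsv"))
  cl <- stage("cluster_pruning", prune_clusters(sqc$samples, pol))
  readr::write_tsv(cl$clusters, out("clusters.tsv"))
  samples <- cl$samples
  counts$n_samples_analysis <- nrow(samples)
  counts$n_clusters <- sum(cl$clusters$retained)

  vqc <- stage("variant_qc",
               filter_variants(cohort$variants, cohort$genotypes, th))
  readr::write_tsv(vqc$audit, out("qc_audit.tsv"))
  counts$n_variants_retained <- nrow(vqc$variants)
  counts$n_genotypes_retained <- nrow(vqc$genotypes)

  pruned <- stage("coverage_harmonization", prune_sites(
    cohort$coverage, distinct(vqc$variants, .data$chrom, .data$pos),
    samples, pol))
  readr::write_tsv(pruned$removed, out("removed_sites.tsv"))
  counts$n_sites_removed <- nrow(pruned$removed)

  registry <- model_registry()
  unknown <- setdiff(config$models, names(registry))
  if (length(unknown)) {
    abort(sprintf("unknown model(s) in config: %s",
                  paste(unknown, collapse = ", ")))
  }
  matrices <- list()
  results <- list()
  for (mod in config$models) {
    qv <- stage(paste0("qualify_", mod), qualifying_variants(
      vqc$variants, vqc$genotypes, samples, registry[[mod]],
      domains = cohort$domains, removed_sites = pruned$removed))
    readr::write_tsv(qv$qualifying, out(sprintf("qv_%s.tsv", mod)))
    counts[[paste0("n_qv_", mod)]] <- nrow(qv$qualifying)
    if (!nrow(qv$qualifying)) next
    mat <- stage(paste0("collapse_", mod),
                 build_matrix(qv$qualifying, samples))
    matrices[[mod]] <- mat
    strat <- stratify(mat, samples)
    readr::write_tsv(strat, out(sprintf("strata_%s.tsv", mod)))
    res <- stage(paste0("test_", mod),
                 cmh_scan(strat, alpha = config$alpha)) |>
      mutate(model = mod, .after = "unit")
    readr::write_tsv(res, out(sprintf("results_%s.tsv", mod)))
    results[[mod]] <- res
  }

  qq <- list()
  if (config$n_permutations > 0) {
    for (mod in intersect(config$qq_models, names(matrices))) {
      q <- stage(paste0("qq_", mod), empirical_qq(
        matrices[[mod]], samples,
        n_permutations = config$n_permutations,
        seed = derive_seed(config$seed, paste0("qq_", mod))))
      readr::write_tsv(q$data, out(sprintf("qq_%s.tsv", mod)))
      writeLines(sprintf("%.6f", q$lambda),
                 out(sprintf("lambda_%s.txt", mod)))
      qq[[mod]] <- q
    }
  }

  tiers <- NULL
  if (!is.null(config$gene_sets)) {
    sets <- if (identical(config$gene_sets, "builtin")) {
      als_gene_tiers()
    } else {
      read_gene_sets(config$gene_sets)
    }
    tier_models <- intersect(c("ptv", "ptv_missense", "missense",
                               "synonymous"), names(matrices))
    if (length(tier_models)) {
      tiers <- stage("geneset", run_tiers(matrices, sets,
                                          models = tier_models,
                                          samples = samples))
      readr::write_tsv(tiers, out("geneset_results.tsv"))
    }
  }

  inputs <- purrr::compact(config[c("vcf", "manifest", "kinship",
                                    "domains")])
  manifest <- list(
    package = "rarecollapse",
    version = as.character(utils::packageVersion("rarecollapse")),
    seed = config$seed,
    config = config[setdiff(names(config), NULL)],
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    counts = counts
  )
  jsonlite::write_json(manifest, out("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(samples = samples, results = results,
                 matrices = matrices, qq = qq, tiers = tiers,
                 manifest = manifest, out_dir = config$out_dir))
}
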