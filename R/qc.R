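#' Quality-control thresholds
#'
#' Defaults encode the cohort's published filter set: site quality >= 50,
#' quality-by-depth >= 5, genotype quality >= 20, read position rank sum
#' >= -3, mapping quality >= 40, mapping quality rank sum > -10 (strict),
#' depth >= 10, Fisher strand bias <= 60 for SNVs and <= 200 for indels,
#' heterozygous allele balance >= 0.30, VQSR tranche in {PASS,
#' VQSRTrancheSNP90.00to99.00, VQSRTrancheSNP99.00to99.90}, sample
#' contamination <= 2% (strictly more than 2% excludes) and CCDS coverage
#' >= 90%.
#'
#' @param ... Named overrides of any threshold listed above.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(...) {
  th <- list(
    min_qual = 50,
    min_qd = 5,
    min_gq = 20,
    min_read_pos_rank_sum = -3,
    min_mq = 40,
    min_mq_rank_sum_exclusive = -10,
    min_depth = 10,
    max_fs_snv = 60,
    max_fs_indel = 200,
    min_het_allele_balance = 0.30,
    allowed_vqsr = c("PASS", "VQSRTrancheSNP90.00to99.00",
                     "VQSRTrancheSNP99.00to99.90"),
    max_contamination = 0.02,
    min_ccds_coverage = 0.90
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(th))
  if (length(unknown)) {
    abort(sprintf("unknown QC threshold(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  th[names(dots)] <- dots
  structure(th, class = "qc_thresholds")
}

#' Sample-level quality control and relatedness pruning
#'
#' Excludes samples with contamination strictly above 2% or CCDS coverage
#' strictly below 90%, then resolves relatedness: from every related pair
#' of degree <= 2 exactly one member is excluded, preferring to retain
#' cases. Third-degree pairs are unrestricted. Pruning is greedy and
#' deterministic: repeatedly remove the sample maximizing (is-control,
#' number of remaining degree-<=2 partners, sample id) until no such pair
#' remains.
#'
#' @param samples Sample manifest tibble (`sample_id`, `phenotype`,
#'   `cluster`, `contamination`, `ccds_coverage`).
#' @param kinship Tibble of related pairs (`id1`, `id2`, `degree`); degrees
#'   must be 1, 2 or 3 and ids must appear in `samples`.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `samples` (retained rows) and `log` (one row per
#'   excluded sample: `sample_id`, `reason`).
#' @export
filter_samples <- function(samples, kinship = NULL,
                           thresholds = qc_thresholds()) {
  assert_columns(samples, c("sample_id", "phenotype", "contamination",
                            "ccds_coverage"), "samples")
  if (is.null(kinship)) {
    kinship <- tibble(id1 = character(), id2 = character(),
                      degree = integer())
  }
  if (nrow(kinship)) {
    ids <- c(kinship$id1, kinship$id2)
    unknown <- setdiff(ids, samples$sample_id)
    if (length(unknown)) {
      abort(sprintf("kinship references unknown sample(s): %s",
                    paste(head(unknown, 5), collapse = ", ")))
    }
    if (!all(kinship$degree %in% 1:3)) {
      abort("kinship `degree` must be 1, 2 or 3")
    }
  }
  log <- tibble(sample_id = character(), reason = character())
  bad_cont <- samples$contamination > thresholds$max_contamination
  bad_ccds <- samples$ccds_coverage < thresholds$min_ccds_coverage
  log <- bind_rows(
    tibble(sample_id = samples$sample_id[bad_cont],
           reason = "contamination"),
    tibble(sample_id = samples$sample_id[bad_ccds & !bad_cont],
           reason = "ccds_coverage")
  )
  keep <- samples[!(bad_cont | bad_ccds), ]

  edges <- kinship |>
    filter(.data$degree <= 2,
           .data$id1 %in% keep$sample_id,
           .data$id2 %in% keep$sample_id)
  while (nrow(edges)) {
    deg <- c(table(c(edges$id1, edges$id2)))
    cand <- tibble(sample_id = names(deg), n_edges = as.integer(deg)) |>
      left_join(select(keep, "sample_id", "phenotype"), by = "sample_id") |>
      arrange(desc(.data$phenotype == "control"), desc(.data$n_edges),
              desc(.data$sample_id))
    drop_id <- cand$sample_id[1]
    log <- bind_rows(log, tibble(sample_id = drop_id,
                                 reason = "relatedness"))
    keep <- filter(keep, .data$sample_id != drop_id)
    edges <- filter(edges, .data$id1 != drop_id, .data$id2 != drop_id)
  }
  list(samples = keep, log = log)
}

# name of the first TRUE column per row of a logical matrix (NA if none)
first_true <- function(m) {
  if (!nrow(m)) return(character(0))
  idx <- max.col(cbind(m, TRUE), ties.method = "first")
  out <- colnames(m)[idx]
  out[idx > ncol(m)] <- NA_character_
  out
}

# fixed audit order: site-level rules first, then genotype-level rules
QC_RULE_ORDER <- c("qual", "qd", "read_pos_rank_sum", "mq", "mq_rank_sum",
                   "fs", "vqsr_tranche", "external_fail_flag",
                   "in_ccds_or_splice", "gq", "depth", "allele_balance")

#' Variant- and genotype-level quality control
#'
#' A carrier genotype is retained iff its variant passes every site-level
#' rule and the genotype passes every genotype-level rule. Missing
#' rank-sum statistics pass (they are only emitted when computable).
#' The audit partitions every excluded genotype by its first failing rule
#' in the fixed order: qual, qd, read_pos_rank_sum, mq, mq_rank_sum, fs,
#' vqsr_tranche, external_fail_flag, in_ccds_or_splice, gq, depth,
#' allele_balance.
#'
#' @param variants Variant tibble (site-level fields).
#' @param genotypes Carrier genotype tibble (`variant_id`, `sample_id`,
#'   `gt`, `dp`, `gq`, `ab`).
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `variants` (site-passing variants), `genotypes`
#'   (fully retained carrier genotypes) and `audit` (tibble `rule`,
#'   `n_genotypes` over the fixed rule order).
#' @export
filter_variants <- function(variants, genotypes,
                            thresholds = qc_thresholds()) {
  th <- thresholds
  assert_columns(variants, c("variant_id", "variant_class", "qual", "qd",
                             "read_pos_rank_sum", "mq", "mq_rank_sum",
                             "fs", "vqsr_tranche", "external_fail_flag",
                             "in_ccds_or_splice"), "variants")
  pass_na <- function(x, ok) is.na(x) | ok
  site_fail <- cbind(
    qual = !(variants$qual >= th$min_qual),
    qd = !(variants$qd >= th$min_qd),
    read_pos_rank_sum = !pass_na(
      variants$read_pos_rank_sum,
      variants$read_pos_rank_sum >= th$min_read_pos_rank_sum),
    mq = !(variants$mq >= th$min_mq),
    mq_rank_sum = !pass_na(
      variants$mq_rank_sum,
      variants$mq_rank_sum > th$min_mq_rank_sum_exclusive),
    fs = !(variants$fs <= ifelse(variants$variant_class == "indel",
                                 th$max_fs_indel, th$max_fs_snv)),
    vqsr_tranche = !(variants$vqsr_tranche %in% th$allowed_vqsr),
    external_fail_flag = variants$external_fail_flag,
    in_ccds_or_splice = !variants$in_ccds_or_splice
  )
  site_fail[is.na(site_fail)] <- TRUE
  first_site_fail <- first_true(site_fail)
  variants$`.first_fail` <- first_site_fail
  site_pass_ids <- variants$variant_id[is.na(first_site_fail)]

  g <- genotypes |>
    left_join(select(variants, "variant_id", ".first_fail"),
              by = "variant_id")
  is_het <- g$gt %in% c("0/1", "1/0", "0|1", "1|0")
  geno_fail <- cbind(
    gq = !(g$gq >= th$min_gq),
    depth = !(g$dp >= th$min_depth),
    allele_balance = is_het & !(g$ab >= th$min_het_allele_balance)
  )
  geno_fail[is.na(geno_fail)] <- TRUE
  first_geno_fail <- first_true(geno_fail)
  reason <- ifelse(!is.na(g$`.first_fail`), g$`.first_fail`,
                   first_geno_fail)
  retained <- g[is.na(reason), setdiff(names(g), ".first_fail")]
  audit <- tibble(rule = QC_RULE_ORDER) |>
    left_join(
      tibble(rule = reason[!is.na(reason)]) |> count(.data$rule),
      by = "rule"
    ) |>
    mutate(n_genotypes = tidyr::replace_na(.data$n, 0L)) |>
    select("rule", "n_genotypes")
  variants$`.first_fail` <- NULL
  list(
    variants = filter(variants, .data$variant_id %in% site_pass_ids),
    genotypes = as_tibble(retained),
    audit = audit
  )
}
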