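test_that("null configuration has all truth odds ratios equal to one", {
  co <- tiny_cohort(seed = 7)
  expect_true(all(co$truth$genes$planted_or == 1))
  expect_false(any(co$truth$genes$planted))
})

test_that("planted carrier rates are recovered within binomial sampling error", {
  rate <- 0.013
  co <- simulate_cohort(sim_config(
    n_cases = 4000, n_controls = 4000, n_genes = 10, seed = 21,
    planted_genes = list(planted_gene("PG", "missense", rate, 0.0008))
  ))
  miss_sites <- co$variants |>
    filter(.data$gene == "PG", .data$effect == "missense_variant")
  carriers <- co$genotypes |>
    filter(.data$variant_id %in% miss_sites$variant_id) |>
    inner_join(select(co$samples, "sample_id", "phenotype"),
               by = "sample_id") |>
    filter(.data$phenotype == "case") |>
    distinct(.data$sample_id)
  n_cases <- sum(co$samples$phenotype == "case")
  sd3 <- 3 * sqrt(rate * (1 - rate) / n_cases)
  expect_lt(abs(nrow(carriers) / n_cases - rate), sd3)
})

test_that("identical seeds give byte-identical fixture bundles", {
  build <- function() simulate_cohort(sim_config(
    n_cases = 20, n_controls = 30, n_genes = 6, seed = 99,
    qc_failure_rate = 0.2, n_related_pairs = 2,
    artifact_sites = list(list(case_coverage_pct = 70,
                               control_coverage_pct = 100))
  ))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixture_bundle(build(), d1)
  p2 <- write_fixture_bundle(build(), d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[f]), readLines(p2[f]), label = f)
  }
})

test_that("cluster assignments conserve arm totals exactly", {
  cl <- tibble(name = c("a", "b", "c", "d"),
               case_frac = c(0.41, 0.29, 0.17, 0.13),
               control_frac = c(0.55, 0.25, 0.12, 0.08))
  co <- simulate_cohort(sim_config(n_cases = 103, n_controls = 207,
                                   clusters = cl, n_genes = 3, seed = 1))
  counts <- count(co$samples, .data$phenotype)
  expect_equal(counts$n[counts$phenotype == "case"], 103)
  expect_equal(counts$n[counts$phenotype == "control"], 207)
  expect_setequal(unique(co$samples$cluster), cl$name)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(n_cases = -1, n_controls = 10), "n_cases")
  expect_error(sim_config(n_cases = 10, n_controls = 10,
                          background_carrier_rate = 1.5),
               "background_carrier_rate")
  bad_cl <- tibble(name = "x", case_frac = 0.7, control_frac = 1)
  expect_error(sim_config(n_cases = 5, n_controls = 5, clusters = bad_cl),
               "case_frac")
  expect_error(planted_gene("G", "missense", 2, 0.1), "rates")
  expect_error(
    sim_config(n_cases = 5, n_controls = 5,
               planted_genes = list(planted_gene("G", "missense", .1, .1),
                                    planted_gene("G", "PTV", .1, .1))),
    "unique")
})

test_that("an empty cohort writes a valid header-only VCF", {
  co <- simulate_cohort(sim_config(n_cases = 0, n_controls = 0,
                                   n_genes = 0, seed = 5))
  d <- withr::local_tempdir()
  paths <- write_fixture_bundle(co, d)
  lines <- readLines(paths["vcf"])
  expect_true(all(startsWith(lines, "#")))
  expect_match(lines[1], "VCFv4.2", fixed = TRUE)
  rc <- read_cohort(paths["vcf"], paths["manifest"])
  expect_identical(nrow(rc$variants), 0L)
})

test_that("planted artifact sites are flagged in the truth table", {
  co <- simulate_cohort(sim_config(
    n_cases = 30, n_controls = 30, n_genes = 8, seed = 13,
    artifact_sites = list(
      list(case_coverage_pct = 60, control_coverage_pct = 100),
      list(case_coverage_pct = 100, control_coverage_pct = 55)
    )
  ))
  expect_identical(sum(co$truth$sites$artifact), 2L)
  # artifact plumbing produced low-coverage rows for the affected sites
  art_ids <- co$truth$sites$variant_id[co$truth$sites$artifact]
  expect_true(all(art_ids %in% co$coverage$variant_id))
})

test_that("planted QC failures carry the violating field value", {
  co <- simulate_cohort(sim_config(n_cases = 10, n_controls = 10,
                                   n_genes = 30, seed = 17,
                                   qc_failure_rate = 0.3))
  flagged <- co$truth$sites |> filter(!is.na(.data$qc_rule))
  expect_gt(nrow(flagged), 0)
  th <- qc_thresholds()
  for (i in seq_len(nrow(flagged))) {
    v <- co$variants[co$variants$variant_id == flagged$variant_id[i], ]
    ok <- switch(flagged$qc_rule[i],
      qual = v$qual < th$min_qual,
      qd = v$qd < th$min_qd,
      read_pos_rank_sum = v$read_pos_rank_sum < th$min_read_pos_rank_sum,
      mq = v$mq < th$min_mq,
      mq_rank_sum = v$mq_rank_sum <= th$min_mq_rank_sum_exclusive,
      fs = v$fs > ifelse(v$variant_class == "indel", th$max_fs_indel,
                         th$max_fs_snv),
      vqsr_tranche = !(v$vqsr_tranche %in% th$allowed_vqsr),
      in_ccds_or_splice = !v$in_ccds_or_splice,
      external_fail_flag = v$external_fail_flag
    )
    expect_true(ok, label = flagged$qc_rule[i])
  }
})

test_that("variant allele counts are consistent with emitted genotypes", {
  co <- tiny_cohort(seed = 31, n_cases = 100, n_controls = 100)
  # every carrier genotype references an existing variant and sample
  expect_true(all(co$genotypes$variant_id %in% co$variants$variant_id))
  expect_true(all(co$genotypes$sample_id %in% co$samples$sample_id))
  expect_true(all(co$genotypes$ab > 0 & co$genotypes$ab < 1))
  expect_true(all(co$genotypes$alt_reads <= co$genotypes$dp))
})
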