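test_that("contamination and CCDS-coverage bounds behave as printed", {
  s <- manifest_fixture(4)
  s$contamination <- c(0.021, 0.020, 0.001, 0.001)
  s$ccds_coverage <- c(0.99, 0.99, 0.899, 0.900)
  res <- filter_samples(s)
  expect_setequal(res$samples$sample_id, c("S02", "S04"))
  expect_identical(
    res$log$reason[res$log$sample_id == "S01"], "contamination")
  expect_identical(
    res$log$reason[res$log$sample_id == "S03"], "ccds_coverage")
})

test_that("relatedness pruning keeps one of each close pair, preferring cases", {
  s <- manifest_fixture(6)   # S01 case, S02 control, ...
  kin <- tibble(id1 = c("S01", "S03"), id2 = c("S02", "S04"),
                degree = c(2L, 3L))
  res <- filter_samples(s, kin)
  # degree-2 case/control pair: control S02 excluded, case S01 kept
  expect_true("S01" %in% res$samples$sample_id)
  expect_false("S02" %in% res$samples$sample_id)
  expect_identical(res$log$reason[res$log$sample_id == "S02"],
                   "relatedness")
  # degree-3 pair: both retained
  expect_true(all(c("S03", "S04") %in% res$samples$sample_id))
})

test_that("relatedness pruning is deterministic on chains and case-case pairs", {
  s <- manifest_fixture(4)
  s$phenotype <- c("case", "case", "case", "case")
  kin <- tibble(id1 = c("S01", "S02"), id2 = c("S02", "S03"),
                degree = c(1L, 2L))
  res <- filter_samples(s, kin)
  # S02 has two close partners: removing it resolves both edges
  expect_setequal(res$samples$sample_id, c("S01", "S03", "S04"))
  # exactly one exclusion with exactly one reason each
  expect_identical(nrow(res$log), 1L)
})

test_that("kinship rows naming unknown samples error", {
  s <- manifest_fixture(2)
  expect_error(
    filter_samples(s, tibble(id1 = "S01", id2 = "NOPE", degree = 1L)),
    "unknown")
})

test_that("every QC threshold flips at its printed boundary", {
  th <- qc_thresholds()
  site_cases <- list(
    list(field = "qual", pass = 50, fail = 49.99),
    list(field = "qd", pass = 5, fail = 4.99),
    list(field = "read_pos_rank_sum", pass = -3, fail = -3.01),
    list(field = "mq", pass = 40, fail = 39.99),
    # strict: exactly -10 fails, just above passes
    list(field = "mq_rank_sum", pass = -9.99, fail = -10),
    list(field = "fs", pass = 60, fail = 60.01),
    list(field = "vqsr_tranche", pass = "VQSRTrancheSNP99.00to99.90",
         fail = "VQSRTrancheSNP99.90to100.00"),
    list(field = "external_fail_flag", pass = FALSE, fail = TRUE),
    list(field = "in_ccds_or_splice", pass = TRUE, fail = FALSE)
  )
  g <- genotype_fixture()
  for (case in site_cases) {
    v_pass <- do.call(variant_fixture, setNames(list(case$pass), case$field))
    v_fail <- do.call(variant_fixture, setNames(list(case$fail), case$field))
    expect_identical(nrow(filter_variants(v_pass, g, th)$genotypes), 1L,
                     label = paste(case$field, "pass"))
    res <- filter_variants(v_fail, g, th)
    expect_identical(nrow(res$genotypes), 0L,
                     label = paste(case$field, "fail"))
    expect_identical(
      res$audit$n_genotypes[res$audit$rule == case$field], 1L,
      label = paste(case$field, "audit"))
  }
  geno_cases <- list(
    list(field = "gq", pass = 20L, fail = 19L),
    list(field = "dp", pass = 10L, fail = 9L, rule = "depth"),
    list(field = "ab", pass = 0.30, fail = 0.29, rule = "allele_balance")
  )
  v <- variant_fixture()
  for (case in geno_cases) {
    rule <- case$rule %||% case$field
    g_pass <- genotype_fixture(); g_pass[[case$field]] <- case$pass
    g_fail <- genotype_fixture(); g_fail[[case$field]] <- case$fail
    expect_identical(nrow(filter_variants(v, g_pass, th)$genotypes), 1L,
                     label = paste(rule, "pass"))
    res <- filter_variants(v, g_fail, th)
    expect_identical(nrow(res$genotypes), 0L, label = paste(rule, "fail"))
    expect_identical(res$audit$n_genotypes[res$audit$rule == rule], 1L)
  }
})

test_that("indels get the relaxed strand-bias bound", {
  g <- genotype_fixture()
  snv <- variant_fixture(fs = 61)
  indel <- variant_fixture(fs = 61, variant_class = "indel",
                           ref = "AT", alt = "A",
                           effect = "frameshift_variant")
  expect_identical(nrow(filter_variants(snv, g)$genotypes), 0L)
  expect_identical(nrow(filter_variants(indel, g)$genotypes), 1L)
  indel_fail <- variant_fixture(fs = 200.5, variant_class = "indel")
  expect_identical(nrow(filter_variants(indel_fail, g)$genotypes), 0L)
})

test_that("allele-balance applies to heterozygous genotypes only", {
  v <- variant_fixture()
  hom <- genotype_fixture(gt = "1/1", ab = 1.0)
  hom$ab <- NA_real_  # hom-alt AD often gives no ref reads
  expect_identical(nrow(filter_variants(v, hom)$genotypes), 1L)
  het_low <- genotype_fixture(gt = "0/1", ab = 0.29)
  expect_identical(nrow(filter_variants(v, het_low)$genotypes), 0L)
})

test_that("missing rank-sum statistics pass the filter", {
  g <- genotype_fixture()
  v <- variant_fixture(read_pos_rank_sum = NA_real_,
                       mq_rank_sum = NA_real_)
  expect_identical(nrow(filter_variants(v, g)$genotypes), 1L)
})

test_that("filtering is idempotent and the audit partitions exclusions", {
  co <- simulate_cohort(sim_config(n_cases = 50, n_controls = 80,
                                   n_genes = 40, seed = 23,
                                   qc_failure_rate = 0.3))
  # add some genotype-level failures by hand
  g <- co$genotypes
  g$gq[seq_len(min(5, nrow(g)))] <- 5L
  r1 <- filter_variants(co$variants, g)
  expect_identical(sum(r1$audit$n_genotypes),
                   nrow(g) - nrow(r1$genotypes))
  r2 <- filter_variants(r1$variants, r1$genotypes)
  expect_equal(as.data.frame(r2$genotypes), as.data.frame(r1$genotypes))
  expect_equal(as.data.frame(r2$variants), as.data.frame(r1$variants))
  expect_identical(sum(r2$audit$n_genotypes), 0L)
})
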