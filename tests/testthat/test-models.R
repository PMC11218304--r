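qv_setup <- function(n_samples = 2000) {
  samples <- tibble(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    phenotype = rep(c("case", "control"), length.out = n_samples),
    cluster = "cl1"
  )
  domains <- tibble(
    gene = "G1", transcript = "TX_G1", chrom = "1",
    start = c(1L, 501L), end = c(500L, 1000L),
    subrvis_percentile = c(10, 80)
  )
  list(samples = samples, domains = domains)
}

test_that("the registry ships six nonsynonymous models plus the synonymous control", {
  reg <- model_registry()
  expect_length(reg, 7)
  domain_models <- names(reg)[vapply(reg, function(m) {
    !is.null(m$subrvis_max_percentile)
  }, TRUE)]
  expect_length(domain_models, 3)
  expect_identical(reg$synonymous$effect_classes, "synonymous_variant")
  expect_null(reg$synonymous$subrvis_max_percentile)
  expect_error(model_registry(extra = list(model_spec("ptv", "stop_gained"))),
               "duplicate")
})

test_that("internal allele frequency counts alleles over called chromosomes", {
  g3 <- bind_rows(lapply(1:3, function(i) {
    genotype_fixture(sample_id = sprintf("S%02d", i))
  }))
  af <- internal_af(g3, n_samples = 10000)
  expect_equal(af$internal_af, 3 / 20000)
  # a single homozygous carrier among 1,000 called samples: AF exactly 0.1%
  hom <- genotype_fixture(gt = "1/1")
  af_hom <- internal_af(hom, n_samples = 1000)
  expect_equal(af_hom$internal_af, 1e-3)
})

test_that("the internal-AF gate is strict at 0.1%", {
  samples <- qv_setup(1000)$samples
  v <- variant_fixture()
  hom <- genotype_fixture(gt = "1/1")   # AF exactly 1e-3: must fail
  res <- qualifying_variants(v, hom, samples, model_registry()$missense)
  expect_identical(nrow(res$qualifying), 0L)
  het <- genotype_fixture(gt = "0/1")   # AF 5e-4: passes
  res2 <- qualifying_variants(v, het, samples, model_registry()$missense)
  expect_identical(nrow(res2$qualifying), 1L)
})

test_that("a single gnomAD population at or above 0.1% disqualifies", {
  fx <- qv_setup()
  g <- genotype_fixture()
  v_bad <- variant_fixture(gnomad_af_eas = 0.002)
  res <- qualifying_variants(v_bad, g, fx$samples, model_registry()$missense)
  expect_identical(nrow(res$qualifying), 0L)
  expect_identical(
    res$audit$n_variants[res$audit$gate == "gnomad_af"], 1L)
  v_edge <- variant_fixture(gnomad_af_eas = 0.001)   # boundary: >= fails
  expect_identical(
    nrow(qualifying_variants(v_edge, g, fx$samples,
                             model_registry()$missense)$qualifying), 0L)
  v_ok <- variant_fixture(gnomad_af_eas = 0.00099)
  expect_identical(
    nrow(qualifying_variants(v_ok, g, fx$samples,
                             model_registry()$missense)$qualifying), 1L)
})

test_that("the subRVIS restriction is strict at the percentile threshold", {
  fx <- qv_setup()
  g <- genotype_fixture()
  model <- model_registry()$missense_domain
  # domain percentile 10 (pos 100): qualifies
  v_in <- variant_fixture(pos = 100L)
  expect_identical(
    nrow(qualifying_variants(v_in, g, fx$samples, model,
                             domains = fx$domains)$qualifying), 1L)
  # tolerant domain (percentile 80, pos 600): does not qualify
  v_out <- variant_fixture(pos = 600L, variant_id = "1:600:A:T")
  g_out <- genotype_fixture(variant_id = "1:600:A:T")
  res <- qualifying_variants(v_out, g_out, fx$samples, model,
                             domains = fx$domains)
  expect_identical(nrow(res$qualifying), 0L)
  # strictness at exactly the threshold
  dom25 <- fx$domains
  dom25$subrvis_percentile <- c(25, 80)
  expect_identical(
    nrow(qualifying_variants(v_in, g, fx$samples, model,
                             domains = dom25)$qualifying), 0L)
  dom249 <- fx$domains
  dom249$subrvis_percentile <- c(24.9, 80)
  expect_identical(
    nrow(qualifying_variants(v_in, g, fx$samples, model,
                             domains = dom249)$qualifying), 1L)
  # position covered by no interval: unannotated audit bin
  v_off <- variant_fixture(pos = 5000L, variant_id = "1:5000:A:T")
  g_off <- genotype_fixture(variant_id = "1:5000:A:T")
  res_off <- qualifying_variants(v_off, g_off, fx$samples, model,
                                 domains = fx$domains)
  expect_identical(nrow(res_off$qualifying), 0L)
  expect_identical(
    res_off$audit$n_variants[res_off$audit$gate == "unannotated"], 1L)
})

test_that("model algebra holds on a simulated cohort", {
  co <- tiny_cohort(seed = 37, n_cases = 500, n_controls = 700,
                    n_genes = 30)
  vqc <- filter_variants(co$variants, co$genotypes)
  reg <- model_registry()
  run <- function(m) {
    qualifying_variants(vqc$variants, vqc$genotypes, co$samples, reg[[m]],
                        domains = co$domains)$qualifying
  }
  ptv <- run("ptv"); mis <- run("missense"); both <- run("ptv_missense")
  syn <- run("synonymous"); dom <- run("ptv_missense_domain")
  key <- function(q) paste(q$variant_id, q$sample_id)
  # ptv_missense is exactly the union of ptv and missense
  expect_setequal(key(both), union(key(ptv), key(mis)))
  # domain-restricted set is contained in the unrestricted set
  expect_true(all(key(dom) %in% key(both)))
  # synonymous and nonsynonymous qualifying sets are disjoint
  expect_length(intersect(key(syn), key(both)), 0)
})

test_that("tightening the gnomAD bound never adds qualifying variants", {
  co <- tiny_cohort(seed = 41, n_cases = 400, n_controls = 500,
                    n_genes = 25, common_af_fraction = 0.3)
  vqc <- filter_variants(co$variants, co$genotypes)
  key <- function(q) paste(q$variant_id, q$sample_id)
  thresholds <- c(0.01, 0.001, 0.0001)
  sets <- lapply(thresholds, function(t) {
    m <- model_spec("m", c(PTV_CLASSES <- c("stop_gained",
                                            "frameshift_variant",
                                            "splice_acceptor_variant",
                                            "splice_donor_variant"),
                           "missense_variant"), max_gnomad_af = t)
    key(qualifying_variants(vqc$variants, vqc$genotypes, co$samples,
                            m, domains = co$domains)$qualifying)
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("coverage-pruned sites are masked only in the affected cluster", {
  samples <- bind_rows(
    tibble(sample_id = sprintf("A%02d", 1:20),
           phenotype = rep(c("case", "control"), 10), cluster = "A"),
    tibble(sample_id = sprintf("B%02d", 1:20),
           phenotype = rep(c("case", "control"), 10), cluster = "B")
  )
  v <- variant_fixture()
  g <- bind_rows(genotype_fixture(sample_id = "A01"),
                 genotype_fixture(sample_id = "B01"))
  removed <- tibble(cluster = "A", chrom = "1", pos = 100L)
  toy_model <- model_spec("toy_missense", "missense_variant",
                          max_internal_af = 0.5)
  res <- qualifying_variants(v, g, samples, toy_model,
                             removed_sites = removed)
  expect_identical(res$qualifying$sample_id, "B01")
})
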