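# Independent oracles and fixture builders shared across test files.

# Brute-force exact CMH p-value: enumerate every cell configuration
# consistent with the fixed margins, score each by its joint central
# hypergeometric probability computed directly from binomial coefficients,
# and sum the mass of all case-carrier totals whose point probability does
# not exceed the observed one (with the 1 + 1e-7 tie tolerance).
enum_cmh_p <- function(tab) {
  m1 <- tab$a + tab$b
  m2 <- tab$c + tab$d
  k <- tab$a + tab$c
  grids <- lapply(seq_len(nrow(tab)), function(i) {
    max(0, k[i] - m2[i]):min(k[i], m1[i])
  })
  cfg <- as.matrix(expand.grid(grids))
  pr <- apply(cfg, 1, function(a) {
    prod(choose(m1, a) * choose(m2, k - a) / choose(m1 + m2, k))
  })
  s <- rowSums(cfg)
  ps <- tapply(pr, s, sum)
  p_obs <- ps[[as.character(sum(tab$a))]]
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# Random stratified 2x2 table with per-stratum margins bounded by max_m.
random_strat_table <- function(n_strata, max_m = 12) {
  tibble::tibble(
    unit = "u",
    cluster = paste0("cl", seq_len(n_strata)),
    a = NA_integer_, b = NA_integer_, c = NA_integer_, d = NA_integer_
  ) |>
    dplyr::mutate(
      m1 = sample(1:max_m, n_strata, replace = TRUE),
      m2 = sample(1:max_m, n_strata, replace = TRUE),
      a = vapply(.data$m1, function(m) sample(0:m, 1), 1L),
      c = vapply(.data$m2, function(m) sample(0:m, 1), 1L),
      b = .data$m1 - .data$a,
      d = .data$m2 - .data$c
    ) |>
    dplyr::select("unit", "cluster", "a", "b", "c", "d")
}

# Small deterministic cohort fixture used across module tests.
tiny_cohort <- function(seed = 42, n_cases = 60, n_controls = 120,
                        n_genes = 12, ...) {
  simulate_cohort(sim_config(
    n_cases = n_cases, n_controls = n_controls,
    n_genes = n_genes, seed = seed, ...
  ))
}

# Hand-built manifest for targeted QC tests.
manifest_fixture <- function(n = 6) {
  tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    phenotype = rep(c("case", "control"), length.out = n),
    cluster = "cl1",
    kit = "idt",
    contamination = 0.001,
    ccds_coverage = 0.99
  )
}

# One fully passing SNV variant row; override fields to probe thresholds.
variant_fixture <- function(...) {
  v <- tibble::tibble(
    variant_id = "1:100:A:T", chrom = "1", pos = 100L, ref = "A",
    alt = "T", variant_class = "SNV", qual = 500, qd = 20,
    read_pos_rank_sum = 0, mq = 55, mq_rank_sum = 0, fs = 10,
    vqsr_tranche = "PASS", effect = "missense_variant", gene = "G1",
    transcript = "TX_G1", in_ccds_or_splice = TRUE,
    external_fail_flag = FALSE, gnomad_af_afr = 0, gnomad_af_amr = 0,
    gnomad_af_eas = 0, gnomad_af_nfe = 0, gnomad_af_sas = 0
  )
  over <- list(...)
  for (nm in names(over)) v[[nm]] <- over[[nm]]
  v
}

genotype_fixture <- function(variant_id = "1:100:A:T", sample_id = "S01",
                             gt = "0/1", dp = 40L, gq = 90L, ab = 0.5) {
  tibble::tibble(variant_id = variant_id, sample_id = sample_id, gt = gt,
                 dp = dp, gq = gq, alt_reads = as.integer(round(dp * ab)),
                 ab = ab)
}
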