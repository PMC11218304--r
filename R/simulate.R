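#' Configure a synthetic case/control rare-variant cohort
#'
#' Builds a validated simulation configuration. The simulator emulates the
#' statistical structure a collapsing burden analysis assumes: a
#' multi-cluster case/control cohort, rare variants (internal AF well below
#' 0.1%), per-gene dominant carriers drawn independently per sample,
#' optional planted case- or control-enriched genes (with optional
#' concentration of case signal inside intolerant subRVIS domains),
#' differential-coverage artifact sites, and variants planted to violate a
#' single QC threshold.
#'
#' Carriers are generated per (gene, effect-class, cluster, phenotype) as a
#' binomial count followed by uniform assignment to samples, which is
#' exactly equivalent to independent Bernoulli draws per sample — linkage
#' is negligible in the rare-variant regime. Each carrier is then assigned
#' to one of the gene's variant sites of the matching class; case carriers
#' of a planted gene fall into intolerant-domain sites (subRVIS percentile
#' below 25) with probability `domain_concentration`.
#'
#' @param n_cases,n_controls Cohort arm sizes.
#' @param clusters Data frame with columns `name`, `case_frac`,
#'   `control_frac`; each fraction column must sum to 1. Cluster
#'   case:control imbalance is the confounding the stratified test
#'   controls for.
#' @param n_genes Number of simulated genes (planted genes included).
#' @param variants_per_gene Mean number of variant sites per gene.
#' @param background_carrier_rate Probability that a sample carries a rare
#'   variant in a given gene (split across the gene's site classes).
#'   Default 0.005, matching per-gene carrier counts typical of exome
#'   collapsing cohorts.
#' @param planted_genes List of [planted_gene()] specifications.
#' @param artifact_sites List of `list(case_coverage_pct =, control_coverage_pct =)`
#'   entries; each plants one site whose fraction of samples at >= 10x
#'   depth differs between cases and controls.
#' @param qc_failure_rate Fraction of background variant sites planted to
#'   violate exactly one site-level QC threshold.
#' @param common_af_fraction Fraction of background variants given a gnomAD
#'   allele frequency >= 0.1% in exactly one population (to exercise the
#'   per-population frequency gate).
#' @param n_related_pairs Number of related sample pairs (degree 1-3) to
#'   record in the kinship table.
#' @param domain_layout Optional tibble (`gene`, `rel_start`, `rel_end`,
#'   `subrvis_percentile`) overriding the random two-domain layout; `rel_*`
#'   are fractions of the gene span.
#' @param seed Integer seed; fully determines the simulated cohort.
#' @return A `sim_config` object (validated list).
#' @seealso [simulate_cohort()], [als_cohort_config()]
#' @export
sim_config <- function(n_cases,
                       n_controls,
                       clusters = default_clusters(),
                       n_genes = 50,
                       variants_per_gene = 8,
                       background_carrier_rate = 0.005,
                       planted_genes = list(),
                       artifact_sites = list(),
                       qc_failure_rate = 0,
                       common_af_fraction = 0.05,
                       n_related_pairs = 0,
                       domain_layout = NULL,
                       seed = 1L) {
  cfg <- list(
    n_cases = n_cases, n_controls = n_controls,
    clusters = as_tibble(clusters),
    n_genes = n_genes, variants_per_gene = variants_per_gene,
    background_carrier_rate = background_carrier_rate,
    planted_genes = planted_genes,
    artifact_sites = artifact_sites,
    qc_failure_rate = qc_failure_rate,
    common_af_fraction = common_af_fraction,
    n_related_pairs = n_related_pairs,
    domain_layout = domain_layout,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_count <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 ||
        x != round(x)) {
      abort(sprintf("`%s` must be a single non-negative integer", field))
    }
  }
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
      abort(sprintf("`%s` must be a probability in [0, 1]", field))
    }
  }
  chk_count(cfg$n_cases, "n_cases")
  chk_count(cfg$n_controls, "n_controls")
  chk_count(cfg$n_genes, "n_genes")
  chk_count(cfg$n_related_pairs, "n_related_pairs")
  chk_prob(cfg$background_carrier_rate, "background_carrier_rate")
  chk_prob(cfg$qc_failure_rate, "qc_failure_rate")
  chk_prob(cfg$common_af_fraction, "common_af_fraction")
  cl <- cfg$clusters
  assert_columns(cl, c("name", "case_frac", "control_frac"), "clusters")
  if (abs(sum(cl$case_frac) - 1) > 1e-8) {
    abort("`clusters$case_frac` must sum to 1")
  }
  if (abs(sum(cl$control_frac) - 1) > 1e-8) {
    abort("`clusters$control_frac` must sum to 1")
  }
  if (any(cl$case_frac < 0) || any(cl$control_frac < 0)) {
    abort("cluster fractions must be non-negative")
  }
  for (pg in cfg$planted_genes) {
    if (!inherits(pg, "planted_gene")) {
      abort("`planted_genes` entries must be built with planted_gene()")
    }
  }
  if (anyDuplicated(vapply(cfg$planted_genes, `[[`, "", "gene"))) {
    abort("`planted_genes` gene names must be unique")
  }
  for (a in cfg$artifact_sites) {
    if (is.null(a$case_coverage_pct) || is.null(a$control_coverage_pct) ||
        a$case_coverage_pct < 0 || a$case_coverage_pct > 100 ||
        a$control_coverage_pct < 0 || a$control_coverage_pct > 100) {
      abort("`artifact_sites` entries need case_coverage_pct and control_coverage_pct in [0, 100]")
    }
  }
  invisible(cfg)
}

#' @rdname sim_config
#' @param gene Gene symbol for the planted signal.
#' @param effect_class One of `"PTV"`, `"missense"`, `"synonymous"`.
#' @param case_carrier_rate,control_carrier_rate Per-sample carrier
#'   probabilities in each arm; their odds ratio is the planted effect.
#' @param domain_concentration Probability that a case carrier's variant
#'   lands in an intolerant domain (subRVIS percentile < 25); `NA` leaves
#'   placement uniform like controls.
#' @export
planted_gene <- function(gene, effect_class = c("missense", "PTV", "synonymous"),
                         case_carrier_rate, control_carrier_rate,
                         domain_concentration = NA_real_) {
  effect_class <- match.arg(effect_class)
  for (r in c(case_carrier_rate, control_carrier_rate)) {
    if (!is.numeric(r) || r < 0 || r > 1) {
      abort("carrier rates must be probabilities in [0, 1]")
    }
  }
  if (!is.na(domain_concentration) &&
      (domain_concentration < 0 || domain_concentration > 1)) {
    abort("`domain_concentration` must be in [0, 1] (or NA)")
  }
  structure(
    list(gene = gene, effect_class = effect_class,
         case_carrier_rate = case_carrier_rate,
         control_carrier_rate = control_carrier_rate,
         domain_concentration = domain_concentration),
    class = "planted_gene"
  )
}

#' @rdname sim_config
#' @export
default_clusters <- function() {
  tibble(
    name = c("cl1", "cl2", "cl3"),
    case_frac = c(0.5, 0.3, 0.2),
    control_frac = c(0.3, 0.5, 0.2)
  )
}

#' Configuration emulating a large multi-ethnic ALS-scale cohort
#'
#' 6,970 cases and 22,524 controls spread over 12 ancestry clusters with a
#' dominant European-like cluster and uneven case:control ratios.
#'
#' @param ... Passed on to [sim_config()] (e.g. `n_genes`,
#'   `planted_genes`, `seed`).
#' @export
als_cohort_config <- function(...) {
  cl <- tibble(
    name = sprintf("cl%02d", 1:12),
    case_frac = c(0.60, 0.08, 0.06, 0.05, 0.05, 0.04,
                  0.03, 0.03, 0.02, 0.02, 0.01, 0.01),
    control_frac = c(0.50, 0.10, 0.08, 0.06, 0.05, 0.05,
                     0.04, 0.04, 0.03, 0.02, 0.02, 0.01)
  )
  sim_config(n_cases = 6970, n_controls = 22524, clusters = cl, ...)
}

# length-safe sampling: never falls back to sample(1:x) for scalar x
sample_vec <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

GNOMAD_POPS <- c("afr", "amr", "eas", "nfe", "sas")
PTV_EFFECTS <- c("stop_gained", "frameshift_variant",
                 "splice_acceptor_variant", "splice_donor_variant")
EFFECT_CLASS_MAP <- c(
  stop_gained = "PTV", frameshift_variant = "PTV",
  splice_acceptor_variant = "PTV", splice_donor_variant = "PTV",
  missense_variant = "missense", synonymous_variant = "synonymous",
  inframe_deletion = "other"
)

#' Simulate a cohort
#'
#' Generates variants, carrier genotypes, a sample manifest, kinship pairs,
#' domain annotations, sparse low-coverage records and a truth table. The
#' seed in the configuration fully determines the output.
#'
#' @param config A [sim_config()] object.
#' @return An `rc_cohort` list with tibbles `variants`, `genotypes`
#'   (carrier rows: `variant_id`, `sample_id`, `gt`, `dp`, `gq`,
#'   `alt_reads`, `ab`), `samples`, `kinship`, `domains`, `coverage`
#'   (rows only for sample-site pairs below 10x depth), and `truth`
#'   (`$genes` with planted odds ratios, `$sites` with artifact and
#'   planted-QC flags).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  samples <- sim_samples(cfg)
  genes <- sim_genes(cfg)
  domains <- sim_domains(cfg, genes)
  variants <- sim_sites(cfg, genes, domains)
  geno <- sim_carriers(cfg, genes, variants, samples, domains)
  art <- sim_artifacts(cfg, genes, variants, samples)
  variants <- art$variants
  coverage <- art$coverage
  # carriers losing depth at artifact sites get their genotype depth lowered
  if (nrow(coverage)) {
    hit <- geno |>
      inner_join(select(coverage, "variant_id", "sample_id", low_dp = "dp"),
                 by = c("variant_id", "sample_id"))
    if (nrow(hit)) {
      geno <- geno |>
        left_join(select(coverage, "variant_id", "sample_id", low_dp = "dp"),
                  by = c("variant_id", "sample_id")) |>
        mutate(
          dp = ifelse(is.na(.data$low_dp), .data$dp, .data$low_dp),
          alt_reads = ifelse(is.na(.data$low_dp), .data$alt_reads,
                             pmax(1, round(.data$dp / 2))),
          ab = .data$alt_reads / .data$dp
        ) |>
        select(-"low_dp")
    }
  }
  qc <- sim_qc_failures(cfg, genes, variants)
  variants <- qc$variants
  kinship <- sim_kinship(cfg, samples)
  truth_genes <- genes |>
    transmute(
      gene = .data$gene, planted = .data$planted,
      effect_class = .data$planted_class,
      case_carrier_rate = .data$case_rate,
      control_carrier_rate = .data$control_rate,
      planted_or = ifelse(
        .data$case_rate %in% c(0, 1) | .data$control_rate %in% c(0, 1),
        ifelse(.data$case_rate == .data$control_rate, 1, NA_real_),
        (.data$case_rate / (1 - .data$case_rate)) /
          (.data$control_rate / (1 - .data$control_rate))
      ),
      domain_concentration = .data$domain_conc
    )
  truth_sites <- variants |>
    transmute(
      variant_id = .data$variant_id, chrom = .data$chrom, pos = .data$pos,
      artifact = .data$variant_id %in% art$artifact_ids,
      qc_rule = .data$planted_qc_rule
    )
  variants$planted_qc_rule <- NULL
  structure(
    list(
      variants = variants, genotypes = geno, samples = samples,
      kinship = kinship, domains = domains, coverage = coverage,
      truth = list(genes = truth_genes, sites = truth_sites),
      config = cfg
    ),
    class = "rc_cohort"
  )
}

#' @export
print.rc_cohort <- function(x, ...) {
  cat(sprintf(
    "<rc_cohort> %d cases / %d controls in %d clusters; %d genes, %d variants, %d carrier genotypes\n",
    sum(x$samples$phenotype == "case"),
    sum(x$samples$phenotype == "control"),
    nrow(x$config$clusters), x$config$n_genes,
    nrow(x$variants), nrow(x$genotypes)
  ))
  invisible(x)
}

sim_samples <- function(cfg) {
  cl <- cfg$clusters
  case_n <- apportion(cfg$n_cases, cl$case_frac)
  ctrl_n <- apportion(cfg$n_controls, cl$control_frac)
  kits <- c("agilent65", "idt", "nimblegen_v3", "wgs")
  samples <- bind_rows(
    tibble(
      sample_id = sprintf("CASE%05d", seq_len(cfg$n_cases)),
      phenotype = "case",
      cluster = rep(cl$name, case_n)
    ),
    tibble(
      sample_id = sprintf("CTRL%05d", seq_len(cfg$n_controls)),
      phenotype = "control",
      cluster = rep(cl$name, ctrl_n)
    )
  )
  samples |>
    mutate(
      kit = sample(kits, n(), replace = TRUE),
      contamination = round(runif(n(), 0, 0.015), 4),
      ccds_coverage = round(runif(n(), 0.92, 0.995), 4)
    )
}

sim_genes <- function(cfg) {
  planted <- cfg$planted_genes
  planted_names <- vapply(planted, `[[`, "", "gene")
  n_bg <- cfg$n_genes - length(planted)
  if (n_bg < 0) abort("`n_genes` is smaller than the number of planted genes")
  planted_class <- vapply(planted, `[[`, "", "effect_class")
  case_rate <- vapply(planted, `[[`, 0, "case_carrier_rate")
  control_rate <- vapply(planted, `[[`, 0, "control_carrier_rate")
  domain_conc <- vapply(planted, `[[`, 0, "domain_concentration")
  genes <- tibble(
    gene = c(planted_names, sprintf("GENE%04d", seq_len(n_bg))),
    planted = c(rep(TRUE, length(planted)), rep(FALSE, n_bg)),
    planted_class = c(planted_class, rep(NA_character_, n_bg)),
    case_rate = c(case_rate, rep(cfg$background_carrier_rate, n_bg)),
    control_rate = c(control_rate, rep(cfg$background_carrier_rate, n_bg)),
    domain_conc = c(domain_conc, rep(NA_real_, n_bg))
  )
  genes |>
    mutate(
      transcript = paste0("TX_", .data$gene),
      chrom = as.character(((row_number() - 1L) %% 22L) + 1L),
      span_start = 1e6 + ((row_number() - 1L) %/% 22L) * 10000L,
      span_end = .data$span_start + 2999L
    )
}

sim_domains <- function(cfg, genes) {
  # two domains per gene split at 40% of the span; planted genes with a
  # domain concentration get a guaranteed intolerant first domain
  if (!nrow(genes)) {
    return(tibble(gene = character(), transcript = character(),
                  chrom = character(), start = integer(), end = integer(),
                  subrvis_percentile = double()))
  }
  rows <- purrr::pmap(genes, function(gene, planted, planted_class,
                                      case_rate, control_rate, domain_conc,
                                      transcript, chrom, span_start,
                                      span_end) {
    if (!is.null(cfg$domain_layout)) {
      custom <- cfg$domain_layout[cfg$domain_layout$gene == gene, ]
      if (nrow(custom)) {
        return(tibble(
          gene = gene, transcript = transcript, chrom = chrom,
          start = as.integer(span_start + round(custom$rel_start * 2999)),
          end = as.integer(span_start + round(custom$rel_end * 2999)),
          subrvis_percentile = custom$subrvis_percentile
        ))
      }
    }
    cut <- span_start + 1199L
    forced <- isTRUE(planted) && !is.na(domain_conc)
    perc1 <- if (forced) runif(1, 5, 20) else runif(1, 0, 100)
    perc2 <- if (forced) runif(1, 50, 95) else runif(1, 0, 100)
    tibble(
      gene = gene, transcript = transcript, chrom = chrom,
      start = as.integer(c(span_start, cut + 1L)),
      end = as.integer(c(cut, span_end)),
      subrvis_percentile = round(c(perc1, perc2), 2)
    )
  })
  bind_rows(rows)
}

BASES <- c("A", "C", "G", "T")

sim_sites <- function(cfg, genes, domains) {
  if (!nrow(genes)) {
    af0 <- stats::setNames(
      rep(list(double()), length(GNOMAD_POPS)),
      paste0("gnomad_af_", GNOMAD_POPS))
    return(tibble(
      variant_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), variant_class = character(),
      effect = character(), gene = character(), transcript = character(),
      qual = double(), qd = double(), read_pos_rank_sum = double(),
      mq = double(), mq_rank_sum = double(), fs = double(),
      vqsr_tranche = character(), in_ccds_or_splice = logical(),
      external_fail_flag = logical(), planted_qc_rule = character(),
      !!!af0
    ))
  }
  effect_pool <- c("missense_variant", "synonymous_variant", "stop_gained",
                   "frameshift_variant", "splice_acceptor_variant",
                   "splice_donor_variant", "inframe_deletion")
  effect_prob <- c(0.45, 0.30, 0.08, 0.07, 0.03, 0.03, 0.04)
  per_gene <- purrr::pmap(genes, function(gene, planted, planted_class,
                                          case_rate, control_rate,
                                          domain_conc, transcript, chrom,
                                          span_start, span_end) {
    n_sites <- max(1L, rpois(1, cfg$variants_per_gene))
    if (planted) n_sites <- max(n_sites, 8L)
    pos <- sort(sample(span_start:span_end, n_sites))
    effect <- sample(effect_pool, n_sites, replace = TRUE,
                     prob = effect_prob)
    if (planted) {
      # planted signal is allelically heterogeneous: enough sites of the
      # planted class that carriers average ~2 per site (rare variants
      # stay below the internal-AF gate), split between the intolerant
      # 40% of the span and the remainder so domain concentration has room
      exp_carriers <- case_rate * cfg$n_cases + control_rate * cfg$n_controls
      n_cls <- max(6, ceiling(exp_carriers / 2))
      n_low <- min(ceiling(n_cls / 2), 1100L)
      n_hi <- min(n_cls - n_low, 1700L)
      n_cls <- n_low + n_hi
      cls_effects <- switch(planted_class,
        PTV = sample(PTV_EFFECTS, n_cls, replace = TRUE),
        missense = rep("missense_variant", n_cls),
        synonymous = rep("synonymous_variant", n_cls)
      )
      cut <- span_start + 1199L
      lowpos <- sort(sample(span_start:cut, n_low))
      hipos <- sort(sample((cut + 1L):span_end, n_hi))
      keep <- -seq_len(min(6L, n_sites))
      rest_pos <- setdiff(pos[keep], c(lowpos, hipos))
      rest_eff <- effect[keep][match(rest_pos, pos[keep])]
      pos <- c(lowpos, hipos, rest_pos)
      effect <- c(cls_effects, rest_eff)
      o <- order(pos)
      pos <- pos[o]
      effect <- effect[o]
      n_sites <- length(pos)
    }
    dup <- duplicated(pos)
    pos <- pos[!dup]; effect <- effect[!dup]; n_sites <- length(pos)
    is_indel <- effect %in% c("frameshift_variant", "inframe_deletion")
    ref <- ifelse(is_indel,
                  paste0(sample(BASES, n_sites, replace = TRUE), "A"),
                  sample(BASES, n_sites, replace = TRUE))
    alt <- substr(ref, 1, 1)
    alt_snv <- vapply(substr(ref, 1, 1), function(b) {
      sample(setdiff(BASES, b), 1)
    }, "")
    alt[!is_indel] <- alt_snv[!is_indel]
    tibble(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      variant_class = ifelse(is_indel, "indel", "SNV"),
      effect = effect, gene = gene, transcript = transcript
    )
  })
  variants <- bind_rows(per_gene) |>
    mutate(
      variant_id = paste(.data$chrom, .data$pos, .data$ref, .data$alt,
                         sep = ":"),
      qual = round(runif(n(), 60, 1500), 1),
      qd = round(runif(n(), 8, 30), 2),
      read_pos_rank_sum = round(runif(n(), -2, 2), 3),
      mq = round(runif(n(), 50, 60), 2),
      mq_rank_sum = round(runif(n(), -3, 3), 3),
      fs = round(runif(n(), 0, 25), 3),
      vqsr_tranche = sample(
        c("PASS", "VQSRTrancheSNP90.00to99.00", "VQSRTrancheSNP99.00to99.90"),
        n(), replace = TRUE, prob = c(0.9, 0.06, 0.04)),
      in_ccds_or_splice = TRUE,
      external_fail_flag = FALSE,
      planted_qc_rule = NA_character_
    )
  # gnomAD per-population frequencies: mostly absent/tiny, with a chosen
  # fraction of background sites common in exactly one population
  n <- nrow(variants)
  af <- matrix(0, n, length(GNOMAD_POPS),
               dimnames = list(NULL, paste0("gnomad_af_", GNOMAD_POPS)))
  tiny <- runif(n) < 0.45
  af[tiny, ] <- signif(matrix(runif(sum(tiny) * ncol(af), 0, 5e-5),
                              ncol = ncol(af)), 3)
  bg_gene <- variants$gene %in% genes$gene[!genes$planted]
  common <- which(bg_gene & runif(n) < cfg$common_af_fraction)
  if (length(common)) {
    pop <- sample(ncol(af), length(common), replace = TRUE)
    af[cbind(common, pop)] <- signif(runif(length(common), 1e-3, 1e-2), 3)
  }
  bind_cols(variants, as_tibble(af)) |>
    relocate("variant_id")
}

# carriers per gene/class/cluster/phenotype: binomial count + uniform ids
sim_carriers <- function(cfg, genes, variants, samples, domains) {
  site_class <- EFFECT_CLASS_MAP[variants$effect]
  intoler <- domain_percentile_at(variants, domains) < 25
  groups <- samples |>
    mutate(idx = row_number()) |>
    group_by(.data$cluster, .data$phenotype) |>
    summarise(ids = list(.data$sample_id), .groups = "drop")
  vid_out <- vector("list", nrow(genes) * 8L)
  sid_out <- vector("list", nrow(genes) * 8L)
  oi <- 0L
  for (g in seq_len(nrow(genes))) {
    grow <- genes[g, ]
    sites_g <- which(variants$gene == grow$gene)
    if (!length(sites_g)) next
    cls_g <- site_class[sites_g]
    for (cls in c("PTV", "missense", "synonymous")) {
      cls_sites <- sites_g[cls_g == cls]
      if (!length(cls_sites)) next
      is_planted_cls <- isTRUE(grow$planted) &&
        identical(grow$planted_class, cls)
      if (is_planted_cls) {
        rate_case <- grow$case_rate
        rate_ctrl <- grow$control_rate
      } else {
        share <- length(cls_sites) / length(sites_g)
        rate_case <- rate_ctrl <- cfg$background_carrier_rate * share
      }
      if (rate_case == 0 && rate_ctrl == 0) next
      for (r in seq_len(nrow(groups))) {
        ids <- groups$ids[[r]]
        rate <- if (groups$phenotype[r] == "case") rate_case else rate_ctrl
        ncar <- rbinom(1, length(ids), rate)
        if (ncar == 0) next
        car_ids <- if (ncar == length(ids)) ids else sample_vec(ids, ncar)
        dc <- grow$domain_conc
        if (is_planted_cls && !is.na(dc) && groups$phenotype[r] == "case") {
          lowset <- cls_sites[intoler[cls_sites]]
          hiset <- cls_sites[!intoler[cls_sites]]
          pick_low <- runif(ncar) < dc
          site_idx <- integer(ncar)
          if (length(lowset)) {
            site_idx[pick_low] <- sample_vec(lowset, sum(pick_low), replace = TRUE)
          } else pick_low[] <- FALSE
          if (length(hiset)) {
            site_idx[!pick_low] <- sample_vec(hiset, sum(!pick_low), replace = TRUE)
          } else {
            site_idx[!pick_low] <- sample_vec(lowset, sum(!pick_low), replace = TRUE)
          }
        } else {
          site_idx <- sample_vec(cls_sites, ncar, replace = TRUE)
        }
        oi <- oi + 1L
        vid_out[[oi]] <- variants$variant_id[site_idx]
        sid_out[[oi]] <- car_ids
      }
    }
  }
  geno <- tibble(
    variant_id = unlist(vid_out[seq_len(oi)], use.names = FALSE) %||%
      character(),
    sample_id = unlist(sid_out[seq_len(oi)], use.names = FALSE) %||%
      character()
  ) |>
    distinct(.data$variant_id, .data$sample_id)
  n <- nrow(geno)
  dp <- sample(20:80, n, replace = TRUE)
  alt_reads <- pmax(1L, as.integer(round(dp * runif(n, 0.35, 0.65))))
  geno |>
    mutate(
      gt = "0/1", dp = dp, gq = sample(60:99, n, replace = TRUE),
      alt_reads = alt_reads, ab = alt_reads / dp
    ) |>
    arrange(.data$variant_id, .data$sample_id)
}

# subRVIS percentile of the domain containing each variant (NA if none)
domain_percentile_at <- function(variants, domains) {
  hit <- variants |>
    select("variant_id", "gene", "pos") |>
    left_join(domains, by = "gene", relationship = "many-to-many") |>
    filter(.data$pos >= .data$start, .data$pos <= .data$end) |>
    distinct(.data$variant_id, .keep_all = TRUE)
  out <- hit$subrvis_percentile[match(variants$variant_id, hit$variant_id)]
  out
}

sim_artifacts <- function(cfg, genes, variants, samples) {
  n_art <- length(cfg$artifact_sites)
  if (n_art == 0) {
    return(list(variants = variants, artifact_ids = character(),
                coverage = tibble(variant_id = character(),
                                  chrom = character(), pos = integer(),
                                  sample_id = character(),
                                  depth10 = logical(), dp = integer())))
  }
  bg_sites <- which(variants$gene %in% genes$gene[!genes$planted])
  if (length(bg_sites) < n_art) {
    abort("not enough background variant sites to place artifact sites")
  }
  art_idx <- sample_vec(bg_sites, n_art)
  cov <- vector("list", n_art)
  for (i in seq_len(n_art)) {
    spec <- cfg$artifact_sites[[i]]
    v <- variants[art_idx[i], ]
    is_case <- samples$phenotype == "case"
    p10 <- ifelse(is_case, spec$case_coverage_pct, spec$control_coverage_pct) / 100
    low <- runif(nrow(samples)) >= p10
    if (!any(low)) next
    cov[[i]] <- tibble(
      variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
      sample_id = samples$sample_id[low],
      depth10 = FALSE,
      dp = sample(3:9, sum(low), replace = TRUE)
    )
  }
  list(variants = variants,
       artifact_ids = variants$variant_id[art_idx],
       coverage = bind_rows(cov))
}

QC_FAIL_VALUES <- list(
  qual = function(v) { v$qual <- 30; v },
  qd = function(v) { v$qd <- 2; v },
  read_pos_rank_sum = function(v) { v$read_pos_rank_sum <- -5; v },
  mq = function(v) { v$mq <- 20; v },
  mq_rank_sum = function(v) { v$mq_rank_sum <- -15; v },
  fs = function(v) { v$fs <- if (v$variant_class == "SNV") 80 else 250; v },
  vqsr_tranche = function(v) { v$vqsr_tranche <- "VQSRTrancheSNP99.90to100.00"; v },
  in_ccds_or_splice = function(v) { v$in_ccds_or_splice <- FALSE; v },
  external_fail_flag = function(v) { v$external_fail_flag <- TRUE; v }
)

sim_qc_failures <- function(cfg, genes, variants) {
  if (cfg$qc_failure_rate == 0) return(list(variants = variants))
  bg <- which(variants$gene %in% genes$gene[!genes$planted])
  n_fail <- round(cfg$qc_failure_rate * length(bg))
  if (n_fail == 0) return(list(variants = variants))
  idx <- sample_vec(bg, n_fail)
  rules <- sample(names(QC_FAIL_VALUES), n_fail, replace = TRUE)
  for (j in seq_len(n_fail)) {
    variants[idx[j], ] <- QC_FAIL_VALUES[[rules[j]]](variants[idx[j], ])
    variants$planted_qc_rule[idx[j]] <- rules[j]
  }
  list(variants = variants)
}

sim_kinship <- function(cfg, samples) {
  if (cfg$n_related_pairs == 0 || nrow(samples) < 2) {
    return(tibble(id1 = character(), id2 = character(), degree = integer()))
  }
  n <- min(cfg$n_related_pairs, floor(nrow(samples) / 2))
  ids <- sample(samples$sample_id, 2L * n)
  tibble(
    id1 = ids[seq_len(n)],
    id2 = ids[n + seq_len(n)],
    degree = sample(1:3, n, replace = TRUE)
  )
}
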