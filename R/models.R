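#' Define a qualifying-variant model
#'
#' A model is the conjunction of an effect-class set, per-population gnomAD
#' and internal allele-frequency gates (both strict `< 0.001` by default),
#' dominant genotype coding (at least one alternate allele), and an
#' optional intolerant-domain restriction (variant must fall in a domain
#' with subRVIS percentile strictly below the threshold).
#'
#' @param name Model identifier (unique within a registry).
#' @param effect_classes Character vector of Sequence Ontology-style
#'   effect terms.
#' @param max_gnomad_af Strict upper bound applied to *each* gnomAD
#'   population frequency; a single population at or above the bound
#'   disqualifies the variant.
#' @param max_internal_af Strict upper bound on the cohort-internal allele
#'   frequency.
#' @param subrvis_max_percentile Domain restriction threshold (25 for the
#'   intolerant-domain models) or `NULL` for whole-gene collapsing.
#' @param genotype_mode Only `"dominant"` is supported.
#' @return A `model_spec` object.
#' @export
model_spec <- function(name, effect_classes, max_gnomad_af = 0.001,
                       max_internal_af = 0.001,
                       subrvis_max_percentile = NULL,
                       genotype_mode = "dominant") {
  if (!length(effect_classes)) abort("`effect_classes` must be non-empty")
  for (v in c(max_gnomad_af, max_internal_af)) {
    if (v <= 0 || v >= 1) abort("AF thresholds must be in (0, 1)")
  }
  if (!identical(genotype_mode, "dominant")) {
    abort("only dominant genotype coding is supported")
  }
  structure(
    list(name = name, effect_classes = effect_classes,
         max_gnomad_af = max_gnomad_af,
         max_internal_af = max_internal_af,
         subrvis_max_percentile = subrvis_max_percentile,
         genotype_mode = genotype_mode),
    class = "model_spec"
  )
}

PTV_CLASSES <- c("stop_gained", "frameshift_variant",
                 "splice_acceptor_variant", "splice_donor_variant")
MISSENSE_CLASSES <- "missense_variant"
SYNONYMOUS_CLASSES <- "synonymous_variant"

#' Built-in model registry
#'
#' The six nonsynonymous models — PTV, missense and PTV+missense, each
#' with and without the subRVIS < 25 intolerant-domain restriction — plus
#' the synonymous negative-control model (never domain-restricted).
#' PTV = stop gained, frameshift, canonical splice acceptor/donor;
#' start/stop-loss and in-frame indels are deliberately excluded (pass
#' custom [model_spec()]s through `extra` to change membership).
#'
#' @param extra Optional list of additional [model_spec()]s.
#' @return Named list of `model_spec` objects (duplicate names error).
#' @export
model_registry <- function(extra = list()) {
  base <- list(
    model_spec("ptv", PTV_CLASSES),
    model_spec("missense", MISSENSE_CLASSES),
    model_spec("ptv_missense", c(PTV_CLASSES, MISSENSE_CLASSES)),
    model_spec("ptv_domain", PTV_CLASSES, subrvis_max_percentile = 25),
    model_spec("missense_domain", MISSENSE_CLASSES,
               subrvis_max_percentile = 25),
    model_spec("ptv_missense_domain", c(PTV_CLASSES, MISSENSE_CLASSES),
               subrvis_max_percentile = 25),
    model_spec("synonymous", SYNONYMOUS_CLASSES)
  )
  models <- c(base, extra)
  names(models) <- vapply(models, `[[`, "", "name")
  if (anyDuplicated(names(models))) {
    abort(sprintf("duplicate model name(s): %s",
                  paste(unique(names(models)[duplicated(names(models))]),
                        collapse = ", ")))
  }
  models
}

#' Cohort-internal allele frequency per variant
#'
#' `AF = alternate allele count / (2 x called samples at the site)`,
#' computed on the full QC-retained cohort (cases and controls together,
#' no leave-one-out). Heterozygous genotypes contribute one alternate
#' allele, homozygous-alternate genotypes two.
#'
#' @param genotypes QC-retained carrier genotype tibble (`variant_id`,
#'   `gt`).
#' @param n_samples Number of QC-retained samples, used as the called
#'   denominator for variants without an explicit `an_called`.
#' @param variants Optional variant tibble; when it carries `an_called`
#'   (from [read_cohort()]) that per-site called allele number is used.
#' @return Tibble `variant_id`, `ac`, `an`, `internal_af`. Variants with
#'   zero called samples get `internal_af = NA` and are excluded (with a
#'   logged reason) by [qualifying_variants()].
#' @export
internal_af <- function(genotypes, n_samples, variants = NULL) {
  ac <- genotypes |>
    group_by(.data$variant_id) |>
    summarise(
      ac = sum(ifelse(.data$gt %in% c("1/1", "1|1"), 2L, 1L)),
      .groups = "drop"
    )
  if (!is.null(variants) && "an_called" %in% names(variants)) {
    ac <- ac |>
      left_join(select(variants, "variant_id", an = "an_called"),
                by = "variant_id") |>
      mutate(an = ifelse(is.na(.data$an), 2L * n_samples, .data$an))
  } else {
    ac$an <- 2L * n_samples
  }
  mutate(ac, internal_af = ifelse(.data$an == 0, NA_real_,
                                  .data$ac / .data$an))
}

#' Select qualifying variants under a model
#'
#' Applies, in order: effect-class membership, the per-population gnomAD
#' frequency gate, the internal allele-frequency gate, the per-cluster
#' coverage-harmonization site mask, and (for domain-restricted models)
#' the subRVIS intolerant-domain restriction. Inputs are assumed
#' QC-retained ([filter_variants()], [filter_samples()]).
#'
#' @param variants QC-retained variant tibble.
#' @param genotypes QC-retained carrier genotypes.
#' @param samples Analysis samples (cluster-assigned).
#' @param model A [model_spec()].
#' @param domains Domain annotation tibble (required when the model is
#'   domain-restricted).
#' @param removed_sites Per-cluster removed sites from [prune_sites()]
#'   (`cluster`, `chrom`, `pos`), or `NULL` to skip the mask.
#' @return List with `qualifying` (tibble `sample_id`, `gene`,
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `effect`, `model`) and
#'   `audit` (counts of variants dropped per gate, including the
#'   `unannotated` bin for domain models).
#' @export
qualifying_variants <- function(variants, genotypes, samples, model,
                                domains = NULL, removed_sites = NULL) {
  stopifnot(inherits(model, "model_spec"))
  af_cols <- grep("^gnomad_af_", names(variants), value = TRUE)
  audit <- c(effect = 0L, gnomad_af = 0L, internal_af = 0L,
             af_undefined = 0L, unannotated = 0L, domain = 0L)

  v <- variants
  n0 <- nrow(v)
  v <- filter(v, .data$effect %in% model$effect_classes)
  audit["effect"] <- n0 - nrow(v)

  if (length(af_cols)) {
    pass_gnomad <- rowSums(
      as.matrix(v[, af_cols]) >= model$max_gnomad_af, na.rm = TRUE
    ) == 0
    audit["gnomad_af"] <- sum(!pass_gnomad)
    v <- v[pass_gnomad, ]
  }

  iaf <- internal_af(genotypes, n_samples = nrow(samples),
                     variants = variants)
  v <- left_join(v, select(iaf, "variant_id", "internal_af"),
                 by = "variant_id")
  v$internal_af[is.na(v$internal_af)] <- 0   # no retained carriers: AF 0
  undef <- if ("an_called" %in% names(variants)) {
    v$variant_id %in% variants$variant_id[variants$an_called == 0]
  } else {
    rep(FALSE, nrow(v))
  }
  audit["af_undefined"] <- sum(undef)
  before <- nrow(v)
  v <- v[!undef & v$internal_af < model$max_internal_af, ]
  audit["internal_af"] <- before - audit[["af_undefined"]] - nrow(v)

  if (!is.null(model$subrvis_max_percentile)) {
    if (is.null(domains) || !nrow(domains)) {
      abort("domain-restricted model requires a domain annotation table")
    }
    perc <- domain_percentile_at(v, domains)
    audit["unannotated"] <- sum(is.na(perc))
    audit["domain"] <- sum(!is.na(perc) &
                             perc >= model$subrvis_max_percentile)
    v <- v[!is.na(perc) & perc < model$subrvis_max_percentile, ]
  }

  qv <- genotypes |>
    inner_join(
      select(v, "variant_id", "gene", "chrom", "pos", "ref", "alt",
             "effect"),
      by = "variant_id"
    ) |>
    inner_join(select(samples, "sample_id", "cluster"), by = "sample_id")
  if (!is.null(removed_sites) && nrow(removed_sites)) {
    qv <- anti_join(qv, removed_sites, by = c("cluster", "chrom", "pos"))
  }
  qv <- qv |>
    transmute(.data$sample_id, .data$gene, .data$variant_id, .data$chrom,
              .data$pos, .data$ref, .data$alt, .data$effect,
              model = model$name)
  list(qualifying = qv,
       audit = tibble(gate = names(audit), n_variants = as.integer(audit)))
}
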