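#' Read gene-set files
#'
#' Each file is plain text, one gene symbol per line (blank lines and
#' `#` comments ignored); the set name is the file name without
#' extension.
#'
#' @param paths Character vector of file paths, or a single directory
#'   containing `.txt` files.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.txt$", full.names = TRUE)
  }
  if (!length(paths)) abort("no gene-set files found")
  sets <- lapply(paths, function(p) {
    x <- readr::read_lines(p)
    x <- trimws(x)
    unique(x[nzchar(x) & !startsWith(x, "#")])
  })
  names(sets) <- tools::file_path_sans_ext(basename(paths))
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty)) {
    abort(sprintf("gene set(s) with no genes: %s",
                  paste(empty, collapse = ", ")))
  }
  sets
}

#' Bundled ALS gene tier lists
#'
#' Editable curation fixtures for the four association-strength tiers
#' (Definite, Moderate, Plus, Limited), shipped as plain-text files in
#' `inst/extdata/genesets/`.
#'
#' @return Named list of gene symbol vectors.
#' @export
als_gene_tiers <- function() {
  dir <- system.file("extdata", "genesets", package = "rarecollapse")
  sets <- read_gene_sets(dir)
  order <- c("als_definite", "als_moderate", "als_plus", "als_limited")
  sets[intersect(order, names(sets))]
}

#' Collapse a gene set to a per-sample carrier indicator
#'
#' @param x A [build_matrix()] gene-level result.
#' @param genes Character vector of gene symbols (genes absent from the
#'   matrix are ignored; a set with no genes present is untestable).
#' @return Named 0/1 vector over samples, or `NULL` when no set gene is
#'   present.
#' @export
collapse_gene_set <- function(x, genes) {
  stopifnot(inherits(x, "collapsing_matrix"))
  present <- intersect(genes, rownames(x$matrix))
  if (!length(present)) return(NULL)
  ind <- as.integer(colSums(x$matrix[present, , drop = FALSE]) > 0)
  names(ind) <- colnames(x$matrix)
  ind
}

#' Gene-set burden test under one model
#'
#' Builds the set-level dominant indicator (a sample is a carrier iff it
#' carries a qualifying variant in any gene of the set), stratifies by
#' cluster and applies the exact two-sided CMH test with the MH pooled
#' odds ratio.
#'
#' @param x A gene-level [build_matrix()] result for one model.
#' @param gene_sets Named list of gene symbol vectors (may overlap).
#' @param samples Analysis samples (defaults to the matrix's own).
#' @return Tibble with one row per set: carrier counts, `or_mh`, CI,
#'   `p_value`, plus `n_genes_present` and a `testable` flag.
#' @export
geneset_burden <- function(x, gene_sets, samples = NULL) {
  stopifnot(inherits(x, "collapsing_matrix"))
  samples <- samples %||% x$samples
  samples <- samples[match(colnames(x$matrix), samples$sample_id), ]
  purrr::imap(gene_sets, function(genes, set_name) {
    ind <- collapse_gene_set(x, genes)
    if (is.null(ind)) {
      return(tibble(
        unit = set_name, n_genes_present = 0L, testable = FALSE,
        n_strata = NA_integer_, case_carriers = NA_integer_,
        control_carriers = NA_integer_, or_mh = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_
      ))
    }
    strat <- samples |>
      mutate(carrier = ind[.data$sample_id]) |>
      group_by(.data$cluster) |>
      summarise(
        a = sum(.data$carrier == 1 & .data$phenotype == "case"),
        b = sum(.data$carrier == 0 & .data$phenotype == "case"),
        c = sum(.data$carrier == 1 & .data$phenotype == "control"),
        d = sum(.data$carrier == 0 & .data$phenotype == "control"),
        .groups = "drop"
      )
    fit <- exact_cmh(strat)
    tibble(
      unit = set_name,
      n_genes_present = length(intersect(genes, rownames(x$matrix))),
      testable = !fit$untestable,
      n_strata = fit$n_strata,
      case_carriers = sum(strat$a),
      control_carriers = sum(strat$c),
      or_mh = unname(fit$estimate),
      ci_low = fit$conf.int[1],
      ci_high = fit$conf.int[2],
      p_value = fit$p.value
    )
  }) |>
    bind_rows()
}

#' Tiered gene-set burden across collapsing models
#'
#' One exact CMH result per (tier, model) pair, in forest-plot order:
#' tiers in the supplied order, models within tier.
#'
#' @param matrices Named list of gene-level [build_matrix()] results, one
#'   per model (names are model names).
#' @param gene_sets Named list of tier gene sets (e.g.
#'   [als_gene_tiers()]).
#' @param models Models to include, in display order; defaults to the
#'   four burden models (PTV, PTV+missense, missense, synonymous
#'   control). Models absent from `matrices` error.
#' @param samples Analysis samples (defaults to the matrices' own).
#' @return Tibble `tier`, `model`, counts, `or_mh`, CI, `p_value`.
#' @export
run_tiers <- function(matrices, gene_sets,
                      models = c("ptv", "ptv_missense", "missense",
                                 "synonymous"),
                      samples = NULL) {
  if (!length(models)) {
    return(tibble(tier = character(), model = character(),
                  n_strata = integer(), case_carriers = integer(),
                  control_carriers = integer(), or_mh = double(),
                  ci_low = double(), ci_high = double(),
                  p_value = double()))
  }
  missing <- setdiff(models, names(matrices))
  if (length(missing)) {
    abort(sprintf("no collapsing matrix supplied for model(s): %s",
                  paste(missing, collapse = ", ")))
  }
  purrr::map(models, function(mod) {
    geneset_burden(matrices[[mod]], gene_sets, samples = samples) |>
      mutate(model = mod) |>
      rename(tier = "unit")
  }) |>
    bind_rows() |>
    mutate(tier = factor(.data$tier, levels = names(gene_sets))) |>
    arrange(.data$tier, match(.data$model, models)) |>
    mutate(tier = as.character(.data$tier)) |>
    select("tier", "model", "n_strata", "case_carriers",
           "control_carriers", "or_mh", "ci_low", "ci_high", "p_value",
           "n_genes_present", "testable")
}

#' Forest plot of tiered gene-set burden results
#'
#' @param tiers Result of [run_tiers()].
#' @return A ggplot (odds ratios with 95% CIs on a log scale).
#' @export
plot_forest <- function(tiers) {
  d <- tiers |>
    filter(.data$testable, is.finite(.data$or_mh), .data$or_mh > 0) |>
    mutate(row = paste(.data$tier, .data$model, sep = " / "))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or_mh,
                                  y = stats::reorder(.data$row,
                                                     dplyr::row_number()))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2, na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "MH pooled odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
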