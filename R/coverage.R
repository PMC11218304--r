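#' Cluster analysis policy
#'
#' Clusters with fewer than 5 participants, or fewer than 3 cases, are not
#' analyzed; sites whose case/control 10x-coverage percentages differ by
#' strictly more than 7 points are removed per cluster.
#'
#' @param min_participants,min_cases,max_coverage_diff_pct Overrides.
#' @return A `cluster_policy` list.
#' @export
cluster_policy <- function(min_participants = 5, min_cases = 3,
                           max_coverage_diff_pct = 7.0) {
  if (min_participants < 1 || min_cases < 1) {
    abort("cluster policy counts must be positive")
  }
  if (max_coverage_diff_pct <= 0 || max_coverage_diff_pct >= 100) {
    abort("`max_coverage_diff_pct` must be in (0, 100)")
  }
  structure(list(min_participants = min_participants,
                 min_cases = min_cases,
                 max_coverage_diff_pct = max_coverage_diff_pct),
            class = "cluster_policy")
}

#' Drop clusters too small to analyze
#'
#' @param samples Sample manifest tibble (QC-retained).
#' @param policy A [cluster_policy()].
#' @return List with `samples` (restricted to analysis clusters) and
#'   `clusters` (per-cluster counts, `retained` flag and drop `reason`).
#' @export
prune_clusters <- function(samples, policy = cluster_policy()) {
  assert_columns(samples, c("sample_id", "phenotype", "cluster"), "samples")
  clusters <- samples |>
    group_by(.data$cluster) |>
    summarise(
      n_cases = sum(.data$phenotype == "case"),
      n_controls = sum(.data$phenotype == "control"),
      .groups = "drop"
    ) |>
    mutate(
      n_total = .data$n_cases + .data$n_controls,
      reason = case_when(
        .data$n_total < policy$min_participants ~ "too_few_participants",
        .data$n_cases < policy$min_cases ~ "too_few_cases",
        TRUE ~ NA_character_
      ),
      retained = is.na(.data$reason)
    )
  keep <- clusters$cluster[clusters$retained]
  list(samples = filter(samples, .data$cluster %in% keep),
       clusters = clusters)
}

#' Case/control coverage harmonization: per-cluster site pruning
#'
#' Within each analysis cluster, a site is removed iff the absolute
#' difference between the percentage of cases and the percentage of
#' controls with at least 10x depth exceeds `max_coverage_diff_pct`
#' (strictly; a difference of exactly 7.0 is retained). Retained-site sets
#' may differ between clusters.
#'
#' @param coverage Low-coverage records: tibble with `chrom`, `pos`,
#'   `sample_id` and logical `depth10`. Sample-site pairs absent from the
#'   table are assumed covered at >= 10x, so both a complete per-sample
#'   table and a sparse table listing only `depth10 == FALSE` rows work.
#' @param sites Tibble of candidate sites (`chrom`, `pos`); typically
#'   `distinct(variants, chrom, pos)`.
#' @param samples Sample manifest restricted to analysis clusters.
#' @param policy A [cluster_policy()].
#' @return List with `removed` (tibble `cluster`, `chrom`, `pos`,
#'   `case_pct`, `control_pct`) and `retained` (tibble `cluster`, `chrom`,
#'   `pos`): together they partition `sites` x clusters.
#' @export
prune_sites <- function(coverage, sites, samples,
                        policy = cluster_policy()) {
  assert_columns(sites, c("chrom", "pos"), "sites")
  assert_columns(samples, c("sample_id", "phenotype", "cluster"), "samples")
  sites <- distinct(sites, .data$chrom, .data$pos)
  arm_n <- samples |>
    group_by(.data$cluster) |>
    summarise(n_cases = sum(.data$phenotype == "case"),
              n_controls = sum(.data$phenotype == "control"),
              .groups = "drop")
  if (any(arm_n$n_cases == 0 | arm_n$n_controls == 0)) {
    abort("coverage percentages undefined: a cluster has an empty arm (run prune_clusters first)")
  }
  low <- coverage |>
    filter(!.data$depth10) |>
    inner_join(select(samples, "sample_id", "phenotype", "cluster"),
               by = "sample_id") |>
    group_by(.data$cluster, .data$chrom, .data$pos, .data$phenotype) |>
    summarise(n_low = n(), .groups = "drop") |>
    pivot_wider(names_from = "phenotype", values_from = "n_low",
                values_fill = 0L)
  for (col in c("case", "control")) {
    if (!col %in% names(low)) low[[col]] <- 0L
  }
  grid <- expand_grid(cluster = arm_n$cluster, sites) |>
    left_join(low, by = c("cluster", "chrom", "pos")) |>
    mutate(across(c("case", "control"), ~ tidyr::replace_na(.x, 0L))) |>
    left_join(arm_n, by = "cluster") |>
    mutate(
      case_pct = 100 * (.data$n_cases - .data$case) / .data$n_cases,
      control_pct = 100 * (.data$n_controls - .data$control) /
        .data$n_controls,
      removed = abs(.data$case_pct - .data$control_pct) >
        policy$max_coverage_diff_pct
    )
  list(
    removed = grid |>
      filter(.data$removed) |>
      select("cluster", "chrom", "pos", "case_pct", "control_pct"),
    retained = grid |>
      filter(!.data$removed) |>
      select("cluster", "chrom", "pos")
  )
}
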