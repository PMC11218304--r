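#' Build the per-unit dominant carrier indicator matrix
#'
#' Rows are test units (genes by default), columns are analysis samples;
#' an entry is 1 iff the sample carries at least one qualifying variant
#' mapped to the unit. Units with no qualifying carriers are excluded from
#' testing but recorded.
#'
#' @param qualifying Qualifying-variant tibble from
#'   [qualifying_variants()].
#' @param samples Analysis sample tibble; its `sample_id`s define the
#'   columns.
#' @param units Unit identifiers (default: genes observed in
#'   `qualifying`). Qualifying variants mapped to a gene outside `units`
#'   are an annotation inconsistency and error.
#' @return A `collapsing_matrix`: list with the sparse 0/1 `matrix`,
#'   `samples`, the `model` name and `zero_units` (units dropped for
#'   having no carriers).
#' @export
build_matrix <- function(qualifying, samples, units = NULL) {
  assert_columns(qualifying, c("sample_id", "gene"), "qualifying variants")
  if (is.null(units)) units <- sort(unique(qualifying$gene))
  missing_units <- setdiff(unique(qualifying$gene), units)
  if (length(missing_units)) {
    abort(sprintf(
      "qualifying variants map to gene(s) absent from the unit list: %s",
      paste(head(missing_units, 5), collapse = ", ")))
  }
  unknown <- setdiff(unique(qualifying$sample_id), samples$sample_id)
  if (length(unknown)) {
    abort(sprintf("qualifying variants reference unknown sample(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  i <- match(qualifying$gene, units)
  j <- match(qualifying$sample_id, samples$sample_id)
  m <- sparseMatrix(i = i, j = j, x = 1,
                    dims = c(length(units), nrow(samples)),
                    dimnames = list(units, samples$sample_id))
  m <- drop0(m)
  m@x <- rep(1, length(m@x))
  carriers <- rowSums(m)
  zero_units <- units[carriers == 0]
  m <- m[carriers > 0, , drop = FALSE]
  structure(
    list(matrix = m, samples = samples,
         model = if (nrow(qualifying)) qualifying$model[1] else NA_character_,
         zero_units = zero_units),
    class = "collapsing_matrix"
  )
}

#' @export
print.collapsing_matrix <- function(x, ...) {
  cat(sprintf(
    "<collapsing_matrix> model %s: %d unit(s) x %d sample(s), %d carrier entries (%d zero unit(s) dropped)\n",
    x$model, nrow(x$matrix), ncol(x$matrix), length(x$matrix@x),
    length(x$zero_units)))
  invisible(x)
}

#' Cluster-stratified 2x2 carrier tables for every unit
#'
#' @param x A [build_matrix()] result.
#' @param samples Analysis samples (defaults to the matrix's own); every
#'   sample must have a cluster.
#' @return Tibble with one row per unit x cluster: `unit`, `cluster`,
#'   `a` (case carriers), `b` (case non-carriers), `c` (control
#'   carriers), `d` (control non-carriers). Zero-carrier strata are kept:
#'   margins always reproduce the cluster phenotype counts.
#' @export
stratify <- function(x, samples = NULL) {
  stopifnot(inherits(x, "collapsing_matrix"))
  samples <- samples %||% x$samples
  assert_columns(samples, c("sample_id", "phenotype", "cluster"), "samples")
  if (any(is.na(samples$cluster))) abort("every sample needs a cluster")
  m <- x$matrix
  samples <- samples[match(colnames(m), samples$sample_id), ]
  clusters <- sort(unique(samples$cluster))
  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    in_cl <- samples$cluster == cl
    is_case <- in_cl & samples$phenotype == "case"
    is_ctrl <- in_cl & samples$phenotype == "control"
    a <- as.integer(rowSums(m[, is_case, drop = FALSE]))
    c_ <- as.integer(rowSums(m[, is_ctrl, drop = FALSE]))
    out[[ci]] <- tibble(
      unit = rownames(m), cluster = cl,
      a = a, b = sum(is_case) - a,
      c = c_, d = sum(is_ctrl) - c_
    )
  }
  bind_rows(out) |> arrange(.data$unit, .data$cluster)
}

#' Export a collapsing matrix as MatrixMarket + name files
#'
#' @param x A `collapsing_matrix`.
#' @param dir Output directory.
#' @return Paths of the three files, invisibly.
#' @export
write_collapsing_matrix <- function(x, dir) {
  stopifnot(inherits(x, "collapsing_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "matrix.mtx"),
             units = file.path(dir, "units.txt"),
             samples = file.path(dir, "samples.txt"))
  Matrix::writeMM(x$matrix, paths["matrix"])
  writeLines(rownames(x$matrix), paths["units"])
  writeLines(colnames(x$matrix), paths["samples"])
  invisible(paths)
}
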