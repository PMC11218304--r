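#' Permute phenotype labels within ancestry clusters
#'
#' Labels are shuffled independently inside each cluster, so per-cluster
#' case and control counts — and therefore all stratum margins of the
#' exact CMH null — are preserved exactly.
#'
#' @param samples Analysis sample tibble.
#' @param seed Integer seed (deterministic output).
#' @return `samples` with permuted `phenotype`.
#' @export
permute_labels <- function(samples, seed) {
  assert_columns(samples, c("sample_id", "phenotype", "cluster"), "samples")
  withr::with_seed(as.integer(seed), {
    out <- samples
    for (cl in unique(samples$cluster)) {
      idx <- which(samples$cluster == cl)
      out$phenotype[idx] <- samples$phenotype[idx][sample(length(idx))]
    }
    out
  })
}

#' Permutation-based empirical null, QQ data and genomic inflation
#'
#' For each permutation the phenotype labels are shuffled within clusters
#' and every unit's exact CMH p-value is recomputed. Because margins are
#' permutation-invariant, the conditional null distribution of each
#' unit's case-carrier total is computed once and reused: a permutation
#' only moves the observed total. The expected p-value at rank r is the
#' mean over permutations of the r-th smallest p; the bands are pointwise
#' 2.5/97.5 percentiles of that order statistic. The genomic inflation
#' factor lambda is the ratio of the median observed chi-square quantile
#' to the median over all permuted p-values — an empirical expectation
#' that respects the discreteness of collapsing p-values (a uniform
#' reference would misstate inflation for rare-carrier tests).
#'
#' @param x A [build_matrix()] result.
#' @param samples Analysis samples (defaults to the matrix's own).
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @param band_percentiles Lower/upper pointwise band percentiles of the
#'   expected order statistics.
#' @return An `rc_qq` object: `data` (tibble `rank`, `p_observed`,
#'   `p_expected`, `obs_neglog10p`, `exp_neglog10p`, `band_low`,
#'   `band_high`), `lambda`, `n_permutations`, and `observed` (per-unit
#'   observed p-values).
#' @export
empirical_qq <- function(x, samples = NULL, n_permutations = 1000,
                         seed = 1L, band_percentiles = c(2.5, 97.5)) {
  stopifnot(inherits(x, "collapsing_matrix"))
  if (n_permutations < 1) abort("`n_permutations` must be >= 1")
  samples <- samples %||% x$samples
  if (nrow(x$matrix) < 1) abort("need at least one unit to calibrate")
  strat <- stratify(x, samples)
  cache <- cmh_cache(strat)
  m <- x$matrix
  samples <- samples[match(colnames(m), samples$sample_id), ]
  y <- as.numeric(samples$phenotype == "case")
  s_obs <- as.integer(as.vector(m %*% y))
  p_obs <- cache_lookup(cache, s_obs)

  cl_idx <- split(seq_len(nrow(samples)), samples$cluster)
  perm <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_permutations), function(b) {
      yp <- y
      for (idx in cl_idx) yp[idx] <- y[idx][sample(length(idx))]
      yp
    }, numeric(length(y)))
  })
  s_perm <- as.matrix(m %*% perm)
  p_perm <- matrix(cache_lookup(cache, as.integer(s_perm)),
                   nrow = nrow(s_perm))
  sorted <- apply(p_perm, 2, sort)
  if (is.null(dim(sorted))) sorted <- matrix(sorted, nrow = 1)
  exp_p <- rowMeans(sorted)
  bands <- apply(sorted, 1, quantile, probs = band_percentiles / 100,
                 names = FALSE)
  obs_sorted <- sort(p_obs)
  chi_obs <- qchisq(median(p_obs), df = 1, lower.tail = FALSE)
  chi_exp <- qchisq(median(p_perm), df = 1, lower.tail = FALSE)
  lambda <- if (chi_exp == 0) {
    # more than half of all null p-values sit at 1 (very sparse carriers):
    # the median-based inflation factor is undefined at this resolution
    warn("median permuted p-value is 1; lambda is undefined (NA)")
    NA_real_
  } else {
    chi_obs / chi_exp
  }
  data <- tibble(
    rank = seq_along(obs_sorted),
    p_observed = obs_sorted,
    p_expected = exp_p,
    obs_neglog10p = -log10(obs_sorted),
    exp_neglog10p = -log10(exp_p),
    band_low = -log10(bands[2, ]),
    band_high = -log10(bands[1, ])
  )
  structure(
    list(data = data, lambda = lambda, n_permutations = n_permutations,
         observed = tibble(unit = rownames(m), p_value = p_obs)),
    class = "rc_qq"
  )
}

# Precompute, per unit, the conditional pmf of the case-carrier total and
# the two-sided p-value of every point in its support.
cmh_cache <- function(strat) {
  units <- unique(strat$unit)
  lo <- integer(length(units))
  tables <- vector("list", length(units))
  probs <- vector("list", length(units))
  by_unit <- split(strat, factor(strat$unit, levels = units))
  for (u in seq_along(units)) {
    tab <- by_unit[[u]]
    pmf <- cmh_pmf(tab$a + tab$b, tab$c + tab$d, tab$a + tab$c)
    lo[u] <- pmf$lo
    tables[[u]] <- if (length(pmf$logp) == 1L) 1 else cmh_p_table(pmf)
    probs[[u]] <- exp(pmf$logp)
  }
  len <- lengths(tables)
  list(units = units, lo = lo, len = len,
       offset = cumsum(c(0L, len[-length(len)])),
       flat = unlist(tables), probs = probs)
}

# p-values for a units x k matrix (or vector) of case-carrier totals;
# recycles per-unit offsets down columns.
cache_lookup <- function(cache, s) {
  idx <- cache$offset + (s - cache$lo) + 1L
  cache$flat[idx]
}

#' QQ plot of observed vs permutation-expected p-values
#'
#' @param object An `rc_qq` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rc_qq
#' @export
autoplot.rc_qq <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$exp_neglog10p)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$band_low, ymax = .data$band_high),
      fill = "grey85") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$obs_neglog10p),
                        size = 0.8) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      title = sprintf("Permutation-calibrated QQ (lambda = %.3f)",
                      object$lambda)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.rc_qq <- function(x, ...) {
  cat(sprintf(
    "<rc_qq> %d units, %d permutations, lambda = %.3f\n",
    nrow(x$data), x$n_permutations, x$lambda))
  invisible(x)
}
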