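#' Exact stratified Cochran-Mantel-Haenszel machinery
#'
#' The conditional null distribution of the total case-carrier count across
#' strata, given all stratum margins, is the convolution of independent
#' central hypergeometric distributions (one per stratum). All mass is
#' accumulated in log space so that p-values far below 1e-300 of mass away
#' from the mode are still exact.
#'
#' @name cmh-internals
#' @keywords internal
NULL

# Conditional pmf of S = sum of case-carrier cells across strata.
# m1/m2/k: per-stratum case totals, control totals, carrier totals.
# Returns list(lo, logp) with support lo, lo+1, ..., lo + length(logp) - 1.
cmh_pmf <- function(m1, m2, k) {
  lo_i <- pmax(0L, k - m2)
  hi_i <- pmin(k, m1)
  logp <- 0
  for (i in seq_along(m1)) {
    if (hi_i[i] > lo_i[i]) {
      li <- dhyper(lo_i[i]:hi_i[i], m1[i], m2[i], k[i], log = TRUE)
      logp <- conv_log(logp, li)
    }
  }
  if (length(logp) > 1L) logp <- logp - logsumexp(logp)
  list(lo = sum(lo_i), logp = logp)
}

# Two-sided probability-mass p-value for every point of the support:
# p(s) = P(all outcomes with point probability <= P(S = s) * (1 + 1e-7)).
cmh_p_table <- function(pmf) {
  lp <- pmf$logp
  if (length(lp) == 1L) return(1)
  ord <- order(lp)
  cs <- cumsum(exp(lp[ord]))
  pos <- findInterval(lp + log1p(1e-7), lp[ord])
  pmin(cs[pos], 1)
}

#' Exact two-sided Cochran-Mantel-Haenszel test for stratified 2x2 tables
#'
#' Tests the null hypothesis of a common odds ratio of 1 across strata by
#' conditioning on all stratum margins: the total case-carrier count follows
#' the convolution of per-stratum central hypergeometric distributions, and
#' the two-sided p-value sums the probability of every outcome whose point
#' probability does not exceed that of the observed total (probability-mass
#' definition, with a `1 + 1e-7` tolerance factor for ties). No asymptotic
#' approximation is involved. With a single stratum this is the two-sided
#' Fisher exact test.
#'
#' @param table Data frame with one row per stratum and columns `a` (case
#'   carriers), `b` (case non-carriers), `c` (control carriers), `d`
#'   (control non-carriers). A `cluster` column, if present, labels strata.
#' @param alternative `"two.sided"` (probability-mass method, the default)
#'   or `"doubled"` (twice the smaller one-sided tail, capped at 1).
#' @return An object of class `cmh_test` with elements `p.value`,
#'   `estimate` (Mantel-Haenszel pooled odds ratio), `conf.int`
#'   (Robins-Breslow-Greenland 95% interval), `statistic` (observed total
#'   case carriers), `n_strata`, `untestable` (logical: degenerate support),
#'   and the per-stratum table.
#' @examples
#' tab <- data.frame(a = c(4, 3), b = c(96, 97), c = c(1, 0), d = c(199, 200))
#' exact_cmh(tab)
#' @seealso [mh_odds_ratio()], [cmh_scan()]
#' @export
exact_cmh <- function(table, alternative = c("two.sided", "doubled")) {
  alternative <- match.arg(alternative)
  table <- validate_strata(table)
  m1 <- table$a + table$b
  m2 <- table$c + table$d
  k <- table$a + table$c
  pmf <- cmh_pmf(m1, m2, k)
  s_obs <- sum(table$a)
  i_obs <- s_obs - pmf$lo + 1L
  untestable <- length(pmf$logp) == 1L
  if (untestable) {
    p <- 1
  } else if (alternative == "two.sided") {
    p <- cmh_p_table(pmf)[i_obs]
  } else {
    prob <- exp(pmf$logp)
    lower <- sum(prob[seq_len(i_obs)])
    upper <- sum(prob[i_obs:length(prob)])
    p <- min(1, 2 * min(lower, upper))
  }
  or <- mh_odds_ratio(table)
  structure(
    list(
      p.value = p,
      estimate = c("MH odds ratio" = or$or),
      conf.int = c(or$ci_low, or$ci_high),
      statistic = c("case carriers" = s_obs),
      n_strata = nrow(table),
      untestable = untestable,
      alternative = alternative,
      table = table,
      method = "Exact two-sided Cochran-Mantel-Haenszel test"
    ),
    class = "cmh_test"
  )
}

#' @export
print.cmh_test <- function(x, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  cat(sprintf("strata = %d, case carriers = %d, p-value = %.4g\n",
              x$n_strata, x$statistic, x$p.value))
  cat(sprintf("MH pooled OR = %.4g (95%% CI %.4g - %.4g)\n",
              x$estimate, x$conf.int[1], x$conf.int[2]))
  if (x$untestable) cat("note: degenerate support, table untestable\n")
  invisible(x)
}

validate_strata <- function(table) {
  table <- as_tibble(table)
  assert_columns(table, c("a", "b", "c", "d"), "stratified table")
  cells <- as.matrix(table[, c("a", "b", "c", "d")])
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("stratified table cells must be non-negative integer counts")
  }
  table
}

#' Mantel-Haenszel pooled odds ratio with Robins-Breslow-Greenland interval
#'
#' `or_mh = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` over strata `i` with
#' stratum totals `n_i`. The 95% confidence interval uses the
#' Robins-Breslow-Greenland variance of `log(or_mh)`. A zero denominator
#' with a positive numerator yields `Inf` with an undefined interval; a
#' 0/0 ratio is undefined (`NA`, flagged).
#'
#' @inheritParams exact_cmh
#' @return A list with `or`, `ci_low`, `ci_high`, and `defined` (logical).
#' @export
mh_odds_ratio <- function(table) {
  table <- validate_strata(table)
  n <- table$a + table$b + table$c + table$d
  keep <- n > 0
  a <- table$a[keep]; b <- table$b[keep]
  c <- table$c[keep]; d <- table$d[keep]
  n <- n[keep]
  R <- a * d / n
  S <- b * c / n
  sR <- sum(R)
  sS <- sum(S)
  if (sR == 0 && sS == 0) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                defined = FALSE))
  }
  if (sS == 0) {
    return(list(or = Inf, ci_low = NA_real_, ci_high = NA_real_,
                defined = TRUE))
  }
  or <- sR / sS
  if (sR == 0) {
    return(list(or = 0, ci_low = NA_real_, ci_high = NA_real_,
                defined = TRUE))
  }
  P <- (a + d) / n
  Q <- (b + c) / n
  v <- sum(P * R) / (2 * sR^2) +
    sum(P * S + Q * R) / (2 * sR * sS) +
    sum(Q * S) / (2 * sS^2)
  z <- qnorm(0.975)
  list(or = or,
       ci_low = exp(log(or) - z * sqrt(v)),
       ci_high = exp(log(or) + z * sqrt(v)),
       defined = TRUE)
}

#' Run the exact CMH test over every unit of a stratified-table collection
#'
#' @param strata A tibble as produced by [stratify()]: columns `unit`,
#'   `cluster`, `a`, `b`, `c`, `d`, one row per unit x stratum.
#' @param alpha Optional study-wide significance level; when supplied a
#'   `significant` column is added (`p <= alpha`, see
#'   [apply_significance()]).
#' @return A tibble with one row per unit, sorted by p-value: `unit`,
#'   `n_strata`, `case_carriers`, `control_carriers`, `or_mh`, `ci_low`,
#'   `ci_high`, `p_value` (and `significant` when `alpha` is given).
#' @export
cmh_scan <- function(strata, alpha = NULL) {
  assert_columns(strata, c("unit", "a", "b", "c", "d"), "strata")
  res <- strata |>
    group_by(.data$unit) |>
    group_modify(function(tab, key) {
      m1 <- tab$a + tab$b
      m2 <- tab$c + tab$d
      k <- tab$a + tab$c
      pmf <- cmh_pmf(m1, m2, k)
      p <- if (length(pmf$logp) == 1L) 1 else {
        cmh_p_table(pmf)[sum(tab$a) - pmf$lo + 1L]
      }
      or <- mh_odds_ratio(tab)
      tibble(
        n_strata = nrow(tab),
        case_carriers = sum(tab$a),
        control_carriers = sum(tab$c),
        or_mh = or$or,
        ci_low = or$ci_low,
        ci_high = or$ci_high,
        p_value = p
      )
    }) |>
    ungroup() |>
    arrange(.data$p_value, .data$unit)
  if (!is.null(alpha)) res <- apply_significance(res, alpha)
  res
}

#' Flag study-wide significant results
#'
#' The study-wide threshold accounts for the six nonsynonymous collapsing
#' models tested (multiplicity-adjusted alpha = 4.9e-7 by default).
#'
#' @param results Tibble with a `p_value` column (e.g. from [cmh_scan()]).
#' @param alpha Study-wide significance level.
#' @return `results` with a logical `significant` column (`p <= alpha`).
#' @export
apply_significance <- function(results, alpha = 4.9e-7) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single probability in (0, 1)")
  }
  assert_columns(results, "p_value", "results")
  mutate(results, significant = .data$p_value <= alpha)
}

#' Attainable per-unit type-I error of the discrete exact CMH test
#'
#' Because the conditional null is discrete, the realized size of the test
#' at nominal level `alpha` is `P(p(S) <= alpha)` under the null, which can
#' be far below `alpha` for sparse tables. Useful for calibration studies.
#'
#' @inheritParams cmh_scan
#' @param alpha Nominal level.
#' @return Tibble with `unit` and `attainable_alpha`.
#' @export
cmh_attainable_alpha <- function(strata, alpha = 0.05) {
  assert_columns(strata, c("unit", "a", "b", "c", "d"), "strata")
  strata |>
    group_by(.data$unit) |>
    group_modify(function(tab, key) {
      pmf <- cmh_pmf(tab$a + tab$b, tab$c + tab$d, tab$a + tab$c)
      pt <- cmh_p_table(pmf)
      tibble(attainable_alpha = sum(exp(pmf$logp)[pt <= alpha]))
    }) |>
    ungroup()
}
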