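#' One-tailed z-test for control depletion under the domain restriction
#'
#' Intolerant-domain collapsing improves on whole-gene collapsing when it
#' removes proportionally more control qualifying variants than case
#' variants. This test compares the proportion of qualifying variants that
#' are in controls between the gene-level model and the domain-restricted
#' model with a pooled two-proportion z statistic (pooled variance, no
#' continuity correction), one-tailed for the alternative that the control
#' proportion is lower under the domain restriction:
#' `p = 1 - pnorm(z)`.
#'
#' @param gene_case,gene_control Qualifying-variant counts in cases and
#'   controls under the whole-gene model.
#' @param domain_case,domain_control Counts under the domain-restricted
#'   model (each must not exceed its gene-level count).
#' @return An object of classes `rc_ztest` and `htest` with `statistic`
#'   (z), `p.value`, and the two control proportions as `estimate`.
#' @examples
#' # TARDBP-like counts: 44/31 whole-gene vs 43/15 domain-restricted
#' domain_vs_gene_ztest(44, 31, 43, 15)
#' @export
domain_vs_gene_ztest <- function(gene_case, gene_control,
                                 domain_case, domain_control) {
  counts <- c(gene_case, gene_control, domain_case, domain_control)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("qualifying-variant counts must be non-negative integers")
  }
  if (domain_case > gene_case || domain_control > gene_control) {
    abort("domain-restricted counts cannot exceed gene-level counts")
  }
  n1 <- gene_case + gene_control
  n2 <- domain_case + domain_control
  if (n1 == 0 || n2 == 0) {
    abort("both models need at least one qualifying variant")
  }
  p1 <- gene_control / n1
  p2 <- domain_control / n2
  pp <- (gene_control + domain_control) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  structure(
    list(
      statistic = c(z = z),
      p.value = pnorm(z, lower.tail = FALSE),
      estimate = c("gene control proportion" = p1,
                   "domain control proportion" = p2),
      alternative = "control proportion lower under the domain restriction",
      method = "One-tailed pooled two-proportion z-test",
      data.name = sprintf("gene %d/%d vs domain %d/%d (case/control)",
                          gene_case, gene_control,
                          domain_case, domain_control)
    ),
    class = c("rc_ztest", "htest")
  )
}
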