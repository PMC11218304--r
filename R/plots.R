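#' Gene-body map of qualifying variants in cases and controls
#'
#' Dot plot of qualifying-variant positions along a gene, cases above and
#' controls below the axis, with intolerant domains (subRVIS percentile
#' below the threshold) shaded — the per-gene view that motivates the
#' intolerant-domain restriction.
#'
#' @param qualifying Qualifying-variant tibble (one model).
#' @param gene Gene symbol to plot.
#' @param samples Sample manifest (phenotype lookup).
#' @param domains Domain annotation tibble.
#' @param subrvis_threshold Shading threshold (default 25).
#' @return A ggplot.
#' @export
plot_variant_map <- function(qualifying, gene, samples, domains,
                             subrvis_threshold = 25) {
  qv <- qualifying |>
    filter(.data$gene == !!gene) |>
    left_join(select(samples, "sample_id", "phenotype"), by = "sample_id") |>
    count(.data$pos, .data$phenotype, name = "n_carriers") |>
    mutate(y = ifelse(.data$phenotype == "case", .data$n_carriers,
                      -.data$n_carriers))
  dom <- domains |>
    filter(.data$gene == !!gene) |>
    mutate(intolerant = .data$subrvis_percentile < subrvis_threshold)
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = dom,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf, fill = .data$intolerant),
      alpha = 0.25) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "orange", `FALSE` = "steelblue"),
      name = sprintf("subRVIS < %s", subrvis_threshold)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_point(
      data = qv,
      ggplot2::aes(x = .data$pos, y = .data$y,
                   colour = .data$phenotype), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(case = "firebrick", control = "navy")) +
    ggplot2::labs(x = sprintf("%s position (bp)", gene),
                  y = "carriers (controls below, cases above)") +
    ggplot2::theme_minimal()
}
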