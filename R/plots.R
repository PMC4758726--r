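#' Plot methods
#'
#' `autoplot()` methods for the package's result objects, returning
#' ggplot2 objects the caller can theme further: the screening cascade as
#' a survivor-count funnel (log10 axis), the geNorm result as the M-value
#' profile plus the pairwise-variation series, stability rankings as a
#' per-method rank heat-strip, and the efficiency fit as the standard
#' curve with its fitted line.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name refstab-plots
NULL

#' @rdname refstab-plots
#' @exportS3Method ggplot2::autoplot
autoplot.screening_report <- function(object, ...) {
  d <- tidy(object)
  d$stage <- factor(d$stage, levels = d$stage)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.4,
                       size = 3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "survivors (log scale)",
                  title = "Reference-gene screening cascade")
}

#' @rdname refstab-plots
#' @exportS3Method ggplot2::autoplot
autoplot.genorm_result <- function(object, ...) {
  d <- object$m_values
  d$gene_id <- factor(d$gene_id, levels = rev(d$gene_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene_id,
                                  y = .data$statistic)) +
    ggplot2::geom_col(fill = "darkolivegreen") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "geNorm M value (cycles)",
                  title = paste("Most stable pair:",
                                paste(object$stable_pair, collapse = " / ")))
}

#' Plot the geNorm pairwise-variation series
#'
#' @param object A `genorm_result`.
#' @return A ggplot object: V_n/n+1 against the number of references n.
#' @export
plot_pairwise_variation <- function(object) {
  stopifnot(inherits(object, "genorm_result"))
  v <- object$v
  if (!nrow(v)) abort("no pairwise-variation series (fewer than 3 genes)")
  v$label <- sprintf("V%d/%d", v$n, v$n + 1)
  ggplot2::ggplot(v, ggplot2::aes(x = .data$label, y = .data$v)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "pairwise variation V (cycles)",
                  title = "Effect of adding references")
}

#' @rdname refstab-plots
#' @exportS3Method ggplot2::autoplot
autoplot.stability_ranking <- function(object, ...) {
  d <- object$scores
  ord <- object$aggregate |> arrange(.data$group, .data$rank)
  d$gene_id <- factor(d$gene_id, levels = rev(unique(ord$gene_id)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$gene_id,
                                  fill = .data$rank)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$rank), size = 3) +
    ggplot2::scale_fill_gradient(low = "seagreen", high = "indianred") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rank",
                  title = "Stability rank by method (1 = most stable)")
}

#' Plot a dilution standard curve
#'
#' @param series A dilution series (columns `dilution`, `ct`, optional
#'   `gene_id`).
#' @param r2_pass Passed to [fit_efficiency()].
#' @return A ggplot object: CT vs log2 dilution with the least-squares
#'   line and the fitted efficiency in the panel label.
#' @export
plot_efficiency <- function(series, r2_pass = 0.99) {
  series <- as_tibble(series)
  if (!"gene_id" %in% names(series)) series$gene_id <- "series"
  fits <- fit_efficiency(series, r2_pass = r2_pass)
  lab <- setNames(sprintf("%s: E = %.1f%%, R² = %.4f", fits$gene_id,
                          100 * fits$efficiency, fits$r_squared),
                  fits$gene_id)
  ggplot2::ggplot(series, ggplot2::aes(x = log2(.data$dilution),
                                       y = .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, color = "steelblue") +
    ggplot2::facet_wrap(~gene_id,
                        labeller = ggplot2::labeller(gene_id = lab)) +
    ggplot2::labs(x = "log2 dilution", y = "CT (cycles)",
                  title = "Primer-efficiency standard curve")
}
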