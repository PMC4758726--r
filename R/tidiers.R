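#' Tidy and glance methods
#'
#' Broom-style accessors for the package's result objects. `tidy()`
#' returns the per-gene (or per-stage) table; `glance()` a one-row
#' summary.
#'
#' @param x A `screening_report`, `stability_ranking`, `genorm_result`,
#'   `bestkeeper_result` or `normfinder_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name refstab-tidiers
NULL

#' @rdname refstab-tidiers
#' @exportS3Method generics::tidy
tidy.screening_report <- function(x, ...) {
  select(x$stages, "stage", "parameters", "n_in", "n_out")
}

#' @rdname refstab-tidiers
#' @exportS3Method generics::glance
glance.screening_report <- function(x, ...) {
  tibble(n_genes = x$stages$n_in[1],
         n_stages_applied = nrow(x$stages),
         n_candidates = nrow(x$candidates))
}

#' @rdname refstab-tidiers
#' @exportS3Method generics::tidy
tidy.stability_ranking <- function(x, ...) x$scores

#' @rdname refstab-tidiers
#' @exportS3Method generics::glance
glance.stability_ranking <- function(x, ...) {
  x$aggregate |>
    group_by(.data$group) |>
    summarise(n_genes = dplyr::n(),
              top_gene = .data$gene_id[which.min(.data$rank)],
              .groups = "drop") |>
    mutate(n_methods = length(x$methods))
}

#' @rdname refstab-tidiers
#' @exportS3Method generics::tidy
tidy.genorm_result <- function(x, ...) x$m_values

#' @rdname refstab-tidiers
#' @exportS3Method generics::glance
glance.genorm_result <- function(x, ...) {
  tibble(stable_pair = paste(x$stable_pair, collapse = "/"),
         pair_m = x$m_values$statistic[1],
         n_genes = nrow(x$m_values))
}

#' @rdname refstab-tidiers
#' @exportS3Method generics::tidy
tidy.bestkeeper_result <- function(x, ...) x$gene_stats

#' @rdname refstab-tidiers
#' @exportS3Method generics::glance
glance.bestkeeper_result <- function(x, ...) {
  tibble(n_genes = nrow(x$gene_stats), n_samples = x$gene_stats$n[1],
         best_gene = x$gene_stats$gene_id[which.min(x$gene_stats$rank)])
}

#' @rdname refstab-tidiers
#' @exportS3Method generics::tidy
tidy.normfinder_result <- function(x, ...) x$gene_stats

#' @rdname refstab-tidiers
#' @exportS3Method generics::glance
glance.normfinder_result <- function(x, ...) {
  tibble(n_genes = x$g, n_samples = x$n,
         best_gene = x$gene_stats$gene_id[which.min(x$gene_stats$rank)])
}
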