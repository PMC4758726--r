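#' BestKeeper descriptive stability analysis
#'
#' Works directly on the (replicate-collapsed) CT values. For each gene it
#' reports the arithmetic and geometric mean CT, the range, the sample SD
#' in cycles and the CV expressed as a percentage of the arithmetic mean
#' CT (CV = 100 * SD / mean). A per-sample BestKeeper index — the
#' geometric mean of all candidates' CTs — summarises the panel, and each
#' gene's Pearson correlation to the index measures how well it follows
#' the consensus. Genes are ranked by ascending SD, CV breaking ties; a
#' zero-variance gene has an undefined correlation (NA) and is ranked by
#' SD alone.
#'
#' @param ds A single-group CT dataset; CT must be positive (geometric
#'   means), and at least 3 samples are needed for a meaningful
#'   correlation.
#' @return An object of class `bestkeeper_result`: list with
#'   * `gene_stats`: tibble `gene_id`, `method`, `n`, `mean_ct`,
#'     `geo_mean_ct`, `min_ct`, `max_ct`, `statistic` (SD, cycles),
#'     `cv_pct`, `r` (Pearson r vs the index), `rank`;
#'   * `index`: tibble `sample`, `index` (per-sample geometric mean CT).
#' @examples
#' ds <- tidyr::crossing(gene_id = c("a", "b"), sample = paste0("s", 1:3))
#' ds$replicate <- 1L
#' ds$ct <- c(20, 21, 22, 22, 23, 24)
#' bestkeeper(ds)$index
#' @export
bestkeeper <- function(ds) {
  m <- ct_matrix(ds)
  g <- nrow(m); n <- ncol(m)
  if (any(m <= 0)) abort("BestKeeper needs strictly positive CT values")
  if (n < 2) abort("BestKeeper needs at least 2 samples")
  if (n < 3) warn("fewer than 3 samples: Pearson r to the index is unreliable")
  index <- exp(colMeans(log(m)))
  sds <- apply(m, 1, sd)
  means <- rowMeans(m)
  rs <- vapply(seq_len(g), function(i) {
    if (sds[i] == 0 || sd(index) == 0) NA_real_ else cor(m[i, ], index)
  }, numeric(1))
  cv <- 100 * sds / means
  gene_stats <- tibble(
    gene_id = rownames(m), method = "BestKeeper", n = n,
    mean_ct = unname(means), geo_mean_ct = unname(exp(rowMeans(log(m)))),
    min_ct = unname(apply(m, 1, min)), max_ct = unname(apply(m, 1, max)),
    statistic = unname(sds), cv_pct = unname(cv), r = rs,
    rank = rank_stat(sds, cv)
  )
  structure(list(gene_stats = gene_stats,
                 index = tibble(sample = colnames(m), index = unname(index))),
            class = "bestkeeper_result")
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  cat("BestKeeper analysis (", nrow(x$gene_stats), " genes, ",
      x$gene_stats$n[1], " samples)\n", sep = "")
  print(x$gene_stats[, c("gene_id", "statistic", "cv_pct", "r", "rank")],
        n = Inf)
  invisible(x)
}
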