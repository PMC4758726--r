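#' NormFinder model-based stability (single group)
#'
#' Fits the additive model `y_ij = alpha_i + beta_j + eps_ij` to log-scale
#' expression `y_ij = -CT_ij` (log2 quantity up to an additive constant,
#' which cancels under double centering): `alpha_i` is the gene effect,
#' `beta_j` the sample effect, and `Var(eps_ij) = sigma^2_i` the per-gene
#' instability to be estimated. Double-centred residuals
#' `r_ij = y_ij - mean_i - mean_j + mean` give the raw per-gene variances
#' `v_i = sum_j r_ij^2 / (n - 1)`, whose expectations mix the true
#' variances: `E[v_i] = sigma^2_i (g - 2)/g + sum_k sigma^2_k / g^2`.
#' Inverting that system yields the unbiased estimator
#' `sigma2_i = v_i g/(g - 2) - sum(v)/((g - 1)(g - 2))`; the reported
#' stability value is `sqrt(max(0, sigma2_i))` (the estimator can go
#' negative at small n and is clamped before the square root). Lower is
#' more stable; units are log2 cycles.
#'
#' @param ds A single-group CT dataset with at least 3 genes (the
#'   estimator is undefined at g = 2) and 2 samples.
#' @return An object of class `normfinder_result`: list with
#'   `gene_stats` (tibble `gene_id`, `method`, `v`, `sigma2`, `statistic`
#'   = stability value, `rank`), `g`, `n`.
#' @examples
#' ds <- tidyr::crossing(gene_id = c("a", "b", "c"), sample = paste0("s", 1:4))
#' ds$replicate <- 1L
#' ds$ct <- rep(c(20, 21, 22, 23), times = 3) # purely additive -> all 0
#' normfinder(ds)$gene_stats$statistic
#' @export
normfinder <- function(ds) {
  m <- ct_matrix(ds)
  g <- nrow(m); n <- ncol(m)
  if (g < 3) abort("NormFinder needs at least 3 genes")
  if (n < 2) abort("NormFinder needs at least 2 samples")
  y <- -m
  r <- y - rowMeans(y) - rep(colMeans(y), each = g) + mean(y)
  v <- rowSums(r^2) / (n - 1)
  sigma2 <- v * g / (g - 2) - sum(v) / ((g - 1) * (g - 2))
  stability <- sqrt(pmax(0, sigma2))
  gene_stats <- tibble(
    gene_id = rownames(m), method = "NormFinder",
    v = unname(v), sigma2 = unname(sigma2),
    statistic = unname(stability), rank = rank_stat(stability)
  )
  structure(list(gene_stats = gene_stats, g = g, n = n),
            class = "normfinder_result")
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat("NormFinder stability (", x$g, " genes x ", x$n, " samples)\n", sep = "")
  print(x$gene_stats[, c("gene_id", "statistic", "rank")], n = Inf)
  invisible(x)
}
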